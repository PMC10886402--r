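## Image, mask and annotation I/O plus preprocessing and augmentation.
##
## Conventions: images are H x W matrices (row = y, column = x), 0-based
## pixel coordinates with origin at the top-left, x rightwards, y downwards;
## pixel (r, c) occupies the unit square [c, c+1) x [r, r+1) and has its
## centre at (c + 0.5, r + 0.5). Masks are {0, 1} in memory and 0/255 in
## 8-bit PNG files.

#' Read / write 8-bit grayscale images and masks as PNG
#'
#' Images are stored as 8-bit grey PNG (lossless for integer 0..255 data);
#' masks with foreground 255, background 0.
#'
#' @param path file path.
#' @param image integer matrix with values in 0..255.
#' @param mask binary (0/1) matrix.
#' @return `read_image_png` an integer matrix 0..255; `read_mask_png` a 0/1
#'   integer matrix.
#' @export
read_image_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3) a <- a[, , 1]
  matrix(as.integer(round(a * 255)), nrow(a), ncol(a))
}

#' @rdname read_image_png
#' @export
write_image_png <- function(image, path) {
  stopifnot(is.matrix(image), all(image >= 0), all(image <= 255))
  png::writePNG(image / 255, path)
  invisible(path)
}

#' @rdname read_image_png
#' @export
read_mask_png <- function(path) {
  a <- read_image_png(path)
  matrix(as.integer(a > 127), nrow(a), ncol(a))
}

#' @rdname read_image_png
#' @export
write_mask_png <- function(mask, path) {
  stopifnot(is.matrix(mask), all(mask %in% c(0, 1)))
  png::writePNG(mask * 1.0, path)
  invisible(path)
}

#' Read a LabelMe-style polygon annotation file
#'
#' Parses the JSON dialect written by the LabelMe annotation tool: a `shapes`
#' array whose entries carry `label` and `points` (a list of (x, y) vertex
#' coordinates in the image frame, origin top-left), plus `imageHeight` /
#' `imageWidth`.
#'
#' @param path JSON file path.
#' @return list with `polygons` (list of lists with `label` and `points`,
#'   an n x 2 matrix of (x, y)) and `image_size` (height, width).
#' @export
read_labelme <- function(path) {
  j <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  for (key in c("imageHeight", "imageWidth"))
    if (is.null(j[[key]])) stop("annotation file missing key: ", key)
  if (is.null(j$shapes)) stop("annotation file missing key: shapes")
  polygons <- lapply(j$shapes, function(sh) {
    if (is.null(sh$points)) stop("annotation shape missing key: points")
    pts <- do.call(rbind, lapply(sh$points, function(p) {
      as.numeric(unlist(p)[1:2])
    }))
    if (is.null(pts) || nrow(pts) < 3)
      stop("polygon must have at least 3 points")
    colnames(pts) <- c("x", "y")
    list(label = sh$label %||% "", points = pts)
  })
  list(polygons = polygons,
       image_size = c(height = as.integer(j$imageHeight),
                      width = as.integer(j$imageWidth)))
}

#' Rasterize polygons to a binary mask
#'
#' A pixel is foreground iff its centre lies inside (even-odd rule) or on the
#' boundary of any polygon; overlapping polygons union. Pixel (r, c) has its
#' centre at (x = c + 0.5, y = r + 0.5) in the annotation coordinate frame.
#'
#' @param polys list of polygons: each either an n x 2 (x, y) matrix or a
#'   list with a `points` matrix (as from [read_labelme()]).
#' @param height,width output mask size in pixels.
#' @return binary (0/1) integer matrix.
#' @export
polygons_to_mask <- function(polys, height, width) {
  stopifnot(height > 0, width > 0)
  mats <- lapply(polys, function(p) {
    m <- if (is.matrix(p)) p else p$points
    storage.mode(m) <- "double"
    if (nrow(m) < 3) stop("polygon must have at least 3 points")
    m
  })
  for (m in mats) {
    if (all(m[, 1] < 0) || all(m[, 1] > width) ||
        all(m[, 2] < 0) || all(m[, 2] > height))
      warning("polygon entirely outside mask bounds contributes nothing")
  }
  cpp_poly_mask(as.integer(height), as.integer(width), mats)
}

#' Preprocessing specification
#'
#' Crop (optional) followed by scaling to a square canvas; images are
#' resampled bilinearly, masks with nearest-neighbour so they stay binary.
#'
#' @param crop_box NULL (no crop) or numeric(4) = (x0, y0, x1, y1), 0-based,
#'   x1/y1 exclusive.
#' @param output_side output side in pixels (default 512).
#' @param interpolation "bilinear" (images) or "nearest" (masks).
#' @return object of class `preprocess_spec`.
#' @export
preprocess_spec <- function(crop_box = NULL, output_side = 512L,
                            interpolation = c("bilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  stopifnot(output_side > 0)
  if (!is.null(crop_box)) {
    stopifnot(length(crop_box) == 4)
    if (crop_box[1] >= crop_box[3] || crop_box[2] >= crop_box[4])
      stop("crop_box must have positive extent")
  }
  structure(list(crop_box = crop_box, output_side = as.integer(output_side),
                 interpolation = interpolation),
            class = "preprocess_spec")
}

#' Preprocess an image or mask
#'
#' Applies the crop (if any) and scales the result to
#' `output_side x output_side`.
#'
#' @param image H x W numeric matrix.
#' @param spec a [preprocess_spec()].
#' @return output_side x output_side matrix (integer if the input was).
#' @export
preprocess <- function(image, spec) {
  stopifnot(is.matrix(image), nrow(image) > 0, ncol(image) > 0,
            inherits(spec, "preprocess_spec"))
  int_in <- is.integer(image)
  if (!is.null(spec$crop_box)) {
    cb <- spec$crop_box
    if (cb[1] < 0 || cb[2] < 0 || cb[3] > ncol(image) || cb[4] > nrow(image))
      stop("crop_box outside image bounds")
    image <- image[(cb[2] + 1):cb[4], (cb[1] + 1):cb[3], drop = FALSE]
  }
  S <- spec$output_side
  h <- nrow(image); w <- ncol(image)
  ## source coordinate of output pixel centre (area-consistent mapping)
  sy <- matrix(rep((seq_len(S) - 0.5) * h / S - 0.5, S), S, S)
  sx <- matrix(rep((seq_len(S) - 0.5) * w / S - 0.5, each = S), S, S)
  method <- if (spec$interpolation == "bilinear") 1L else 0L
  out <- cpp_remap(image * 1.0, sx, sy, method, 0)
  if (int_in && spec$interpolation == "nearest") {
    out <- matrix(as.integer(out), S, S)
  }
  out
}

#' Augmentation specification
#'
#' The augmentation family applied to image/mask training pairs: random
#' rotation, vertical flip, horizontal flip, perspective and elastic
#' deformation, each drawn independently with its own probability. The same
#' spatial transform is applied to image (bilinear) and mask
#' (nearest-neighbour, defensively re-binarized).
#'
#' @param ops character subset of `c("random_rotation", "vertical_flip",
#'   "horizontal_flip", "perspective", "elastic")`.
#' @param probs per-op probabilities in \[0, 1\] (recycled).
#' @param rotation_limit rotation drawn uniformly in +/- this many degrees.
#' @param perspective_scale corner jitter as a fraction of the side.
#' @param elastic_alpha displacement amplitude in pixels.
#' @param elastic_grid coarse control-grid size of the elastic field.
#' @param seed optional default seed used by [augment()].
#' @return object of class `augmentation_spec`.
#' @export
augmentation_spec <- function(ops = c("random_rotation", "vertical_flip",
                                      "horizontal_flip"),
                              probs = 0.5, rotation_limit = 30,
                              perspective_scale = 0.05, elastic_alpha = 10,
                              elastic_grid = 4L, seed = NULL) {
  all_ops <- c("random_rotation", "vertical_flip", "horizontal_flip",
               "perspective", "elastic")
  stopifnot(all(ops %in% all_ops), all(probs >= 0), all(probs <= 1))
  probs <- rep_len(probs, length(ops))
  names(probs) <- ops
  structure(list(ops = ops, probs = probs, rotation_limit = rotation_limit,
                 perspective_scale = perspective_scale,
                 elastic_alpha = elastic_alpha,
                 elastic_grid = as.integer(elastic_grid), seed = seed),
            class = "augmentation_spec")
}

## Solve the 3x3 homography mapping four (x, y) source points onto four
## destination points (direct linear transform, 8 unknowns).
solve_homography <- function(src, dst) {
  A <- matrix(0, 8, 8)
  b <- numeric(8)
  for (i in 1:4) {
    x <- src[i, 1]; y <- src[i, 2]; u <- dst[i, 1]; v <- dst[i, 2]
    A[2 * i - 1, ] <- c(x, y, 1, 0, 0, 0, -u * x, -u * y)
    A[2 * i, ] <- c(0, 0, 0, x, y, 1, -v * x, -v * y)
    b[2 * i - 1] <- u
    b[2 * i] <- v
  }
  h <- solve(A, b)
  matrix(c(h, 1), 3, 3, byrow = TRUE)
}

remap_pair <- function(image, mask, sx, sy) {
  img <- cpp_remap(image * 1.0, sx, sy, 1L, 0)
  mk <- cpp_remap(mask * 1.0, sx, sy, 0L, 0)
  mk <- matrix(as.integer(mk > 0.5), nrow(mk), ncol(mk))
  list(image = img, mask = mk)
}

#' Augment an image/mask pair
#'
#' Applies the spec's operations in a fixed order (flips, rotation,
#' perspective, elastic), each fired with its configured probability;
#' identical spatial transforms are applied to both members of the pair and
#' the mask stays binary.
#'
#' @param image H x W numeric matrix.
#' @param mask H x W binary matrix of the same size.
#' @param spec an [augmentation_spec()].
#' @param seed seed for the draw (defaults to `spec$seed`; `NULL` uses the
#'   current RNG state).
#' @return list with `image` and `mask`.
#' @export
augment <- function(image, mask, spec, seed = spec$seed) {
  stopifnot(inherits(spec, "augmentation_spec"))
  if (!all(dim(image) == dim(mask)))
    stop("image and mask dimensions differ")
  if (!is.null(seed)) {
    old_seed <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, globalenv()))
    set.seed(seed)
  }
  h <- nrow(image); w <- ncol(image)
  int_in <- is.integer(image)
  fire <- function(op) op %in% spec$ops && stats::runif(1) < spec$probs[[op]]

  if (fire("vertical_flip")) {          # flip up-down
    image <- image[rev(seq_len(h)), , drop = FALSE]
    mask <- mask[rev(seq_len(h)), , drop = FALSE]
  }
  if (fire("horizontal_flip")) {        # flip left-right
    image <- image[, rev(seq_len(w)), drop = FALSE]
    mask <- mask[, rev(seq_len(w)), drop = FALSE]
  }
  if (fire("random_rotation")) {
    ang <- stats::runif(1, -spec$rotation_limit, spec$rotation_limit) * pi / 180
    cx <- w / 2; cy <- h / 2
    xs <- matrix(rep(seq_len(w) - 0.5, each = h), h, w) - cx
    ys <- matrix(rep(seq_len(h) - 0.5, w), h, w) - cy
    sx <- cos(ang) * xs - sin(ang) * ys + cx - 0.5
    sy <- sin(ang) * xs + cos(ang) * ys + cy - 0.5
    p <- remap_pair(image, mask, sx, sy)
    image <- p$image; mask <- p$mask
  }
  if (fire("perspective")) {
    corners <- matrix(c(0, 0, w, 0, w, h, 0, h), 4, 2, byrow = TRUE)
    jit <- matrix(stats::runif(8, -1, 1), 4, 2) * spec$perspective_scale *
      c(w, h)[col(matrix(0, 4, 2))]
    Hm <- solve_homography(corners, corners + jit)  # dest -> src
    xs <- matrix(rep(seq_len(w) - 0.5, each = h), h, w)
    ys <- matrix(rep(seq_len(h) - 0.5, w), h, w)
    den <- Hm[3, 1] * xs + Hm[3, 2] * ys + Hm[3, 3]
    sx <- (Hm[1, 1] * xs + Hm[1, 2] * ys + Hm[1, 3]) / den - 0.5
    sy <- (Hm[2, 1] * xs + Hm[2, 2] * ys + Hm[2, 3]) / den - 0.5
    p <- remap_pair(image, mask, sx, sy)
    image <- p$image; mask <- p$mask
  }
  if (fire("elastic")) {
    g <- spec$elastic_grid
    up <- function(coarse) {
      t <- tz(matrix(as.vector(coarse), ncol = 1), 1L, g, g)
      scale <- ceiling(max(h, w) / g)
      big <- matrix(cpp_upsample_fw(t$x, 1L, g, g, as.integer(scale))[, 1],
                    g * scale, g * scale)
      big[seq_len(h), seq_len(w), drop = FALSE]
    }
    dx <- up(matrix(stats::rnorm(g * g), g, g)) * spec$elastic_alpha
    dy <- up(matrix(stats::rnorm(g * g), g, g)) * spec$elastic_alpha
    xs <- matrix(rep(seq_len(w) - 1, each = h), h, w) + dx
    ys <- matrix(rep(seq_len(h) - 1, w), h, w) + dy
    p <- remap_pair(image, mask, xs, ys)
    image <- p$image; mask <- p$mask
  }
  if (int_in && !is.integer(image))
    image <- matrix(as.integer(pmin(pmax(round(image), 0), 255)), h, w)
  list(image = image, mask = mask)
}
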