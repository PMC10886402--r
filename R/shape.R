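## Shape morphometrics of a binary pectoral-muscle mask: region geometry
## (area, convex-hull area, boundary pixels, moment ellipse, bounding box,
## minimum enclosing circle) and the 15 named shape descriptors derived from
## it.

## Welzl's algorithm (iterative, on the convex hull vertices) for the minimum
## enclosing circle of a point set. Points: n x 2 matrix (x, y).
min_enclosing_circle <- function(pts) {
  circ2 <- function(p, q) {
    c((p + q) / 2, sqrt(sum((p - q)^2)) / 2)
  }
  circ3 <- function(p, q, r) {
    ax <- p[1]; ay <- p[2]; bx <- q[1]; by <- q[2]; cx <- r[1]; cy <- r[2]
    d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
    if (abs(d) < 1e-12) {
      ## collinear: take the widest pair
      cands <- list(circ2(p, q), circ2(q, r), circ2(p, r))
      cands[[which.max(vapply(cands, `[`, 0, 3))]]
    } else {
      ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
               (cx^2 + cy^2) * (ay - by)) / d
      uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
               (cx^2 + cy^2) * (bx - ax)) / d
      c(ux, uy, sqrt((ax - ux)^2 + (ay - uy)^2))
    }
  }
  inside <- function(circle, p, tol = 1e-7) {
    sqrt(sum((p - circle[1:2])^2)) <= circle[3] + tol
  }
  n <- nrow(pts)
  if (n == 1) return(c(pts[1, ], 0))
  circle <- circ2(pts[1, ], pts[2, ])
  if (n == 2) return(circle)
  for (i in 3:n) {
    if (inside(circle, pts[i, ])) next
    circle <- circ2(pts[1, ], pts[i, ])
    for (j in seq_len(i - 1)[-1]) {
      if (inside(circle, pts[j, ])) next
      circle <- circ2(pts[i, ], pts[j, ])
      for (k in seq_len(j - 1)) {
        if (inside(circle, pts[k, ])) next
        circle <- circ3(pts[i, ], pts[j, ], pts[k, ])
      }
    }
  }
  circle
}

#' Extract region geometry from a binary mask
#'
#' Measures the largest 8-connected foreground component:
#' \itemize{
#'   \item `A`: its pixel count;
#'   \item `Ca`: pixel count of its filled convex hull (pixels whose centres
#'     lie in the hull of the component's pixel centres);
#'   \item `P`: perimeter. Default `"chain"`: polygonal chain length of the
#'     outer Moore contour (axial steps 1, diagonal steps sqrt(2)), the
#'     standard contour arc length, which is ~1 for the Heywood factor of a
#'     disk. `"pixel"`: count of foreground pixels with at least one
#'     4-neighbour background pixel (image border counts as background) —
#'     the literal boundary-pixel count, which underestimates smooth
#'     perimeters by ~10%;
#'   \item `Mal`, `Mil`: major/minor axis lengths of the ellipse with the
#'     same second central moments as the pixel set;
#'   \item `H`, `W`: tight axis-aligned bounding-box height (rows) and width
#'     (columns);
#'   \item `D`: diameter of the minimum enclosing (circumscribed) circle of
#'     the pixel centres, or, with `diameter = "centroid"`, twice the
#'     centroid-to-farthest-boundary-pixel distance;
#'   \item `centroid`: (x, y) centroid of the pixel centres.
#' }
#'
#' @param mask binary (0/1) matrix with at least one foreground pixel.
#' @param diameter `"enclosing"` (default) or `"centroid"`.
#' @param perimeter `"chain"` (default) or `"pixel"`.
#' @return list of class `region_geometry`.
#' @export
extract_geometry <- function(mask, diameter = c("enclosing", "centroid"),
                             perimeter = c("chain", "pixel")) {
  diameter <- match.arg(diameter)
  perimeter <- match.arg(perimeter)
  stopifnot(is.matrix(mask))
  m <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  if (sum(m) == 0) stop("no foreground region")
  lab <- cpp_label8(m)
  sizes <- tabulate(lab[lab > 0])
  comp <- which.max(sizes)
  m <- matrix(as.integer(lab == comp), nrow(m), ncol(m))

  idx <- which(m == 1, arr.ind = TRUE)
  r <- idx[, 1]; cc <- idx[, 2]
  A <- nrow(idx)
  H <- diff(range(r)) + 1L
  W <- diff(range(cc)) + 1L

  hgt <- nrow(m); wdt <- ncol(m)
  P <- if (perimeter == "chain") {
    cpp_chain_perimeter(m)
  } else {
    ## boundary-pixel count: foreground with a 4-neighbour background
    ## (border = background)
    pad <- matrix(0L, hgt + 2, wdt + 2)
    pad[2:(hgt + 1), 2:(wdt + 1)] <- m
    core <- pad[2:(hgt + 1), 2:(wdt + 1)]
    nb_min <- pmin(pad[1:hgt, 2:(wdt + 1)], pad[3:(hgt + 2), 2:(wdt + 1)],
                   pad[2:(hgt + 1), 1:wdt], pad[2:(hgt + 1), 3:(wdt + 2)])
    sum(core == 1L & nb_min == 0L)
  }

  ## pixel centres in (x, y)
  x <- cc - 0.5
  y <- r - 0.5
  cx <- mean(x); cy <- mean(y)
  mu20 <- mean((x - cx)^2)
  mu02 <- mean((y - cy)^2)
  mu11 <- mean((x - cx) * (y - cy))
  tr <- mu20 + mu02
  det <- mu20 * mu02 - mu11^2
  disc <- sqrt(max(tr^2 / 4 - det, 0))
  l1 <- tr / 2 + disc
  l2 <- max(tr / 2 - disc, 0)
  Mal <- 4 * sqrt(l1)
  Mil <- 4 * sqrt(l2)

  ## convex hull of pixel centres, rasterized with the package's
  ## centre-inside rule (hull vertices in the same frame as the mask)
  hull_idx <- grDevices::chull(x, y)
  hull <- cbind(x[hull_idx], y[hull_idx])
  Ca <- if (nrow(hull) < 3) A else sum(cpp_poly_mask(hgt, wdt, list(hull)))
  Ca <- max(Ca, A)

  pts <- if (nrow(hull) >= 2) hull else cbind(x, y)
  D <- if (diameter == "enclosing") {
    2 * min_enclosing_circle(pts)[3]
  } else {
    2 * sqrt(max((x - cx)^2 + (y - cy)^2))
  }

  structure(list(A = A, Ca = Ca, P = P, Mal = Mal, Mil = Mil,
                 H = as.integer(H), W = as.integer(W), D = D,
                 centroid = c(x = cx, y = cy)),
            class = "region_geometry")
}

#' The 15 shape descriptors of a muscle region
#'
#' Applies the descriptor formulas to a [extract_geometry()] result:
#' area root `Ar = sqrt(A)`, convex-area root `Co = sqrt(Ca)`, perimeter `P`,
#' moment-ellipse axes `Mal`/`Mil`, bounding box `H`/`W`, rectangle-area root
#' `Ra = sqrt(H*W)`, ellipticity `El = Mal/Mil`, circumscribed-circle
#' diameter `D`, equivalent diameter `Ed = 2*sqrt(A/pi)`, Heywood
#' circularity factor `Hcf = P/(2*sqrt(pi*A))`, aspect `As = H/W`, curvature
#' (circle-fill ratio) `Cu = 4*A/(pi*D^2)`, complexity `Cl = P^2/A`.
#'
#' @param geom a `region_geometry`.
#' @return named numeric vector of length 15 in the order Ar, Co, P, Mal,
#'   Mil, H, W, Ra, El, D, Ed, Hcf, As, Cu, Cl.
#' @export
compute_features <- function(geom) {
  stopifnot(inherits(geom, "region_geometry"))
  if (geom$Mil <= 0 || geom$W <= 0)
    stop("degenerate region: zero minor axis or width")
  with(geom, c(
    Ar = sqrt(A),
    Co = sqrt(Ca),
    P = as.numeric(P),
    Mal = Mal,
    Mil = Mil,
    H = as.numeric(H),
    W = as.numeric(W),
    Ra = sqrt(H * W),
    El = Mal / Mil,
    D = D,
    Ed = 2 * sqrt(A / pi),
    Hcf = P / (2 * sqrt(pi * A)),
    As = H / W,
    Cu = 4 * A / (pi * D^2),
    Cl = P^2 / A
  ))
}

#' Names of the 15 shape descriptors (plus live weight) used as regression
#' candidates
#' @return character vector.
#' @export
shape_feature_names <- function() {
  c("Ar", "Co", "P", "Mal", "Mil", "H", "W", "Ra", "El", "D", "Ed", "Hcf",
    "As", "Cu", "Cl")
}

#' Extract the 15 shape descriptors directly from a mask
#'
#' @inheritParams extract_geometry
#' @return named numeric vector of length 15.
#' @export
extract_features <- function(mask, diameter = c("enclosing", "centroid"),
                             perimeter = c("chain", "pixel")) {
  compute_features(extract_geometry(mask, diameter, perimeter))
}

#' Shape-feature table for a set of masks
#'
#' @param masks named list of binary masks, or a directory containing mask
#'   PNG files (basename = sample_id).
#' @return data frame with `sample_id` plus the 15 descriptor columns.
#' @export
features_table <- function(masks) {
  if (is.character(masks)) {
    paths <- list.files(masks, pattern = "\\.png$", full.names = TRUE)
    ids <- sub("\\.png$", "", basename(paths))
    masks <- lapply(paths, read_mask_png)
    names(masks) <- ids
  }
  feats <- t(vapply(masks, extract_features, numeric(15)))
  data.frame(sample_id = names(masks), feats, row.names = NULL)
}
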