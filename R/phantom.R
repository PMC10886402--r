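## Synthetic radiograph phantoms: bright body silhouette on a dark background
## with a smoother, brighter pectoral-muscle blob whose exact pixel set is the
## ground-truth mask, plus Gaussian sensor noise, and a known affine
## weight-generating model linking live weight and true muscle area to
## breast-muscle weight. Every downstream stage (segmentation, morphometrics,
## regression) is testable against these phantoms.

#' Phantom dataset configuration
#'
#' Defaults emulate the study conditions qualitatively: 512 px canvases,
#' muscle areas between 4% and 22% of the image, market-broiler live weights
#' of 1800-3200 g and an affine weight model whose outputs land around
#' 300-800 g of breast muscle. Muscle area is positively linked to live
#' weight (with jitter) so downstream feature selection faces correlated
#' candidates, as in real birds.
#'
#' @param image_side canvas side in pixels.
#' @param n_samples number of phantoms in a dataset.
#' @param muscle_area_range (min, max) muscle area as a fraction of the image
#'   area; both in (0, 1).
#' @param body_intensity,muscle_intensity_delta,background_intensity grey
#'   levels in \[0, 255\]: body silhouette level, additional brightness of the
#'   muscle region, and background level.
#' @param noise_sigma Gaussian sensor-noise standard deviation (grey levels).
#' @param weight_coeffs numeric(3) = (b0 grams, b1 dimensionless on live
#'   weight, b2 grams per pixel of true muscle area).
#' @param weight_noise_sigma standard deviation (grams) of the additive noise
#'   on breast-muscle weight.
#' @param live_weight_range (min, max) live weight in grams.
#' @param seed integer; the same config + seed reproduces a dataset bitwise.
#' @return object of class `phantom_config`.
#' @export
phantom_config <- function(image_side = 512L, n_samples = 100L,
                           muscle_area_range = c(0.04, 0.22),
                           body_intensity = 140, muscle_intensity_delta = 45,
                           background_intensity = 30, noise_sigma = 8,
                           weight_coeffs = c(60, 0.12, 0.004),
                           weight_noise_sigma = 10,
                           live_weight_range = c(1800, 3200), seed = 1L) {
  stopifnot(image_side >= 32, n_samples >= 1,
            length(muscle_area_range) == 2,
            length(weight_coeffs) == 3, length(live_weight_range) == 2,
            live_weight_range[1] < live_weight_range[2])
  if (!(muscle_area_range[1] < muscle_area_range[2]) ||
      any(muscle_area_range <= 0) || any(muscle_area_range >= 1))
    stop("muscle_area_range must satisfy 0 < min < max < 1")
  if (noise_sigma < 0 || weight_noise_sigma < 0)
    stop("noise sigmas must be non-negative")
  structure(list(image_side = as.integer(image_side),
                 n_samples = as.integer(n_samples),
                 muscle_area_range = as.numeric(muscle_area_range),
                 body_intensity = body_intensity,
                 muscle_intensity_delta = muscle_intensity_delta,
                 background_intensity = background_intensity,
                 noise_sigma = noise_sigma,
                 weight_coeffs = as.numeric(weight_coeffs),
                 weight_noise_sigma = weight_noise_sigma,
                 live_weight_range = as.numeric(live_weight_range),
                 seed = as.integer(seed)),
            class = "phantom_config")
}

## Radius profile of a perturbed ellipse: base ellipse radius at polar angle
## theta times (1 + sum of 3-5 low-frequency harmonics, total amplitude
## <= 15% of the radius) -- a smooth, star-shaped (hence connected),
## convex-ish muscle contour.
perturbed_radius <- function(theta, a, b, harm) {
  re <- a * b / sqrt((b * cos(theta))^2 + (a * sin(theta))^2)
  pert <- rep(1, length(theta))
  for (i in seq_len(nrow(harm))) {
    pert <- pert + harm[i, "amp"] * cos(harm[i, "k"] * theta + harm[i, "phase"])
  }
  re * pert
}

## Rasterize the region r <= R(theta) around (cx, cy), major axis rotated by
## psi. Returns an integer 0/1 matrix (rows = y).
rasterize_blob <- function(side, cx, cy, a, b, psi, harm) {
  xs <- matrix(rep(seq_len(side) - 0.5, each = side), side, side)  # col coord
  ys <- matrix(rep(seq_len(side) - 0.5, side), side, side)         # row coord
  dx <- xs - cx
  dy <- ys - cy
  xr <- cos(psi) * dx + sin(psi) * dy
  yr <- -sin(psi) * dx + cos(psi) * dy
  r <- sqrt(xr^2 + yr^2)
  theta <- atan2(yr, xr)
  inside <- r <= perturbed_radius(theta, a, b, harm)
  matrix(as.integer(inside), side, side)
}

#' Generate one phantom sample
#'
#' Deterministic per (config, index): the sample RNG stream is derived from
#' `config$seed` and `index`, so any sample can be regenerated independently.
#' The breast-muscle weight follows the generative relation
#' `b0 + b1 * live_weight + b2 * A + eps`, where `A` is the exact foreground
#' pixel count of the returned mask and `eps ~ N(0, weight_noise_sigma)`.
#'
#' @param config a [phantom_config()].
#' @param index sample index in 1..n_samples.
#' @return list of class `phantom_sample` with fields `image` (integer grey
#'   matrix 0..255), `mask` (0/1 integer matrix), `live_weight`,
#'   `breast_muscle_weight` (grams), `sample_id`.
#' @export
generate_phantom <- function(config, index) {
  stopifnot(inherits(config, "phantom_config"))
  index <- as.integer(index)
  if (index < 1L || index > config$n_samples)
    stop("index out of range")
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed((config$seed %% 19777L) * 100003L + index)

  side <- config$image_side
  lo <- config$live_weight_range[1]
  hi <- config$live_weight_range[2]
  live_weight <- stats::runif(1, lo, hi)
  u <- (live_weight - lo) / (hi - lo)

  ## muscle area fraction: base + slope * normalised live weight + jitter,
  ## kept off the configured range limits so discretization cannot breach them
  fr <- config$muscle_area_range
  f <- fr[1] + (fr[2] - fr[1]) * (0.15 + 0.7 * u) +
    stats::rnorm(1, 0, 0.05 * (fr[2] - fr[1]))
  f <- min(max(f, fr[1] * 1.05), fr[2] * 0.95)
  target_area <- f * side^2

  rho <- stats::runif(1, 0.55, 0.9)           # minor/major axis ratio
  a <- sqrt(target_area / (pi * rho))
  b <- rho * a
  nh <- sample(3:5, 1)
  harm <- cbind(k = sample(2:6, nh),
                amp = stats::runif(nh, 0.01, 0.15 / nh),
                phase = stats::runif(nh, 0, 2 * pi))
  psi <- stats::runif(1, -pi / 6, pi / 6)
  rmax <- a * 1.2
  cx <- side / 2 + stats::runif(1, -0.06, 0.06) * side
  cy <- side * 0.42 + stats::runif(1, -0.05, 0.05) * side
  cx <- min(max(cx, rmax + 2), side - rmax - 2)
  cy <- min(max(cy, rmax + 2), side - rmax - 2)

  mask <- rasterize_blob(side, cx, cy, a, b, psi, harm)
  ## one corrective rescale keeps the discrete area near its target
  sc <- sqrt(target_area / max(sum(mask), 1))
  if (abs(sc - 1) > 0.01) {
    a2 <- min(a * sc, (min(cx, cy, side - cx, side - cy) - 2) / 1.2)
    mask <- rasterize_blob(side, cx, cy, a2, rho * a2, psi, harm)
  }
  A <- sum(mask)

  ## body silhouette: large upright ellipse behind the muscle
  ba <- side * stats::runif(1, 0.40, 0.46)
  bb <- side * stats::runif(1, 0.33, 0.38)
  xs <- matrix(rep(seq_len(side) - 0.5, each = side), side, side)
  ys <- matrix(rep(seq_len(side) - 0.5, side), side, side)
  body <- ((xs - side / 2)^2 / bb^2 + (ys - side * 0.5)^2 / ba^2) <= 1

  img <- matrix(config$background_intensity, side, side)
  img[body] <- config$body_intensity
  img <- img + mask * config$muscle_intensity_delta
  if (config$noise_sigma > 0)
    img <- img + matrix(stats::rnorm(side^2, 0, config$noise_sigma), side, side)
  img <- matrix(as.integer(pmin(pmax(round(img), 0), 255)), side, side)

  w <- config$weight_coeffs
  bmw <- w[1] + w[2] * live_weight + w[3] * A
  if (config$weight_noise_sigma > 0)
    bmw <- bmw + stats::rnorm(1, 0, config$weight_noise_sigma)
  if (bmw <= 0) stop("degenerate config: non-positive breast-muscle weight")

  structure(list(image = img, mask = mask, live_weight = live_weight,
                 breast_muscle_weight = bmw,
                 sample_id = sprintf("phantom_%04d", index)),
            class = "phantom_sample")
}

#' Generate a phantom dataset
#'
#' Generates `n_samples` phantoms, partitions them into train/validation/test
#' splits at the 7:2:1 ratio by a seeded shuffle and (optionally) writes them
#' to disk: `images/<id>.png`, `masks/<id>.png` (8-bit PNG, mask foreground
#' 255), `manifest.csv` (sample_id, split, live_weight_g,
#' breast_muscle_weight_g) and `config.yaml`.
#'
#' @param config a [phantom_config()] with `n_samples >= 10`.
#' @param out_dir output directory, or `NULL` to keep the dataset in memory
#'   only.
#' @return list with `samples` (named by sample_id), `manifest` (data frame),
#'   `splits` (list of sample_id vectors).
#' @export
generate_dataset <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "phantom_config"))
  if (config$n_samples < 10) stop("n_samples must be at least 10")
  n <- config$n_samples
  samples <- lapply(seq_len(n), function(i) generate_phantom(config, i))
  names(samples) <- vapply(samples, `[[`, "", "sample_id")

  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)
  perm <- sample(n)
  n_train <- floor(0.7 * n)
  n_val <- floor(0.2 * n)
  split <- rep("test", n)
  split[perm[seq_len(n_train)]] <- "train"
  split[perm[n_train + seq_len(n_val)]] <- "val"

  manifest <- data.frame(
    sample_id = names(samples), split = split,
    live_weight_g = vapply(samples, `[[`, 0, "live_weight"),
    breast_muscle_weight_g = vapply(samples, `[[`, 0, "breast_muscle_weight"),
    row.names = NULL)

  if (!is.null(out_dir)) {
    for (d in file.path(out_dir, c("images", "masks"))) {
      if (!dir.exists(d) && !dir.create(d, recursive = TRUE))
        stop("cannot create output directory: ", d)
    }
    for (s in samples) {
      write_image_png(s$image,
                      file.path(out_dir, "images",
                                paste0(s$sample_id, ".png")))
      write_mask_png(s$mask,
                     file.path(out_dir, "masks", paste0(s$sample_id, ".png")))
    }
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
    yaml::write_yaml(unclass(config), file.path(out_dir, "config.yaml"))
  }

  list(samples = samples, manifest = manifest,
       splits = split(manifest$sample_id, manifest$split))
}

#' Load a phantom dataset written by [generate_dataset()]
#'
#' @param dir dataset directory containing `images/`, `masks/`,
#'   `manifest.csv`.
#' @return list with `samples`, `manifest`, `splits` as in
#'   [generate_dataset()].
#' @export
load_phantom_dataset <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  samples <- lapply(seq_len(nrow(manifest)), function(i) {
    id <- manifest$sample_id[i]
    list(image = read_image_png(file.path(dir, "images", paste0(id, ".png"))),
         mask = read_mask_png(file.path(dir, "masks", paste0(id, ".png"))),
         live_weight = manifest$live_weight_g[i],
         breast_muscle_weight = manifest$breast_muscle_weight_g[i],
         sample_id = id)
  })
  names(samples) <- manifest$sample_id
  list(samples = samples, manifest = manifest,
       splits = split(manifest$sample_id, manifest$split))
}

#' Group dataset samples by split
#'
#' Convenience accessor returning the samples of a [generate_dataset()] /
#' [load_phantom_dataset()] result grouped as `train` / `val` / `test`,
#' ready for [train_maefnet()].
#'
#' @param ds dataset list with `samples` and `manifest`.
#' @return named list of sample lists.
#' @export
dataset_splits <- function(ds) {
  lapply(c(train = "train", val = "val", test = "test"),
         function(sp) ds$samples[ds$manifest$sample_id[ds$manifest$split == sp]])
}
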