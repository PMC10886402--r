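# Shared fixtures and independent oracles, built in code.

# Small, fast phantom configuration for segmentation tests.
tiny_phantom_config <- function(n = 12L, side = 64L, seed = 3L, ...) {
  phantom_config(image_side = side, n_samples = n, seed = seed, ...)
}

# Independent point-in-polygon oracle: winding-number test plus explicit
# on-segment check, evaluated one pixel centre at a time. Deliberately a
# different algorithm (winding number) from the package rasterizer
# (even-odd crossing count).
oracle_point_in_poly <- function(px, py, poly, tol = 1e-9) {
  n <- nrow(poly)
  wn <- 0
  for (v in seq_len(n)) {
    x1 <- poly[v, 1]; y1 <- poly[v, 2]
    w <- if (v == n) 1L else v + 1L
    x2 <- poly[w, 1]; y2 <- poly[w, 2]
    # boundary check
    cross <- (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)
    len <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
    if (len > 0 && abs(cross) / len <= tol) {
      dot <- (px - x1) * (x2 - x1) + (py - y1) * (y2 - y1)
      if (dot >= -tol * len && dot <= len^2 + tol * len) return(TRUE)
    }
    if (y1 <= py) {
      if (y2 > py && cross > 0) wn <- wn + 1
    } else {
      if (y2 <= py && cross < 0) wn <- wn - 1
    }
  }
  wn != 0
}

oracle_rasterize <- function(poly_list, height, width) {
  out <- matrix(0L, height, width)
  for (r in seq_len(height)) {
    for (c in seq_len(width)) {
      px <- c - 0.5
      py <- r - 0.5
      for (poly in poly_list) {
        if (oracle_point_in_poly(px, py, poly)) {
          out[r, c] <- 1L
          break
        }
      }
    }
  }
  out
}

# Digital disk mask: pixel centres within radius r of the centre.
disk_mask <- function(side, r, cx = side / 2, cy = side / 2) {
  xs <- matrix(rep(seq_len(side) - 0.5, each = side), side, side)
  ys <- matrix(rep(seq_len(side) - 0.5, side), side, side)
  matrix(as.integer((xs - cx)^2 + (ys - cy)^2 <= r^2), side, side)
}

# Axis-aligned filled rectangle mask (h rows x w cols) on a canvas.
rect_mask <- function(side, h, w, r0 = 10L, c0 = 10L) {
  m <- matrix(0L, side, side)
  m[r0:(r0 + h - 1L), c0:(c0 + w - 1L)] <- 1L
  m
}

# Random blob mask guaranteed non-empty (for metric property tests).
random_mask <- function(side = 24L) {
  m <- matrix(as.integer(stats::runif(side * side) < stats::runif(1, 0.1, 0.6)),
              side, side)
  if (sum(m) == 0) m[sample(side^2, 3)] <- 1L
  m
}

# Random simple polygon (star-shaped around a centre: vertices at sorted
# angles), possibly extending beyond the grid. Annotation polygons are
# simple by contract, and for simple polygons the even-odd rule of the
# rasterizer and the winding rule of the oracle agree.
random_simple_polygon <- function(side) {
  nv <- sample(3:9, 1)
  cx <- stats::runif(1, 0, side)
  cy <- stats::runif(1, 0, side)
  ang <- sort(stats::runif(nv, 0, 2 * pi))
  rad <- stats::runif(nv, 0.5, 0.75 * side)
  cbind(cx + rad * cos(ang), cy + rad * sin(ang))
}

# Synthetic predictor table: target affine in live_weight and Ar, all other
# candidates pure noise decoys.
decoy_table <- function(n = 60L, noise = 0.5, seed = 42L) {
  set.seed(seed)
  tab <- as.data.frame(matrix(stats::rnorm(n * 15), n, 15))
  names(tab) <- shape_feature_names()
  tab$live_weight <- stats::runif(n, 1800, 3200)
  tab$Ar <- stats::runif(n, 100, 250)
  tab$breast_muscle_weight <- 50 + 0.15 * tab$live_weight + 2 * tab$Ar +
    stats::rnorm(n, 0, noise)
  tab
}
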