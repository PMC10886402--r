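ns <- asNamespace("maefnet")

encoder_tap_sides <- function(side) {
  enc <- build_encoder()
  t <- ns$prepare_input(matrix(runif(side^2), side, side))
  t <- enc$stem$fwd(t, "eval")
  sides <- integer(0)
  for (i in seq_along(enc$blocks)) {
    t <- enc$blocks[[i]]$fwd(t, "eval")
    if (i %in% enc$taps) sides <- c(sides, t$H)
  }
  sides
}

test_that("pruned encoder taps at strides 4, 8 and 16", {
  set.seed(1)
  expect_equal(encoder_tap_sides(160), c(40L, 20L, 10L))
  expect_equal(encoder_tap_sides(64), c(16L, 8L, 4L))
})

test_that("forward pass closes shapes and is deterministic in eval mode", {
  m <- maefnet(seed = 2)
  for (side in c(64L, 128L)) {
    img <- matrix(runif(side^2), side, side)
    out <- maefnet_forward(m, img)
    expect_equal(dim(out$logits), c(1L, side, side, 2L))
    expect_true(all(is.finite(out$logits)))
    pm <- predict_mask(m, img)
    expect_equal(dim(pm), c(side, side))
    expect_true(all(pm %in% c(0L, 1L)))
    out2 <- maefnet_forward(m, img)
    expect_identical(out$logits, out2$logits)
  }
  expect_error(maefnet_forward(m, matrix(0, 60, 60)), "divisible by 16")
})

test_that("parameter counting is exact and respects freezing", {
  conv <- ns$nn_conv(3, 16, 3)
  expect_equal(length(conv$W), 432)

  m <- maefnet(seed = 3)
  n_all <- count_parameters(m)
  expect_lte(n_all, 1.51e6)
  n_head <- length(m$head$W) + length(m$head$b)
  ns$freeze_module(m$head)
  expect_equal(count_parameters(m), n_all - n_head)
})

test_that("ARM gates channels with sigmoid weights in (0,1)", {
  set.seed(4)
  arm <- ns$nn_arm(6, 4)
  x <- ns$tz(matrix(rnorm(2 * 8 * 8 * 6), ncol = 6), 2L, 8L, 8L)
  y <- arm$fwd(x, "eval")
  expect_equal(ncol(y$x), 4)
  expect_equal(c(y$H, y$W), c(8L, 8L))
  # identity limit: force the gate towards alpha_c = 1
  xp <- arm$reduce$fwd(x, "eval")
  arm$gbn$gamma <- rep(0, 4)
  arm$gbn$beta <- rep(40, 4)
  y1 <- arm$fwd(x, "eval")
  expect_equal(y1$x, xp$x, tolerance = 1e-12)
})

test_that("CAM is a contraction with directionally structured weights", {
  set.seed(5)
  cam <- ns$nn_cam(8, 2)
  x <- ns$tz(matrix(rnorm(2 * 6 * 10 * 8), ncol = 8), 2L, 6L, 10L)
  y <- cam$fwd(x, "eval")
  expect_equal(dim(y$x), dim(x$x))
  expect_true(all(abs(y$x) <= abs(x$x) + 1e-12))
  # spatially constant input per channel and image -> constant output
  xc <- ns$tz(matrix(rep(rnorm(8), each = 6 * 10), ncol = 8), 1L, 6L, 10L)
  yc <- cam$fwd(xc, "eval")
  expect_equal(apply(yc$x, 2, function(col) max(col) - min(col)),
               rep(0, 8), tolerance = 1e-10)
})

test_that("FFM output is bounded between X' and 2X'", {
  set.seed(6)
  ffm <- ns$nn_ffm(5, 4, 6)
  x1 <- ns$tz(matrix(rnorm(2 * 8 * 8 * 5), ncol = 5), 2L, 8L, 8L)
  x2 <- ns$tz(matrix(rnorm(2 * 8 * 8 * 4), ncol = 4), 2L, 8L, 8L)
  # additive-gate limit alpha_c -> 0 recovers X'
  b_orig <- ffm$fc2$b
  ffm$fc2$b <- rep(-40, 6)
  xprime <- ffm$fwd(x1, x2, "eval")$x
  ffm$fc2$b <- b_orig
  y <- ffm$fwd(x1, x2, "eval")$x
  expect_true(all(xprime >= 0))
  expect_true(all(y >= xprime - 1e-10))
  expect_true(all(y <= 2 * xprime + 1e-10))
  x2bad <- ns$tz(x2$x, 2L, 4L, 16L)
  expect_error(ffm$fwd(x1, x2bad, "eval"), "spatial size")
})

test_that("layer backward passes match finite differences", {
  set.seed(8)
  fd_check <- function(mod, x, pname) {
    y0 <- mod$fwd(x, "train")
    R <- matrix(rnorm(length(y0$x)), nrow(y0$x))
    ns$zero_grads(mod)
    y <- mod$fwd(x, "train")
    mod$bwd(ns$tz(R, y$N, y$H, y$W))
    v <- mod[[pname]]
    worst <- 0
    for (j in sample(length(v), min(5, length(v)))) {
      e <- 1e-6
      g_an <- mod[[paste0("g_", pname)]][j]
      v[j] <- v[j] + e; mod[[pname]] <- v
      Lp <- sum(mod$fwd(x, "train")$x * R)
      v[j] <- v[j] - 2 * e; mod[[pname]] <- v
      Lm <- sum(mod$fwd(x, "train")$x * R)
      v[j] <- v[j] + e; mod[[pname]] <- v
      fd <- (Lp - Lm) / (2 * e)
      worst <- max(worst, abs(g_an - fd) / max(1e-4, abs(g_an) + abs(fd)))
    }
    worst
  }
  x <- ns$tz(matrix(rnorm(2 * 8 * 8 * 5), ncol = 5), 2L, 8L, 8L)
  expect_lt(fd_check(ns$nn_conv(5, 7, 3, stride = 2), x, "W"), 1e-5)
  expect_lt(fd_check(ns$nn_dw(5, 3), x, "W"), 1e-5)
  expect_lt(fd_check(ns$nn_bn(5), x, "gamma"), 1e-5)
})

test_that("checkpoints round-trip the full model state", {
  m <- maefnet(seed = 10)
  img <- matrix(runif(64^2), 64, 64)
  before <- maefnet_forward(m, img)$logits
  f <- withr::local_tempfile(fileext = ".rds")
  save_maefnet(m, f)
  m2 <- load_maefnet(f)
  expect_identical(maefnet_forward(m2, img)$logits, before)
})
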