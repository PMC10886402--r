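test_that("RFE recovers informative features among decoys", {
  tab <- decoy_table(n = 60, noise = 0.5)
  res <- rfe_select(tab, k = 5, seed = 7)
  expect_true(all(c("live_weight", "Ar") %in% res$selected))
  # the chosen subset scores at least as well as using everything
  all16 <- res$scores$cv_r2[res$scores$size == 16]
  expect_gte(max(res$scores$cv_r2), all16)
  # asking only for the full size returns all candidates
  res16 <- rfe_select(tab, sizes = 16, k = 5, seed = 7)
  expect_setequal(res16$selected, candidate_features())
})

test_that("RFE keeps exactly one of a duplicated informative column", {
  set.seed(12)
  n <- 50
  tab <- data.frame(f1 = runif(n), f3 = rnorm(n), f4 = rnorm(n),
                    f5 = rnorm(n))
  tab$f2 <- tab$f1
  tab$breast_muscle_weight <- 100 + 30 * tab$f1 + rnorm(n, 0, 0.05)
  res <- rfe_select(tab, features = c("f1", "f2", "f3", "f4", "f5"),
                    k = 5, seed = 3)
  expect_equal(sum(c("f1", "f2") %in% res$selected), 1)
})

test_that("constant columns are dropped with a warning", {
  tab <- decoy_table(n = 40)
  tab$El <- 1
  expect_warning(res <- rfe_select(tab, k = 5, seed = 2), "constant")
  expect_false("El" %in% res$selected)
})

test_that("the SVR near-interpolates exact linear data", {
  set.seed(5)
  n <- 50
  tab <- data.frame(live_weight = runif(n, 1800, 3200),
                    Ar = runif(n, 100, 250))
  tab$breast_muscle_weight <- 0.5 * tab$live_weight + 2 * tab$Ar
  m <- fit_weight_model(tab, c("live_weight", "Ar"),
                        svr_config(cost = 10, epsilon = 1e-3))
  pred <- predict(m, tab)
  met <- regression_metrics(tab$breast_muscle_weight, pred)
  expect_gte(met$r2, 0.999)

  # two points, one feature: with the penalty large enough that
  # regularization cannot dominate, both predictions land inside (on) the
  # epsilon tube
  t2 <- data.frame(live_weight = c(2000, 3000),
                   breast_muscle_weight = c(400, 600))
  m2 <- fit_weight_model(t2, "live_weight", svr_config(cost = 1e6))
  expect_true(all(abs(predict(m2, t2) - t2$breast_muscle_weight) <=
                    svr_config()$epsilon + 1e-6))

  # deterministic refit
  m3 <- fit_weight_model(tab, c("live_weight", "Ar"),
                         svr_config(cost = 10, epsilon = 1e-3))
  expect_identical(coef(m3), coef(m))

  tab$flat <- 5
  expect_error(fit_weight_model(tab, c("live_weight", "flat")),
               "zero-variance")
})

test_that("cross-validation partitions cleanly and reproducibly", {
  tab <- decoy_table(n = 100)
  cv <- cross_validate_weight(tab, c("live_weight", "Ar"), k = 5, seed = 11)
  expect_equal(sort(unname(table(cv$assignments))), rep(20L, 5),
               ignore_attr = TRUE)
  expect_equal(nrow(cv$folds), 5)
  cv2 <- cross_validate_weight(tab, c("live_weight", "Ar"), k = 5, seed = 11)
  expect_identical(cv$assignments, cv2$assignments)
  expect_equal(cv$folds, cv2$folds, tolerance = 1e-12)
  expect_error(cross_validate_weight(tab[1:3, ], k = 5), "exceeds")
  # RMSE >= MAE fold by fold (power-mean inequality)
  expect_true(all(cv$folds$rmse >= cv$folds$mae - 1e-12))
})

test_that("label permutation drives cross-validated R2 to zero", {
  # cohort-scale n: with 20-row test folds the small-sample negative bias
  # of out-of-sample R-squared stays inside the +/- 0.15 band
  tab <- decoy_table(n = 100, noise = 0.5)
  set.seed(31)
  r2s <- replicate(20, {
    ptab <- tab
    ptab$breast_muscle_weight <- sample(ptab$breast_muscle_weight)
    cross_validate_weight(ptab, c("live_weight", "Ar"), k = 5,
                          seed = sample.int(1e6, 1))$mean$r2
  })
  expect_lte(abs(mean(r2s)), 0.15)
})

test_that("mask-to-grams prediction is deterministic and translation-invariant", {
  cfg <- tiny_phantom_config(n = 20L, side = 96L, seed = 23L,
                             weight_noise_sigma = 0)
  ds <- generate_dataset(cfg)
  feats <- features_table(lapply(ds$samples, `[[`, "mask"))
  tab <- predictor_table(feats, ds$manifest)
  m <- fit_weight_model(tab, c("live_weight", "Ar", "H", "W"))

  s <- ds$samples[[3]]
  p1 <- predict_weight(s$mask, s$live_weight, m)
  p2 <- predict_weight(s$mask, s$live_weight, m)
  expect_identical(p1, p2)

  # translate the shape inside the frame: all descriptors are
  # translation-invariant, so the prediction must not move
  idx <- which(s$mask == 1, arr.ind = TRUE)
  shift <- matrix(0L, nrow(s$mask), ncol(s$mask))
  shift[cbind(idx[, 1] - min(idx[, 1]) + 2L,
              idx[, 2] - min(idx[, 2]) + 2L)] <- 1L
  expect_equal(predict_weight(shift, s$live_weight, m), p1,
               tolerance = 1e-10)

  expect_error(predict_weight(matrix(0L, 10, 10), 2000, m), "no foreground")
  expect_error(predict_weight(s$mask, NULL, m), "live weight")
})
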