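test_that("cross-entropy matches closed forms", {
  p <- cbind(c(1, 1, 1), c(0, 0, 0))
  expect_equal(cross_entropy_loss(p, c(0, 0, 0)), 0)
  u <- matrix(0.5, 4, 2)
  expect_equal(cross_entropy_loss(u, c(0, 1, 0, 1)), log(2))
  expect_equal(cross_entropy_loss(matrix(c(0.25, 0.75), 1), 0), -log(0.25))
  # zero probability at the true class is clamped, not NaN
  expect_true(is.finite(cross_entropy_loss(cbind(0, 1), 0)))
  expect_error(cross_entropy_loss(u, c(0, 1, 2, 0)), "class indices")
})

test_that("dice loss matches closed forms", {
  a <- rect_mask(30, 10, 10)
  expect_equal(dice_loss(a, a), 0)
  b <- rect_mask(30, 5, 5, r0 = 22L, c0 = 22L)
  expect_equal(dice_loss(a, b), 1)
  m1 <- matrix(0L, 20, 20); m1[1:10, 1:10] <- 1L   # 100 px
  m2 <- matrix(0L, 20, 20); m2[6:15, 1:10] <- 1L   # 100 px, overlap 50
  expect_equal(dice_loss(m1, m2), 0.5)
  z <- matrix(0L, 5, 5)
  expect_equal(dice_loss(z, z), 0)
  expect_error(dice_loss(m1, matrix(0L, 5, 5)), "shapes differ")
})

test_that("confusion counts tally pixels per class", {
  truth <- rect_mask(20, 10, 10)   # 100 fg / 300 bg
  cc <- confusion_counts(truth, truth)
  expect_equal(cc, list(TP = 100L, FP = 0L, FN = 0L, TN = 300L))
  cc2 <- confusion_counts(matrix(0L, 20, 20), truth)
  expect_equal(cc2$FN, 100)
  expect_equal(cc2$TP, 0)
  allfg <- matrix(1L, 10, 10)
  cc3 <- confusion_counts(1L - allfg, allfg)
  expect_equal(cc3$TP, 0)
  expect_equal(cc3$FN, 100)
  expect_error(confusion_counts(matrix(2L, 2, 2), matrix(1L, 2, 2)),
               "binary")
})

test_that("segmentation metrics follow their defining ratios", {
  m <- seg_metrics(list(TP = 90, FP = 10, FN = 10))
  expect_equal(m$pre, 90)
  expect_equal(m$rec, 90)
  expect_equal(m$iou, 100 * 90 / 110, tolerance = 1e-10)
  expect_equal(round(m$iou, 2), 81.82)
  expect_equal(m$dsc, 90)
  expect_equal(seg_metrics(list(TP = 50, FP = 0, FN = 0)),
               list(pre = 100, rec = 100, iou = 100, dsc = 100))
  expect_equal(seg_metrics(list(TP = 0, FP = 3, FN = 2)),
               list(pre = 0, rec = 0, iou = 0, dsc = 0))
  expect_equal(seg_metrics(list(TP = 0, FP = 0, FN = 0)),
               list(pre = 100, rec = 100, iou = 100, dsc = 100))
})

test_that("DSC and IoU satisfy their algebraic identity on random masks", {
  set.seed(33)
  for (i in 1:100) {
    pred <- random_mask()
    truth <- random_mask()
    sm <- seg_metrics(confusion_counts(pred, truth))
    iou <- sm$iou / 100
    expect_equal(sm$dsc / 100, 2 * iou / (1 + iou), tolerance = 1e-12)
    expect_gte(sm$iou, 0)
    expect_lte(sm$dsc, 100)
    # dice loss complements DSC on the same pair
    expect_equal(dice_loss(pred, truth), 1 - sm$dsc / 100, tolerance = 1e-12)
  }
})

test_that("regression metrics match closed forms", {
  m <- regression_metrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(m, list(r2 = 1, rmse = 0, mae = 0, mre = 0))
  m2 <- regression_metrics(c(100, 200), c(110, 190))
  expect_equal(m2$rmse, 10)
  expect_equal(m2$mae, 10)
  expect_equal(m2$mre, 7.5)
  y <- c(5, 7, 9, 11)
  m3 <- regression_metrics(y, rep(mean(y), 4))
  expect_equal(m3$r2, 0)
  expect_warning(m4 <- regression_metrics(c(0, 1), c(1, 1)), "MRE")
  expect_true(is.na(m4$mre))
  expect_false(is.na(m4$rmse))
})
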