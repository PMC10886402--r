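make_tiny_data <- function(n = 8L, side = 64L, seed = 3L) {
  ds <- generate_dataset(tiny_phantom_config(n = max(n, 10L), side = side,
                                             seed = seed))
  samples <- unname(ds$samples)[seq_len(n)]
  list(train = samples, val = samples)
}

test_that("one epoch of SGD reduces the training cross-entropy", {
  data <- make_tiny_data(n = 4L, side = 64L)
  m <- maefnet(seed = 5)
  bt <- maefnet:::batch_tensors(data$train, 3L)
  ce_of <- function(model) {
    lg <- maefnet:::maefnet_fwd(model, bt$t, "eval")
    cross_entropy_loss(maefnet:::softmax_rows(lg$x), bt$labels)
  }
  ce0 <- ce_of(m)
  r <- train_maefnet(m, data, train_config(epochs = 1, batch_size = 4,
                                           seed = 2))
  expect_lt(ce_of(r$model), ce0)
  expect_equal(nrow(r$history), 1)
  expect_true(is.finite(r$history$train_ce_loss))
  expect_gte(r$history$val_dice_loss, 0)
  expect_lte(r$history$val_dice_loss, 1)
})

test_that("training histories are exactly reproducible under a fixed seed", {
  data <- make_tiny_data(n = 8L, side = 64L)
  r1 <- train_maefnet(maefnet(seed = 9),
                      data, train_config(epochs = 2, seed = 4))
  r2 <- train_maefnet(maefnet(seed = 9),
                      data, train_config(epochs = 2, seed = 4))
  expect_identical(r1$history, r2$history)
  img <- data$train[[1]]$image
  expect_identical(predict_mask(r1$model, img), predict_mask(r2$model, img))
})

test_that("the network overfits a handful of phantoms", {
  # 8 phantoms at 128 px, 50 epochs, augmentation off: training-set IoU
  # must exceed 90% (learning sanity at the published hyperparameters)
  data <- make_tiny_data(n = 8L, side = 128L, seed = 3L)
  m <- maefnet(seed = 7)
  r <- train_maefnet(m, data, train_config(epochs = 50, seed = 5))
  ev <- evaluate_model(r$model, data$train)
  expect_gte(ev$micro$iou, 90)
  # the DSC/IoU identity holds for the aggregate too
  iou <- ev$micro$iou / 100
  expect_equal(ev$micro$dsc / 100, 2 * iou / (1 + iou), tolerance = 1e-10)
})

test_that("degenerate splits are rejected", {
  data <- make_tiny_data(n = 4L, side = 64L)
  expect_error(train_maefnet(maefnet(seed = 1),
                             list(train = data$train, val = list()),
                             train_config(epochs = 1)),
               "non-empty")
})
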