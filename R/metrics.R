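## Segmentation losses and evaluation metrics.

#' Cross-entropy loss
#'
#' Mean negative log-likelihood over pixels:
#' \eqn{-\frac{1}{N}\sum_i \sum_c y_{i,c} \log p_{i,c}} in nats, where N is
#' the number of pixels (times batch). Probabilities are clamped at 1e-12
#' before the logarithm so a zero probability at the true class yields a
#' large finite loss rather than NaN.
#'
#' @param probs numeric matrix, one row per pixel, one column per class;
#'   rows must sum to 1 (within tolerance).
#' @param labels integer vector of 0-based class indices, one per pixel.
#' @return scalar loss in nats.
#' @export
cross_entropy_loss <- function(probs, labels) {
  stopifnot(is.matrix(probs), length(labels) == nrow(probs))
  labels <- as.integer(labels)
  if (any(labels < 0L | labels >= ncol(probs)))
    stop("labels must be 0-based class indices")
  p <- probs[cbind(seq_len(nrow(probs)), labels + 1L)]
  -mean(log(pmax(p, 1e-12)))
}

#' Dice loss between two binary masks
#'
#' \eqn{1 - 2|A \cap B| / (|A| + |B|)} over the predicted and true foreground
#' pixel sets. Two empty masks are a perfect match (loss 0).
#'
#' @param pred_mask,true_mask binary (0/1) matrices of identical shape.
#' @return scalar in \[0, 1\].
#' @export
dice_loss <- function(pred_mask, true_mask) {
  if (!all(dim(pred_mask) == dim(true_mask)))
    stop("mask shapes differ")
  a <- sum(pred_mask != 0)
  b <- sum(true_mask != 0)
  if (a + b == 0) return(0)
  inter <- sum(pred_mask != 0 & true_mask != 0)
  1 - 2 * inter / (a + b)
}

#' Pixel confusion counts
#'
#' Per-pixel 2x2 tally against the foreground (muscle) class: TP/FP/FN/TN.
#'
#' @param pred_mask,true_mask binary (0/1) matrices of identical shape.
#' @return list with integer fields `TP`, `FP`, `FN`, `TN`.
#' @export
confusion_counts <- function(pred_mask, true_mask) {
  if (!all(dim(pred_mask) == dim(true_mask)))
    stop("mask shapes differ")
  pv <- as.vector(pred_mask)
  tv <- as.vector(true_mask)
  if (!all(pv %in% c(0, 1)) || !all(tv %in% c(0, 1)))
    stop("masks must be binary")
  list(TP = sum(pv == 1 & tv == 1),
       FP = sum(pv == 1 & tv == 0),
       FN = sum(pv == 0 & tv == 1),
       TN = sum(pv == 0 & tv == 0))
}

#' Segmentation metrics from confusion counts
#'
#' Precision = TP/(TP+FP), Recall = TP/(TP+FN), IoU = TP/(TP+FP+FN),
#' DSC = 2TP/(2TP+FP+FN), each in percent. When TP+FP+FN = 0 (empty
#' prediction against empty truth) all metrics are defined as 100.
#'
#' @param counts list with fields `TP`, `FP`, `FN` (as from
#'   [confusion_counts()]).
#' @return list with fields `pre`, `rec`, `iou`, `dsc` (percent).
#' @export
seg_metrics <- function(counts) {
  TP <- counts$TP; FP <- counts$FP; FN <- counts$FN
  if (TP + FP + FN == 0)
    return(list(pre = 100, rec = 100, iou = 100, dsc = 100))
  div <- function(num, den) if (den == 0) 0 else num / den
  list(pre = 100 * div(TP, TP + FP),
       rec = 100 * div(TP, TP + FN),
       iou = 100 * TP / (TP + FP + FN),
       dsc = 100 * 2 * TP / (2 * TP + FP + FN))
}

#' Regression metrics
#'
#' Coefficient of determination, root-mean-square error, mean absolute error
#' and mean relative error (percent) between measured and predicted
#' breast-muscle weights.
#'
#' @param actual,predicted numeric vectors of equal length (grams).
#' @return list with fields `r2`, `rmse`, `mae`, `mre`. If any actual value
#'   is zero, `mre` is `NA` with a warning (relative error undefined); the
#'   other metrics are still returned.
#' @export
regression_metrics <- function(actual, predicted) {
  stopifnot(length(actual) == length(predicted), length(actual) > 0)
  err <- predicted - actual
  r2 <- 1 - sum(err^2) / sum((actual - mean(actual))^2)
  rmse <- sqrt(mean(err^2))
  mae <- mean(abs(err))
  if (any(actual == 0)) {
    warning("actual value of 0: MRE undefined")
    mre <- NA_real_
  } else {
    mre <- 100 * mean(abs(err / actual))
  }
  list(r2 = r2, rmse = rmse, mae = mae, mre = mre)
}
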