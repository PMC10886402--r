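## Training loop: SGD with momentum and weight decay, cross-entropy training
## loss, dice validation loss, per-epoch Pre/Rec/IoU/DSC, best-validation-IoU
## checkpointing.

#' Training configuration
#'
#' Defaults follow the published protocol: 100 epochs, batch size 8,
#' constant learning rate 0.01, SGD with momentum 0.9 and weight decay 1e-4.
#'
#' @param epochs number of epochs.
#' @param batch_size mini-batch size.
#' @param learning_rate SGD learning rate (constant over training).
#' @param momentum SGD momentum.
#' @param weight_decay L2 weight decay applied to all parameters.
#' @param seed RNG seed controlling shuffling (and, combined with the model
#'   seed, the full run).
#' @param augment optional [augmentation_spec()] applied to training pairs,
#'   or `NULL` for none.
#' @return object of class `train_config`.
#' @export
train_config <- function(epochs = 100L, batch_size = 8L, learning_rate = 0.01,
                         momentum = 0.9, weight_decay = 1e-4, seed = 1L,
                         augment = NULL) {
  stopifnot(epochs >= 1, batch_size >= 1, learning_rate > 0,
            momentum >= 0, weight_decay >= 0)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, momentum = momentum,
                 weight_decay = weight_decay, seed = as.integer(seed),
                 augment = augment),
            class = "train_config")
}

sgd_new <- function(model, lr, momentum, weight_decay) {
  plist <- list()
  for (mod in maefnet_modules(model)) plist <- c(plist, param_list(mod))
  list(plist = plist, bufs = vector("list", length(plist)), lr = lr,
       momentum = momentum, wd = weight_decay)
}

sgd_step <- function(opt, scale) {
  for (i in seq_along(opt$plist)) {
    p <- opt$plist[[i]]
    if (!p$env$trainable) next
    v <- p$env[[p$name]]
    ## weight decay on convolution weights only; batch-norm parameters and
    ## biases are excluded (standard practice)
    wd <- if (p$name %in% c("gamma", "beta", "b")) 0 else opt$wd
    g <- p$env[[paste0("g_", p$name)]] * scale + wd * v
    buf <- opt$bufs[[i]]
    buf <- if (is.null(buf)) g else opt$momentum * buf + g
    opt$bufs[[i]] <- buf
    p$env[[p$name]] <- v - opt$lr * buf
  }
  opt
}

batch_tensors <- function(samples, input_channels) {
  imgs <- lapply(samples, `[[`, "image")
  t <- prepare_input(imgs, input_channels)
  labels <- unlist(lapply(samples, function(s) as.integer(s$mask)),
                   use.names = FALSE)
  list(t = t, labels = labels)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

## Forward a batch in train mode, compute CE loss and the logits gradient.
train_batch <- function(model, samples, opt) {
  bt <- batch_tensors(samples, model$config$input_channels)
  lg <- maefnet_fwd(model, bt$t, "train")
  p <- softmax_rows(lg$x)
  loss <- cross_entropy_loss(p, bt$labels)
  np <- nrow(p)
  dz <- p
  dz[cbind(seq_len(np), bt$labels + 1L)] <-
    dz[cbind(seq_len(np), bt$labels + 1L)] - 1
  dz <- dz / np
  for (mod in maefnet_modules(model)) zero_grads(mod)
  maefnet_bwd(model, tz(dz, lg$N, lg$H, lg$W))
  opt <- sgd_step(opt, 1)
  list(loss = loss, opt = opt)
}

walk_modules <- function(mod, fn) {
  fn(mod)
  for (ch in mod$children) walk_modules(ch, fn)
  invisible(NULL)
}

#' Recompute batch-norm statistics over a dataset
#'
#' Replaces the exponential-moving-average batch-norm statistics with exact
#' per-channel mean/variance aggregated over the given samples ("precise BN").
#' The moving averages track a drifting weight trajectory during training;
#' refreshing them against the final weights removes the resulting
#' train/eval discrepancy.
#'
#' @param model a [maefnet()] model (updated in place).
#' @param samples list of samples with `image` fields (typically the training
#'   split).
#' @param batch_size forward batch size.
#' @return the model, invisibly.
#' @export
refresh_bn_stats <- function(model, samples, batch_size = 8L) {
  reset <- function(m) {
    if (m$kind == "bn") {
      m$acc_sum <- numeric(m$C)
      m$acc_sq <- numeric(m$C)
      m$acc_n <- 0L
    }
  }
  for (mod in maefnet_modules(model)) walk_modules(mod, reset)
  for (start in seq(1, length(samples), by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, length(samples))
    bt <- batch_tensors(samples[idx], model$config$input_channels)
    maefnet_fwd(model, bt$t, "stats")
  }
  finalize <- function(m) {
    if (m$kind == "bn" && m$acc_n > 0L) {
      m$run_mean <- m$acc_sum / m$acc_n
      m$run_var <- pmax(m$acc_sq / m$acc_n - m$run_mean^2, 0)
    }
  }
  for (mod in maefnet_modules(model)) walk_modules(mod, finalize)
  invisible(model)
}

#' Evaluate a model on a set of samples
#'
#' Runs the network in evaluation mode, thresholds by argmax and reports
#' per-image dice loss and confusion counts, a micro-average (metrics of the
#' pooled pixel counts) and a macro-average (mean of per-image metrics).
#'
#' @param model a [maefnet()] model.
#' @param samples list of samples, each with `image` and `mask` fields.
#' @param batch_size evaluation batch size.
#' @return list with `per_image` (data frame), `micro`, `macro`,
#'   `dice_loss` (mean per-image dice loss).
#' @export
evaluate_model <- function(model, samples, batch_size = 8L) {
  stopifnot(length(samples) > 0)
  rows <- list()
  pooled <- list(TP = 0, FP = 0, FN = 0, TN = 0)
  for (start in seq(1, length(samples), by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, length(samples))
    bt <- batch_tensors(samples[idx], model$config$input_channels)
    lg <- maefnet_fwd(model, bt$t, "eval")
    pred <- (lg$x[, 2] > lg$x[, 1]) * 1L
    off <- 0L
    for (j in seq_along(idx)) {
      npix <- lg$H * lg$W
      pm <- matrix(pred[off + seq_len(npix)], lg$H, lg$W)
      tm <- samples[[idx[j]]]$mask
      cc <- confusion_counts(pm, tm)
      sm <- seg_metrics(cc)
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = samples[[idx[j]]]$sample_id %||% as.character(idx[j]),
        dice_loss = dice_loss(pm, tm),
        pre = sm$pre, rec = sm$rec, iou = sm$iou, dsc = sm$dsc)
      for (nm in names(pooled)) pooled[[nm]] <- pooled[[nm]] + cc[[nm]]
      off <- off + npix
    }
  }
  per_image <- do.call(rbind, rows)
  micro <- seg_metrics(pooled)
  macro <- as.list(colMeans(per_image[, c("pre", "rec", "iou", "dsc")]))
  list(per_image = per_image, micro = micro, macro = macro,
       dice_loss = mean(per_image$dice_loss))
}

#' Train MAEFNet
#'
#' SGD training over the train split with per-epoch validation: training
#' cross-entropy loss, validation dice loss (on hard argmax predictions) and
#' validation Pre/Rec/IoU/DSC are recorded each epoch; the weights with the
#' best validation IoU (micro-average) are restored into the returned model.
#' The run is fully reproducible given `config$seed` and a seeded model.
#'
#' @param model a [maefnet()] model (modified in place and returned).
#' @param data list with `train` and `val` lists of samples (fields `image`,
#'   `mask`, optionally `sample_id`).
#' @param config a [train_config()].
#' @param verbose print a line per epoch.
#' @return list with `model` (best-validation weights), `history` (data frame
#'   of epoch records: epoch, train_ce_loss, val_dice_loss, val_pre, val_rec,
#'   val_iou, val_dsc), `best_epoch`.
#' @export
train_maefnet <- function(model, data, config = train_config(),
                          verbose = FALSE) {
  stopifnot(inherits(config, "train_config"))
  if (length(data$train) == 0 || length(data$val) == 0)
    stop("train and val splits must be non-empty")
  set.seed(config$seed)
  opt <- sgd_new(model, config$learning_rate, config$momentum,
                 config$weight_decay)
  history <- vector("list", config$epochs)
  best_iou <- -Inf
  best_state <- NULL
  best_epoch <- NA_integer_
  for (epoch in seq_len(config$epochs)) {
    ord <- sample(length(data$train))
    losses <- c()
    for (start in seq(1, length(ord), by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, length(ord))]
      batch <- data$train[idx]
      if (!is.null(config$augment)) {
        batch <- lapply(batch, function(s) {
          a <- augment(s$image, s$mask, config$augment,
                       seed = sample.int(.Machine$integer.max, 1))
          s$image <- a$image
          s$mask <- a$mask
          s
        })
      }
      r <- train_batch(model, batch, opt)
      opt <- r$opt
      losses <- c(losses, r$loss)
    }
    ev <- evaluate_model(model, data$val, config$batch_size)
    history[[epoch]] <- data.frame(
      epoch = epoch, train_ce_loss = mean(losses),
      val_dice_loss = ev$dice_loss, val_pre = ev$micro$pre,
      val_rec = ev$micro$rec, val_iou = ev$micro$iou, val_dsc = ev$micro$dsc)
    if (ev$micro$iou > best_iou) {
      best_iou <- ev$micro$iou
      best_state <- collect_state(model)
      best_epoch <- epoch
    }
    if (verbose)
      message(sprintf("epoch %3d  ce %.4f  val dice %.4f  val IoU %.2f",
                      epoch, mean(losses), ev$dice_loss, ev$micro$iou))
  }
  if (!is.null(best_state)) restore_state(model, best_state)
  refresh_bn_stats(model, data$train, config$batch_size)
  list(model = model, history = do.call(rbind, history),
       best_epoch = best_epoch)
}
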