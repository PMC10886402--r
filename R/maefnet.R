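## MAEFNet: lightweight encoder-decoder network for pectoral-muscle
## segmentation in broiler radiographs.
##
## Encoder: MobileNetV3-Large inverted-residual stack truncated so that the
## deepest feature map is at output stride 16 (the stride-32 stage and the
## classification tail are discarded; the truncation point is chosen so the
## whole model stays within a 1.51 M trainable-parameter budget). Multistage
## taps are taken at strides 4, 8 and 16.
##
## Decoder: per tap an Attention Refinement Module (ARM, channel gating) then
## a Coordinate Attention Module (CAM, directional spatial gating); the three
## branches are fused coarse-to-fine by Feature Fusion Modules (FFM), followed
## by a 1x1 two-class head and a 4x bilinear upsample to input resolution.

## ---- decoder modules --------------------------------------------------------

## ARM: X' = ReLU(BN(conv3x3(x))); alpha_c = Sigmoid(BN(conv1x1(GAP(X'))));
## output = X' * alpha_c (broadcast over space). Reduces channels to cout.
nn_arm <- function(cin, cout) {
  self <- new_module("arm")
  self$reduce <- nn_seq(nn_conv(cin, cout, 3), nn_bn(cout), nn_act("relu"))
  self$gconv <- nn_conv(cout, cout, 1)
  self$gbn <- nn_bn(cout)
  self$children <- list(self$reduce, self$gconv, self$gbn)
  self$fwd <- function(t, mode) {
    xp <- self$reduce$fwd(t, mode)
    idx <- rep(seq_len(xp$N), each = xp$H * xp$W)
    s <- rowsum(xp$x, idx, reorder = TRUE) / (xp$H * xp$W)
    z <- self$gbn$fwd(self$gconv$fwd(tz(s, xp$N, 1L, 1L), mode), mode)
    a <- 1 / (1 + exp(-z$x))
    y <- xp$x * a[idx, , drop = FALSE]
    self$cache <- list(xp = xp, idx = idx, a = a)
    tz(y, xp$N, xp$H, xp$W)
  }
  self$bwd <- function(dt) {
    cc <- self$cache
    xp <- cc$xp
    dxp <- dt$x * cc$a[cc$idx, , drop = FALSE]
    da <- rowsum(dt$x * xp$x, cc$idx, reorder = TRUE)
    dz <- da * cc$a * (1 - cc$a)
    ds <- self$gconv$bwd(self$gbn$bwd(tz(dz, xp$N, 1L, 1L)))$x
    dxp <- dxp + ds[cc$idx, , drop = FALSE] / (xp$H * xp$W)
    self$cache <- NULL
    self$reduce$bwd(tz(dxp, xp$N, xp$H, xp$W))
  }
  self
}

## CAM: directional average pools (over width -> H profile, over height -> W
## profile), spatial concatenation, shared 1x1 conv + BN + hard-swish down to
## max(C/r, 8) channels, split, two 1x1 convs back to C channels, sigmoid
## gates: out = x * alpha_H * alpha_W.
nn_cam <- function(C, r = 16) {
  self <- new_module("cam")
  mid <- max(8L, as.integer(C %/% r))
  if (C < 1 || mid < 1) stop("CAM reduction leaves no channels")
  self$squeeze <- nn_seq(nn_conv(C, mid, 1), nn_bn(mid), nn_act("hswish"))
  self$convh <- nn_conv(mid, C, 1, bias = TRUE)
  self$convw <- nn_conv(mid, C, 1, bias = TRUE)
  self$children <- list(self$squeeze, self$convh, self$convw)
  self$fwd <- function(t, mode) {
    N <- t$N; H <- t$H; W <- t$W
    n_idx <- rep(seq_len(N), each = H * W)
    h_idx <- rep(rep(seq_len(H), W), N)
    w_idx <- rep(rep(seq_len(W), each = H), N)
    gh <- (n_idx - 1L) * H + h_idx   # row -> (n, h) group
    gw <- (n_idx - 1L) * W + w_idx   # row -> (n, w) group
    hp <- rowsum(t$x, gh, reorder = TRUE) / W
    wp <- rowsum(t$x, gw, reorder = TRUE) / H
    f <- self$squeeze$fwd(tz(rbind(hp, wp), N, 1L, 1L), mode)
    fh <- f$x[seq_len(N * H), , drop = FALSE]
    fw <- f$x[N * H + seq_len(N * W), , drop = FALSE]
    zh <- self$convh$fwd(tz(fh, N, 1L, 1L), mode)$x
    zw <- self$convw$fwd(tz(fw, N, 1L, 1L), mode)$x
    ah <- 1 / (1 + exp(-zh))
    aw <- 1 / (1 + exp(-zw))
    y <- t$x * ah[gh, , drop = FALSE] * aw[gw, , drop = FALSE]
    self$cache <- list(t = t, gh = gh, gw = gw, ah = ah, aw = aw)
    tz(y, N, H, W)
  }
  self$bwd <- function(dt) {
    cc <- self$cache
    t <- cc$t
    ahr <- cc$ah[cc$gh, , drop = FALSE]
    awr <- cc$aw[cc$gw, , drop = FALSE]
    dx <- dt$x * ahr * awr
    dah <- rowsum(dt$x * t$x * awr, cc$gh, reorder = TRUE)
    daw <- rowsum(dt$x * t$x * ahr, cc$gw, reorder = TRUE)
    dzh <- dah * cc$ah * (1 - cc$ah)
    dzw <- daw * cc$aw * (1 - cc$aw)
    dfh <- self$convh$bwd(tz(dzh, t$N, 1L, 1L))$x
    dfw <- self$convw$bwd(tz(dzw, t$N, 1L, 1L))$x
    dcat <- self$squeeze$bwd(tz(rbind(dfh, dfw), t$N, 1L, 1L))$x
    dhp <- dcat[seq_len(t$N * t$H), , drop = FALSE]
    dwp <- dcat[t$N * t$H + seq_len(t$N * t$W), , drop = FALSE]
    dx <- dx + dhp[cc$gh, , drop = FALSE] / t$W +
      dwp[cc$gw, , drop = FALSE] / t$H
    self$cache <- NULL
    tz(dx, t$N, t$H, t$W)
  }
  self
}

## FFM: channel-concatenate two same-resolution maps, X' = ReLU(BN(conv3x3)),
## alpha_c = Sigmoid(fc(ReLU(fc(GAP(X'))))), out = X' + X' * alpha_c.
nn_ffm <- function(c1, c2, cout, reduction = 4) {
  self <- new_module("ffm")
  self$c1 <- c1; self$c2 <- c2
  mid <- max(8L, as.integer(cout %/% reduction))
  self$reduce <- nn_seq(nn_conv(c1 + c2, cout, 3), nn_bn(cout), nn_act("relu"))
  self$fc1 <- nn_conv(cout, mid, 1, bias = TRUE)
  self$fc2 <- nn_conv(mid, cout, 1, bias = TRUE)
  self$children <- list(self$reduce, self$fc1, self$fc2)
  self$fwd <- function(t1, t2, mode) {
    if (t1$H != t2$H || t1$W != t2$W || t1$N != t2$N)
      stop("FFM inputs must share spatial size")
    t <- tz(cbind(t1$x, t2$x), t1$N, t1$H, t1$W)
    xp <- self$reduce$fwd(t, mode)
    idx <- rep(seq_len(xp$N), each = xp$H * xp$W)
    s <- rowsum(xp$x, idx, reorder = TRUE) / (xp$H * xp$W)
    s1 <- self$fc1$fwd(tz(s, xp$N, 1L, 1L), mode)$x
    a1 <- pmax(s1, 0)
    s2 <- self$fc2$fwd(tz(a1, xp$N, 1L, 1L), mode)$x
    a <- 1 / (1 + exp(-s2))
    y <- xp$x + xp$x * a[idx, , drop = FALSE]
    self$cache <- list(xp = xp, idx = idx, s1 = s1, a = a)
    tz(y, xp$N, xp$H, xp$W)
  }
  self$bwd <- function(dt) {
    cc <- self$cache
    xp <- cc$xp
    ar <- cc$a[cc$idx, , drop = FALSE]
    dxp <- dt$x * (1 + ar)
    da <- rowsum(dt$x * xp$x, cc$idx, reorder = TRUE)
    ds2 <- da * cc$a * (1 - cc$a)
    da1 <- self$fc2$bwd(tz(ds2, xp$N, 1L, 1L))$x
    ds1 <- da1 * (cc$s1 > 0)
    ds <- self$fc1$bwd(tz(ds1, xp$N, 1L, 1L))$x
    dxp <- dxp + ds[cc$idx, , drop = FALSE] / (xp$H * xp$W)
    dcat <- self$reduce$bwd(tz(dxp, xp$N, xp$H, xp$W))
    self$cache <- NULL
    list(tz(dcat$x[, seq_len(self$c1), drop = FALSE], dcat$N, dcat$H, dcat$W),
         tz(dcat$x[, self$c1 + seq_len(self$c2), drop = FALSE],
            dcat$N, dcat$H, dcat$W))
  }
  self
}

## ---- model ------------------------------------------------------------------

#' MAEFNet configuration
#'
#' Architecture hyperparameters of the segmentation network. The defaults
#' realise the lightweight design: a truncated MobileNetV3-Large encoder with
#' taps at output strides 4/8/16, ARM output widths 32/64/128 (shallow to
#' deep), CAM channel reduction 16, FFM fusion widths 64 and 32, and a
#' two-class head. The assembled default model has about 1.12 M trainable
#' parameters, inside the 1.51 M design budget.
#'
#' @param arm_channels integer(3), ARM output channels at strides 4, 8, 16.
#' @param cam_reduction channel reduction ratio inside the CAM (minimum
#'   internal width 8).
#' @param ffm_channels integer(2), output channels of the two fusion stages
#'   (stride-8 fusion, then stride-4 fusion).
#' @param num_classes number of output classes (background, muscle).
#' @param input_channels input channels; grayscale images are replicated to 3
#'   so the standard MobileNetV3 stem is reused.
#' @param use_cam logical; set `FALSE` to drop the coordinate-attention
#'   modules (ablation switch).
#' @return An object of class `maefnet_config`.
#' @export
maefnet_config <- function(arm_channels = c(32L, 64L, 128L),
                           cam_reduction = 16L,
                           ffm_channels = c(64L, 32L),
                           num_classes = 2L,
                           input_channels = 3L,
                           use_cam = TRUE) {
  stopifnot(length(arm_channels) == 3, all(arm_channels >= 1),
            cam_reduction >= 1, length(ffm_channels) == 2,
            num_classes >= 2, input_channels >= 1)
  structure(list(encoder_variant = "mobilenetv3-large-pruned",
                 arm_channels = as.integer(arm_channels),
                 cam_reduction = as.integer(cam_reduction),
                 ffm_channels = as.integer(ffm_channels),
                 num_classes = as.integer(num_classes),
                 input_channels = as.integer(input_channels),
                 use_cam = isTRUE(use_cam)),
            class = "maefnet_config")
}

## MobileNetV3-Large block table through the last stride-16 block that fits
## the parameter budget: (kernel, expansion, out, SE, activation, stride).
## The stride-32 stage and everything after it are discarded.
mnv3_blocks <- function() {
  list(
    list(3L,  16L,  16L, FALSE, "relu",   1L),
    list(3L,  64L,  24L, FALSE, "relu",   2L),
    list(3L,  72L,  24L, FALSE, "relu",   1L),
    list(5L,  72L,  40L, TRUE,  "relu",   2L),
    list(5L, 120L,  40L, TRUE,  "relu",   1L),
    list(5L, 120L,  40L, TRUE,  "relu",   1L),
    list(3L, 240L,  80L, FALSE, "hswish", 2L),
    list(3L, 200L,  80L, FALSE, "hswish", 1L),
    list(3L, 184L,  80L, FALSE, "hswish", 1L),
    list(3L, 184L,  80L, FALSE, "hswish", 1L),
    list(3L, 480L, 112L, TRUE,  "hswish", 1L),
    list(3L, 672L, 112L, TRUE,  "hswish", 1L)
  )
}

#' Build the pruned MobileNetV3-Large encoder
#'
#' Standard MobileNetV3-Large stem plus inverted-residual stack, truncated at
#' output stride 16 (the downsampling ratio is reduced from 32 to 16 by
#' discarding the stride-32 stage and the classification tail). Returns the
#' module list plus the indices of the blocks whose outputs are tapped at
#' strides 4, 8 and 16.
#'
#' @param input_channels number of input channels (default 3).
#' @return list with elements `stem`, `blocks`, `taps` (block indices) and
#'   `tap_channels`.
#' @export
build_encoder <- function(input_channels = 3L) {
  stem <- nn_seq(nn_conv(input_channels, 16L, 3, stride = 2), nn_bn(16L),
                 nn_act("hswish"))
  spec <- mnv3_blocks()
  cin <- 16L
  blocks <- vector("list", length(spec))
  for (i in seq_along(spec)) {
    s <- spec[[i]]
    blocks[[i]] <- nn_invres(cin, s[[2]], s[[3]], s[[1]], s[[6]],
                             se = s[[4]], act = s[[5]])
    cin <- s[[3]]
  }
  list(stem = stem, blocks = blocks, taps = c(3L, 6L, 12L),
       tap_channels = c(24L, 40L, 112L))
}

#' Assemble a MAEFNet model
#'
#' Builds the full segmentation network (encoder, per-tap ARM + CAM, two FFM
#' fusion stages, two-class head, 4x bilinear upsample). Parameters are
#' He-initialised from the current RNG state; pass `seed` for a reproducible
#' build.
#'
#' @param config a [maefnet_config()].
#' @param seed optional integer seed for parameter initialisation.
#' @return An object of class `maefnet`.
#' @export
maefnet <- function(config = maefnet_config(), seed = NULL) {
  stopifnot(inherits(config, "maefnet_config"))
  if (!is.null(seed)) set.seed(seed)
  enc <- build_encoder(config$input_channels)
  ac <- config$arm_channels
  fc <- config$ffm_channels
  tc <- enc$tap_channels
  m <- list(
    config = config,
    stem = enc$stem,
    blocks = enc$blocks,
    taps = enc$taps,
    arm4 = nn_arm(tc[1], ac[1]),
    arm8 = nn_arm(tc[2], ac[2]),
    arm16 = nn_arm(tc[3], ac[3]),
    cam4 = if (config$use_cam) nn_cam(ac[1], config$cam_reduction),
    cam8 = if (config$use_cam) nn_cam(ac[2], config$cam_reduction),
    cam16 = if (config$use_cam) nn_cam(ac[3], config$cam_reduction),
    up16 = nn_up(2),
    ffm8 = nn_ffm(ac[3], ac[2], fc[1]),
    up8 = nn_up(2),
    ffm4 = nn_ffm(fc[1], ac[1], fc[2]),
    head = nn_conv(fc[2], config$num_classes, 1, bias = TRUE),
    up_out = nn_up(4)
  )
  class(m) <- "maefnet"
  m
}

maefnet_modules <- function(model) {
  mods <- c(list(model$stem), model$blocks,
            list(model$arm4, model$arm8, model$arm16),
            Filter(Negate(is.null),
                   list(model$cam4, model$cam8, model$cam16)),
            list(model$ffm8, model$ffm4, model$head))
  mods
}

#' Count trainable parameters
#'
#' Sums the element counts of every trainable parameter array in the model.
#' Parameters of frozen modules (see the internal `freeze_module()`) are
#' excluded.
#'
#' @param model a [maefnet()] model.
#' @return integer scalar.
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "maefnet"))
  total <- 0L
  for (mod in maefnet_modules(model)) {
    for (p in param_list(mod)) {
      if (p$env$trainable) total <- total + length(p$env[[p$name]])
    }
  }
  total
}

## Forward pass on a prepared input tensor. Returns list(logits tensor, taps).
maefnet_fwd <- function(model, t, mode) {
  if (t$H %% 16L != 0L || t$W %% 16L != 0L)
    stop("input side must be divisible by 16")
  t <- model$stem$fwd(t, mode)
  taps <- list()
  for (i in seq_along(model$blocks)) {
    t <- model$blocks[[i]]$fwd(t, mode)
    if (i %in% model$taps) taps[[length(taps) + 1L]] <- t
  }
  d4 <- model$arm4$fwd(taps[[1]], mode)
  d8 <- model$arm8$fwd(taps[[2]], mode)
  d16 <- model$arm16$fwd(taps[[3]], mode)
  if (!is.null(model$cam4)) {
    d4 <- model$cam4$fwd(d4, mode)
    d8 <- model$cam8$fwd(d8, mode)
    d16 <- model$cam16$fwd(d16, mode)
  }
  u16 <- model$up16$fwd(d16, mode)
  f8 <- model$ffm8$fwd(u16, d8, mode)
  u8 <- model$up8$fwd(f8, mode)
  f4 <- model$ffm4$fwd(u8, d4, mode)
  logits <- model$up_out$fwd(model$head$fwd(f4, mode), mode)
  logits
}

## Backward pass from the logits gradient through the whole network.
maefnet_bwd <- function(model, dlogits) {
  dh <- model$head$bwd(model$up_out$bwd(dlogits))
  df4 <- model$ffm4$bwd(dh)
  du8 <- df4[[1]]; dd4 <- df4[[2]]
  df8 <- model$ffm8$bwd(model$up8$bwd(du8))
  du16 <- df8[[1]]; dd8 <- df8[[2]]
  dd16 <- model$up16$bwd(du16)
  if (!is.null(model$cam4)) {
    dd4 <- model$cam4$bwd(dd4)
    dd8 <- model$cam8$bwd(dd8)
    dd16 <- model$cam16$bwd(dd16)
  }
  dt4 <- model$arm4$bwd(dd4)
  dt8 <- model$arm8$bwd(dd8)
  dt16 <- model$arm16$bwd(dd16)
  g <- dt16
  for (i in rev(seq_along(model$blocks))) {
    g <- model$blocks[[i]]$bwd(g)
    if (i - 1L == model$taps[2]) g$x <- g$x + dt8$x
    if (i - 1L == model$taps[1]) g$x <- g$x + dt4$x
  }
  model$stem$bwd(g)
}

## Build the network input tensor from a list of grayscale images
## (H x W matrices on a 0..255 or 0..1 scale); intensities are scaled to
## [0, 1] and replicated to `input_channels` identical channels.
prepare_input <- function(images, input_channels = 3L) {
  if (is.matrix(images)) images <- list(images)
  H <- nrow(images[[1]]); W <- ncol(images[[1]])
  v <- unlist(lapply(images, function(im) {
    stopifnot(is.matrix(im), nrow(im) == H, ncol(im) == W)
    im <- as.numeric(im)
    if (max(im) > 1) im <- im / 255
    im
  }), use.names = FALSE)
  x <- matrix(rep(v, input_channels), ncol = input_channels)
  tz(x, length(images), H, W)
}

#' Run MAEFNet on images
#'
#' Forward pass in evaluation mode (batch-norm running statistics). Input
#' sides must be divisible by 16.
#'
#' @param model a [maefnet()] model.
#' @param images a grayscale image matrix or list of equally sized matrices
#'   (0..255 or 0..1 scale).
#' @return list with `logits` (an N x H x W x num_classes array of
#'   unnormalised class scores) and the input geometry.
#' @export
maefnet_forward <- function(model, images) {
  t <- prepare_input(images, model$config$input_channels)
  lg <- maefnet_fwd(model, t, "eval")
  arr <- array(lg$x, dim = c(lg$H, lg$W, lg$N, ncol(lg$x)))
  arr <- aperm(arr, c(3, 1, 2, 4))
  list(logits = arr, N = lg$N, H = lg$H, W = lg$W)
}

#' Predict a binary pectoral-muscle mask
#'
#' Argmax over the two-class logits at input resolution.
#'
#' @inheritParams maefnet_forward
#' @param image a grayscale image matrix.
#' @return H x W binary (0/1) integer matrix.
#' @export
predict_mask <- function(model, image) {
  out <- maefnet_forward(model, image)
  fg <- out$logits[1, , , 2] > out$logits[1, , , 1]
  matrix(as.integer(fg), out$H, out$W)
}

#' @export
print.maefnet <- function(x, ...) {
  cat("MAEFNet segmentation model\n")
  cat("  encoder: ", x$config$encoder_variant,
      " (taps at strides 4/8/16, channels 24/40/112)\n", sep = "")
  cat("  decoder: ARM ", paste(x$config$arm_channels, collapse = "/"),
      if (x$config$use_cam) " + CAM (r=" else " (CAM disabled",
      if (x$config$use_cam) paste0(x$config$cam_reduction, ")") else ")",
      ", FFM ", paste(x$config$ffm_channels, collapse = "/"), "\n", sep = "")
  cat("  classes: ", x$config$num_classes, "\n", sep = "")
  cat("  trainable parameters: ",
      format(count_parameters(x), big.mark = ","), "\n", sep = "")
  invisible(x)
}

## ---- checkpointing ----------------------------------------------------------

collect_state <- function(model) {
  mods <- maefnet_modules(model)
  state <- list()
  walk <- function(m, path) {
    entry <- list()
    for (nm in m$par) entry[[nm]] <- m[[nm]]
    if (m$kind == "bn") {
      entry$run_mean <- m$run_mean
      entry$run_var <- m$run_var
    }
    state[[path]] <<- entry
    for (i in seq_along(m$children)) walk(m$children[[i]], paste0(path, ".", i))
  }
  for (i in seq_along(mods)) walk(mods[[i]], as.character(i))
  state
}

restore_state <- function(model, state) {
  mods <- maefnet_modules(model)
  walk <- function(m, path) {
    entry <- state[[path]]
    for (nm in m$par) m[[nm]] <- entry[[nm]]
    if (m$kind == "bn") {
      m$run_mean <- entry$run_mean
      m$run_var <- entry$run_var
    }
    for (i in seq_along(m$children)) walk(m$children[[i]], paste0(path, ".", i))
  }
  for (i in seq_along(mods)) walk(mods[[i]], as.character(i))
  invisible(model)
}

#' Save / load a MAEFNet checkpoint
#'
#' The checkpoint is a single serialized file holding the architecture
#' configuration, all weights and batch-norm running statistics, and a format
#' version.
#'
#' @param model a [maefnet()] model.
#' @param path file path.
#' @return `load_maefnet` returns the restored model.
#' @export
save_maefnet <- function(model, path) {
  saveRDS(list(format = 1L, config = model$config,
               state = collect_state(model)), path)
  invisible(path)
}

#' @rdname save_maefnet
#' @export
load_maefnet <- function(path) {
  ck <- readRDS(path)
  stopifnot(identical(ck$format, 1L))
  model <- maefnet(ck$config)
  restore_state(model, ck$state)
  model
}
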