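## Minimal neural-network layer framework.
##
## A batched feature map ("tensor") is a list(x, N, H, W) where x is an
## (N*H*W) x C matrix; rows are ordered image-major, then column-major within
## the image (row index = (n-1)*H*W + (w-1)*H + h). Global vectors (one value
## per image and channel) are tensors with H = W = 1.
##
## A module is an environment holding parameter arrays, their gradient
## accumulators ("g_<name>"), child modules, and fwd/bwd closures. Gradients
## accumulate across calls; zero_grads() resets them before each batch.

tz <- function(x, N, H, W) list(x = x, N = N, H = H, W = W)

new_module <- function(kind) {
  self <- new.env(parent = emptyenv())
  self$kind <- kind
  self$children <- list()
  self$par <- character()
  self$trainable <- TRUE
  self
}

add_param <- function(self, name, value) {
  self[[name]] <- value
  self[[paste0("g_", name)]] <- array(0, dim = dim(value) %||% length(value))
  self$par <- c(self$par, name)
  invisible(self)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
param_list <- function(self) {
  out <- lapply(self$par, function(nm) list(env = self, name = nm))
  for (ch in self$children) out <- c(out, param_list(ch))
  out
}

zero_grads <- function(self) {
  for (nm in self$par) {
    g <- self[[paste0("g_", nm)]]
    self[[paste0("g_", nm)]] <- array(0, dim = dim(g) %||% length(g))
  }
  for (ch in self$children) zero_grads(ch)
  invisible(self)
}

## Multiply each column c of m by v[c].
cmul <- function(m, v) m * rep(v, each = nrow(m))

## ---- primitive layers -------------------------------------------------------

## Convolution; k = 1 collapses to a plain GEMM. He-normal initialisation.
nn_conv <- function(cin, cout, k = 1, stride = 1, pad = NULL, bias = FALSE) {
  self <- new_module("conv")
  pad <- pad %||% (k %/% 2)
  self$k <- k; self$stride <- stride; self$pad <- pad
  self$cin <- cin; self$cout <- cout
  add_param(self, "W", matrix(stats::rnorm(cin * k * k * cout,
                                           sd = sqrt(2 / (cin * k * k))),
                              cin * k * k, cout))
  self$bias <- bias
  if (bias) add_param(self, "b", numeric(cout))
  self$fwd <- function(t, mode) {
    stopifnot(ncol(t$x) == self$cin)
    if (self$k == 1L && self$stride == 1L) {
      cols <- t$x
      Ho <- t$H; Wo <- t$W
    } else {
      cols <- cpp_im2col(t$x, t$N, t$H, t$W, self$k, self$stride, self$pad)
      Ho <- (t$H + 2 * self$pad - self$k) %/% self$stride + 1L
      Wo <- (t$W + 2 * self$pad - self$k) %/% self$stride + 1L
    }
    y <- cols %*% self$W
    if (self$bias) y <- y + rep(self$b, each = nrow(y))
    self$cache <- list(cols = cols, N = t$N, H = t$H, W = t$W)
    tz(y, t$N, Ho, Wo)
  }
  self$bwd <- function(dt) {
    cc <- self$cache
    self$g_W <- self$g_W + crossprod(cc$cols, dt$x)
    if (self$bias) self$g_b <- self$g_b + colSums(dt$x)
    dcols <- tcrossprod(dt$x, self$W)
    if (self$k == 1L && self$stride == 1L) {
      dx <- dcols
    } else {
      dx <- cpp_col2im(dcols, cc$N, cc$H, cc$W, self$cin, self$k, self$stride,
                       self$pad)
    }
    self$cache <- NULL
    tz(dx, cc$N, cc$H, cc$W)
  }
  self
}

## Depthwise convolution (one k x k filter per channel, no bias).
nn_dw <- function(C, k, stride = 1) {
  self <- new_module("dwconv")
  self$k <- k; self$stride <- stride; self$pad <- k %/% 2; self$C <- C
  add_param(self, "W", matrix(stats::rnorm(k * k * C, sd = sqrt(2 / (k * k))),
                              k * k, C))
  self$fwd <- function(t, mode) {
    y <- cpp_dwconv_fw(t$x, self$W, t$N, t$H, t$W, self$k, self$stride,
                       self$pad)
    Ho <- (t$H + 2 * self$pad - self$k) %/% self$stride + 1L
    Wo <- (t$W + 2 * self$pad - self$k) %/% self$stride + 1L
    self$cache <- t
    tz(y, t$N, Ho, Wo)
  }
  self$bwd <- function(dt) {
    t <- self$cache
    r <- cpp_dwconv_bw(dt$x, t$x, self$W, t$N, t$H, t$W, self$k, self$stride,
                       self$pad)
    self$g_W <- self$g_W + r$dw
    self$cache <- NULL
    tz(r$dx, t$N, t$H, t$W)
  }
  self
}

## Batch normalisation over all rows (batch x spatial) per channel.
## Training mode uses batch statistics and updates running estimates with
## momentum 0.1; eval mode uses the running estimates. eps = 1e-5.
nn_bn <- function(C, eps = 1e-5, momentum = 0.1) {
  self <- new_module("bn")
  self$C <- C; self$eps <- eps; self$momentum <- momentum
  add_param(self, "gamma", rep(1, C))
  add_param(self, "beta", numeric(C))
  self$run_mean <- numeric(C)
  self$run_var <- rep(1, C)
  self$fwd <- function(t, mode) {
    x <- t$x
    if (mode == "train" || mode == "stats") {
      m <- colMeans(x)
      v <- colMeans(x * x) - m * m
      v[v < 0] <- 0
      if (mode == "stats") {
        ## accumulate exact dataset statistics (precise-BN refresh)
        self$acc_sum <- self$acc_sum + m
        self$acc_sq <- self$acc_sq + v + m * m
        self$acc_n <- self$acc_n + 1L
      } else {
        self$run_mean <- (1 - self$momentum) * self$run_mean +
          self$momentum * m
        n <- nrow(x)
        vu <- if (n > 1) v * n / (n - 1) else v
        self$run_var <- (1 - self$momentum) * self$run_var + self$momentum * vu
      }
    } else {
      m <- self$run_mean
      v <- self$run_var
    }
    istd <- 1 / sqrt(v + self$eps)
    r <- cpp_bn_fw(x, m, istd, self$gamma, self$beta)
    self$cache <- if (mode == "train") list(xhat = r$xhat, istd = istd)
    tz(r$y, t$N, t$H, t$W)
  }
  self$acc_sum <- numeric(C)
  self$acc_sq <- numeric(C)
  self$acc_n <- 0L
  self$bwd <- function(dt) {
    cc <- self$cache
    dy <- dt$x
    M <- nrow(dy)
    dbeta <- colSums(dy)
    dgamma <- colSums(dy * cc$xhat)
    self$g_beta <- self$g_beta + dbeta
    self$g_gamma <- self$g_gamma + dgamma
    dx <- cpp_bn_bw(dy, cc$xhat, self$gamma * cc$istd, dbeta / M, dgamma / M)
    self$cache <- NULL
    tz(dx, dt$N, dt$H, dt$W)
  }
  self
}

## Elementwise activations.
nn_act <- function(type = c("relu", "hswish", "hsigmoid", "sigmoid")) {
  type <- match.arg(type)
  self <- new_module(paste0("act_", type))
  self$type <- type
  self$code <- match(type, c("relu", "hswish", "hsigmoid", "sigmoid")) - 1L
  self$fwd <- function(t, mode) {
    y <- cpp_act_fw(t$x, self$code)
    self$cache <- if (self$code == 3L) y else t$x
    tz(y, t$N, t$H, t$W)
  }
  self$bwd <- function(dt) {
    dx <- cpp_act_bw(dt$x, self$cache, self$code)
    self$cache <- NULL
    tz(dx, dt$N, dt$H, dt$W)
  }
  self
}

## Global average pooling to a per-image channel vector (tensor with H=W=1).
nn_gap <- function() {
  self <- new_module("gap")
  self$fwd <- function(t, mode) {
    idx <- rep(seq_len(t$N), each = t$H * t$W)
    y <- rowsum(t$x, idx, reorder = TRUE) / (t$H * t$W)
    self$cache <- list(H = t$H, W = t$W, N = t$N)
    tz(y, t$N, 1L, 1L)
  }
  self$bwd <- function(dt) {
    cc <- self$cache
    dx <- dt$x[rep(seq_len(cc$N), each = cc$H * cc$W), , drop = FALSE] /
      (cc$H * cc$W)
    self$cache <- NULL
    tz(dx, cc$N, cc$H, cc$W)
  }
  self
}

## Bilinear upsampling by an integer factor.
nn_up <- function(scale) {
  self <- new_module("upsample")
  self$scale <- as.integer(scale)
  self$fwd <- function(t, mode) {
    y <- cpp_upsample_fw(t$x, t$N, t$H, t$W, self$scale)
    self$cache <- list(N = t$N, H = t$H, W = t$W)
    tz(y, t$N, t$H * self$scale, t$W * self$scale)
  }
  self$bwd <- function(dt) {
    cc <- self$cache
    dx <- cpp_upsample_bw(dt$x, cc$N, cc$H, cc$W, self$scale)
    self$cache <- NULL
    tz(dx, cc$N, cc$H, cc$W)
  }
  self
}

## Sequential container.
nn_seq <- function(...) {
  self <- new_module("seq")
  self$children <- list(...)
  self$fwd <- function(t, mode) {
    for (ch in self$children) t <- ch$fwd(t, mode)
    t
  }
  self$bwd <- function(dt) {
    for (ch in rev(self$children)) dt <- ch$bwd(dt)
    dt
  }
  self
}

## Squeeze-and-excitation block (as used inside MobileNetV3 inverted residual
## blocks): global pool -> FC/ReLU -> FC/hard-sigmoid -> channel gate.
nn_se <- function(C, Csq) {
  self <- new_module("se")
  self$fc1 <- nn_conv(C, Csq, 1, bias = TRUE)
  self$fc2 <- nn_conv(Csq, C, 1, bias = TRUE)
  self$children <- list(self$fc1, self$fc2)
  self$fwd <- function(t, mode) {
    idx <- rep(seq_len(t$N), each = t$H * t$W)
    s <- rowsum(t$x, idx, reorder = TRUE) / (t$H * t$W)
    s1 <- self$fc1$fwd(tz(s, t$N, 1L, 1L), mode)
    a1 <- pmax(s1$x, 0)
    s2 <- self$fc2$fwd(tz(a1, t$N, 1L, 1L), mode)
    g <- pmin(pmax((s2$x + 3) / 6, 0), 1)
    y <- t$x * g[idx, , drop = FALSE]
    self$cache <- list(t = t, idx = idx, s1 = s1$x, s2 = s2$x, g = g)
    tz(y, t$N, t$H, t$W)
  }
  self$bwd <- function(dt) {
    cc <- self$cache
    t <- cc$t
    dx <- dt$x * cc$g[cc$idx, , drop = FALSE]
    dg <- rowsum(dt$x * t$x, cc$idx, reorder = TRUE)
    ds2 <- dg * ((cc$s2 > -3 & cc$s2 < 3) / 6)
    da1 <- self$fc2$bwd(tz(ds2, t$N, 1L, 1L))$x
    ds1 <- da1 * (cc$s1 > 0)
    ds <- self$fc1$bwd(tz(ds1, t$N, 1L, 1L))$x
    dx <- dx + ds[cc$idx, , drop = FALSE] / (t$H * t$W)
    self$cache <- NULL
    tz(dx, t$N, t$H, t$W)
  }
  self
}

## MobileNetV3 inverted residual block: 1x1 expansion (skipped when the
## expansion width equals the input width), depthwise conv, optional SE,
## 1x1 linear projection; identity skip when stride 1 and cin == cout.
nn_invres <- function(cin, expc, cout, k, stride, se = FALSE,
                      act = c("relu", "hswish")) {
  act <- match.arg(act)
  self <- new_module("invres")
  self$skip <- (stride == 1L && cin == cout)
  mods <- list()
  if (expc != cin) {
    mods <- c(mods, list(nn_conv(cin, expc, 1), nn_bn(expc), nn_act(act)))
  }
  mods <- c(mods, list(nn_dw(expc, k, stride), nn_bn(expc), nn_act(act)))
  if (se) {
    csq <- make_divisible(expc / 4, 8)
    mods <- c(mods, list(nn_se(expc, csq)))
  }
  proj_bn <- nn_bn(cout)
  ## zero-init the projection gain when a skip exists, so the block starts
  ## as an identity map (standard residual initialisation)
  if (self$skip) proj_bn$gamma <- rep(0, cout)
  mods <- c(mods, list(nn_conv(expc, cout, 1), proj_bn))
  self$body <- nn_seq()
  self$body$children <- mods
  self$children <- list(self$body)
  self$fwd <- function(t, mode) {
    y <- self$body$fwd(t, mode)
    if (self$skip) y$x <- y$x + t$x
    y
  }
  self$bwd <- function(dt) {
    dx <- self$body$bwd(dt)
    if (self$skip) dx$x <- dx$x + dt$x
    dx
  }
  self
}

## Round channel counts to multiples of `divisor`, never dropping below 90%
## of the requested value (MobileNet convention).
make_divisible <- function(v, divisor = 8, min_value = divisor) {
  new_v <- max(min_value, as.integer(v + divisor / 2) %/% divisor * divisor)
  if (new_v < 0.9 * v) new_v <- new_v + divisor
  as.integer(new_v)
}

## Mark every parameter of a module (sub)tree as frozen: excluded from
## count_parameters() and skipped by the optimiser.
freeze_module <- function(self) {
  self$trainable <- FALSE
  for (ch in self$children) freeze_module(ch)
  invisible(self)
}
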