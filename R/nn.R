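# Numerical engine for the multitask Siamese network.
#
# Feature maps are stored as (H*W*T) x C matrices, row order: pixel (row
# fastest, then column) fastest, then frame. `array(X, c(H, W, T, C))`
# recovers the 4-D view. Both ROI streams are stacked along the frame axis
# (frames 1..T forehead, T+1..2T cheek) so every per-frame operation runs
# once through BLAS for the whole Siamese pair; weight sharing between the
# two branches is therefore structural, not copied.

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Leaky rectified linear unit
#'
#' Elementwise `x` for `x >= 0`, `alpha * x` otherwise.
#'
#' @param x Numeric scalar, vector or array.
#' @param alpha Negative-side slope (default 0.01).
#' @return Same shape as `x`.
#' @export
leaky_relu <- function(x, alpha = 0.01) {
  # branch-free: x for x >= 0, alpha*x otherwise
  0.5 * (1 + alpha) * x + 0.5 * (1 - alpha) * abs(x)
}

# d/dx leaky_relu at cached pre-activation sign
leaky_relu_grad <- function(pre, dy, alpha = 0.01) {
  dy * (alpha + (1 - alpha) * (pre >= 0))
}

# Index tables for a k x k same-padded convolution over an H x W grid.
# `nidx[p, tap]` is the linear index into the padded (Hp x Wp) plane feeding
# output pixel p through that tap; `interior` are the unpadded rows.
# Convolution weights are stored as a (k^2 * Cin) x Cout matrix with rows
# ordered channel-fastest within tap.
conv_meta <- function(H, W, k) {
  list(H = H, W = W, k = as.integer(k), pad = (as.integer(k) - 1L) %/% 2L)
}

# Same-padded k x k convolution of X: (H*W*T) x C, direct compiled kernel.
# The input is returned alongside Y because the backward pass needs it for
# the weight gradient.
conv2d_forward <- function(X, meta, TT, Wmat, b) {
  list(Y = conv2d_fwd_cpp(X, meta$H, meta$W, TT, meta$k, Wmat, b), Xin = X)
}

conv2d_backward <- function(dY, Xin, meta, TT, Wmat, Cin) {
  conv2d_bwd_cpp(Xin, dY, meta$H, meta$W, TT, meta$k, Wmat)
}

# ---- CBAM channel attention ------------------------------------------------

# descriptors and gates for X (HW*TT) x C; returns gates (TT x C) + cache
channel_attention_forward <- function(X, HW, TT, W1, b1, W2, b2) {
  C <- ncol(X)
  arr <- array(X, c(HW, TT, C))
  avg <- colMeans(arr)                               # TT x C
  if (TT == 1L) avg <- matrix(avg, 1L, C)
  Xm <- matrix(X, HW)                                # HW x (TT*C)
  mi <- max.col(t(Xm), ties.method = "first")        # argmax pixel per (t,c)
  mx <- matrix(Xm[mi + (seq_len(TT * C) - 1L) * HW], TT, C)
  Za <- avg %*% W1 + rep(b1, each = TT)
  Zm <- mx %*% W1 + rep(b1, each = TT)
  Ha <- pmax(Za, 0); Hm <- pmax(Zm, 0)
  S <- Ha %*% W2 + Hm %*% W2 + rep(2 * b2, each = TT)
  g <- sigmoid(S)                                    # TT x C
  Y <- X * rep(g, each = HW)[seq_len(HW * TT * C)]
  dim(Y) <- dim(X)
  list(Y = Y, g = g, avg = avg, mx = mx, mi = mi, Za = Za, Zm = Zm,
       Ha = Ha, Hm = Hm)
}

channel_attention_backward <- function(dY, X, HW, TT, cache, W1, W2) {
  C <- ncol(X)
  gfull <- rep(cache$g, each = HW)[seq_len(HW * TT * C)]
  dX <- dY * gfull
  dim(dX) <- dim(X)
  prod_arr <- array(dY * X, c(HW, TT, C))
  dg <- colMeans(prod_arr) * HW                      # sum over pixels
  if (TT == 1L) dg <- matrix(dg, 1L, C)
  dS <- dg * cache$g * (1 - cache$g)
  dHa <- dS %*% t(W2); dHm <- dS %*% t(W2)
  dZa <- dHa * (cache$Za > 0); dZm <- dHm * (cache$Zm > 0)
  dW1 <- crossprod(cache$avg, dZa) + crossprod(cache$mx, dZm)
  db1 <- colSums(dZa) + colSums(dZm)
  dW2 <- crossprod(cache$Ha, dS) + crossprod(cache$Hm, dS)
  db2 <- 2 * colSums(dS)
  davg <- dZa %*% t(W1)                              # TT x C
  dmx <- dZm %*% t(W1)
  # average path spreads uniformly over pixels
  dX <- dX + rep(davg / HW, each = HW)[seq_len(HW * TT * C)]
  # max path routes to the argmax pixel of each (frame, channel)
  dXm <- matrix(0, HW, TT * C)
  dXm[cache$mi + (seq_len(TT * C) - 1L) * HW] <- as.vector(dmx)
  dim(dX) <- c(HW * TT, C)
  dX <- dX + matrix(dXm, HW * TT, C)
  list(dX = dX, dW1 = dW1, db1 = db1, dW2 = dW2, db2 = db2)
}

# ---- CBAM spatial attention ------------------------------------------------

spatial_attention_forward <- function(X, meta, TT, Wsa, bsa) {
  C <- ncol(X)
  meanmap <- rowMeans(X)
  maxv <- X[, 1L]
  argc <- rep(1L, length(maxv))
  if (C > 1L) for (ch in 2:C) {
    upd <- X[, ch] > maxv
    maxv[upd] <- X[upd, ch]
    argc[upd] <- ch
  }
  Z <- cbind(meanmap, maxv, deparse.level = 0)       # (HW*TT) x 2
  cv <- conv2d_forward(Z, meta, TT, Wsa, bsa)
  g <- sigmoid(cv$Y[, 1L])                           # per (pixel, frame)
  Y <- X * g
  list(Y = Y, g = g, argc = argc, Z = cv$Xin)
}

spatial_attention_backward <- function(dY, X, meta, TT, cache, Wsa) {
  C <- ncol(X)
  dX <- dY * cache$g
  dgv <- rowSums(dY * X)
  ds <- matrix(dgv * cache$g * (1 - cache$g), ncol = 1L)
  cb <- conv2d_backward(ds, cache$Z, meta, TT, Wsa, 2L)
  dmean <- cb$dX[, 1L]; dmax <- cb$dX[, 2L]
  dX <- dX + dmean / C
  dX[cbind(seq_along(cache$argc), cache$argc)] <-
    dX[cbind(seq_along(cache$argc), cache$argc)] + dmax
  list(dX = dX, dW = cb$dW, db = cb$db)
}

# ---- 2x2 max pooling (H, W even) -------------------------------------------

maxpool_forward <- function(X, H, W, TT) {
  C <- ncol(X)
  arr <- array(X, c(H, W, TT, C))
  io <- seq(1L, H, 2L); jo <- seq(1L, W, 2L)
  cand <- list(arr[io, jo, , , drop = FALSE],
               arr[io + 1L, jo, , , drop = FALSE],
               arr[io, jo + 1L, , , drop = FALSE],
               arr[io + 1L, jo + 1L, , , drop = FALSE])
  Y <- pmax(cand[[1]], cand[[2]], cand[[3]], cand[[4]])
  masks <- vector("list", 4L)
  taken <- array(FALSE, dim(Y))
  for (k in 1:4) {
    m <- (cand[[k]] == Y) & !taken
    masks[[k]] <- m
    taken <- taken | m
  }
  list(Y = matrix(Y, nrow = (H %/% 2L) * (W %/% 2L) * TT), masks = masks,
       Ho = H %/% 2L, Wo = W %/% 2L)
}

maxpool_backward <- function(dY, pool, H, W, TT, C) {
  dYa <- array(dY, c(pool$Ho, pool$Wo, TT, C))
  dArr <- array(0, c(H, W, TT, C))
  io <- seq(1L, H, 2L); jo <- seq(1L, W, 2L)
  dArr[io, jo, , ] <- dYa * pool$masks[[1]]
  dArr[io + 1L, jo, , ] <- dYa * pool$masks[[2]]
  dArr[io, jo + 1L, , ] <- dYa * pool$masks[[3]]
  dArr[io + 1L, jo + 1L, , ] <- dYa * pool$masks[[4]]
  matrix(dArr, nrow = H * W * TT)
}

# ---- public single-map attention ops ---------------------------------------

#' CBAM channel-attention gates for one feature map
#'
#' Average- and max-pooled channel descriptors pass through a shared
#' two-layer bottleneck (ReLU in the middle); the summed outputs are squashed
#' by a sigmoid, giving one multiplicative gate per channel, strictly in
#' (0, 1).
#'
#' @param features `h x w x c` numeric array.
#' @param params List with `W1` (`c x h`), `b1`, `W2` (`h x c`), `b2`; if
#'   omitted, zero weights are used (all gates 0.5).
#' @param reduction_ratio Bottleneck reduction (default 8, >= 1).
#' @return Numeric vector of `c` gates in (0, 1).
#' @export
channel_attention <- function(features, params = NULL, reduction_ratio = 8) {
  stopifnot(length(dim(features)) == 3L)
  if (reduction_ratio < 1) stop("reduction_ratio must be >= 1")
  d <- dim(features); C <- d[3]
  hidden <- max(1L, as.integer(round(C / reduction_ratio)))
  if (is.null(params)) {
    params <- list(W1 = matrix(0, C, hidden), b1 = numeric(hidden),
                   W2 = matrix(0, hidden, C), b2 = numeric(C))
  }
  X <- matrix(aperm(features, c(1, 2, 3)), nrow = d[1] * d[2])  # (hw) x c
  out <- channel_attention_forward(X, d[1] * d[2], 1L, params$W1, params$b1,
                                   params$W2, params$b2)
  as.numeric(out$g)
}

#' CBAM spatial-attention gates for one feature map
#'
#' Channel-wise mean and max maps are stacked and convolved with a single
#' `kernel_size x kernel_size` filter (same padding); the sigmoid of the
#' result is a per-location gate in (0, 1).
#'
#' @param features `h x w x c` numeric array.
#' @param params List with `W` (`kernel_size^2 * 2 x 1`) and `b`; zero
#'   weights (gates 0.5) if omitted.
#' @param kernel_size Odd convolution kernel size (default 7).
#' @return `h x w` matrix of gates in (0, 1).
#' @export
spatial_attention <- function(features, params = NULL, kernel_size = 7) {
  stopifnot(length(dim(features)) == 3L, kernel_size %% 2 == 1)
  d <- dim(features)
  if (is.null(params)) {
    params <- list(W = matrix(0, 2 * kernel_size^2, 1), b = 0)
  }
  meta <- conv_meta(d[1], d[2], as.integer(kernel_size))
  X <- matrix(features, nrow = d[1] * d[2])
  out <- spatial_attention_forward(X, meta, 1L, params$W, params$b)
  matrix(out$g, d[1], d[2])
}
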