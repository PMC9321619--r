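#' Architecture hyperparameters for the multitask Siamese network
#'
#' The network has two identical branches (forehead and cheek) that share one
#' parameter set. Each branch stage applies: 3x3 convolution (same padding)
#' -> leaky ReLU -> 1x1 channel-reducing convolution -> leaky ReLU -> CBAM
#' channel attention -> CBAM spatial attention -> optional 2x2 max pooling.
#' A per-frame dense readout (flatten -> 1) inside the branch turns each
#' frame into one sample; the two branch traces are merged by elementwise
#' addition to give the PPG output (no dense layer after the Add). In
#' multitask mode the added per-frame feature vectors pass through dropout
#' and one dense layer to give the respiration trace.
#'
#' The default widths are frozen so that the trainable-parameter total lands
#' on the published budgets: 722,892 (multitask, prints as 0.72 M) and
#' 692,791 for the single-task variant (prints as 0.69 M).
#'
#' @param n_frames Frames per clip, T (default 600).
#' @param roi_shape `(height, width, channels)` of each ROI (default
#'   `c(40, 140, 3)`).
#' @param conv_filters Per-stage 3x3 convolution output channels.
#' @param reduce_filters Per-stage 1x1 convolution output channels.
#' @param pool Logical per stage: 2x2 max pooling after the stage.
#' @param cbam_ratio Channel-attention bottleneck reduction ratio.
#' @param spatial_kernel Spatial-attention kernel size (odd).
#' @param leaky_alpha Leaky-ReLU negative slope (> 0, default 0.01).
#' @param dropout_rates Ordered shallow-to-deep: after stage 2, before the
#'   PPG readout, before the respiration head (defaults 0.25, 0.5, 0.6).
#' @param multitask Build the respiration head (TRUE) or the single-task
#'   PPG-only variant (FALSE).
#' @param budget_m Optional parameter budget in millions; construction warns
#'   if the realised count deviates from it by more than 10%. `NULL`
#'   disables the check (used for reduced experimental specs).
#' @return List of class `model_spec`.
#' @export
model_spec <- function(n_frames = 600L, roi_shape = c(40L, 140L, 3L),
                       conv_filters = c(32L, 128L, 500L),
                       reduce_filters = c(16L, 128L, 86L),
                       pool = c(TRUE, TRUE, FALSE),
                       cbam_ratio = 8L, spatial_kernel = 7L,
                       leaky_alpha = 0.01,
                       dropout_rates = c(0.25, 0.5, 0.6),
                       multitask = TRUE,
                       budget_m = if (multitask) 0.72 else 0.69) {
  stopifnot(n_frames >= 1, length(roi_shape) == 3L, all(roi_shape >= 1),
            length(conv_filters) == length(reduce_filters),
            length(pool) == length(conv_filters),
            all(conv_filters >= 1), all(reduce_filters >= 1),
            cbam_ratio >= 1, spatial_kernel %% 2 == 1,
            leaky_alpha > 0, length(dropout_rates) == 3L,
            all(dropout_rates >= 0), all(dropout_rates < 1))
  H <- roi_shape[1]; W <- roi_shape[2]
  for (s in seq_along(pool)) {
    if (pool[s]) {
      if (H %% 2L != 0L || W %% 2L != 0L) {
        stop(sprintf("stage %d pooling needs even spatial dims, got %dx%d",
                     s, H, W))
      }
      H <- H %/% 2L; W <- W %/% 2L
    }
  }
  structure(list(n_frames = as.integer(n_frames),
                 roi_shape = as.integer(roi_shape),
                 conv_filters = as.integer(conv_filters),
                 reduce_filters = as.integer(reduce_filters),
                 pool = as.logical(pool),
                 cbam_ratio = as.integer(cbam_ratio),
                 spatial_kernel = as.integer(spatial_kernel),
                 leaky_alpha = leaky_alpha,
                 dropout_rates = dropout_rates,
                 multitask = isTRUE(multitask),
                 budget_m = budget_m),
            class = "model_spec")
}

#' Reduced spec for desk-scale experiments
#'
#' Same architecture family at a size a single CPU trains in minutes:
#' 128-frame clips, 32 (w) x 12 (h) ROIs, narrow widths, no budget check.
#'
#' @inheritParams model_spec
#' @param ... Further overrides passed to [model_spec()].
#' @return A `model_spec`.
#' @export
reduced_model_spec <- function(n_frames = 128L, roi_shape = c(12L, 32L, 3L),
                               conv_filters = c(8L, 12L, 16L),
                               reduce_filters = c(4L, 6L, 8L),
                               multitask = TRUE, ...) {
  model_spec(n_frames = n_frames, roi_shape = roi_shape,
             conv_filters = conv_filters, reduce_filters = reduce_filters,
             multitask = multitask, budget_m = NULL, ...)
}

glorot <- function(nr, nc, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

# spatial dims and layer index tables for each stage
stage_geometry <- function(spec) {
  H <- spec$roi_shape[1]; W <- spec$roi_shape[2]
  geom <- vector("list", length(spec$conv_filters))
  for (s in seq_along(geom)) {
    geom[[s]] <- list(
      H = H, W = W,
      conv = conv_meta(H, W, 3L),
      sa = conv_meta(H, W, spec$spatial_kernel)
    )
    if (spec$pool[s]) { H <- H %/% 2L; W <- W %/% 2L }
  }
  attr(geom, "final") <- c(H = H, W = W)
  geom
}

#' Build the multitask Siamese network
#'
#' Allocates and initialises one shared parameter set (Glorot-uniform
#' weights, zero biases, seeded) plus the geometry tables the forward and
#' backward passes reuse. Both branches reference this single set, so weight
#' sharing holds by construction for any number of optimisation steps.
#'
#' @param spec A [model_spec()].
#' @param seed Integer seed for the initialisation draw.
#' @return Object of class `siam_model`: `spec`, `params` (named list of
#'   arrays), `geom`.
#' @export
build_model <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "model_spec"))
  geom <- stage_geometry(spec)
  fin <- attr(geom, "final")
  cin <- spec$roi_shape[3]
  params <- list()
  with_local_seed(seed, {
    for (s in seq_along(spec$conv_filters)) {
      co <- spec$conv_filters[s]; rd <- spec$reduce_filters[s]
      hid <- max(1L, as.integer(round(rd / spec$cbam_ratio)))
      k2s <- spec$spatial_kernel^2
      params[[sprintf("s%d.conv.W", s)]] <-
        glorot(9L * cin, co, 9L * cin, 9L * co)
      params[[sprintf("s%d.conv.b", s)]] <- numeric(co)
      params[[sprintf("s%d.red.W", s)]] <- glorot(co, rd, co, rd)
      params[[sprintf("s%d.red.b", s)]] <- numeric(rd)
      params[[sprintf("s%d.ca.W1", s)]] <- glorot(rd, hid, rd, hid)
      params[[sprintf("s%d.ca.b1", s)]] <- numeric(hid)
      params[[sprintf("s%d.ca.W2", s)]] <- glorot(hid, rd, hid, rd)
      params[[sprintf("s%d.ca.b2", s)]] <- numeric(rd)
      params[[sprintf("s%d.sa.W", s)]] <-
        glorot(2L * k2s, 1L, 2L * k2s, k2s)
      params[[sprintf("s%d.sa.b", s)]] <- 0
      cin <- rd
    }
    d <- fin["H"] * fin["W"] * cin
    params[["ppg.W"]] <- as.numeric(glorot(d, 1L, d, 1L))
    params[["ppg.b"]] <- 0
    if (spec$multitask) {
      params[["resp.W"]] <- as.numeric(glorot(d, 1L, d, 1L))
      params[["resp.b"]] <- 0
    }
  })
  model <- structure(list(spec = spec, params = params, geom = geom),
                     class = "siam_model")
  if (!is.null(spec$budget_m)) {
    got <- count_parameters(model)
    if (abs(got - spec$budget_m * 1e6) > 0.1 * spec$budget_m * 1e6) {
      warning(sprintf(
        "parameter count %d deviates >10%% from the %.2f M budget",
        got, spec$budget_m))
    }
  }
  model
}

#' Count trainable parameters, shared weights counted once
#'
#' Both Siamese branches reference the same parameter arrays, so the count
#' is simply the total length of the single shared set.
#'
#' @param model A `siam_model`.
#' @return Integer scalar.
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "siam_model"))
  sum(vapply(model$params, length, numeric(1)))
}

#' @export
print.siam_model <- function(x, ...) {
  cat(sprintf("<siam_model> %s  T=%d  ROI %dx%dx%d  params=%s\n",
              if (x$spec$multitask) "multitask" else "single-task",
              x$spec$n_frames, x$spec$roi_shape[1], x$spec$roi_shape[2],
              x$spec$roi_shape[3],
              format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

# (T,H,W,C) array or roi_stream -> (H*W*T) x C feature matrix
as_feature_matrix <- function(x, spec) {
  if (inherits(x, "roi_stream")) x <- x$pixels
  d <- dim(x)
  stopifnot(length(d) == 4L)
  if (!all(d[2:4] == spec$roi_shape)) {
    stop(sprintf("ROI shape %dx%dx%d does not match spec %dx%dx%d",
                 d[2], d[3], d[4],
                 spec$roi_shape[1], spec$roi_shape[2], spec$roi_shape[3]))
  }
  arr <- aperm(x, c(2, 3, 1, 4))                    # (H, W, T, C)
  matrix(arr, nrow = d[2] * d[3] * d[1])
}

drop_mask <- function(n, rate) {
  (stats::runif(n) >= rate) / (1 - rate)
}

# Forward pass over the stacked Siamese pair. Returns predictions and, when
# `keep_cache`, everything the backward pass needs. Dropout (training only)
# draws from the current RNG stream.
mts_forward <- function(model, Xf, Xc, training = FALSE, keep_cache = FALSE) {
  spec <- model$spec; pm <- model$params
  TT1 <- nrow(Xf) / (spec$roi_shape[1] * spec$roi_shape[2])
  X <- rbind(Xf, Xc)
  TT <- 2L * TT1
  cin <- spec$roi_shape[3]
  caches <- vector("list", length(spec$conv_filters))
  for (s in seq_along(spec$conv_filters)) {
    g <- model$geom[[s]]
    HW <- g$H * g$W
    cv <- conv2d_forward(X, g$conv, TT, pm[[sprintf("s%d.conv.W", s)]],
                         pm[[sprintf("s%d.conv.b", s)]])
    A1 <- leaky_relu(cv$Y, spec$leaky_alpha)
    Rpre <- A1 %*% pm[[sprintf("s%d.red.W", s)]]
    Rpre <- Rpre + rep(pm[[sprintf("s%d.red.b", s)]], each = nrow(Rpre))
    A2 <- leaky_relu(Rpre, spec$leaky_alpha)
    ca <- channel_attention_forward(A2, HW, TT,
                                    pm[[sprintf("s%d.ca.W1", s)]],
                                    pm[[sprintf("s%d.ca.b1", s)]],
                                    pm[[sprintf("s%d.ca.W2", s)]],
                                    pm[[sprintf("s%d.ca.b2", s)]])
    sa <- spatial_attention_forward(ca$Y, g$sa, TT,
                                    pm[[sprintf("s%d.sa.W", s)]],
                                    pm[[sprintf("s%d.sa.b", s)]])
    Xs <- sa$Y
    pl <- NULL
    if (spec$pool[s]) {
      pl <- maxpool_forward(Xs, g$H, g$W, TT)
      Xs <- pl$Y
    }
    dmask <- NULL
    if (s == 2L && training && spec$dropout_rates[1] > 0) {
      dmask <- drop_mask(length(Xs), spec$dropout_rates[1])
      Xs <- Xs * dmask
    }
    caches[[s]] <- if (keep_cache) {
      list(Xin = X, A1pre = cv$Y, A1 = A1, Rpre = Rpre,
           A2 = A2, ca = ca, caY = ca$Y, sa = sa, pool = pl, dmask = dmask)
    } else NULL
    X <- Xs
    cin <- spec$reduce_filters[s]
  }
  fin <- attr(model$geom, "final")
  HWf <- fin["H"] * fin["W"]
  Cf <- spec$reduce_filters[length(spec$reduce_filters)]
  arr <- array(X, c(HWf, TT, Cf))
  Vall <- matrix(aperm(arr, c(1, 3, 2)), nrow = HWf * Cf)   # d x 2T
  mask_v <- NULL
  Vd <- Vall
  if (training && spec$dropout_rates[2] > 0) {
    mask_v <- drop_mask(length(Vall), spec$dropout_rates[2])
    Vd <- Vall * mask_v
  }
  p_all <- as.numeric(crossprod(Vd, pm[["ppg.W"]])) + pm[["ppg.b"]]
  ppg <- p_all[seq_len(TT1)] + p_all[TT1 + seq_len(TT1)]
  resp <- NULL; Md <- NULL; mask_m <- NULL
  if (spec$multitask) {
    M <- Vall[, seq_len(TT1), drop = FALSE] +
      Vall[, TT1 + seq_len(TT1), drop = FALSE]
    Md <- M
    if (training && spec$dropout_rates[3] > 0) {
      mask_m <- drop_mask(length(M), spec$dropout_rates[3])
      Md <- M * mask_m
    }
    resp <- as.numeric(crossprod(Md, pm[["resp.W"]])) + pm[["resp.b"]]
  }
  out <- list(ppg = ppg, resp = resp)
  if (keep_cache) {
    out$cache <- list(stages = caches, Vall = Vall, Vd = Vd, Md = Md,
                      mask_v = mask_v, mask_m = mask_m, TT = TT, TT1 = TT1,
                      HWf = HWf, Cf = Cf)
  }
  out
}

# Backward pass. dppg/dresp are gradients of the loss w.r.t. the two output
# traces. Returns a named gradient list congruent with model$params; shared
# parameters receive the sum of both branches' contributions automatically
# because the branches are one stacked batch.
mts_backward <- function(model, cache, dppg, dresp = NULL) {
  spec <- model$spec; pm <- model$params
  TT <- cache$TT; TT1 <- cache$TT1
  gr <- list()
  dp_all <- c(dppg, dppg)
  gr[["ppg.W"]] <- as.numeric(cache$Vd %*% dp_all)
  gr[["ppg.b"]] <- sum(dp_all)
  dVall <- outer(pm[["ppg.W"]], dp_all)
  if (!is.null(cache$mask_v)) dVall <- dVall * cache$mask_v
  if (spec$multitask && !is.null(dresp)) {
    gr[["resp.W"]] <- as.numeric(cache$Md %*% dresp)
    gr[["resp.b"]] <- sum(dresp)
    dMd <- outer(pm[["resp.W"]], dresp)
    if (!is.null(cache$mask_m)) dMd <- dMd * cache$mask_m
    dVall <- dVall + cbind(dMd, dMd)
  } else if (spec$multitask) {
    gr[["resp.W"]] <- numeric(length(pm[["resp.W"]]))
    gr[["resp.b"]] <- 0
  }
  arrV <- array(dVall, c(cache$HWf, cache$Cf, TT))
  dX <- matrix(aperm(arrV, c(1, 3, 2)), nrow = cache$HWf * TT)
  for (s in rev(seq_along(spec$conv_filters))) {
    g <- model$geom[[s]]
    st <- cache$stages[[s]]
    C <- spec$reduce_filters[s]
    if (!is.null(st$dmask)) dX <- dX * st$dmask
    if (spec$pool[s]) {
      dX <- maxpool_backward(dX, st$pool, g$H, g$W, TT, C)
    }
    sb <- spatial_attention_backward(dX, st$caY, g$sa, TT, st$sa,
                                     pm[[sprintf("s%d.sa.W", s)]])
    gr[[sprintf("s%d.sa.W", s)]] <- sb$dW
    gr[[sprintf("s%d.sa.b", s)]] <- sb$db
    cb <- channel_attention_backward(sb$dX, st$A2, g$H * g$W, TT, st$ca,
                                     pm[[sprintf("s%d.ca.W1", s)]],
                                     pm[[sprintf("s%d.ca.W2", s)]])
    gr[[sprintf("s%d.ca.W1", s)]] <- cb$dW1
    gr[[sprintf("s%d.ca.b1", s)]] <- cb$db1
    gr[[sprintf("s%d.ca.W2", s)]] <- cb$dW2
    gr[[sprintf("s%d.ca.b2", s)]] <- cb$db2
    dA2 <- leaky_relu_grad(st$Rpre, cb$dX, spec$leaky_alpha)
    gr[[sprintf("s%d.red.W", s)]] <- crossprod(st$A1, dA2)
    gr[[sprintf("s%d.red.b", s)]] <- colSums(dA2)
    dA1 <- dA2 %*% t(pm[[sprintf("s%d.red.W", s)]])
    dA1 <- leaky_relu_grad(st$A1pre, dA1, spec$leaky_alpha)
    cin <- if (s == 1L) spec$roi_shape[3] else spec$reduce_filters[s - 1L]
    cvb <- conv2d_backward(dA1, st$Xin, g$conv, TT,
                           pm[[sprintf("s%d.conv.W", s)]], cin)
    gr[[sprintf("s%d.conv.W", s)]] <- cvb$dW
    gr[[sprintf("s%d.conv.b", s)]] <- cvb$db
    dX <- cvb$dX
  }
  gr
}

#' Predict PPG and respiration traces for one clip
#'
#' Runs the Siamese forward pass in evaluation mode (no dropout). Feeding
#' the two ROI streams in either order gives the identical PPG trace because
#' the branches share weights and the merge is an elementwise addition.
#'
#' @param object A `siam_model`.
#' @param forehead,cheek [roi_stream()]s or `(T, h, w, c)` arrays matching
#'   the spec's ROI shape.
#' @param fps Sampling rate to stamp on the output traces; taken from
#'   `forehead` when it is an `roi_stream`.
#' @param ... Unused.
#' @return List with `ppg` and (multitask only) `resp` as [vital_trace()]s
#'   of length T.
#' @export
predict.siam_model <- function(object, forehead, cheek, fps = NULL, ...) {
  if (is.null(fps)) {
    fps <- if (inherits(forehead, "roi_stream")) forehead$fps else 20
  }
  Xf <- as_feature_matrix(forehead, object$spec)
  Xc <- as_feature_matrix(cheek, object$spec)
  out <- mts_forward(object, Xf, Xc, training = FALSE)
  res <- list(ppg = vital_trace(out$ppg, fps, "ppg"))
  if (object$spec$multitask) {
    res$resp <- vital_trace(out$resp, fps, "respiration")
  }
  res
}
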