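#' Pearson correlation between two equal-length signals
#'
#' Centred cross-correlation normalised by the product of centred norms.
#' If either input is constant the correlation is undefined; the value 0 is
#' returned with attribute `degenerate = TRUE` so callers can keep a training
#' loop alive on pathological batches while still seeing the flag.
#'
#' @param x,y Numeric vectors of equal length N >= 2.
#' @return Scalar in \[-1, 1\], possibly carrying attribute `degenerate`.
#' @export
pearson_r <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 2L) stop("need at least 2 samples")
  xc <- x - mean(x); yc <- y - mean(y)
  nx <- sqrt(sum(xc^2)); ny <- sqrt(sum(yc^2))
  if (nx == 0 || ny == 0) {
    return(structure(0, degenerate = TRUE))
  }
  r <- sum(xc * yc) / (nx * ny)
  max(-1, min(1, r))
}

#' Negative-Pearson loss: 1 - r(x, y), bounded in \[0, 2\]
#'
#' Invariant under positive affine rescaling of either argument, which makes
#' it a natural objective for traces whose absolute scale is arbitrary
#' (camera-derived signals carry no calibrated amplitude).
#'
#' @inheritParams pearson_r
#' @return Scalar in \[0, 2\] (1 with attribute `degenerate` if an input is
#'   constant).
#' @export
pearson_loss <- function(x, y) {
  r <- pearson_r(x, y)
  out <- 1 - as.numeric(r)
  if (isTRUE(attr(r, "degenerate"))) attr(out, "degenerate") <- TRUE
  out
}

#' Weighted multitask loss over PPG and respiration traces
#'
#' @param pred List with numeric elements `ppg` and (optionally) `resp`.
#' @param truth List with numeric elements `ppg` and `resp` matching `pred`
#'   lengths.
#' @param weights Length-2 nonnegative vector `c(w_ppg, w_resp)`, not both
#'   zero.
#' @return List of class `loss_value`: `total` and `per_task` (named map of
#'   per-task Pearson losses, each in \[0, 2\]).
#' @export
multitask_loss <- function(pred, truth, weights = c(1, 1)) {
  stopifnot(length(weights) == 2L, all(weights >= 0), any(weights > 0))
  per <- c(ppg = as.numeric(pearson_loss(truth$ppg, pred$ppg)))
  if (!is.null(pred$resp)) {
    if (length(pred$resp) != length(truth$resp)) {
      stop("respiration prediction/truth length mismatch")
    }
    per <- c(per, resp = as.numeric(pearson_loss(truth$resp, pred$resp)))
  }
  w <- weights[seq_along(per)]
  structure(list(total = sum(w * per), per_task = per),
            class = "loss_value")
}

#' Training configuration
#'
#' Defaults follow the published optimisation recipe: Adam with learning rate
#' 1e-4, beta1 = 0.9, beta2 = 0.999, batch size one, and an epoch budget of
#' 250 read as an upper bound ("within 250 epochs"); clips are split
#' train:val:test at 3:1:1.
#'
#' @param learning_rate Adam step size.
#' @param beta1,beta2 Adam exponential decay rates for the moment estimates.
#' @param max_epochs Upper bound on training epochs.
#' @param batch_size Clips per gradient step (the published recipe uses 1).
#' @param loss_weights Nonnegative `c(w_ppg, w_resp)`.
#' @param split_ratio Positive length-3 vector, train:val:test.
#' @param seed Integer seed controlling shuffling, init and dropout.
#' @return List of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, beta1 = 0.9, beta2 = 0.999,
                         max_epochs = 250L, batch_size = 1L,
                         loss_weights = c(1, 1), split_ratio = c(3, 1, 1),
                         seed = 1L) {
  stopifnot(learning_rate > 0, beta1 > 0, beta1 < 1, beta2 > 0, beta2 < 1,
            max_epochs >= 1, batch_size >= 1,
            length(loss_weights) == 2L, all(loss_weights >= 0),
            any(loss_weights > 0),
            length(split_ratio) == 3L, all(split_ratio > 0))
  structure(list(learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 loss_weights = loss_weights, split_ratio = split_ratio,
                 seed = as.integer(seed)),
            class = "train_config")
}
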