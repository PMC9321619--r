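# Gradient of the negative-Pearson loss L = 1 - r(x, y) w.r.t. the
# prediction y. Because the centred reference xc sums to zero, the mean
# term drops and dL/dy_i = -(xc_i/(nx*ny) - r*yc_i/ny^2). Constant
# predictions (ny = 0) get a zero gradient, mirroring the r = 0 fallback.
pearson_loss_grad <- function(x, y) {
  xc <- x - mean(x); yc <- y - mean(y)
  nx <- sqrt(sum(xc^2)); ny <- sqrt(sum(yc^2))
  if (nx == 0 || ny == 0) return(numeric(length(y)))
  r <- sum(xc * yc) / (nx * ny)
  -(xc / (nx * ny) - r * yc / ny^2)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(params, grads, state, lr, beta1, beta2, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

as_train_item <- function(clip, spec) {
  list(Xf = as_feature_matrix(clip$forehead, spec),
       Xc = as_feature_matrix(clip$cheek, spec),
       ppg = clip$ppg_truth$samples,
       resp = clip$resp_truth$samples)
}

#' Split clip indices train:val:test
#'
#' Clips are shuffled with the given seed and assigned by the floor of each
#' proportion; remainder clips go to the training split.
#'
#' @param n Number of clips.
#' @param ratio Positive length-3 vector (default 3:1:1).
#' @param seed Integer seed for the shuffle.
#' @return List of integer index vectors `train`, `val`, `test`.
#' @export
split_clips <- function(n, ratio = c(3, 1, 1), seed = 1L) {
  stopifnot(n >= 0, length(ratio) == 3L, all(ratio > 0))
  idx <- with_local_seed(seed, sample.int(n))
  base <- floor(n * ratio / sum(ratio))
  base[1] <- n - base[2] - base[3]
  list(train = sort(idx[seq_len(base[1])]),
       val = sort(idx[base[1] + seq_len(base[2])]),
       test = sort(idx[base[1] + base[2] + seq_len(base[3])]))
}

#' Train the Siamese network with Adam
#'
#' One gradient step per clip (batch size one), negative-Pearson loss per
#' task combined with the configured weights. Per-epoch training and
#' validation losses are logged; the parameter set with the lowest
#' validation total (or training total when no validation clips are given)
#' is retained in the returned model. Two fits with identical inputs and
#' seed produce identical histories and parameters.
#'
#' @param model A `siam_model` from [build_model()].
#' @param clips List of `synthetic_clip`-like objects (fields `forehead`,
#'   `cheek`, `ppg_truth`, `resp_truth`).
#' @param config A [train_config()].
#' @param val_clips Optional held-out clips for model selection.
#' @param epochs Number of epochs; defaults to `config$max_epochs`.
#' @param verbose Print per-epoch losses.
#' @return List of class `fit_result`: `model` (best parameters), `history`
#'   (data.frame), `best_epoch`.
#' @export
fit_model <- function(model, clips, config = train_config(),
                      val_clips = NULL, epochs = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "siam_model"), inherits(config, "train_config"))
  if (length(clips) == 0L) stop("empty training set")
  epochs <- as.integer(epochs %||% config$max_epochs)
  spec <- model$spec
  items <- lapply(clips, as_train_item, spec = spec)
  vitems <- lapply(val_clips %||% list(), as_train_item, spec = spec)
  w <- config$loss_weights
  state <- adam_init(model$params)
  hist <- vector("list", epochs)
  best <- list(score = Inf, params = model$params, epoch = 0L)
  eval_loss <- function(its) {
    tot <- c(total = 0, ppg = 0, resp = 0)
    for (it in its) {
      fw <- mts_forward(model, it$Xf, it$Xc, training = FALSE)
      lp <- as.numeric(pearson_loss(it$ppg, fw$ppg))
      lr_ <- if (spec$multitask) {
        as.numeric(pearson_loss(it$resp, fw$resp))
      } else 0
      tot <- tot + c(w[1] * lp + w[2] * lr_, lp, lr_)
    }
    tot / max(1L, length(its))
  }
  with_local_seed(config$seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(length(items))
      tr <- c(total = 0, ppg = 0, resp = 0)
      for (i in ord) {
        it <- items[[i]]
        fw <- mts_forward(model, it$Xf, it$Xc, training = TRUE,
                          keep_cache = TRUE)
        lp <- as.numeric(pearson_loss(it$ppg, fw$ppg))
        lr_ <- if (spec$multitask) {
          as.numeric(pearson_loss(it$resp, fw$resp))
        } else 0
        total <- w[1] * lp + w[2] * lr_
        if (!is.finite(total)) {
          stop(sprintf("non-finite loss at epoch %d (clip %d)", ep, i))
        }
        tr <- tr + c(total, lp, lr_)
        dppg <- w[1] * pearson_loss_grad(it$ppg, fw$ppg)
        dresp <- if (spec$multitask) {
          w[2] * pearson_loss_grad(it$resp, fw$resp)
        } else NULL
        gr <- mts_backward(model, fw$cache, dppg, dresp)
        upd <- adam_step(model$params, gr, state, config$learning_rate,
                         config$beta1, config$beta2)
        model$params <- upd$params
        state <- upd$state
      }
      tr <- tr / length(items)
      vl <- if (length(vitems) > 0L) eval_loss(vitems) else
        c(total = NA_real_, ppg = NA_real_, resp = NA_real_)
      score <- if (length(vitems) > 0L) vl["total"] else tr["total"]
      if (is.finite(score) && score < best$score) {
        best <- list(score = score, params = model$params, epoch = ep)
      }
      hist[[ep]] <- data.frame(
        epoch = ep, train_total = tr["total"], train_ppg = tr["ppg"],
        train_resp = tr["resp"], val_total = vl["total"],
        val_ppg = vl["ppg"], val_resp = vl["resp"], row.names = NULL)
      if (verbose) {
        message(sprintf("epoch %3d  train %.4f  val %s", ep, tr["total"],
                        ifelse(is.na(vl["total"]), "-",
                               sprintf("%.4f", vl["total"]))))
      }
    }
  })
  model$params <- best$params
  structure(list(model = model, history = do.call(rbind, hist),
                 best_epoch = best$epoch),
            class = "fit_result")
}

#' Per-clip predicted vs. reference rates for a clip set
#'
#' For each clip, the model's predicted PPG and respiration traces and the
#' ground-truth traces are pushed through the same rate estimator
#' ([estimate_rate()]); the paired rates feed [compute_metrics()].
#'
#' @param model A trained `siam_model`.
#' @param clips List of clips with ground-truth traces.
#' @return List with `rates` (data.frame: clip, hr_pred, hr_true, rr_pred,
#'   rr_true) and `metrics` (list with `hr` and `rr` [compute_metrics()]
#'   reports; `rr` is NULL for single-task models).
#' @export
rate_report <- function(model, clips) {
  rows <- lapply(seq_along(clips), function(i) {
    cl <- clips[[i]]
    pr <- predict(model, cl$forehead, cl$cheek)
    hr_p <- estimate_rate(pr$ppg)
    hr_t <- estimate_rate(cl$ppg_truth)
    rr_p <- if (!is.null(pr$resp)) estimate_rate(pr$resp) else NA_real_
    rr_t <- estimate_rate(cl$resp_truth)
    data.frame(clip = i, hr_pred = hr_p, hr_true = hr_t,
               rr_pred = rr_p, rr_true = rr_t)
  })
  rates <- do.call(rbind, rows)
  metrics <- list(hr = compute_metrics(rates$hr_pred, rates$hr_true),
                  rr = if (!anyNA(rates$rr_pred)) {
                    compute_metrics(rates$rr_pred, rates$rr_true)
                  } else NULL)
  list(rates = rates, metrics = metrics)
}
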