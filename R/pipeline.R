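# End-to-end wiring: simulate -> train -> predict -> evaluate. Each command
# writes its resolved configuration and seed next to its outputs so a run
# can be reproduced from its output directory alone.

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Simulate a set of clips to disk
#'
#' @param out_dir Output directory; one `clip_NNN` subdirectory per clip
#'   plus a `manifest.json` listing entries and the resolved configuration.
#' @param n Number of clips.
#' @param base_config [sim_config()] template.
#' @param hr_range,rr_range Per-clip rate ranges passed to
#'   [simulate_clips()].
#' @param seed Integer seed.
#' @return Manifest list, invisibly.
#' @export
cmd_simulate <- function(out_dir, n, base_config = sim_config(),
                         hr_range = c(0.9, 2.4), rr_range = NULL,
                         seed = 1L) {
  clips <- simulate_clips(n, base_config, hr_range, rr_range, seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  entries <- character(0)
  for (i in seq_along(clips)) {
    sub <- sprintf("clip_%03d", i)
    write_clip(clips[[i]], file.path(out_dir, sub))
    entries <- c(entries, sub)
  }
  if (n == 0L) warning("simulated an empty clip set")
  manifest <- list(n = n, entries = entries, seed = seed,
                   base_config = unclass(base_config),
                   hr_range = hr_range, rr_range = rr_range)
  write_json_file(manifest, file.path(out_dir, "manifest.json"))
  invisible(manifest)
}

load_clip_set <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  lapply(man$entries, function(e) read_clip(file.path(dir, e)))
}

#' Train a model on a simulated clip directory or clip list
#'
#' Clips are split train:val:test by clip with a seeded shuffle
#' ([split_clips()]); the model is fitted on the training split with the
#' validation split used for checkpoint selection. The checkpoint, history
#' CSV and resolved configuration are written to `out_dir`.
#'
#' @param clips Clip-set directory (from [cmd_simulate()]) or list of clips.
#' @param spec A [model_spec()].
#' @param config A [train_config()].
#' @param out_dir Output directory.
#' @param epochs Optional epoch override (<= `config$max_epochs`).
#' @return The [fit_model()] result plus the split, invisibly.
#' @export
cmd_train <- function(clips, spec, config = train_config(), out_dir,
                      epochs = NULL) {
  if (is.character(clips)) clips <- load_clip_set(clips)
  if (length(clips) == 0L) stop("no clips to train on")
  sp <- split_clips(length(clips), config$split_ratio, config$seed)
  model <- build_model(spec, seed = config$seed)
  fit <- fit_model(model, clips[sp$train], config,
                   val_clips = if (length(sp$val)) clips[sp$val] else NULL,
                   epochs = epochs)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(fit$model, file.path(out_dir, "checkpoint.rds"))
  utils::write.csv(fit$history, file.path(out_dir, "history.csv"),
                   row.names = FALSE)
  write_json_file(list(spec = unclass(spec), train = unclass(config),
                       split = sp, best_epoch = fit$best_epoch),
                  file.path(out_dir, "run_config.json"))
  invisible(c(fit, list(split = sp)))
}

#' Predict traces for one clip with a trained checkpoint
#'
#' Writes `ppg.csv` (and `resp.csv` for multitask checkpoints) with columns
#' `frame`, `time`, `value`, exactly T rows each.
#'
#' @param checkpoint Path to `checkpoint.rds` or a `siam_model`.
#' @param clip Clip directory (from [cmd_simulate()]) or clip object.
#' @param out_dir Output directory.
#' @return List of predicted [vital_trace()]s, invisibly.
#' @export
cmd_predict <- function(checkpoint, clip, out_dir) {
  model <- if (is.character(checkpoint)) {
    if (!file.exists(checkpoint)) {
      stop("checkpoint not found: ", checkpoint)
    }
    readRDS(checkpoint)
  } else checkpoint
  stopifnot(inherits(model, "siam_model"))
  if (is.character(clip)) clip <- read_clip(clip)
  pr <- predict(model, clip$forehead, clip$cheek)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dump_trace <- function(tr, path) {
    n <- length(tr$samples)
    utils::write.csv(data.frame(frame = seq_len(n) - 1L,
                                time = (seq_len(n) - 1L) / tr$fs,
                                value = tr$samples),
                     path, row.names = FALSE)
  }
  dump_trace(pr$ppg, file.path(out_dir, "ppg.csv"))
  if (!is.null(pr$resp)) dump_trace(pr$resp, file.path(out_dir, "resp.csv"))
  invisible(pr)
}

read_trace_csv <- function(path, kind) {
  df <- utils::read.csv(path)
  if (!all(c("time", "value") %in% names(df))) {
    stop("trace CSV needs columns time, value: ", path)
  }
  fs <- 1 / stats::median(diff(df$time))
  vital_trace(df$value, fs, kind)
}

#' Evaluate predicted traces against references
#'
#' Each prediction directory (from [cmd_predict()]) is paired by name with a
#' reference clip directory; predicted and reference traces go through the
#' same rate estimator and the paired rates are summarised with
#' [compute_metrics()]. Writes `rates.csv` and `metrics.json`.
#'
#' @param pred_dirs Named or parallel vector of prediction directories.
#' @param ref_dirs Vector of reference clip directories, same length/order.
#' @param out_dir Output directory.
#' @return List with `rates` and `metrics`, invisibly.
#' @export
cmd_evaluate <- function(pred_dirs, ref_dirs, out_dir) {
  if (length(pred_dirs) != length(ref_dirs)) {
    miss <- if (length(pred_dirs) < length(ref_dirs)) {
      setdiff(basename(ref_dirs), basename(pred_dirs))
    } else setdiff(basename(pred_dirs), basename(ref_dirs))
    stop("prediction/reference clip lists differ; unmatched: ",
         paste(miss, collapse = ", "))
  }
  rows <- lapply(seq_along(pred_dirs), function(i) {
    ref <- read_clip(ref_dirs[i])
    ppg_p <- read_trace_csv(file.path(pred_dirs[i], "ppg.csv"), "ppg")
    hr_p <- estimate_rate(ppg_p)
    hr_t <- estimate_rate(ref$ppg_truth)
    resp_path <- file.path(pred_dirs[i], "resp.csv")
    rr_p <- if (file.exists(resp_path)) {
      estimate_rate(read_trace_csv(resp_path, "respiration"))
    } else NA_real_
    rr_t <- estimate_rate(ref$resp_truth)
    data.frame(clip = basename(ref_dirs[i]), hr_pred = hr_p, hr_true = hr_t,
               rr_pred = rr_p, rr_true = rr_t)
  })
  rates <- do.call(rbind, rows)
  metrics <- list(
    hr = unclass(compute_metrics(rates$hr_pred, rates$hr_true)),
    rr = if (!anyNA(rates$rr_pred)) {
      unclass(compute_metrics(rates$rr_pred, rates$rr_true))
    } else NULL)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(rates, file.path(out_dir, "rates.csv"), row.names = FALSE)
  write_json_file(metrics, file.path(out_dir, "metrics.json"))
  invisible(list(rates = rates, metrics = metrics))
}

#' Reduced-scale end-to-end synthetic experiment
#'
#' Generates training and held-out clip sets, trains the given spec from a
#' seeded initialisation, and reports held-out heart-rate and
#' respiration-rate metrics. Everything is derived from `seed`, so two runs
#' with the same arguments are bit-identical.
#'
#' @param n_train,n_test Clip counts.
#' @param spec A [model_spec()] (default [reduced_model_spec()]).
#' @param config A [train_config()].
#' @param sim [sim_config()] template matching the spec's frame count and
#'   ROI shape.
#' @param epochs Training epochs.
#' @param seed Master seed.
#' @return List: `metrics` (hr/rr reports), `rates`, `history`,
#'   `best_epoch`.
#' @export
run_synthetic_experiment <- function(n_train = 32L, n_test = 8L,
                                     spec = reduced_model_spec(),
                                     config = train_config(),
                                     sim = NULL, epochs = 30L, seed = 1L) {
  if (is.null(sim)) {
    sim <- sim_config(fps = 10, n_frames = spec$n_frames,
                      roi_height = spec$roi_shape[1],
                      roi_width = spec$roi_shape[2])
  }
  train_clips <- simulate_clips(n_train, sim, seed = seed)
  test_clips <- simulate_clips(n_test, sim, seed = seed + 1000L)
  config$seed <- seed
  model <- build_model(spec, seed = seed)
  fit <- fit_model(model, train_clips, config, epochs = epochs)
  rep <- rate_report(fit$model, test_clips)
  list(metrics = rep$metrics, rates = rep$rates, history = fit$history,
       best_epoch = fit$best_epoch)
}
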