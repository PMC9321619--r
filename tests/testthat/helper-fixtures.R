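# Shared fixtures: everything is generated in code at test time.

# minimal two-stage spec for fast structural/gradient tests
tiny_spec <- function(multitask = TRUE, dropout = c(0, 0, 0), n_frames = 8L) {
  model_spec(n_frames = n_frames, roi_shape = c(4L, 8L, 2L),
             conv_filters = c(3L, 4L), reduce_filters = c(2L, 3L),
             pool = c(TRUE, FALSE), dropout_rates = dropout,
             multitask = multitask, budget_m = NULL)
}

# random feature matrix for a tiny-spec branch input
tiny_input <- function(n_frames = 8L, seed = 1) {
  set.seed(seed)
  matrix(runif(4 * 8 * n_frames * 2), 4 * 8 * n_frames, 2)
}

# small, fast synthetic clip configuration (12x16 ROI, 6.4 s at 20 FPS)
small_sim <- function(...) {
  args <- list(fps = 20, n_frames = 128L, roi_width = 16L, roi_height = 12L,
               rr_hz = 0.35)
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}

# evaluate a digital filter's transfer function at frequency f (Hz)
filter_gain <- function(filt, f, fs) {
  z <- exp(-1i * 2 * pi * f / fs * (seq_along(filt$b) - 1))
  abs(sum(filt$b * z) / sum(filt$a * exp(-1i * 2 * pi * f / fs *
                                           (seq_along(filt$a) - 1))))
}
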