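# Synthetic forehead/cheek ROI clip generator. Emulates the data contract of
# a consumer-webcam recording setup: 20 FPS, 600-frame clips, 140x40 RGB
# regions, 8-bit quantisation, with a cardiac colour modulation concentrated
# in the green channel and a respiratory modulation expressed both as a
# global intensity change and as a sub-pixel vertical translation.

HR_BAND_HZ <- c(0.66, 3.3)
RR_BAND_HZ <- c(0.1, 0.4)

# run expr with a private RNG stream, restoring the caller's state
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Synthetic-clip configuration
#'
#' Defaults emulate the recording conditions the pipeline targets: 20 frames
#' per second, 600-frame clips, 140 (w) x 40 (h) three-channel regions.
#' `hr_hz` must lie in the cardiac analysis band (0.66--3.3 Hz) and `rr_hz`
#' in the respiratory band (0.1--0.4 Hz); outside those bands the embedded
#' truth would be unrecoverable by design. At least two respiration cycles
#' must fit in the clip (`n_frames >= 2 * fps / rr_hz`).
#'
#' Amplitudes are relative modulation depths on the 8-bit intensity scale:
#' `ppg_amplitude = 0.02` moves the green channel by about 5 of 255 levels,
#' a deliberately strong but physiologically shaped pulse signal.
#'
#' @param fps Frames per second.
#' @param n_frames Clip length in frames.
#' @param roi_width,roi_height ROI size in pixels.
#' @param hr_hz Cardiac fundamental (Hz).
#' @param rr_hz Respiratory fundamental (Hz).
#' @param ppg_amplitude Relative cardiac modulation depth in \[0, 1\].
#' @param resp_amplitude Relative respiratory intensity-modulation depth.
#' @param resp_shift_px Peak respiratory vertical translation in pixels
#'   (<= 1); set 0 to disable the motion mechanism.
#' @param pixel_noise_sd Per-pixel Gaussian noise, 8-bit intensity units.
#' @param drift_amplitude Slow illumination drift amplitude, intensity units.
#' @param drift_hz Drift frequency (< 0.05 Hz).
#' @param seed Integer seed; identical config + seed gives a bit-identical
#'   clip.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(fps = 20, n_frames = 600L, roi_width = 140L,
                       roi_height = 40L, hr_hz = 1.2, rr_hz = 0.25,
                       ppg_amplitude = 0.02, resp_amplitude = 0.02,
                       resp_shift_px = 0.5, pixel_noise_sd = 2,
                       drift_amplitude = 3, drift_hz = 0.02, seed = 1L) {
  if (fps <= 0 || n_frames < 2 || roi_width < 1 || roi_height < 1) {
    stop("fps, n_frames and ROI dimensions must be positive")
  }
  if (hr_hz < HR_BAND_HZ[1] || hr_hz > HR_BAND_HZ[2]) {
    stop(sprintf("hr_hz=%g outside the cardiac analysis band [%g, %g] Hz",
                 hr_hz, HR_BAND_HZ[1], HR_BAND_HZ[2]))
  }
  if (rr_hz < RR_BAND_HZ[1] || rr_hz > RR_BAND_HZ[2]) {
    stop(sprintf("rr_hz=%g outside the respiratory analysis band [%g, %g] Hz",
                 rr_hz, RR_BAND_HZ[1], RR_BAND_HZ[2]))
  }
  if (n_frames < 2 * fps / rr_hz) {
    stop("n_frames too short: fewer than two respiration cycles fit")
  }
  stopifnot(ppg_amplitude >= 0, ppg_amplitude <= 1,
            resp_amplitude >= 0, resp_amplitude <= 1,
            resp_shift_px >= 0, resp_shift_px <= 1,
            pixel_noise_sd >= 0, drift_amplitude >= 0, drift_hz < 0.05)
  structure(list(fps = fps, n_frames = as.integer(n_frames),
                 roi_width = as.integer(roi_width),
                 roi_height = as.integer(roi_height),
                 hr_hz = hr_hz, rr_hz = rr_hz,
                 ppg_amplitude = ppg_amplitude,
                 resp_amplitude = resp_amplitude,
                 resp_shift_px = resp_shift_px,
                 pixel_noise_sd = pixel_noise_sd,
                 drift_amplitude = drift_amplitude, drift_hz = drift_hz,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Pulse-like ground-truth waveform
#'
#' Fundamental sinusoid plus a 0.3-amplitude second harmonic, normalised to
#' \[-1, 1\]. The harmonic gives the pulse an asymmetric shape so peak
#' detection is exercised beyond a pure sine.
#'
#' @param t Time points in seconds.
#' @param hr_hz Cardiac fundamental in Hz.
#' @return Numeric vector in \[-1, 1\].
#' @export
ppg_waveform <- function(t, hr_hz) {
  w <- sin(2 * pi * hr_hz * t) + 0.3 * sin(4 * pi * hr_hz * t)
  th <- seq(0, 2 * pi, length.out = 4096L)
  w / max(abs(sin(th) + 0.3 * sin(2 * th)))
}

#' An ROI video stream
#'
#' @param pixels frames x height x width x channels array with values in
#'   \[0, 1\].
#' @param fps Frames per second.
#' @param region_label `"forehead"` or `"cheek"`.
#' @param source_box Optional `(x0, y0, x1, y1)` 0-based half-open crop box in
#'   the source video.
#' @return List of class `roi_stream`.
#' @export
roi_stream <- function(pixels, fps, region_label = c("forehead", "cheek"),
                       source_box = NULL) {
  region_label <- match.arg(region_label)
  stopifnot(length(dim(pixels)) == 4L, fps > 0)
  rng <- range(pixels)
  if (rng[1] < 0 || rng[2] > 1) stop("roi_stream pixels must lie in [0, 1]")
  structure(list(pixels = pixels, fps = fps, region_label = region_label,
                 source_box = source_box),
            class = "roi_stream")
}

#' Spatially averaged channel trace of an ROI stream
#'
#' @param stream An [roi_stream()].
#' @param channel Channel index (2 = green for RGB data).
#' @return Numeric vector, one value per frame.
#' @export
mean_channel_trace <- function(stream, channel = 2L) {
  px <- stream$pixels[, , , channel, drop = FALSE]
  d <- dim(px)
  rowMeans(matrix(px, nrow = d[1]))
}

# one region's frame stack, 8-bit quantised then scaled to [0, 1];
# noise is drawn from the current RNG stream
render_region <- function(cfg, ppg, resp, base_rgb, ppg_gain, tex_phase) {
  ti <- seq_len(cfg$n_frames) - 1L
  t <- ti / cfg$fps
  H <- cfg$roi_height; W <- cfg$roi_width; TT <- cfg$n_frames
  drift <- cfg$drift_amplitude * sin(2 * pi * cfg$drift_hz * t + 0.3)
  shift <- cfg$resp_shift_px * resp
  # spatial texture: two vertical cycles so a vertical shift changes the
  # pattern rather than adding a constant
  tex_at <- function(y) 10 * sin(2 * pi * 2 * y / H + tex_phase)
  gw <- c(0.25, 1, 0.25) * ppg_gain          # cardiac signal mostly green
  out <- array(0, dim = c(TT, H, W, 3L))
  yrow <- seq_len(H)
  tex_t <- outer(shift, yrow, function(s, y) tex_at(y + s))  # TT x H
  for (ch in 1:3) {
    mod_t <- base_rgb[ch] +
      255 * cfg$ppg_amplitude * gw[ch] * ppg +
      255 * cfg$resp_amplitude * resp + drift          # TT
    plane <- array(rep(mod_t + tex_t, times = W), dim = c(TT, H, W))
    if (cfg$pixel_noise_sd > 0) {
      plane <- plane + array(stats::rnorm(TT * H * W, 0, cfg$pixel_noise_sd),
                             dim = c(TT, H, W))
    }
    out[, , , ch] <- round(pmin(pmax(plane, 0), 255))
  }
  out / 255
}

#' Generate a synthetic forehead/cheek clip with ground-truth traces
#'
#' Each frame's mean colour is a skin-tone base plus the cardiac waveform
#' (predominantly in the green channel), plus a global respiratory intensity
#' modulation and a sub-pixel respiratory vertical translation of the facial
#' texture, plus per-pixel Gaussian noise and a slow illumination drift.
#' Pixels are 8-bit quantised with clipping before rescaling to \[0, 1\].
#' The ground-truth waveforms are analytic functions of `hr_hz`/`rr_hz`
#' alone, so `ppg_truth` does not depend on respiratory parameters or on the
#' noise seed.
#'
#' @param config A [sim_config()].
#' @return List of class `synthetic_clip`: `forehead`, `cheek`
#'   ([roi_stream()]s), `ppg_truth`, `resp_truth` ([vital_trace()]s) and
#'   `config`. Identical config (including seed) gives bit-identical output.
#' @export
generate_clip <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  t <- (seq_len(config$n_frames) - 1L) / config$fps
  ppg <- ppg_waveform(t, config$hr_hz)
  resp <- sin(2 * pi * config$rr_hz * t)
  with_local_seed(config$seed, {
    fore <- render_region(config, ppg, resp,
                          base_rgb = c(185, 125, 105), ppg_gain = 0.8,
                          tex_phase = 0)
    cheek <- render_region(config, ppg, resp,
                           base_rgb = c(180, 120, 100), ppg_gain = 1,
                           tex_phase = pi / 3)
    structure(list(
      forehead = roi_stream(fore, config$fps, "forehead"),
      cheek = roi_stream(cheek, config$fps, "cheek"),
      ppg_truth = vital_trace(ppg, config$fps, "ppg"),
      resp_truth = vital_trace(resp, config$fps, "respiration"),
      config = config
    ), class = "synthetic_clip")
  })
}

#' Generate a set of clips with varied rates
#'
#' Per-clip heart and respiration frequencies are drawn uniformly from the
#' given ranges (seeded), and each clip gets its own derived noise seed, so a
#' set is fully reproducible from `seed`.
#'
#' @param n Number of clips.
#' @param base_config A [sim_config()] template.
#' @param hr_range,rr_range Length-2 frequency ranges (Hz) inside the
#'   analysis bands.
#' @param seed Integer seed for rate draws and per-clip seeds.
#' @return List of `synthetic_clip` objects.
#' @export
simulate_clips <- function(n, base_config = sim_config(),
                           hr_range = c(0.9, 2.4), rr_range = NULL,
                           seed = 1L) {
  if (is.null(rr_range)) {
    lo <- max(RR_BAND_HZ[1], 2 * base_config$fps / base_config$n_frames)
    rr_range <- c(lo, RR_BAND_HZ[2])
  }
  stopifnot(n >= 0, hr_range[1] >= HR_BAND_HZ[1],
            hr_range[2] <= HR_BAND_HZ[2],
            rr_range[1] >= RR_BAND_HZ[1], rr_range[2] <= RR_BAND_HZ[2],
            rr_range[1] >= 2 * base_config$fps / base_config$n_frames)
  draws <- with_local_seed(seed, list(
    hr = stats::runif(n, hr_range[1], hr_range[2]),
    rr = stats::runif(n, rr_range[1], rr_range[2])
  ))
  lapply(seq_len(n), function(i) {
    cfg <- base_config
    cfg$hr_hz <- draws$hr[i]
    cfg$rr_hz <- draws$rr[i]
    cfg$seed <- (base_config$seed + 7919L * i) %% .Machine$integer.max
    generate_clip(cfg)
  })
}

#' Write a synthetic clip to disk
#'
#' The two ROI streams are stored as a stacked-frame archive (`.rds` arrays),
#' the ground-truth traces as a CSV sidecar with `time`, `ppg`, `respiration`
#' columns, and the configuration as a JSON manifest.
#'
#' @param clip A `synthetic_clip`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_clip <- function(clip, dir) {
  stopifnot(inherits(clip, "synthetic_clip"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(clip$forehead$pixels, file.path(dir, "forehead.rds"))
  saveRDS(clip$cheek$pixels, file.path(dir, "cheek.rds"))
  t <- (seq_along(clip$ppg_truth$samples) - 1L) / clip$config$fps
  utils::write.csv(
    data.frame(time = t, ppg = clip$ppg_truth$samples,
               respiration = clip$resp_truth$samples),
    file.path(dir, "truth.csv"), row.names = FALSE)
  jsonlite::write_json(unclass(clip$config),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a clip written by [write_clip()]
#'
#' @param dir Clip directory.
#' @return A `synthetic_clip`.
#' @export
read_clip <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  cfg <- do.call(sim_config, man[setdiff(names(man), character(0))])
  truth <- utils::read.csv(file.path(dir, "truth.csv"))
  structure(list(
    forehead = roi_stream(readRDS(file.path(dir, "forehead.rds")), cfg$fps,
                          "forehead"),
    cheek = roi_stream(readRDS(file.path(dir, "cheek.rds")), cfg$fps,
                       "cheek"),
    ppg_truth = vital_trace(truth$ppg, cfg$fps, "ppg"),
    resp_truth = vital_trace(truth$respiration, cfg$fps, "respiration"),
    config = cfg
  ), class = "synthetic_clip")
}
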