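#' Construct a vital-sign trace
#'
#' A `vital_trace` couples a 1-D physiological signal with its sampling rate
#' and kind. The kind selects the analysis band downstream: `"ppg"` traces are
#' analysed in the cardiac band (0.66--3.3 Hz, beats per minute) and
#' `"respiration"` traces in the respiratory band (0.1--0.4 Hz, respirations
#' per minute).
#'
#' @param samples Numeric vector, the per-frame signal (length >= 2, finite).
#' @param fs Sampling rate in Hz (> 0).
#' @param kind One of `"ppg"` or `"respiration"`.
#' @return An object of class `vital_trace` with fields `samples`, `fs`,
#'   `kind`.
#' @export
vital_trace <- function(samples, fs, kind = c("ppg", "respiration")) {
  kind <- match.arg(kind)
  samples <- as.numeric(samples)
  if (length(samples) < 2L) stop("vital_trace needs at least 2 samples")
  if (!all(is.finite(samples))) stop("vital_trace samples must be finite")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("fs must be a single positive number")
  }
  structure(list(samples = samples, fs = fs, kind = kind),
            class = "vital_trace")
}

#' @export
print.vital_trace <- function(x, ...) {
  cat(sprintf("<vital_trace> kind=%s  n=%d  fs=%g Hz  (%.1f s)\n",
              x$kind, length(x$samples), x$fs, length(x$samples) / x$fs))
  invisible(x)
}

#' Butterworth band specification
#'
#' @param order Filter order of the underlying Butterworth design.
#' @param low_hz,high_hz Passband edges in Hz; `0 < low_hz < high_hz`.
#' @return An object of class `band_spec`.
#' @seealso [hr_band()], [rr_band()] for the two canonical analysis bands.
#' @export
band_spec <- function(order, low_hz, high_hz) {
  stopifnot(order >= 1, low_hz > 0, high_hz > low_hz)
  structure(list(order = as.integer(order), low_hz = low_hz,
                 high_hz = high_hz), class = "band_spec")
}

#' Cardiac analysis band: fourth-order Butterworth, 0.66--3.3 Hz
#' @return A [band_spec()].
#' @export
hr_band <- function() band_spec(4L, 0.66, 3.3)

#' Respiratory analysis band: second-order Butterworth, 0.1--0.4 Hz
#' @return A [band_spec()].
#' @export
rr_band <- function() band_spec(2L, 0.1, 0.4)

band_for_kind <- function(kind) {
  switch(kind, ppg = hr_band(), respiration = rr_band(),
         stop("unknown trace kind: ", kind))
}

# Zero-phase IIR filtering with odd-reflection edge padding: the signal is
# extended at both ends by its mirrored, sign-flipped continuation (length
# 3 * (filter length - 1), capped at n - 1) before the forward and backward
# passes, so the trace ends do not ring against an implicit zero boundary.
filtfilt_odd <- function(b, a, x) {
  n <- length(x)
  nfilt <- max(length(a), length(b))
  padlen <- min(n - 1L, 3L * (nfilt - 1L))
  if (padlen > 0L) {
    pre <- 2 * x[1L] - x[seq(padlen + 1L, 2L)]
    post <- 2 * x[n] - x[seq(n - 1L, n - padlen)]
    ext <- c(pre, x, post)
  } else {
    ext <- x
  }
  y <- signal::filter(b, a, ext)
  y <- rev(signal::filter(b, a, rev(y)))
  as.numeric(y[seq(padlen + 1L, padlen + n)])
}

#' Bandpass-filter a vital trace
#'
#' Applies a Butterworth bandpass of the requested order and cutoffs,
#' forward--backward (zero phase), so peak times are not shifted by filter
#' group delay. Output length equals input length.
#'
#' @param trace A [vital_trace()].
#' @param band A [band_spec()]; defaults to the band implied by `trace$kind`.
#' @return A filtered [vital_trace()] of the same kind and rate.
#' @export
bandpass <- function(trace, band = NULL) {
  stopifnot(inherits(trace, "vital_trace"))
  if (is.null(band)) band <- band_for_kind(trace$kind)
  stopifnot(inherits(band, "band_spec"))
  nyq <- trace$fs / 2
  if (band$high_hz >= nyq) {
    stop(sprintf(
      "band high cutoff %.3g Hz violates the Nyquist limit %.3g Hz at fs=%g",
      band$high_hz, nyq, trace$fs))
  }
  filt <- signal::butter(band$order, c(band$low_hz, band$high_hz) / nyq,
                         type = "pass")
  out <- filtfilt_odd(filt$b, filt$a, trace$samples)
  vital_trace(out, trace$fs, trace$kind)
}

# Topographic prominence of each candidate peak: drop from the peak to the
# highest of the two lowest points separating it from higher terrain.
peak_prominences <- function(x, idx) {
  n <- length(x)
  vapply(idx, function(i) {
    h <- x[i]
    lmin <- h
    j <- i - 1L
    while (j >= 1L && x[j] <= h) {
      if (x[j] < lmin) lmin <- x[j]
      j <- j - 1L
    }
    left_base <- if (j >= 1L) lmin else min(x[1L:i])
    rmin <- h
    j <- i + 1L
    while (j <= n && x[j] <= h) {
      if (x[j] < rmin) rmin <- x[j]
      j <- j + 1L
    }
    right_base <- if (j <= n) rmin else min(x[i:n])
    h - max(left_base, right_base)
  }, numeric(1))
}

#' Detect peaks in a filtered vital trace
#'
#' Local maxima are kept if their topographic prominence is at least
#' `prominence_frac` times the signal standard deviation and they are at
#' least `1 / band$high_hz` seconds from any taller accepted peak (taller
#' peaks win the distance contest). Peaks close to the trace edges are kept;
#' no edge exclusion zone is applied.
#'
#' @param trace A (typically bandpassed) [vital_trace()].
#' @param band The [band_spec()] supplying the minimum-separation scale;
#'   defaults from `trace$kind`.
#' @param prominence_frac Prominence threshold as a fraction of `sd(samples)`.
#' @return An object of class `peak_series`: list with `times` (seconds,
#'   strictly increasing, sample k at time (k-1)/fs) and `n`.
#' @export
detect_peaks <- function(trace, band = NULL, prominence_frac = 0.3) {
  stopifnot(inherits(trace, "vital_trace"))
  if (is.null(band)) band <- band_for_kind(trace$kind)
  x <- trace$samples
  n <- length(x)
  cand <- which(x[2:(n - 1L)] > x[1:(n - 2L)] &
                x[2:(n - 1L)] > x[3:n]) + 1L
  if (length(cand) > 0L) {
    prom <- peak_prominences(x, cand)
    cand <- cand[prom >= prominence_frac * stats::sd(x)]
  }
  if (length(cand) >= 2L) {
    min_sep <- trace$fs / band$high_hz          # samples
    ord <- cand[order(x[cand], decreasing = TRUE)]
    kept <- integer(0)
    for (i in ord) {
      if (all(abs(kept - i) >= min_sep)) kept <- c(kept, i)
    }
    cand <- sort(kept)
  }
  if (length(cand) < 2L) {
    stop("insufficient peaks: need at least 2, found ", length(cand))
  }
  peak_series((cand - 1L) / trace$fs)
}

#' Construct a peak series
#'
#' @param times Strictly increasing peak time instants in seconds.
#' @return An object of class `peak_series`.
#' @export
peak_series <- function(times) {
  times <- as.numeric(times)
  if (is.unsorted(times, strictly = TRUE)) {
    stop("peak times must be strictly increasing")
  }
  structure(list(times = times, n = length(times)), class = "peak_series")
}

#' Rate from mean inter-peak interval
#'
#' The rate in events per minute is 60 divided by the mean interval between
#' consecutive peaks, which telescopes to `60 * (N - 1) / (p_N - p_1)`.
#'
#' @param peaks A [peak_series()] with at least 2 peaks.
#' @return Rate scalar (BPM for cardiac peaks, RPM for respiratory peaks).
#' @export
rate_from_peaks <- function(peaks) {
  stopifnot(inherits(peaks, "peak_series"))
  if (peaks$n < 2L) stop("need at least 2 peaks to form a rate")
  60 / mean(diff(peaks$times))
}

#' Estimate heart or respiration rate from a raw trace
#'
#' Composition of [bandpass()], [detect_peaks()] and [rate_from_peaks()].
#' `kind = "ppg"` uses the order-4, 0.66--3.3 Hz cardiac band (result in BPM);
#' `kind = "respiration"` the order-2, 0.1--0.4 Hz respiratory band (RPM).
#'
#' @param trace A [vital_trace()].
#' @param band Optional [band_spec()] override.
#' @inheritParams detect_peaks
#' @return Rate scalar in events per minute.
#' @export
estimate_rate <- function(trace, band = NULL, prominence_frac = 0.3) {
  if (is.null(band)) band <- band_for_kind(trace$kind)
  filtered <- bandpass(trace, band)
  peaks <- detect_peaks(filtered, band, prominence_frac)
  rate_from_peaks(peaks)
}

#' Agreement metrics between predicted and reference rates
#'
#' Pearson correlation R, mean absolute error and root-mean-square error over
#' paired per-clip rates.
#'
#' @param pred_rates,true_rates Equal-length numeric vectors (length >= 2).
#' @return An object of class `metrics_report`: list with `R`, `MAE`, `RMSE`,
#'   `n`.
#' @export
compute_metrics <- function(pred_rates, true_rates) {
  pred_rates <- as.numeric(pred_rates)
  true_rates <- as.numeric(true_rates)
  if (length(pred_rates) != length(true_rates)) {
    stop("pred_rates and true_rates must have equal length")
  }
  if (length(pred_rates) < 2L) stop("need at least 2 paired rates")
  err <- pred_rates - true_rates
  structure(list(
    R = stats::cor(pred_rates, true_rates),
    MAE = mean(abs(err)),
    RMSE = sqrt(mean(err^2)),
    n = length(err)
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> n=%d  R=%.4f  MAE=%.3f  RMSE=%.3f\n",
              x$n, x$R, x$MAE, x$RMSE))
  invisible(x)
}
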