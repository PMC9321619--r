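# quadrature amplitude of a tone at frequency f in a signal sampled at fs,
# edges trimmed to dodge filter transients
tone_amplitude <- function(x, f, fs, trim = 0.1) {
  n <- length(x)
  keep <- seq(floor(n * trim) + 1, n - floor(n * trim))
  t <- (keep - 1) / fs
  x <- x[keep]
  2 * sqrt(mean(x * sin(2 * pi * f * t))^2 + mean(x * cos(2 * pi * f * t))^2)
}

test_that("cardiac band passes in-band tones and rejects out-of-band tones", {
  fs <- 20
  t <- (0:1199) / fs
  pass_tone <- vital_trace(sin(2 * pi * 1.0 * t), fs, "ppg")
  out <- bandpass(pass_tone)
  expect_gt(tone_amplitude(out$samples, 1.0, fs), 0.95)
  stop_tone <- vital_trace(sin(2 * pi * 0.2 * t), fs, "ppg")
  out2 <- bandpass(stop_tone)
  expect_lt(tone_amplitude(out2$samples, 0.2, fs), 0.10)
})

test_that("forward-backward filtering realises the squared Butterworth gain", {
  fs <- 20
  t <- (0:2399) / fs
  filt <- signal::butter(4, c(0.66, 3.3) / (fs / 2), type = "pass")
  for (f in c(0.4, 1.0, 2.0, 3.0)) {
    tr <- vital_trace(sin(2 * pi * f * t), fs, "ppg")
    got <- tone_amplitude(bandpass(tr)$samples, f, fs)
    expect_equal(got, filter_gain(filt, f, fs)^2, tolerance = 0.02)
  }
})

test_that("bandpass is linear in the zero signal and zero phase for peaks", {
  fs <- 20
  tr <- vital_trace(rep(0, 200), fs, "ppg")
  expect_equal(bandpass(tr)$samples, rep(0, 200))
  # zero-phase property: peak positions of a clean in-band tone survive
  t <- (0:599) / fs
  x <- sin(2 * pi * 1.2 * t)
  raw_pk <- detect_peaks(vital_trace(x, fs, "ppg"), hr_band())
  fil_pk <- detect_peaks(bandpass(vital_trace(x, fs, "ppg")), hr_band())
  expect_equal(raw_pk$n, fil_pk$n)
  expect_true(all(abs(raw_pk$times - fil_pk$times) <= 1 / fs + 1e-9))
})

test_that("bandpass refuses cutoffs at or above Nyquist", {
  tr <- vital_trace(sin(1:100), 6, "ppg")   # Nyquist 3 < 3.3
  expect_error(bandpass(tr, hr_band()), "Nyquist")
})

test_that("peak detection finds every cycle of a clean tone", {
  fs <- 20
  t <- (0:599) / fs                          # 30 s
  pk <- detect_peaks(vital_trace(sin(2 * pi * 1.2 * t), fs, "ppg"),
                     hr_band())
  expect_equal(pk$n, 36)
  expect_equal(diff(pk$times), rep(1 / 1.2, 35), tolerance = 0.05)
})

test_that("peak detection survives additive ripple once bandpassed", {
  fs <- 20
  t <- (0:599) / fs
  clean <- sin(2 * pi * 1.2 * t)
  noisy <- clean + 0.1 * sin(2 * pi * 9 * t)
  pk_clean <- detect_peaks(vital_trace(clean, fs, "ppg"), hr_band())
  pk_noisy <- detect_peaks(bandpass(vital_trace(noisy, fs, "ppg")),
                           hr_band())
  expect_equal(pk_noisy$n, pk_clean$n)
})

test_that("constant or near-flat signals yield an insufficient-peaks error", {
  tr <- vital_trace(rep(1, 100), 20, "ppg")
  expect_error(detect_peaks(tr, hr_band()), "insufficient peaks")
})

test_that("rate_from_peaks reproduces worked examples and telescopes", {
  expect_equal(rate_from_peaks(peak_series(0:5)), 60)
  expect_equal(rate_from_peaks(peak_series(c(0, 0.5, 1.0, 1.5))), 120)
  expect_equal(rate_from_peaks(peak_series(c(0, 0.8, 1.7, 2.7))), 60 / 0.9)
  expect_error(rate_from_peaks(peak_series(1.5)), "at least 2")
  set.seed(11)
  for (i in 1:50) {
    n <- sample(2:40, 1)
    p <- cumsum(runif(n, 0.3, 2))
    r1 <- rate_from_peaks(peak_series(p))
    r2 <- 60 * (n - 1) / (p[n] - p[1])
    expect_equal(r1, r2)
  }
})

test_that("estimate_rate recovers clean synthetic tones in each band", {
  fs <- 20
  t <- (0:1199) / fs
  hr <- estimate_rate(vital_trace(ppg_waveform(t, 1.2), fs, "ppg"))
  expect_lt(abs(hr - 72), 1)
  rr <- estimate_rate(vital_trace(sin(2 * pi * 0.25 * t), fs, "respiration"))
  expect_lt(abs(rr - 15), 0.5)
})

test_that("trace kind selects the documented band and order", {
  expect_equal(rr_band()$order, 2L)
  expect_equal(c(rr_band()$low_hz, rr_band()$high_hz), c(0.1, 0.4))
  expect_equal(hr_band()$order, 4L)
  expect_equal(c(hr_band()$low_hz, hr_band()$high_hz), c(0.66, 3.3))
  # a respiration-kind trace must be analysed in the respiratory band:
  # a 1.2 Hz tone has no respiratory content, so rate estimation fails
  fs <- 20
  t <- (0:599) / fs
  tr <- vital_trace(sin(2 * pi * 1.2 * t), fs, "respiration")
  est <- tryCatch(estimate_rate(tr), error = function(e) NA_real_)
  if (!is.na(est)) expect_true(est >= 6 && est <= 24)
})

test_that("rates stay inside the analysis band whenever peaks exist", {
  set.seed(4)
  fs <- 20
  t <- (0:599) / fs
  for (i in 1:10) {
    x <- rnorm(600)
    est <- tryCatch(estimate_rate(vital_trace(x, fs, "ppg")),
                    error = function(e) NA_real_)
    if (!is.na(est)) {
      expect_gte(est, 60 * 0.66 * 0.9)   # small slack for edge peaks
      expect_lte(est, 60 * 3.3)
    }
  }
})

test_that("compute_metrics matches hand arithmetic and its invariants", {
  m <- compute_metrics(c(72, 80), c(70, 78))
  expect_equal(m$MAE, 2)
  expect_equal(m$RMSE, 2)
  p <- c(70, 75, 82, 91)
  m2 <- compute_metrics(p, p)
  expect_equal(m2$R, 1)
  expect_equal(m2$MAE, 0)
  expect_equal(m2$RMSE, 0)
  m3 <- compute_metrics(2 * p + 5, p)
  expect_equal(m3$R, 1)
  expect_gt(m3$MAE, 0)
  set.seed(9)
  for (i in 1:20) {
    a <- rnorm(10, 70, 10); b <- rnorm(10, 70, 10)
    mm <- compute_metrics(a, b)
    expect_lte(mm$MAE, mm$RMSE + 1e-12)
    expect_true(mm$R >= -1 && mm$R <= 1)
  }
  expect_error(compute_metrics(1:3, 1:4), "equal length")
})
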