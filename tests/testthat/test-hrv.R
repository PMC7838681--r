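test_that("interbeat intervals are consecutive beat-time differences", {
  expect_equal(ibi_series(c(0, 1, 2, 3))$ibi, c(1, 1, 1))
  expect_equal(ibi_series(c(0, 1.0, 2.1, 3.0))$ibi, c(1.0, 1.1, 0.9))
  expect_error(ibi_series(c(0, 1, 1)))       # non-monotone
  expect_error(ibi_series(c(0, 1)))          # too few
  # denervated simulation: every interval is the intrinsic period
  sim <- simulate_cvs("awake", duration = 80, transient = 10, noise = FALSE,
                      denervated = TRUE)
  expect_lt(max(abs(ibi_series(sim)$ibi - 1.1)), 1e-6)
})

test_that("resampling preserves constants and recovers smooth modulations", {
  s <- ibi_series(seq(0, 100, by = 1))
  r <- resample_ibi(s, rate = 4)
  expect_equal(diff(r$resampled$t)[1], 0.25)
  expect_true(all(abs(r$resampled$ibi_ms - 1000) < 1e-6))
  # ibi(t) = 1 + 0.1 sin(2 pi 0.1 t) sampled at the beats it generates;
  # each interval's value is that of the generating function at the beat
  # closing it (fixed-point iteration), matching the series' stamping
  bt <- 0; t <- 0
  while (t < 300) {
    ib <- 1
    for (j in 1:4) ib <- 1 + 0.1 * sin(2 * pi * 0.1 * (t + ib))
    t <- t + ib; bt <- c(bt, t)
  }
  r2 <- resample_ibi(ibi_series(bt), rate = 4)
  inner <- r2$resampled$t > 5 & r2$resampled$t < 290
  truth <- 1000 * (1 + 0.1 * sin(2 * pi * 0.1 * r2$resampled$t[inner]))
  rel_rms <- sqrt(mean((r2$resampled$ibi_ms[inner] - truth)^2)) / 1000
  expect_lt(rel_rms, 0.02)
  expect_error(resample_ibi(ibi_series(c(0, 1, 2, 3)), rate = 0.5))
})

test_that("band power lands sinusoids in the correct bands", {
  mk <- function(f0, amp_ms = 30) {
    bt <- 0; t <- 0
    while (t < 1500) { t <- t + 1 + amp_ms / 1000 * sin(2 * pi * f0 * t); bt <- c(bt, t) }
    resample_ibi(ibi_series(bt), rate = 4)
  }
  lo <- mk(0.10)
  expect_equal(band_power(lo, 0.05, 0.15), 30^2 / 2, tolerance = 0.05)
  expect_lt(band_power(lo, 0.15, 0.4), 0.01 * band_power(lo, 0.05, 0.15))
  hi <- mk(0.29)
  expect_gt(band_power(hi, 0.15, 0.4), 100 * band_power(hi, 0.05, 0.15))
  # widening a band never decreases power
  expect_gte(band_power(lo, 0.04, 0.16), band_power(lo, 0.05, 0.15))
  expect_error(band_power(lo, 0.3, 3))  # above Nyquist
})

test_that("Welch PSD satisfies Parseval within 1%", {
  set.seed(8)
  x <- rnorm(2^16) + 5 * sin(2 * pi * 0.1 * (1:2^16) / 4)
  w <- welch_psd(x, fs = 4)
  expect_lt(abs(sum(w$psd) * w$df - var(x)) / var(x), 0.01)
})

test_that("lf_hf returns both indices from a simulation", {
  sim <- simulate_cvs("awake", duration = 400, transient = 100, seed = 2)
  sx <- lf_hf(resample_ibi(ibi_series(sim)))
  expect_gt(sx$lf, 0)
  expect_gt(sx$hf, 0)
  expect_s3_class(sx, "spectral_indices")
})

test_that("zero-phase band-pass has the required frequency response", {
  fs <- 4
  t <- seq(0, 2000, by = 1 / fs)
  gain_at <- function(f0) {
    bt <- 0; tt <- 0
    while (tt < 2000) { tt <- tt + 1; bt <- c(bt, tt) }
    ser <- ibi_series(bt)
    ser <- resample_ibi(ser, rate = fs)
    ser$resampled$ibi_ms <- 1000 * sin(2 * pi * f0 * ser$resampled$t)
    out <- bandpass_ibi(ser)$resampled$ibi_ms
    n <- length(out)
    core <- seq(round(n * 0.2), round(n * 0.8))
    sd(out[core]) / sd(1000 * sin(2 * pi * f0 * ser$resampled$t[core]))
  }
  expect_lt(gain_at(0.01), 0.10)   # deep stop band
  expect_gt(gain_at(0.20), 0.90)   # pass band
  expect_lt(gain_at(0.025), 0.10)  # >= 20 dB at half the lower edge
  expect_lt(gain_at(0.80), 0.10)   # >= 20 dB at twice the upper edge
  # zero in, zero out
  bt <- seq(0, 500, by = 1)
  ser <- resample_ibi(ibi_series(bt))
  expect_lt(max(abs(bandpass_ibi(ser)$resampled$ibi_ms)), 1e-8)
})
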