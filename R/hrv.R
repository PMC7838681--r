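# Heart-rate-variability toolkit: interbeat-interval extraction and
# resampling, Welch spectra with LF/HF band powers, and zero-phase
# band-pass filtering.

#' Interbeat-interval series from beat times
#'
#' `ibi[k] = beat_times[k+1] - beat_times[k]`; each interval is stamped
#' with the time of the beat that closes it. For a `cvs_simulation` the
#' transient stretch is dropped first.
#'
#' @param x strictly increasing beat times (s), or a `cvs_simulation`.
#' @param ... unused.
#' @return An object of class `ibi_series`: list with `beat_times` (times
#'   closing each interval, s) and `ibi` (s).
#' @examples
#' ibi_series(c(0, 1, 2, 3))$ibi
#' @export
ibi_series <- function(x, ...) UseMethod("ibi_series")

#' @export
ibi_series.numeric <- function(x, ...) {
  if (length(x) < 3) stop("need at least 3 beat times")
  if (any(diff(x) <= 0)) stop("beat times must be strictly increasing")
  structure(list(beat_times = x[-1], ibi = diff(x)), class = "ibi_series")
}

#' @export
ibi_series.cvs_simulation <- function(x, ...) {
  bt <- x$beat_times[x$beat_times > x$settings$transient]
  ibi_series(bt)
}

#' @export
print.ibi_series <- function(x, ...) {
  cat(sprintf("<ibi_series> %d intervals | mean %.0f ms | range %.0f-%.0f ms%s\n",
              length(x$ibi), 1000 * mean(x$ibi),
              1000 * min(x$ibi), 1000 * max(x$ibi),
              if (is.null(x$resampled)) "" else
                sprintf(" | resampled at %g Hz", x$rate)))
  invisible(x)
}

#' Resample an interbeat-interval series onto a uniform grid
#'
#' Cubic interpolation of `(beat_time, ibi)` onto a uniform grid, with the
#' values converted to milliseconds. A uniform grid is required for the
#' spectral estimators; 4 Hz (the default) is standard HRV practice and
#' leaves the 0.4 Hz band edge far below Nyquist.
#'
#' @param series an `ibi_series`.
#' @param rate grid rate in Hz (> 0.8).
#' @return the series with `resampled` (data frame `t` in s, `ibi_ms`) and
#'   `rate` fields added.
#' @export
resample_ibi <- function(series, rate = 4) {
  stopifnot(inherits(series, "ibi_series"), rate > 2 * 0.4)
  bt <- series$beat_times
  if (length(bt) < 4) stop("insufficient beats for cubic resampling")
  grid <- seq(ceiling(bt[1] * rate) / rate, floor(bt[length(bt)] * rate) / rate,
              by = 1 / rate)
  y <- spline(bt, series$ibi * 1000, xout = grid, method = "fmm")$y
  series$resampled <- data.frame(t = grid, ibi_ms = y)
  series$rate <- rate
  series
}

resampled_or_stop <- function(series) {
  if (is.null(series$resampled)) {
    stop("series has no resampled component; call resample_ibi() first")
  }
  series
}

#' Welch power spectral density
#'
#' Mean-removed, Hann-windowed, 50%-overlapping segment-averaged one-sided
#' periodogram. Normalised as a density: the sum of `psd * df` over all
#' returned frequencies equals the series variance (Parseval), up to
#' estimator fluctuation.
#'
#' @param x numeric series (for HRV work, the resampled IBI in ms).
#' @param fs sampling rate (Hz).
#' @param nperseg segment length in samples (default: 256 s worth, capped
#'   at the series length).
#' @param overlap fractional segment overlap (default 0.5).
#' @return list with `freq` (Hz, excluding DC), `psd` (density, x-unit^2
#'   per Hz) and `df` (Hz).
#' @export
welch_psd <- function(x, fs, nperseg = min(length(x), round(256 * fs)),
                      overlap = 0.5) {
  n <- length(x)
  nperseg <- min(as.integer(nperseg), n)
  stopifnot(nperseg >= 8)
  step <- max(1L, floor(nperseg * (1 - overlap)))
  starts <- seq(1L, n - nperseg + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(nperseg) / nperseg))
  u <- sum(w^2)
  nf <- nperseg %/% 2
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L)]
    seg <- seg - mean(seg)
    sp <- fft(w * seg)
    acc <- acc + Mod(sp[2:(nf + 1)])^2
  }
  psd <- 2 * acc / (length(starts) * fs * u)
  if (nperseg %% 2 == 0) psd[nf] <- psd[nf] / 2  # Nyquist bin is not doubled
  list(freq = (1:nf) * fs / nperseg, psd = psd, df = fs / nperseg)
}

#' Spectral band power of an interbeat-interval series
#'
#' Integrates the Welch power spectral density of the mean-removed
#' resampled series (in ms) over `[f_lo, f_hi]`, returning ms^2.
#'
#' @param series a resampled `ibi_series` (see [resample_ibi()]).
#' @param f_lo,f_hi band edges in Hz; `f_hi` must not exceed Nyquist.
#' @param ... passed to [welch_psd()].
#' @return band power in ms^2.
#' @export
band_power <- function(series, f_lo, f_hi, ...) {
  series <- resampled_or_stop(series)
  stopifnot(f_lo < f_hi, f_hi <= series$rate / 2)
  w <- welch_psd(series$resampled$ibi_ms, series$rate, ...)
  if (f_lo >= w$freq[length(w$freq)]) stop("band outside resolvable range")
  sum(w$psd[w$freq >= f_lo & w$freq <= f_hi]) * w$df
}

#' LF and HF spectral indices
#'
#' Band powers of the interbeat-interval series in the low-frequency
#' (0.05-0.15 Hz, sympathetic) and high-frequency (0.15-0.4 Hz,
#' parasympathetic/respiratory) bands.
#'
#' @param series an `ibi_series`; resampled at 4 Hz automatically if
#'   needed.
#' @param ... passed to [welch_psd()].
#' @return An object of class `spectral_indices`: list with `lf`, `hf`
#'   (ms^2) and the `psd` (data frame `freq`, `density`).
#' @export
lf_hf <- function(series, ...) {
  if (is.null(series$resampled)) series <- resample_ibi(series)
  w <- welch_psd(series$resampled$ibi_ms, series$rate, ...)
  structure(list(
    lf = sum(w$psd[w$freq >= 0.05 & w$freq <= 0.15]) * w$df,
    hf = sum(w$psd[w$freq >= 0.15 & w$freq <= 0.4]) * w$df,
    psd = data.frame(freq = w$freq, density = w$psd)
  ), class = "spectral_indices")
}

#' @export
print.spectral_indices <- function(x, ...) {
  cat(sprintf("<spectral_indices> LF %.0f ms^2 | HF %.0f ms^2\n", x$lf, x$hf))
  invisible(x)
}

#' Zero-phase band-pass filter for interbeat-interval series
#'
#' Forward-backward (zero-phase) Butterworth band-pass of the resampled
#' series, by default over 0.05-0.4 Hz, the band used for the complexity
#' analysis. The two-pass order-2 design attenuates sinusoids one octave
#' outside the band by more than 20 dB while passing the band interior
#' essentially unchanged.
#'
#' @param series a resampled `ibi_series`.
#' @param f_lo,f_hi band edges in Hz.
#' @param order Butterworth section order of each pass.
#' @return the series with `resampled$ibi_ms` replaced by the filtered,
#'   mean-removed signal.
#' @export
bandpass_ibi <- function(series, f_lo = 0.05, f_hi = 0.4, order = 2) {
  series <- resampled_or_stop(series)
  x <- series$resampled$ibi_ms
  # record must cover ~10 periods of the lowest passband frequency
  if (length(x) / series$rate < 10 / f_lo) stop("record too short for the band")
  bf <- signal::butter(order, c(f_lo, f_hi) / (series$rate / 2), type = "pass")
  series$resampled$ibi_ms <- signal::filtfilt(bf, x - mean(x))
  series
}
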