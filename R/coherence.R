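#' Windowing configuration for coherence estimation
#'
#' The default analysis segment is 16 s at 250 Hz, of which 15.872 s
#' (3968 samples) are used so that a maximal 128-ms lag always leaves the same
#' span. That span divides evenly into 8 non-overlapping windows of 496
#' samples (1.984 s), giving a spectral resolution of 1/1.984 = 0.504 Hz.
#'
#' @param n_windows Number of non-overlapping windows.
#' @param window_samples Samples per window.
#' @param fs Sampling rate, Hz.
#' @return Object of class `windowing_config`.
#' @examples
#' windowing_config()$resolution_hz
#' @export
windowing_config <- function(n_windows = 8, window_samples = 496, fs = 250) {
  assert_field(n_windows >= 1, "n_windows", "must be >= 1")
  assert_field(window_samples >= 2, "window_samples", "must be >= 2")
  structure(
    list(n_windows = as.integer(n_windows),
         window_samples = as.integer(window_samples),
         fs = fs,
         window_s = window_samples / fs,
         resolution_hz = fs / window_samples,
         total_samples = as.integer(n_windows * window_samples)),
    class = "windowing_config"
  )
}

# windowing for the 4-s peak-search segment: 2 windows of 496 samples
peak_windowing_config <- function(fs = 250) {
  windowing_config(n_windows = 2, window_samples = 496, fs = fs)
}

#' Frequency band definitions
#'
#' Default bands: alpha 8-12 Hz, beta 13-30 Hz, low gamma 30-45 Hz,
#' high gamma 45-63 Hz.
#'
#' @return Tibble with columns `band`, `lo`, `hi` (Hz).
#' @examples
#' cmc_bands()
#' @export
cmc_bands <- function() {
  tibble(
    band = c("alpha", "beta", "low_gamma", "high_gamma"),
    lo = c(8, 13, 30, 45),
    hi = c(12, 30, 45, 63)
  )
}

band_limits <- function(band, bands = cmc_bands()) {
  row <- bands[bands$band == band, ]
  if (nrow(row) != 1) {
    abort(sprintf("unknown band '%s'", band), class = "cmcwave_validation_error")
  }
  c(lo = row$lo, hi = row$hi)
}

# Split a signal of length n_windows * window_samples into a matrix
# (window_samples x n_windows), pad, and forward-transform.
win_spectra <- function(x, wincfg, N) {
  xmat <- matrix(x, nrow = wincfg$window_samples, ncol = wincfg$n_windows)
  pw <- pad_windows(xmat, N)
  list(FX = stats::mvfft(pw$padded), idx = pw$idx)
}

# Core estimator shared by wavelet_coherence() and the lag scan:
# per window, time-average the cross- and auto-spectra over the unpadded
# span, form |coherency| per window, then average across windows.
coherence_from_spectra <- function(FX, FY, idx, fs, bank, wincfg) {
  Wxs <- cwt_from_spectra(FX, fs, bank, idx)
  Wys <- cwt_from_spectra(FY, fs, bank, idx)
  vapply(seq_along(bank$cfs), function(k) {
    WX <- Wxs[[k]]; WY <- Wys[[k]]
    sxy <- colMeans(WX * Conj(WY))
    sxx <- colMeans(Mod(WX)^2)
    syy <- colMeans(Mod(WY)^2)
    coh_w <- Mod(sxy) / sqrt(sxx * syy)
    coh_w[!is.finite(coh_w)] <- 0  # silent window (zero power): no coherence
    mean(coh_w)
  }, numeric(1))
}

#' Windowed wavelet coherence between two signals
#'
#' For each non-overlapping window the cross-spectrum `Wx * Conj(Wy)` and the
#' auto-spectra are time-averaged over the unpadded span of the window; the
#' coherency is the normalized cross-spectrum of these averages and the
#' window's coherence is its modulus. The reported value per center frequency
#' is the mean of the per-window coherences. Averaging before normalizing is
#' essential: a per-sample ratio has modulus identically 1.
#'
#' @param x,y Numeric vectors of equal length `n_windows * window_samples`.
#' @param bank A [wavelet_bank()].
#' @param wincfg A [windowing_config()].
#' @return A tibble of class `coh_spectrum` with columns `cf` (Hz) and
#'   `coherence` (in `[0, 1]`), and attributes `n_windows` and `fs`.
#' @examples
#' w <- windowing_config(n_windows = 2)
#' x <- rnorm(w$total_samples)
#' wavelet_coherence(x, x, wavelet_bank(), w)
#' @export
wavelet_coherence <- function(x, y, bank = wavelet_bank(), wincfg = windowing_config()) {
  assert_finite_signal(x, "x")
  assert_finite_signal(y, "y")
  if (length(x) != length(y)) {
    abort("`x` and `y` must have equal length", class = "cmcwave_validation_error")
  }
  if (length(x) != wincfg$total_samples) {
    abort(sprintf("signal length %d does not equal n_windows * window_samples = %d",
                  length(x), wincfg$total_samples),
          class = "cmcwave_validation_error")
  }
  N <- next_pow2(2L * wincfg$window_samples)
  sx <- win_spectra(x, wincfg, N)
  sy <- win_spectra(y, wincfg, N)
  coh <- coherence_from_spectra(sx$FX, sy$FX, sx$idx, wincfg$fs, bank, wincfg)
  out <- tibble(cf = bank$cfs, coherence = pmin(coh, 1))
  class(out) <- c("coh_spectrum", class(out))
  attr(out, "n_windows") <- wincfg$n_windows
  attr(out, "fs") <- wincfg$fs
  out
}

#' Peak coherence frequency inside a band
#'
#' Returns the bank center frequency inside `[lo, hi]` with maximal coherence.
#' Ties (including a flat spectrum) resolve to the lowest cf in the band.
#'
#' @param cohspec A `coh_spectrum` tibble (typically from the 4-s peak
#'   segment).
#' @param band Band name (see [cmc_bands()]) or a `c(lo, hi)` pair in Hz.
#' @param bands Band definition table.
#' @return Peak center frequency, Hz.
#' @export
band_peak_frequency <- function(cohspec, band, bands = cmc_bands()) {
  lim <- if (is.character(band)) band_limits(band, bands) else c(lo = band[1], hi = band[2])
  sel <- cohspec$cf >= lim["lo"] & cohspec$cf <= lim["hi"]
  if (!any(sel)) {
    abort(sprintf("no center frequency inside [%g, %g] Hz", lim["lo"], lim["hi"]),
          class = "cmcwave_validation_error")
  }
  cf <- cohspec$cf[sel]
  co <- cohspec$coherence[sel]
  cf[which.max(co)]  # which.max takes the first (lowest cf) on ties
}

#' Mean coherence over a band
#'
#' @inheritParams band_peak_frequency
#' @return Mean coherence over the bank cfs falling in the band.
#' @export
band_mean <- function(cohspec, band, bands = cmc_bands()) {
  lim <- if (is.character(band)) band_limits(band, bands) else c(lo = band[1], hi = band[2])
  sel <- cohspec$cf >= lim["lo"] & cohspec$cf <= lim["hi"]
  if (!any(sel)) {
    abort(sprintf("no center frequency inside [%g, %g] Hz", lim["lo"], lim["hi"]),
          class = "cmcwave_validation_error")
  }
  mean(cohspec$coherence[sel])
}

#' Snap a frequency to the nearest bank center frequency
#'
#' Used when per-trial peak frequencies are averaged per participant: the mean
#' generally falls between bank cfs and is snapped to the nearest one.
#'
#' @param f Frequency, Hz.
#' @param bank A [wavelet_bank()].
#' @return The nearest bank cf, Hz.
#' @export
snap_to_bank <- function(f, bank) {
  bank$cfs[which.min(abs(bank$cfs - f))]
}
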