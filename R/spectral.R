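#' Power spectral density from zero-padded boxcar windows
#'
#' The signal is cut into non-overlapping boxcar (rectangular) windows of
#' `window_s` seconds, each window is zero-padded to the next power of two at
#' least twice its length, and the one-sided periodograms are averaged.
#' Density normalization: the integral of the PSD over frequency equals the
#' signal's mean square (a Parseval identity that holds exactly under
#' zero-padding).
#'
#' @param x Numeric signal (microvolts).
#' @param fs Sampling rate, Hz.
#' @param window_s Window length, s.
#' @return Tibble of class `psd_spectrum` with columns `freq` (Hz) and
#'   `power` (uV^2/Hz); attribute `n_windows`.
#' @export
psd_boxcar <- function(x, fs, window_s = 2) {
  assert_finite_signal(x)
  L <- round(window_s * fs)
  nw <- floor(length(x) / L)
  if (nw < 1L) {
    abort(sprintf("signal shorter than one %g-s window", window_s),
          class = "cmcwave_validation_error")
  }
  N <- next_pow2(2L * L)
  xmat <- matrix(x[seq_len(nw * L)], nrow = L)
  pw <- pad_windows(xmat, N)
  FX <- stats::mvfft(pw$padded)
  P <- Mod(FX)^2 / (fs * L)
  half <- N %/% 2L + 1L
  one_sided <- P[seq_len(half), , drop = FALSE]
  if (half > 2L) one_sided[2:(half - 1L), ] <- 2 * one_sided[2:(half - 1L), ]
  out <- tibble(freq = (seq_len(half) - 1L) * fs / N,
                power = rowMeans(one_sided))
  class(out) <- c("psd_spectrum", class(out))
  attr(out, "n_windows") <- nw
  attr(out, "fs") <- fs
  out
}

#' Band power by trapezoidal integration of a PSD
#'
#' @param spectrum A `psd_spectrum` tibble.
#' @param band Band name (see [cmc_bands()]) or a `c(lo, hi)` pair, Hz.
#' @param bands Band definition table.
#' @return Integrated power over the band, uV^2.
#' @export
band_power <- function(spectrum, band, bands = cmc_bands()) {
  lim <- if (is.character(band)) band_limits(band, bands) else c(lo = band[1], hi = band[2])
  if (lim["lo"] < min(spectrum$freq) - 1e-9 || lim["hi"] > max(spectrum$freq) + 1e-9) {
    abort(sprintf("band [%g, %g] Hz outside spectrum range [%g, %g] Hz",
                  lim["lo"], lim["hi"], min(spectrum$freq), max(spectrum$freq)),
          class = "cmcwave_validation_error")
  }
  sel <- spectrum$freq >= lim["lo"] & spectrum$freq <= lim["hi"]
  trapz_integral(spectrum$freq[sel], spectrum$power[sel])
}

#' Group-level PSD summary
#'
#' Averages trial PSDs within participant (per task and channel), then across
#' participants, reporting the mean and the standard error of the mean at
#' each frequency.
#'
#' @param psd_table Tidy tibble with columns `participant`, `group`, `task`,
#'   `channel`, `freq`, `power` (one row per trial x frequency).
#' @return Tibble with `group`, `task`, `channel`, `freq`, `mean_power`,
#'   `sem`.
#' @export
summarise_psd <- function(psd_table) {
  psd_table |>
    group_by(.data$participant, .data$group, .data$task, .data$channel, .data$freq) |>
    summarise(power = mean(.data$power), .groups = "drop") |>
    group_by(.data$group, .data$task, .data$channel, .data$freq) |>
    summarise(mean_power = mean(.data$power),
              sem = sd(.data$power) / sqrt(n()),
              .groups = "drop")
}
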