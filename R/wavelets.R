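#' Center frequencies of the Cauchy wavelet bank
#'
#' The bank is non-linearly scaled: the j-th center frequency is
#' `cf_j = (1/scale) * (j + q)^r`. With the defaults (`scale = 12`,
#' `q = 1.45`, `r = 1.959`, `j = 1..30`) this spans roughly 0.5-72 Hz with
#' constant relative spectral resolution, which suits simultaneous EEG/EMG
#' analysis from slow cortical rhythms up to high gamma.
#'
#' @param scale Dimensionless scaling factor; larger values shift the whole
#'   bank towards lower frequencies (cf is proportional to 1/scale).
#' @param q,r Shape parameters of the index-to-frequency rule.
#' @param j_range Integer vector of wavelet indices.
#' @return Numeric vector of center frequencies in Hz, strictly increasing.
#' @examples
#' center_frequencies()
#' @export
center_frequencies <- function(scale = 12, q = 1.45, r = 1.959, j_range = 1:30) {
  assert_field(is.numeric(scale) && length(scale) == 1 && scale > 0, "scale", "must be a positive number")
  assert_field(is.numeric(r) && r > 0, "r", "must be positive")
  assert_field(length(j_range) >= 1, "j_range", "must be non-empty")
  assert_field(all(j_range + q > 0), "j_range", "j + q must be positive")
  cfs <- (1 / scale) * (j_range + q)^r
  cfs
}

#' Construct a Cauchy wavelet bank
#'
#' Bundles the family parameters with the derived center frequencies. All
#' spectral stages (coherence, ECG wavelet intensity, lag scans) operate on a
#' bank object, so a single configuration flows through the whole pipeline.
#'
#' @inheritParams center_frequencies
#' @return An object of class `wavelet_bank`: a list with `scale`, `q`, `r`,
#'   `j_range`, `cfs` (Hz) and `mode` (per-cf exponent, `cf * scale`).
#' @examples
#' bank <- wavelet_bank()
#' range(bank$cfs)
#' @export
wavelet_bank <- function(scale = 12, q = 1.45, r = 1.959, j_range = 1:30) {
  cfs <- center_frequencies(scale, q, r, j_range)
  structure(
    list(scale = scale, q = q, r = r, j_range = as.integer(j_range),
         cfs = cfs, mode = cfs * scale),
    class = "wavelet_bank"
  )
}

#' @export
print.wavelet_bank <- function(x, ...) {
  cat(sprintf("<wavelet_bank> %d Cauchy wavelets, cf %.3g-%.3g Hz (scale %g, q %g, r %g)\n",
              length(x$cfs), min(x$cfs), max(x$cfs), x$scale, x$q, x$r))
  invisible(x)
}

# restrict a bank to center frequencies inside [lo, hi]
bank_subset <- function(bank, lo, hi) {
  keep <- bank$cfs >= lo & bank$cfs <= hi
  if (!any(keep)) {
    abort(sprintf("no bank center frequency inside [%g, %g] Hz", lo, hi),
          class = "cmcwave_validation_error")
  }
  structure(
    list(scale = bank$scale, q = bank$q, r = bank$r,
         j_range = bank$j_range[keep], cfs = bank$cfs[keep],
         mode = bank$mode[keep]),
    class = "wavelet_bank"
  )
}

# bank with a single arbitrary center frequency (used by the lag scan)
bank_single_cf <- function(bank, cf) {
  structure(
    list(scale = bank$scale, q = bank$q, r = bank$r,
         j_range = NA_integer_, cfs = cf, mode = cf * bank$scale),
    class = "wavelet_bank"
  )
}

#' Frequency-domain gain of one Cauchy wavelet
#'
#' `Fpsi(f) = (f/cf)^mode * exp((1 - f/cf) * mode)` with `mode = cf * scale`.
#' The gain is 1 exactly at `f = cf`, 0 at `f = 0`, and decays on both sides
#' with a relative bandwidth set by `scale`. Evaluated in log space so that
#' large exponents (mode can exceed 800 at high cf) do not overflow.
#'
#' @param f Numeric vector of non-negative Fourier frequencies, Hz.
#' @param cf Center frequency, Hz (> 0).
#' @param scale Bank scaling factor.
#' @return Non-negative gain, same length as `f`.
#' @examples
#' wavelet_filter(c(0, 5, 10, 20), cf = 10)
#' @export
wavelet_filter <- function(f, cf, scale = 12) {
  assert_field(is.numeric(cf) && length(cf) == 1 && cf > 0, "cf", "must be a positive number")
  mode <- cf * scale
  ratio <- f / cf
  g <- numeric(length(f))
  pos <- which(ratio > 0)
  g[pos] <- exp(mode * (log(ratio[pos]) + 1 - ratio[pos]))
  g
}

# Symmetric zero-padding of a window matrix (time x windows) to N rows.
# Returns list(padded matrix, index range of the original samples).
pad_windows <- function(xmat, N) {
  n <- nrow(xmat)
  pre <- (N - n) %/% 2L
  post <- N - n - pre
  padded <- rbind(
    matrix(0, pre, ncol(xmat)),
    xmat,
    matrix(0, post, ncol(xmat))
  )
  list(padded = padded, idx = seq.int(pre + 1L, pre + n))
}

# Frequency-domain analytic CWT of pre-transformed window spectra.
# FX: complex matrix N x n_windows (mvfft of padded windows).
# Returns, per cf, a complex matrix n x n_windows of coefficients restricted
# to the unpadded span `idx`.
cwt_from_spectra <- function(FX, fs, bank, idx) {
  N <- nrow(FX)
  f <- (seq_len(N) - 1L) * fs / N
  half <- N %/% 2L + 1L            # bins 1..half are non-negative freqs
  lapply(seq_along(bank$cfs), function(k) {
    G <- numeric(N)
    G[seq_len(half)] <- wavelet_filter(f[seq_len(half)], bank$cfs[k], bank$scale)
    if (N %% 2L == 0L) G[half] <- G[half] / 2  # split Nyquist
    if (ncol(FX) >= 8L && length(idx) <= 1024L) {
      # support-restricted inverse (memoized; see make_inverter)
      wc <- list(window_samples = length(idx), fs = fs)
      make_inverter(G, wc, N,
                    cache_key = inverter_key(N, wc, bank$cfs[k], bank$scale))(FX)
    } else {
      W <- stats::mvfft(FX * G, inverse = TRUE) / N
      W[idx, , drop = FALSE]
    }
  })
}

#' Continuous wavelet transform of one window
#'
#' Frequency-domain implementation: the signal is symmetrically zero-padded to
#' the next power of two at least twice its length, Fourier-transformed, and
#' multiplied by each wavelet's one-sided gain (negative frequencies zeroed),
#' yielding complex analytic coefficients whose phase is meaningful for
#' coherency computation.
#'
#' @param x Numeric vector, one analysis window.
#' @param bank A [wavelet_bank()].
#' @param fs Sampling rate, Hz.
#' @return A list of class `tf_map` with `coefficients` (complex matrix,
#'   cfs x time), `cfs` and `fs`.
#' @examples
#' tf <- cwt(sin(2 * pi * 10 * seq(0, 1, by = 1 / 250)), wavelet_bank(), fs = 250)
#' dim(tf$coefficients)
#' @export
cwt <- function(x, bank, fs) {
  assert_finite_signal(x)
  if (length(x) < 2L) {
    abort("window must contain at least 2 samples", class = "cmcwave_validation_error")
  }
  n <- length(x)
  N <- next_pow2(2L * n)
  pw <- pad_windows(matrix(x, ncol = 1), N)
  FX <- stats::mvfft(pw$padded)
  Ws <- cwt_from_spectra(FX, fs, bank, pw$idx)
  coef <- t(vapply(Ws, function(w) w[, 1], complex(n)))
  structure(list(coefficients = coef, cfs = bank$cfs, fs = fs), class = "tf_map")
}
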