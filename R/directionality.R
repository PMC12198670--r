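#' Lag-scanned coherence at a single center frequency
#'
#' EEG and EMG are shifted against each other in steps of one sample (4 ms at
#' 250 Hz) up to `max_lag_ms` in both directions; at each lag the windowed
#' wavelet coherence at `peak_cf` is recomputed on a fixed-length overlapping
#' span so values are comparable across lags. With the defaults the span is
#' 3968 samples = 15.872 s regardless of lag.
#'
#' Sign convention: positive lag means the EEG precedes the EMG (efferent,
#' cortex-to-muscle side); negative lag means the EMG precedes the EEG
#' (afferent side).
#'
#' @param eeg,emg Analysis-segment signals at `wincfg$fs` (default 16 s at
#'   250 Hz = 4000 samples); must be at least
#'   `wincfg$total_samples + max_lag` samples long.
#' @param peak_cf Center frequency at which coherence is evaluated, Hz
#'   (typically a per-band peak from the 4-s segment).
#' @param bank A [wavelet_bank()] (supplies the family `scale`).
#' @param wincfg A [windowing_config()].
#' @param max_lag_ms Maximal shift in either direction, ms.
#' @return Tibble of class `lag_profile` with columns `lag_ms` and
#'   `coherence`; attributes `peak_cf`, `smoothed = FALSE`.
#' @export
lagged_coherence <- function(eeg, emg, peak_cf, bank = wavelet_bank(),
                             wincfg = windowing_config(), max_lag_ms = 128) {
  assert_finite_signal(eeg, "eeg")
  assert_finite_signal(emg, "emg")
  if (length(eeg) != length(emg)) {
    abort("`eeg` and `emg` must have equal length", class = "cmcwave_validation_error")
  }
  fs <- wincfg$fs
  max_lag <- as.integer(round(max_lag_ms / 1000 * fs))
  span <- wincfg$total_samples
  if (length(eeg) < span + max_lag) {
    abort(sprintf("segment too short: need >= %d samples for a %g ms lag scan, got %d",
                  span + max_lag, max_lag_ms, length(eeg)),
          class = "cmcwave_validation_error")
  }
  prof <- lag_profiles_multi(eeg, emg, peak_cf, bank, wincfg, max_lag)
  lags <- seq.int(-max_lag, max_lag)
  out <- tibble(lag_ms = lags * 1000 / fs, coherence = pmin(prof[, 1], 1))
  class(out) <- c("lag_profile", class(out))
  attr(out, "peak_cf") <- peak_cf
  attr(out, "smoothed") <- FALSE
  attr(out, "fs") <- fs
  out
}

# Lag-scanned coherence at several center frequencies at once.
# Returns a matrix (2 * max_lag + 1) x length(cfs); row i is lag
# (i - max_lag - 1) samples. All lags share the forward transforms: the
# shifted windows of every lag are batched into a single mvfft and the fixed
# side is computed once, so adding a cf costs only one inverse transform.
lag_profiles_multi <- function(eeg, emg, cfs, bank, wincfg, max_lag) {
  L <- wincfg$window_samples
  nw <- wincfg$n_windows
  fs <- wincfg$fs
  span <- wincfg$total_samples
  N <- next_pow2(2L * L)
  pre <- (N - L) %/% 2L
  idx <- seq.int(pre + 1L, pre + L)
  f <- (seq_len(N) - 1L) * fs / N
  half <- N %/% 2L + 1L

  # batched spectra of shifted windows: offsets[k] is the shift of batch k
  batch_spectra <- function(x, offsets) {
    starts <- rep(offsets, each = nw) + rep((seq_len(nw) - 1L) * L, times = length(offsets))
    M <- matrix(0, N, length(starts))
    M[idx, ] <- x[outer(seq_len(L), starts, `+`)]
    stats::mvfft(M)
  }

  FX_fix_eeg <- batch_spectra(eeg, 0L)                   # N x nw
  FX_fix_emg <- batch_spectra(emg, 0L)
  F_pos <- batch_spectra(emg, seq.int(0L, max_lag))      # lags 0..max_lag
  F_neg <- batch_spectra(eeg, seq.int(1L, max_lag))      # lags -1..-max_lag

  per_window_coh <- function(W_move, W_fix, n_batch) {
    Wf <- W_fix[, rep(seq_len(nw), times = n_batch), drop = FALSE]
    sxy <- colMeans(W_move * Conj(Wf))
    sxx <- colMeans(Mod(W_move)^2)
    syy <- colMeans(Mod(Wf)^2)
    coh <- Mod(sxy) / sqrt(sxx * syy)
    coh[!is.finite(coh)] <- 0
    colMeans(matrix(coh, nrow = nw))
  }

  vapply(cfs, function(cf) {
    G <- numeric(N)
    G[seq_len(half)] <- wavelet_filter(f[seq_len(half)], cf, bank$scale)
    if (N %% 2L == 0L) G[half] <- G[half] / 2
    inv <- function(FM) stats::mvfft(FM * G, inverse = TRUE)[idx, , drop = FALSE] / N
    Wfe <- inv(FX_fix_eeg)
    Wfm <- inv(FX_fix_emg)
    coh_pos <- per_window_coh(inv(F_pos), Wfe, max_lag + 1L)
    coh_neg <- per_window_coh(inv(F_neg), Wfm, max_lag)
    c(rev(coh_neg), coh_pos)
  }, numeric(2L * max_lag + 1L))
}

#' Moving-average smoothing of a lag profile
#'
#' Centered moving average over `span_ms` (5 points at the default 4-ms lag
#' spacing: the point and its two neighbours on each side). Edges use the
#' available shrinking window.
#'
#' @param profile A `lag_profile` tibble.
#' @param span_ms Smoothing span, ms.
#' @return Smoothed `lag_profile` (attribute `smoothed = TRUE`).
#' @export
smooth_lag_profile <- function(profile, span_ms = 16) {
  step_ms <- if (nrow(profile) > 1) diff(profile$lag_ms[1:2]) else span_ms
  half <- max(1L, round(span_ms / step_ms / 2))
  n <- nrow(profile)
  sm <- vapply(seq_len(n), function(i) {
    j <- max(1L, i - half):min(n, i + half)
    mean(profile$coherence[j])
  }, numeric(1))
  out <- profile
  out$coherence <- sm
  attr(out, "smoothed") <- TRUE
  out
}

#' Afferent and efferent CMC and delays from a lag profile
#'
#' The efferent side comprises positive lags (EEG precedes EMG), the afferent
#' side negative lags; lag 0 belongs to neither. Per side, the transmission
#' delay is the magnitude of the coherence-maximizing lag and the directional
#' CMC is the coherence at that lag. On an all-equal side the smallest
#' absolute lag is taken.
#'
#' @param profile A (preferably smoothed) `lag_profile`.
#' @return One-row tibble with `afferent_cmc`, `afferent_delay_ms`,
#'   `efferent_cmc`, `efferent_delay_ms`, `direction` (side of the global
#'   maximum) and `peak_cf`.
#' @export
estimate_directional_cmc <- function(profile) {
  side <- function(sel) {
    lag <- profile$lag_ms[sel]
    coh <- profile$coherence[sel]
    ord <- order(abs(lag))   # ties at equal coherence -> smallest |lag|
    lag <- lag[ord]; coh <- coh[ord]
    i <- which.max(coh)
    c(cmc = coh[i], delay = abs(lag[i]))
  }
  aff <- side(profile$lag_ms < 0)
  eff <- side(profile$lag_ms > 0)
  tibble(
    afferent_cmc = unname(aff["cmc"]), afferent_delay_ms = unname(aff["delay"]),
    efferent_cmc = unname(eff["cmc"]), efferent_delay_ms = unname(eff["delay"]),
    dominant_direction = if (eff["cmc"] >= aff["cmc"]) "efferent" else "afferent",
    peak_cf = attr(profile, "peak_cf") %||% NA_real_
  )
}

#' Lag scan, smoothing and directional estimate in one call
#'
#' @inheritParams lagged_coherence
#' @param span_ms Smoothing span passed to [smooth_lag_profile()].
#' @return As [estimate_directional_cmc()].
#' @export
directional_cmc <- function(eeg, emg, peak_cf, bank = wavelet_bank(),
                            wincfg = windowing_config(), max_lag_ms = 128,
                            span_ms = 16) {
  prof <- lagged_coherence(eeg, emg, peak_cf, bank, wincfg, max_lag_ms)
  estimate_directional_cmc(smooth_lag_profile(prof, span_ms))
}
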