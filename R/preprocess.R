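#' Pre-processing configuration
#'
#' Defaults follow the standing-CMC protocol: a second-order Butterworth
#' 50-Hz notch (49-51 Hz band-stop), 1-Hz high-pass and 100-Hz low-pass,
#' 5-s edge trimming, downsampling to 250 Hz. Filters are applied zero-phase
#' (forward-backward) by default because phase distortion would corrupt the
#' transmission-delay estimate downstream.
#'
#' @param notch_hz Notch center, Hz (0 disables).
#' @param notch_bw_hz Notch bandwidth, Hz.
#' @param notch_order Butterworth order of the band-stop prototype.
#' @param hp_hz High-pass cutoff, Hz.
#' @param lp_hz Low-pass cutoff, Hz.
#' @param fs_target Target rate after downsampling, Hz.
#' @param trim_s Seconds trimmed from each end.
#' @param zero_phase Forward-backward filtering if `TRUE`.
#' @return Object of class `preprocess_config`.
#' @export
preprocess_config <- function(notch_hz = 50, notch_bw_hz = 2, notch_order = 2,
                              hp_hz = 1, lp_hz = 100, fs_target = 250,
                              trim_s = 5, zero_phase = TRUE) {
  assert_field(hp_hz < lp_hz, "hp_hz", "must be below lp_hz")
  assert_field(lp_hz < fs_target / 2, "lp_hz", "must be below fs_target / 2")
  structure(list(notch_hz = notch_hz, notch_bw_hz = notch_bw_hz,
                 notch_order = notch_order, hp_hz = hp_hz, lp_hz = lp_hz,
                 fs_target = fs_target, trim_s = trim_s,
                 zero_phase = zero_phase),
            class = "preprocess_config")
}

# Butterworth cascade for the configured chain at sampling rate fs
chain_filters <- function(fs, cfg) {
  filts <- list()
  if (cfg$notch_hz > 0) {
    edges <- c(cfg$notch_hz - cfg$notch_bw_hz / 2, cfg$notch_hz + cfg$notch_bw_hz / 2)
    filts$notch <- signal::butter(cfg$notch_order, edges / (fs / 2), type = "stop")
  }
  filts$hp <- signal::butter(2, cfg$hp_hz / (fs / 2), type = "high")
  filts$lp <- signal::butter(4, cfg$lp_hz / (fs / 2), type = "low")
  filts
}

# complex frequency response of an IIR filter on the length-N DFT grid
# (Horner evaluation of numerator and denominator polynomials in z^-1)
iir_response <- function(filt, N) {
  z <- exp(-2i * pi * (seq_len(N) - 1L) / N)
  horner <- function(coef) {
    acc <- rep(coef[length(coef)] + 0i, N)
    for (j in seq(length(coef) - 1L, 1L)) acc <- acc * z + coef[j]
    acc
  }
  horner(filt$b) / horner(filt$a)
}

# Zero-phase response of the whole chain: the product of squared magnitudes,
# the exact transfer function of forward-backward application of each filter.
chain_zero_phase_response <- function(filts, N) {
  Reduce(`*`, lapply(filts, function(f) Mod(iir_response(f, N))^2))
}

filter_columns <- function(m, fs, cfg) {
  filts <- chain_filters(fs, cfg)
  if (cfg$zero_phase) {
    # spectral implementation of forward-backward filtering (circular
    # boundary; edge transients fall in the trimmed 5-s margins)
    N <- nrow(m)
    R <- chain_zero_phase_response(filts, N)
    Re(stats::mvfft(stats::mvfft(m) * R, inverse = TRUE)) / N
  } else {
    out <- m
    for (f in filts) out <- apply(out, 2, function(x) as.numeric(signal::filter(f, x)))
    out
  }
}

#' Notch + band-pass filtering of a single channel
#'
#' Applies the 50-Hz notch, then the 1-Hz high-pass and 100-Hz low-pass. In
#' zero-phase mode (the default) the cascade is applied forward-backward --
#' realized spectrally as multiplication by the squared magnitude response,
#' which introduces no group delay.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate, Hz.
#' @param cfg A [preprocess_config()].
#' @return Filtered signal.
#' @export
filter_signal <- function(x, fs, cfg = preprocess_config()) {
  assert_finite_signal(x)
  if (fs <= 2 * cfg$lp_hz) {
    abort(sprintf("sampling rate %g Hz too low for a %g Hz low-pass", fs, cfg$lp_hz),
          class = "cmcwave_validation_error")
  }
  as.numeric(filter_columns(matrix(x, ncol = 1), fs, cfg))
}

#' Apply the filter chain to every channel of a recording
#'
#' @param rec A [recording()].
#' @param cfg A [preprocess_config()].
#' @return Filtered recording.
#' @export
apply_filters <- function(rec, cfg = preprocess_config()) {
  stopifnot(inherits(rec, "cmc_recording"))
  if (rec$fs_eeg <= 2 * cfg$lp_hz || rec$fs_emg <= 2 * cfg$lp_hz) {
    abort(sprintf("sampling rate too low for a %g Hz low-pass", cfg$lp_hz),
          class = "cmcwave_validation_error")
  }
  out <- rec
  out$eeg <- filter_columns(rec$eeg, rec$fs_eeg, cfg)
  out$emg <- filter_columns(rec$emg, rec$fs_emg, cfg)
  colnames(out$eeg) <- colnames(rec$eeg)
  colnames(out$emg) <- colnames(rec$emg)
  out
}

#' Trim transient-contaminated edges
#'
#' @param rec A [recording()].
#' @param trim_s Seconds removed from each end.
#' @return Trimmed recording (a 30-s trial becomes 20 s with the default 5 s).
#' @export
trim_edges <- function(rec, trim_s = 5) {
  stopifnot(inherits(rec, "cmc_recording"))
  if (trim_s == 0) return(rec)
  dur <- recording_duration(rec)
  if (dur <= 2 * trim_s) {
    abort(sprintf("recording of %.3g s too short to trim %g s from each end", dur, trim_s),
          class = "cmcwave_validation_error")
  }
  cut <- function(m, fs) {
    k <- round(trim_s * fs)
    m[seq.int(k + 1L, nrow(m) - k), , drop = FALSE]
  }
  out <- rec
  out$eeg <- cut(rec$eeg, rec$fs_eeg)
  out$emg <- cut(rec$emg, rec$fs_emg)
  out
}

#' ECG removal from one EMG channel by wavelet-intensity beat detection and
#' template subtraction
#'
#' The QRS complexes of ECG contamination dominate the low-frequency wavelet
#' intensity of an EMG channel. The algorithm (i) computes the summed wavelet
#' intensity over a small bank of time-localized wavelets (the EMG-intensity
#' scale 0.3, whose ~25-ms support matches a QRS complex; the narrow-band
#' coherence bank would smear a beat over seconds); (ii) smooths the
#' intensity over ~25 ms and detects beats as peaks above
#' `median + 0.25 * (max - median)` separated by a refractory period, refined
#' to the strongest deflection at the full rate; (iii) ensemble-averages the
#' EMG around the detected beats into a smoothed beat template;
#' (iv) subtracts a per-beat least-squares-scaled copy of the template. If
#' fewer than 3 beats are detected the channel is returned unchanged with an
#' empty beat list.
#'
#' @param x EMG channel.
#' @param fs Sampling rate, Hz.
#' @param intensity_bank Wavelet bank for the beat-band intensity; only cfs
#'   at or below `max_cf` are used.
#' @param max_cf Upper center frequency of the beat-band intensity, Hz.
#' @param refractory_s Minimal beat separation, s.
#' @param template_halfwidth_s Template half-width, s.
#' @param smooth_ms Moving-average span applied to the template, ms.
#' @return Cleaned channel with attributes `beat_samples` (detected beat
#'   indices) and `template`.
#' @export
remove_ecg <- function(x, fs,
                       intensity_bank = wavelet_bank(scale = 0.3, j_range = 0:2),
                       max_cf = 40,
                       refractory_s = 0.3, template_halfwidth_s = 0.15,
                       smooth_ms = 10) {
  assert_finite_signal(x)
  low <- bank_subset(intensity_bank, 0, max_cf)
  # beat localization runs on a decimated copy (the beat band lives far below
  # the decimated Nyquist), then peaks are refined at the full rate
  dec <- max(1L, floor(fs / 500))
  xd <- x[seq.int(1L, length(x), by = dec)]
  fsd <- fs / dec
  inten <- ecg_band_intensity(xd, fsd, low)
  k <- max(3L, round(0.025 * fsd))
  inten <- as.numeric(stats::filter(inten, rep(1 / k, k), sides = 2))
  inten[is.na(inten)] <- 0
  thr <- median(inten) + 0.25 * (max(inten) - median(inten))
  peaks_d <- detect_peaks(inten, thr, round(refractory_s * fsd))
  half_ref <- round(0.01 * fs)
  peaks <- vapply(peaks_d, function(p) {
    c0 <- (p - 1L) * dec + 1L
    win <- max(1L, c0 - half_ref):min(length(x), c0 + half_ref)
    win[which.max(abs(x[win]))]
  }, integer(1))
  if (length(peaks) < 3L) {
    out <- x
    attr(out, "beat_samples") <- integer(0)
    return(out)
  }
  half <- round(template_halfwidth_s * fs)
  full <- peaks[peaks > half & peaks <= length(x) - half]
  if (length(full) < 3L) {
    out <- x
    attr(out, "beat_samples") <- integer(0)
    return(out)
  }
  segs <- vapply(full, function(p) x[(p - half):(p + half)], numeric(2L * half + 1L))
  tmpl <- rowMeans(segs)
  k <- max(1L, round(smooth_ms / 1000 * fs))
  tmpl <- as.numeric(stats::filter(tmpl, rep(1 / k, k), sides = 2))
  tmpl[is.na(tmpl)] <- 0
  out <- x
  denom <- sum(tmpl^2)
  for (p in full) {
    idx <- (p - half):(p + half)
    a <- sum(out[idx] * tmpl) / denom
    out[idx] <- out[idx] - a * tmpl
  }
  attr(out, "beat_samples") <- full
  attr(out, "template") <- tmpl
  out
}

# summed |W|^2 over the low-cf rows of the wavelet transform; modest padding
# suffices here (the trace only localizes beats)
ecg_band_intensity <- function(x, fs, bank) {
  n <- length(x)
  N <- stats::nextn(n + round(fs), c(2, 3, 5))
  pw <- pad_windows(matrix(x, ncol = 1), N)
  FX <- stats::mvfft(pw$padded)
  Ws <- cwt_from_spectra(FX, fs, bank, pw$idx)
  Reduce(`+`, lapply(Ws, function(w) Mod(w[, 1])^2))
}

# local maxima above thr, greedily enforcing a refractory distance
detect_peaks <- function(x, thr, refractory) {
  n <- length(x)
  is_peak <- which(x > thr &
                   x >= c(-Inf, x[-n]) &
                   x >= c(x[-1], -Inf))
  if (!length(is_peak)) return(integer(0))
  ord <- is_peak[order(x[is_peak], decreasing = TRUE)]
  kept <- integer(0)
  for (p in ord) {
    if (!length(kept) || all(abs(kept - p) >= refractory)) kept <- c(kept, p)
  }
  sort(kept)
}

#' Remove ECG contamination from all EMG channels of a recording
#'
#' @param rec A [recording()].
#' @param ... Passed to [remove_ecg()].
#' @return Recording with cleaned EMG; attribute `ecg_beats` lists detected
#'   beat indices per channel.
#' @export
remove_ecg_recording <- function(rec, ...) {
  stopifnot(inherits(rec, "cmc_recording"))
  out <- rec
  beats <- list()
  for (ch in colnames(rec$emg)) {
    cleaned <- remove_ecg(rec$emg[, ch], rec$fs_emg, ...)
    beats[[ch]] <- attr(cleaned, "beat_samples")
    out$emg[, ch] <- as.numeric(cleaned)
  }
  attr(out, "ecg_beats") <- beats
  out
}

#' Common average reference
#'
#' Subtracts the per-sample mean across EEG channels from every EEG channel;
#' EMG (bipolar, own reference) is untouched.
#'
#' @param x A [recording()] or a time-by-channel EEG matrix (>= 2 channels).
#' @return Same type as the input, re-referenced.
#' @export
common_average_reference <- function(x) {
  car_mat <- function(m) {
    if (ncol(m) < 2L) {
      abort("common average reference needs at least 2 EEG channels",
            class = "cmcwave_validation_error")
    }
    m - rowMeans(m)
  }
  if (inherits(x, "cmc_recording")) {
    x$eeg <- car_mat(x$eeg)
    x
  } else {
    car_mat(as.matrix(x))
  }
}

#' Downsample a signal by integer decimation
#'
#' Assumes the 100-Hz low-pass has already been applied, so decimation to
#' 250 Hz is alias-free.
#'
#' @param x Numeric signal.
#' @param fs Current rate, Hz.
#' @param fs_target Target rate, Hz; `fs` must be an integer multiple.
#' @return Decimated signal.
#' @export
resample_signal <- function(x, fs, fs_target = 250) {
  if (fs == fs_target) return(x)
  if (fs %% fs_target != 0) {
    abort(sprintf("cannot decimate %g Hz to %g Hz by an integer factor", fs, fs_target),
          class = "cmcwave_validation_error")
  }
  x[seq.int(1L, length(x), by = fs %/% fs_target)]
}

#' Downsample a recording to a common rate
#'
#' @param rec A [recording()].
#' @param fs_target Target rate, Hz (default 250).
#' @return Recording with both modalities at `fs_target`.
#' @export
resample_250 <- function(rec, fs_target = 250) {
  stopifnot(inherits(rec, "cmc_recording"))
  ds <- function(m, fs) {
    out <- apply(m, 2, resample_signal, fs = fs, fs_target = fs_target)
    colnames(out) <- colnames(m)
    out
  }
  out <- rec
  out$eeg <- ds(rec$eeg, rec$fs_eeg)
  out$emg <- ds(rec$emg, rec$fs_emg)
  out$fs_eeg <- fs_target
  out$fs_emg <- fs_target
  out
}

#' Split a trimmed 20-s trial into peak-search and analysis segments
#'
#' The first 4 s serve to locate per-band peak coherence frequencies without
#' biasing the later analysis; the remaining 16 s carry the significance and
#' directionality computations. The two segments partition the trial.
#'
#' @param rec A 20-s [recording()] at a common rate (250 Hz).
#' @param peak_s Length of the peak-search segment, s.
#' @return List with `peak` and `analysis` recordings.
#' @export
segment_trial <- function(rec, peak_s = 4) {
  stopifnot(inherits(rec, "cmc_recording"))
  if (rec$fs_eeg != rec$fs_emg) {
    abort("segment_trial expects a recording downsampled to a common rate",
          class = "cmcwave_validation_error")
  }
  dur <- recording_duration(rec)
  if (abs(dur - 20) > 1e-6) {
    abort(sprintf("expected a 20-s trimmed trial, got %.4g s", dur),
          class = "cmcwave_validation_error")
  }
  k <- round(peak_s * rec$fs_eeg)
  take <- function(m, idx) m[idx, , drop = FALSE]
  peak <- rec; analysis <- rec
  peak$eeg <- take(rec$eeg, seq_len(k)); peak$emg <- take(rec$emg, seq_len(k))
  idx <- seq.int(k + 1L, nrow(rec$eeg))
  analysis$eeg <- take(rec$eeg, idx); analysis$emg <- take(rec$emg, idx)
  list(peak = peak, analysis = analysis)
}

#' Full pre-processing chain
#'
#' notch -> band-pass -> trim -> ECG removal (EMG) -> common average
#' reference (EEG, if >= 2 channels) -> downsample to 250 Hz.
#'
#' @param rec A raw [recording()].
#' @param cfg A [preprocess_config()].
#' @param remove_ecg_artifacts Run the ECG template-subtraction stage.
#' @param car Apply the common average reference to EEG.
#' @return Pre-processed recording at `cfg$fs_target`.
#' @export
preprocess_recording <- function(rec, cfg = preprocess_config(),
                                 remove_ecg_artifacts = TRUE, car = TRUE) {
  out <- apply_filters(rec, cfg)
  out <- trim_edges(out, cfg$trim_s)
  if (remove_ecg_artifacts) out <- remove_ecg_recording(out)
  if (car && ncol(out$eeg) >= 2L) out <- common_average_reference(out)
  resample_250(out, cfg$fs_target)
}
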