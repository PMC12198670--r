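# Batched trial-level spectral machinery.
#
# The public per-pair functions (wavelet_coherence, coherence_threshold,
# lagged_coherence) recompute channel transforms on every call, which is the
# clearest formulation but wasteful inside the cohort pipeline where each EEG
# channel takes part in several pairs. The helpers here compute per-channel
# window transforms once per trial and combine them per pair; they must (and
# are tested to) agree with the public functions.

# one-sided Cauchy gain on the length-N DFT grid
gain_vector <- function(N, fs, cf, scale) {
  f <- (seq_len(N) - 1L) * fs / N
  half <- N %/% 2L + 1L
  G <- numeric(N)
  G[seq_len(half)] <- wavelet_filter(f[seq_len(half)], cf, scale)
  if (N %% 2L == 0L) G[half] <- G[half] / 2
  G
}

# spectra of windows shifted by each offset: columns ordered offset-major,
# window-minor; rows 1..N (padded symmetrically)
shifted_window_spectra <- function(x, offsets, wincfg, N) {
  L <- wincfg$window_samples
  nw <- wincfg$n_windows
  pre <- (N - L) %/% 2L
  starts <- rep(offsets, each = nw) + rep((seq_len(nw) - 1L) * L, times = length(offsets))
  M <- matrix(0, N, length(starts))
  M[seq.int(pre + 1L, pre + L), ] <- x[sequence(rep(L, length(starts)), from = starts + 1L)]
  stats::mvfft(M)
}

# Inverse-transform-and-restrict operator for one wavelet gain vector.
# The gain has compact support on the DFT grid, so the inverse transform
# restricted to the unpadded span is a small complex matrix product
# (span x |support|) -- far cheaper than a full-length inverse FFT when many
# window columns share the same gain.
.inverter_cache <- new.env(parent = emptyenv())

make_inverter <- function(G, wincfg, N, cache_key = NULL) {
  if (!is.null(cache_key)) {
    hit <- get0(cache_key, envir = .inverter_cache)
    if (!is.null(hit)) return(hit)
  }
  pre <- (N - wincfg$window_samples) %/% 2L
  idx <- seq.int(pre + 1L, pre + wincfg$window_samples)
  S <- which(G > 1e-14 * max(G, 1e-300))
  out <- if (!length(S)) {
    function(FX) matrix(0 + 0i, length(idx), ncol(FX))
  } else {
    E <- exp(2i * pi * outer(idx - 1L, S - 1L) / N) / N
    Gs <- G[S]
    function(FX) E %*% (FX[S, , drop = FALSE] * Gs)
  }
  if (!is.null(cache_key)) assign(cache_key, out, envir = .inverter_cache)
  out
}

inverter_key <- function(N, wincfg, cf, scale) {
  sprintf("%d_%d_%.9g_%.9g_%.9g", N, wincfg$window_samples, wincfg$fs, cf, scale)
}

# Subspace (Gram-matrix) form of the restricted wavelet transform. For gain
# support S, coefficients over the unpadded span are W = E (Gs * FX_S) with
# E the span x |S| inverse-basis matrix; every span sum the coherence needs
# is then a quadratic form in the Gram matrix M = E^H E:
#   sum_t Wx Conj(Wy) = v_y^H M v_x,  v = Gs * FX_S.
# Working with v (|S| rows) instead of W (span rows) makes the per-window
# cross/auto sums small BLAS products. Exactly equivalent to the full
# transform; M is cached per (N, window, fs, cf, scale).
vspace_cf <- function(cf, scale, wincfg, N) {
  key <- paste0("v_", inverter_key(N, wincfg, cf, scale))
  hit <- get0(key, envir = .inverter_cache)
  if (!is.null(hit)) return(hit)
  G <- gain_vector(N, wincfg$fs, cf, scale)
  pre <- (N - wincfg$window_samples) %/% 2L
  idx <- seq.int(pre + 1L, pre + wincfg$window_samples)
  S <- which(G > 1e-14 * max(G, 1e-300))
  E <- exp(2i * pi * outer(idx - 1L, S - 1L) / N) / N
  M <- crossprod(Conj(E), E)
  out <- list(S = S, Gs = G[S], M = M)
  assign(key, out, envir = .inverter_cache)
  out
}

# v-coefficients and their Gram image for a spectra matrix
v_pair <- function(vs, FX) {
  v <- FX[vs$S, , drop = FALSE] * vs$Gs
  W <- vs$M %*% v
  list(v = v, W = W, auto = pmax(Re(colSums(Conj(v) * W)), 0))
}

# per-window coherence for aligned column pairs, averaged over window blocks
coh_aligned_v <- function(px, py, nw) {
  cross <- colSums(Conj(px$v) * py$W)
  coh <- Mod(cross) / sqrt(px$auto * py$auto)
  coh[!is.finite(coh)] <- 0
  colMeans(matrix(coh, nrow = nw))
}

# forward window spectra of one channel (matrix span x n_signals allowed)
channel_window_spectra <- function(x, wincfg, N) {
  x <- as.matrix(x)
  L <- wincfg$window_samples
  nw <- wincfg$n_windows
  xmat <- matrix(as.numeric(x[seq_len(nw * L), ]), nrow = L)
  stats::mvfft(pad_windows(xmat, N)$padded)
}

# v-space cache over all cfs of a bank for a set of channels
vcache_channels <- function(rec, chs, bank, wincfg) {
  N <- next_pow2(2L * wincfg$window_samples)
  out <- lapply(chs, function(ch) {
    x <- if (ch %in% colnames(rec$eeg)) rec$eeg[, ch] else rec$emg[, ch]
    FX <- channel_window_spectra(x, wincfg, N)
    lapply(bank$cfs, function(cf) {
      v_pair(vspace_cf(cf, bank$scale, wincfg, N), FX)
    })
  })
  names(out) <- chs
  out
}

# Per-trial band table using per-channel caches; equivalent to calling
# wavelet_coherence() pair by pair.
trial_band_table_fast <- function(segments, cfg) {
  bands <- cmc_bands()
  used <- bands[bands$band %in% cfg$bands_used, ]
  span_bank <- bank_subset(cfg$bank, min(used$lo), max(used$hi))
  peak_w <- peak_windowing_config(cfg$wincfg$fs)
  eeg_ch <- intersect(cfg$eeg_channels %||% colnames(segments$peak$eeg),
                      colnames(segments$peak$eeg))
  emg_ch <- intersect(cfg$emg_channels %||% colnames(segments$peak$emg),
                      colnames(segments$peak$emg))
  pkE <- vcache_channels(segments$peak, eeg_ch, span_bank, peak_w)
  pkM <- vcache_channels(segments$peak, emg_ch, span_bank, peak_w)
  anE <- vcache_channels(segments$analysis, eeg_ch, span_bank, cfg$wincfg)
  anM <- vcache_channels(segments$analysis, emg_ch, span_bank, cfg$wincfg)
  coh_spec <- function(cx, cy, nw) {
    vapply(seq_along(cx), function(k) coh_aligned_v(cx[[k]], cy[[k]], nw), numeric(1))
  }
  purrr::map_dfr(eeg_ch, function(ei) {
    purrr::map_dfr(emg_ch, function(mi) {
      pk <- tibble(cf = span_bank$cfs,
                   coherence = pmin(coh_spec(pkE[[ei]], pkM[[mi]], peak_w$n_windows), 1))
      an <- tibble(cf = span_bank$cfs,
                   coherence = pmin(coh_spec(anE[[ei]], anM[[mi]], cfg$wincfg$n_windows), 1))
      purrr::map_dfr(seq_len(nrow(used)), function(b) {
        tibble(eeg = ei, emg = mi, band = used$band[b],
               peak_cf = band_peak_frequency(pk, c(used$lo[b], used$hi[b])),
               band_mean = band_mean(an, c(used$lo[b], used$hi[b])))
      })
    })
  })
}

# Per-trial surrogate thresholds. AAFT surrogates are generated once per
# channel and shared across the pairs of the trial (each pair still sees
# n_surrogates independent null pairs); deterministic given `seed`.
trial_thresholds_fast <- function(segments, bt, cfg, seed) {
  wincfg <- cfg$wincfg
  span <- wincfg$total_samples
  scfg <- cfg$surrogate
  bands <- cmc_bands()
  used <- bands[bands$band %in% unique(bt$band), ]
  chs <- unique(c(bt$eeg, bt$emg))
  ch_seeds <- derive_seeds(seed, length(chs))
  sur <- lapply(seq_along(chs), function(i) {
    ch <- chs[i]
    x <- if (ch %in% colnames(segments$analysis$eeg)) {
      segments$analysis$eeg[seq_len(span), ch]
    } else {
      segments$analysis$emg[seq_len(span), ch]
    }
    with_seed_if(ch_seeds[i], {
      vapply(seq_len(scfg$n_surrogates), function(s) aaft(x), numeric(span))
    })
  })
  names(sur) <- chs
  # one forward transform per channel, v-space coefficients per band cf
  N <- next_pow2(2L * wincfg$window_samples)
  FXs <- lapply(sur, channel_window_spectra, wincfg = wincfg, N = N)
  thr <- numeric(nrow(bt))
  for (b in seq_len(nrow(used))) {
    sub <- bank_subset(cfg$bank, used$lo[b], used$hi[b])
    P <- lapply(FXs, function(FX) {
      lapply(sub$cfs, function(cf) v_pair(vspace_cf(cf, sub$scale, wincfg, N), FX))
    })
    rows <- which(bt$band == used$band[b])
    for (r in rows) {
      per_cf <- vapply(seq_along(sub$cfs), function(k) {
        coh_aligned_v(P[[bt$eeg[r]]][[k]], P[[bt$emg[r]]][[k]], wincfg$n_windows)
      }, numeric(scfg$n_surrogates))
      bm <- rowMeans(matrix(per_cf, nrow = scfg$n_surrogates))
      thr[r] <- threshold_statistic(bm, scfg)
    }
  }
  thr
}

# Per-trial lag scans for all pairs and bands at once. The forward spectra of
# the shifted windows are per-channel (pair-independent) and the inverse
# transforms are per (channel, cf); both are cached.
trial_lag_scan_fast <- function(segments, bt, peak_cf_of_band, cfg, max_lag) {
  wincfg <- cfg$wincfg
  nw <- wincfg$n_windows
  N <- next_pow2(2L * wincfg$window_samples)
  eeg_ch <- unique(bt$eeg)
  emg_ch <- unique(bt$emg)
  get_sig <- function(ch) {
    if (ch %in% colnames(segments$analysis$eeg)) segments$analysis$eeg[, ch]
    else segments$analysis$emg[, ch]
  }
  F_fix <- lapply(c(eeg_ch, emg_ch), function(ch)
    shifted_window_spectra(get_sig(ch), 0L, wincfg, N))
  names(F_fix) <- c(eeg_ch, emg_ch)
  F_pos <- lapply(emg_ch, function(ch)
    shifted_window_spectra(get_sig(ch), seq.int(0L, max_lag), wincfg, N))
  names(F_pos) <- emg_ch
  F_neg <- lapply(eeg_ch, function(ch)
    shifted_window_spectra(get_sig(ch), seq.int(1L, max_lag), wincfg, N))
  names(F_neg) <- eeg_ch

  cfs <- unique(unlist(peak_cf_of_band))
  Vs <- list()
  for (cf in cfs) {
    vs <- vspace_cf(cf, cfg$bank$scale, wincfg, N)
    key <- sprintf("%.6f", cf)
    Vs[[key]] <- list(
      fix = lapply(F_fix, function(FX) v_pair(vs, FX)),
      pos = lapply(F_pos, function(FX) v_pair(vs, FX)),
      neg = lapply(F_neg, function(FX) v_pair(vs, FX))
    )
  }

  # windowed coherence of a fixed block (nw windows) against every window of
  # a lag batch; cross terms are quadratic forms v_fix^H M v_move = W_fix^H v_move
  coh_fix_vs_batch <- function(fix, move) {
    C <- ncol(move$v)
    wcol <- rep(seq_len(nw), times = C %/% nw)
    sel <- cbind(wcol, seq_len(C))
    cross <- crossprod(Conj(fix$W), move$v)[sel]
    coh <- Mod(cross) / sqrt(move$auto * fix$auto[wcol])
    coh[!is.finite(coh)] <- 0
    colMeans(matrix(coh, nrow = nw))
  }

  lapply(seq_len(nrow(bt)), function(r) {
    cf <- peak_cf_of_band[[bt$band[r]]]
    W <- Vs[[sprintf("%.6f", cf)]]
    coh_pos <- coh_fix_vs_batch(W$fix[[bt$eeg[r]]], W$pos[[bt$emg[r]]])
    coh_neg <- coh_fix_vs_batch(W$fix[[bt$emg[r]]], W$neg[[bt$eeg[r]]])
    pmin(c(rev(coh_neg), coh_pos), 1)
  })
}
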