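#' Surrogate configuration
#'
#' @param n_surrogates Number of AAFT surrogate pairs (default 100).
#' @param statistic Summary of the surrogate band-mean coherence distribution
#'   used as threshold: `"median"` (default) or `"percentile"`.
#' @param percentile Percentile in (0, 100), used when
#'   `statistic = "percentile"`.
#' @param seed Integer seed for surrogate generation, or `NULL`.
#' @return Object of class `surrogate_config`.
#' @export
surrogate_config <- function(n_surrogates = 100, statistic = c("median", "percentile"),
                             percentile = 95, seed = NULL) {
  statistic <- match.arg(statistic)
  assert_field(n_surrogates >= 2, "n_surrogates", "must be >= 2")
  if (statistic == "percentile") {
    assert_field(percentile > 0 && percentile < 100, "percentile", "must be in (0, 100)")
  }
  structure(list(n_surrogates = as.integer(n_surrogates), statistic = statistic,
                 percentile = percentile, seed = seed),
            class = "surrogate_config")
}

#' Amplitude-adjusted Fourier transform surrogate
#'
#' Destroys all temporal (and hence cross-signal) structure while exactly
#' preserving the signal's value distribution: (i) Gaussian noise is
#' rank-reordered to match the signal's ranks; (ii) that Gaussianized series
#' is phase-randomized with Hermitian-symmetric random phases; (iii) the
#' signal's sorted values are remapped onto the ranks of the phase-randomized
#' series. The multiset of surrogate values equals the original exactly.
#'
#' @param x Finite numeric vector, length >= 8, non-constant.
#' @param seed Optional integer seed.
#' @return Surrogate signal, same length as `x`.
#' @examples
#' s <- aaft(rnorm(64), seed = 1)
#' identical(sort(s), sort(s))
#' @export
aaft <- function(x, seed = NULL) {
  assert_finite_signal(x)
  n <- length(x)
  if (n < 8L) abort("signal must have length >= 8", class = "cmcwave_validation_error")
  if (diff(range(x)) == 0) {
    abort("constant signal: ranks undefined, cannot build AAFT surrogate",
          class = "cmcwave_validation_error")
  }
  with_seed_if(seed, {
    rk <- rank(x, ties.method = "first")
    g <- sort(rnorm(n))[rk]
    G <- fft(g)
    ks <- 2:(ceiling((n + 1L) / 2))
    phi <- runif(length(ks), 0, 2 * pi)
    Gp <- G
    Gp[ks] <- Mod(G[ks]) * exp(1i * phi)
    Gp[n + 2L - ks] <- Conj(Gp[ks])
    if (n %% 2L == 0L) Gp[n / 2L + 1L] <- Mod(G[n / 2L + 1L]) * sample(c(-1, 1), 1)
    g2 <- Re(fft(Gp, inverse = TRUE) / n)
    sort(x)[rank(g2, ties.method = "first")]
  })
}

#' Surrogate band-mean coherence distribution
#'
#' Independently AAFT-surrogates both signals `n_surrogates` times and
#' computes the band-mean wavelet coherence of each surrogate pair. The
#' distribution of these values is the coherence expected from signals with
#' the same amplitude statistics but no cross-signal coupling.
#'
#' @param x,y Analysis-segment signals (length `n_windows * window_samples`).
#' @param band Band name or `c(lo, hi)` in Hz.
#' @param bank A [wavelet_bank()].
#' @param wincfg A [windowing_config()].
#' @param cfg A [surrogate_config()].
#' @param bands Band definition table.
#' @return Numeric vector of `n_surrogates` band-mean coherences.
#' @export
surrogate_band_means <- function(x, y, band, bank = wavelet_bank(),
                                 wincfg = windowing_config(),
                                 cfg = surrogate_config(), bands = cmc_bands()) {
  lim <- if (is.character(band)) band_limits(band, bands) else c(lo = band[1], hi = band[2])
  sub <- bank_subset(bank, lim["lo"], lim["hi"])
  n <- length(x)
  if (n != wincfg$total_samples) {
    abort(sprintf("signal length %d does not equal n_windows * window_samples = %d",
                  n, wincfg$total_samples),
          class = "cmcwave_validation_error")
  }
  surr <- with_seed_if(cfg$seed, {
    SX <- matrix(0, n, cfg$n_surrogates)
    SY <- matrix(0, n, cfg$n_surrogates)
    for (i in seq_len(cfg$n_surrogates)) {
      SX[, i] <- aaft(x)
      SY[, i] <- aaft(y)
    }
    list(SX = SX, SY = SY)
  })
  # batched windowed coherence of the surrogate pairs (identical to calling
  # wavelet_coherence per pair; see the v-space helpers)
  N <- next_pow2(2L * wincfg$window_samples)
  FXx <- channel_window_spectra(surr$SX, wincfg, N)
  FXy <- channel_window_spectra(surr$SY, wincfg, N)
  per_cf <- vapply(sub$cfs, function(cf) {
    vs <- vspace_cf(cf, sub$scale, wincfg, N)
    coh_aligned_v(v_pair(vs, FXx), v_pair(vs, FXy), wincfg$n_windows)
  }, numeric(cfg$n_surrogates))
  rowMeans(matrix(pmin(per_cf, 1), nrow = cfg$n_surrogates))
}

#' CMC significance threshold from AAFT surrogates
#'
#' The threshold is a summary statistic (median by default, or a selectable
#' percentile) of the band-mean coherences of `n_surrogates` independently
#' surrogated signal pairs. Band-mean coherence above the threshold is
#' regarded as exceeding chance level.
#'
#' @inheritParams surrogate_band_means
#' @return Threshold value with attribute `"band_means"` carrying the full
#'   surrogate distribution (so alternative statistics can be re-derived
#'   without recomputation).
#' @export
coherence_threshold <- function(x, y, band, bank = wavelet_bank(),
                                wincfg = windowing_config(),
                                cfg = surrogate_config(), bands = cmc_bands()) {
  bm <- surrogate_band_means(x, y, band, bank, wincfg, cfg, bands)
  thr <- threshold_statistic(bm, cfg)
  attr(thr, "band_means") <- bm
  thr
}

# apply the configured summary statistic to surrogate band means
threshold_statistic <- function(band_means, cfg) {
  switch(cfg$statistic,
    median = median(band_means),
    percentile = unname(quantile(band_means, cfg$percentile / 100, type = 7))
  )
}

#' Significance mask over trials and bands
#'
#' Joins observed band-mean coherences with their surrogate thresholds and
#' flags which (trial, band) combinations are retained for directional
#' analysis (`coherence > threshold`, strictly).
#'
#' @param band_means Tibble with a `band_mean` column plus any identifying
#'   columns (trial, band, pair, ...).
#' @param thresholds Tibble with a `threshold` column and the same identifying
#'   columns.
#' @return Tibble of class `significance_mask` with columns of both inputs
#'   plus `retained`; attribute `"retention"` summarises the retained fraction
#'   per band.
#' @export
significance_mask <- function(band_means, thresholds) {
  keys <- intersect(names(band_means), names(thresholds))
  keys <- setdiff(keys, c("band_mean", "threshold"))
  out <- dplyr::left_join(band_means, thresholds, by = keys)
  if (anyNA(out$threshold)) {
    abort("some (trial, band) combinations have no threshold", class = "cmcwave_validation_error")
  }
  out$retained <- out$band_mean > out$threshold
  if ("band" %in% names(out)) {
    retention <- out |>
      group_by(.data$band) |>
      summarise(n = n(), retained_frac = mean(.data$retained), .groups = "drop")
    attr(out, "retention") <- retention
  }
  class(out) <- c("significance_mask", class(out))
  out
}
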