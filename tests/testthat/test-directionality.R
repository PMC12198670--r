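test_that("the overlapping span at maximal shift is exactly 15.872 s", {
  w <- windowing_config()
  max_lag <- round(128 / 1000 * w$fs)
  expect_equal(4000 - max_lag, w$total_samples)
  expect_equal(w$total_samples / w$fs, 15.872)
})

test_that("a pure delayed copy yields a lag profile peaking at the true delay", {
  w <- windowing_config()
  n <- w$total_samples + 32
  set.seed(2)
  src <- rnorm(n + 6)
  eeg <- src[seq_len(n) + 6]
  emg <- src[seq_len(n)]                # EMG lags EEG by 6 samples = 24 ms
  prof <- lagged_coherence(eeg, emg, peak_cf = 20, wavelet_bank(), w)
  expect_equal(prof$lag_ms[which.max(prof$coherence)], 24)
  expect_equal(max(prof$coherence), 1, tolerance = 1e-6)

  # swapping the roles mirrors the profile
  rev_prof <- lagged_coherence(emg, eeg, peak_cf = 20, wavelet_bank(), w)
  expect_equal(rev_prof$coherence, rev(prof$coherence), tolerance = 1e-10)

  zero <- lagged_coherence(eeg, eeg, peak_cf = 20, wavelet_bank(), w)
  expect_equal(zero$lag_ms[which.max(zero$coherence)], 0)
  expect_equal(zero$coherence, rev(zero$coherence), tolerance = 1e-10)
})

test_that("lag scans reject too-short segments", {
  w <- windowing_config()
  x <- rnorm(w$total_samples)  # 3968 < 3968 + 32
  expect_error(lagged_coherence(x, x, 10, wavelet_bank(), w), "too short")
})

test_that("lag-profile smoothing is a shrinking-window 5-point moving average", {
  const <- tibble::tibble(lag_ms = seq(-128, 128, 4), coherence = 0.42)
  class(const) <- c("lag_profile", class(const))
  expect_equal(smooth_lag_profile(const)$coherence, rep(0.42, 65))

  spike <- const; spike$coherence <- c(rep(0, 32), 1, rep(0, 32))
  sm <- smooth_lag_profile(spike)
  # direct convolution oracle: interior mass spread over 5 points, conserved
  expect_equal(sm$coherence[31:35], rep(0.2, 5))
  expect_equal(sum(sm$coherence), 1)

  set.seed(4)
  noisy <- const; noisy$coherence <- runif(65)
  once <- smooth_lag_profile(noisy)
  twice <- smooth_lag_profile(once)
  expect_lt(var(twice$coherence), var(once$coherence))
  expect_true(attr(once, "smoothed"))
})

test_that("directional estimates split by lag sign with documented tie-break", {
  lags <- seq(-128, 128, 4)
  coh <- 0.1 + 0 * lags
  coh[lags == 24] <- 0.6
  coh[lags == -48] <- 0.3
  prof <- tibble::tibble(lag_ms = lags, coherence = coh)
  class(prof) <- c("lag_profile", class(prof))
  est <- estimate_directional_cmc(prof)
  expect_equal(est$efferent_delay_ms, 24)
  expect_equal(est$efferent_cmc, 0.6)
  expect_equal(est$afferent_delay_ms, 48)
  expect_equal(est$afferent_cmc, 0.3)
  expect_equal(est$dominant_direction, "efferent")

  # mirror image swaps the two sides
  mirror <- prof; mirror$coherence <- rev(prof$coherence)
  est_m <- estimate_directional_cmc(mirror)
  expect_equal(est_m$afferent_delay_ms, est$efferent_delay_ms)
  expect_equal(est_m$afferent_cmc, est$efferent_cmc)
  expect_equal(est_m$dominant_direction, "afferent")

  flat <- prof; flat$coherence <- rep(0.2, 65)
  est_f <- estimate_directional_cmc(flat)
  expect_equal(est_f$afferent_delay_ms, 4)  # all-equal side -> smallest |lag|
  expect_equal(est_f$efferent_delay_ms, 4)
})

test_that("directional_cmc recovers a generated efferent delay end to end", {
  sp <- coupling_spec(delay_ms = 24, snr_db = 15, emg_coupling = 1, seed = 31)
  segs <- segment_trial(preprocess_recording(make_coupled_trial(sp)))
  pk <- wavelet_coherence(segs$peak$eeg[1:992, "Cz"], segs$peak$emg[1:992, "ExO"],
                          default_bank, windowing_config(n_windows = 2))
  pcf <- band_peak_frequency(pk, "beta")
  est <- directional_cmc(segs$analysis$eeg[, "Cz"], segs$analysis$emg[, "ExO"],
                         pcf, default_bank, default_win)
  expect_equal(est$dominant_direction, "efferent")
  expect_lte(abs(est$efferent_delay_ms - 24), 8)
})
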