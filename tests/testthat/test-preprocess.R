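fs <- 1000
t1 <- seq(0, 4, by = 1 / fs)[-1]

test_that("the notch removes 50 Hz and the band-pass spares 10 Hz", {
  cfg <- preprocess_config()
  mains <- sin(2 * pi * 50 * t1)
  out <- filter_signal(mains, fs, cfg)
  mid <- 500:3500  # away from circular edges (trimmed in the pipeline)
  expect_lte(sqrt(mean(out[mid]^2)) / sqrt(mean(mains[mid]^2)), 0.05)

  ten <- sin(2 * pi * 10 * t1)
  kept <- filter_signal(ten, fs, cfg)
  expect_lt(abs(sqrt(mean(kept[mid]^2)) / sqrt(mean(ten[mid]^2)) - 1), 0.05)

  dc <- rep(100, length(t1))
  expect_lt(max(abs(filter_signal(dc, fs, cfg))), 1)
})

test_that("filtering is linear and zero-phase", {
  cfg <- preprocess_config()
  set.seed(2)
  x <- rnorm(2000); y <- rnorm(2000)
  lhs <- filter_signal(2 * x - 5 * y, fs, cfg)
  rhs <- 2 * filter_signal(x, fs, cfg) - 5 * filter_signal(y, fs, cfg)
  expect_equal(lhs, rhs, tolerance = 1e-9)

  imp <- numeric(2001); imp[1001] <- 1
  fi <- filter_signal(imp, fs, cfg)
  expect_lte(abs(which.max(abs(fi)) - 1001), 1)  # no group delay
  expect_error(filter_signal(x, fs = 150, cfg), "too low")
})

test_that("edge trimming follows the 30 s -> 20 s contract", {
  rec <- make_coupled_trial(coupling_spec(duration_s = 30, ecg_bpm = 0, seed = 1))
  tr <- trim_edges(rec, 5)
  expect_equal(recording_duration(tr), 20)
  expect_equal(nrow(resample_250(tr)$eeg), 5000)
  expect_identical(trim_edges(rec, 0), rec)
  short <- make_coupled_trial(coupling_spec(duration_s = 9, ecg_bpm = 0, seed = 1))
  expect_error(trim_edges(short, 5), "too short")
})

test_that("common average referencing has its defining properties", {
  m <- cbind(a = rnorm(100), b = rnorm(100), c = rnorm(100))
  car <- common_average_reference(m)
  expect_lt(max(abs(rowMeans(car))), 1e-12)
  expect_equal(common_average_reference(car), car)
  same <- cbind(a = rnorm(50), b = 0, c = 0)
  same[, 2] <- same[, 1]; same[, 3] <- same[, 1]
  expect_true(all(abs(common_average_reference(same)) < 1e-12))
  expect_error(common_average_reference(m[, 1, drop = FALSE]), "at least 2")
})

test_that("decimation preserves in-band content", {
  tt <- seq(0, 16, by = 1 / 2000)[-1]
  x <- sin(2 * pi * 20 * tt)
  y <- resample_signal(x, 2000, 250)
  expect_length(y, 4000)
  ps <- psd_boxcar(y, 250)
  expect_lt(abs(ps$freq[which.max(ps$power)] - 20), 0.5)
  amp <- sqrt(2 * cmcwave:::trapz_integral(ps$freq, ps$power))  # sine amplitude
  expect_lt(abs(amp - 1), 0.02)
  expect_identical(resample_signal(y, 250, 250), y)
  expect_error(resample_signal(x, 2000, 300), "integer factor")
  expect_length(resample_signal(rnorm(8000), 500, 250), 4000)
})

test_that("segmentation partitions a 20-s trial into 4 s + 16 s", {
  rec <- resample_250(trim_edges(make_coupled_trial(coupling_spec(ecg_bpm = 0, seed = 2)), 5))
  segs <- segment_trial(rec)
  expect_equal(nrow(segs$peak$eeg), 1000)
  expect_equal(nrow(segs$analysis$eeg), 4000)
  expect_equal(rbind(segs$peak$eeg, segs$analysis$eeg), rec$eeg)
  expect_equal(segs$analysis$eeg[1, ], rec$eeg[1001, ])
  bad <- rec; bad$eeg <- bad$eeg[-(1:250), , drop = FALSE]; bad$emg <- bad$emg[-(1:250), , drop = FALSE]
  expect_error(segment_trial(bad), "20-s")
})

test_that("ECG removal suppresses beat-band intensity and finds the beats", {
  set.seed(10)
  fs_e <- 2000
  n <- 40000
  emg <- rnorm(n)
  ecg <- cmcwave:::make_ecg(n, fs_e, bpm = 70)
  x <- emg + 3 * sqrt(mean(emg^2)) * as.numeric(ecg)
  cleaned <- remove_ecg(x, fs_e)
  truth <- attr(ecg, "beat_samples")
  found <- attr(cleaned, "beat_samples")
  expect_gte(length(found), length(truth) - 2)
  match_err <- vapply(truth[truth > 400 & truth < n - 400],
                      function(b) min(abs(found - b)), numeric(1))
  expect_lte(max(match_err) / fs_e * 1000, 20)  # within +/-20 ms

  low <- cmcwave:::bank_subset(wavelet_bank(scale = 0.3, j_range = 0:2), 0, 40)
  before <- sum(cmcwave:::ecg_band_intensity(x, fs_e, low))
  after <- sum(cmcwave:::ecg_band_intensity(as.numeric(cleaned), fs_e, low))
  base <- sum(cmcwave:::ecg_band_intensity(emg, fs_e, low))
  expect_gte((before - after) / (before - base), 0.8)

  untouched <- remove_ecg(emg, fs_e)
  expect_lt(abs(sqrt(mean(as.numeric(untouched)^2)) / sqrt(mean(emg^2)) - 1), 0.02)
})

test_that("the full chain preserves coupling-band coherence at high SNR", {
  cfg <- analysis_config()
  noisy <- segment_trial(preprocess_recording(make_coupled_trial(coupling_spec(snr_db = 20, seed = 6))))
  clean <- segment_trial(preprocess_recording(make_coupled_trial(coupling_spec(snr_db = 60, seed = 6))))
  w <- windowing_config()
  coh <- function(s) {
    cs <- wavelet_coherence(s$analysis$eeg[1:3968, "Cz"], s$analysis$emg[1:3968, "ExO"],
                            bank_subset_alpha(), w)
    mean(cs$coherence)
  }
  expect_gte(coh(noisy), 0.9 * coh(clean))
})
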