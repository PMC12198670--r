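test_that("trial generation is deterministic and validates its fields", {
  sp <- coupling_spec(seed = 5)
  r1 <- make_coupled_trial(sp)
  r2 <- make_coupled_trial(sp)
  expect_identical(r1$eeg, r2$eeg)
  expect_identical(r1$emg, r2$emg)
  r3 <- make_coupled_trial(coupling_spec(seed = 6))
  expect_false(identical(r1$eeg, r3$eeg))

  expect_error(coupling_spec(duration_s = 0), "duration_s")
  expect_error(coupling_spec(delay_ms = -3), "delay_ms")
  expect_error(coupling_spec(fs_eeg = 2000, fs_emg = 500), "fs_emg")
  expect_error(coupling_spec(fs_eeg = 500, fs_emg = 750), "fs_emg")
  expect_error(coupling_spec(coupling_center_hz = 400), "fs_eeg")
  expect_error(coupling_spec(gain = 0), "gain")
})

test_that("trials carry the advertised channels, rates and contaminants", {
  rec <- make_coupled_trial(coupling_spec(seed = 1))
  expect_s3_class(rec, "cmc_recording")
  expect_identical(colnames(rec$emg), c("ExO", "ES"))
  expect_true(all(c("FC1", "Cz", "C3", "O1") %in% colnames(rec$eeg)))
  expect_equal(recording_duration(rec), 30)
  expect_equal(rec$fs_emg, 2000)
  # 50-Hz line interference present in EMG
  ps <- psd_boxcar(rec$emg[, 1], rec$fs_emg)
  line_bin <- which.min(abs(ps$freq - 50))
  expect_gt(ps$power[line_bin], 10 * median(ps$power[ps$freq > 40 & ps$freq < 60]))
  expect_gt(length(attr(rec, "ecg_beat_samples")), 25)

  none <- make_coupled_trial(coupling_spec(line_hz = 0, ecg_bpm = 0, seed = 1))
  expect_null(attr(none, "ecg_beat_samples"))
})

test_that("EEG spectral power concentrates at the coupling band at high SNR", {
  rec <- make_coupled_trial(coupling_spec(snr_db = 10, coupling2_center_hz = 0,
                                          seed = 9))
  ps <- psd_boxcar(rec$eeg[, "Cz"], rec$fs_eeg)
  keep <- ps$freq > 0.5 & (ps$freq < 49 | ps$freq > 51)  # exclude line and DC
  peak <- ps$freq[keep][which.max(ps$power[keep])]
  expect_lte(abs(peak - 10), 2)

  # with the default two-band drive, the peak sits in one of the coupled bands
  rec2 <- make_coupled_trial(coupling_spec(snr_db = 10, seed = 9))
  ps2 <- psd_boxcar(rec2$eeg[, "Cz"], rec2$fs_eeg)
  keep2 <- ps2$freq > 0.5 & (ps2$freq < 49 | ps2$freq > 51)
  peak2 <- ps2$freq[keep2][which.max(ps2$power[keep2])]
  expect_true(abs(peak2 - 10) <= 2 || abs(peak2 - 20) <= 2)
})

test_that("the generated drives realize the requested delay (cross-correlation oracle)", {
  for (dms in c(8, 24)) {
    sp <- coupling_spec(delay_ms = dms, direction = "efferent", seed = 17)
    rec <- make_coupled_trial(sp)
    d_eeg <- attr(rec, "drive_eeg")   # at EEG rate (500 Hz)
    d_emg <- attr(rec, "drive_emg")   # at EMG rate (2000 Hz)
    lag <- xcorr_peak_lag(d_emg[seq(1, length(d_emg), 4)], d_eeg, 40)
    expect_equal(lag * 1000 / 500, -dms)  # EMG drive trails the EEG drive

    spa <- coupling_spec(delay_ms = dms, direction = "afferent", seed = 17)
    reca <- make_coupled_trial(spa)
    laga <- xcorr_peak_lag(attr(reca, "drive_emg")[seq(1, length(d_emg), 4)],
                           attr(reca, "drive_eeg"), 40)
    expect_equal(laga * 1000 / 500, dms)
  }
})

test_that("direction none yields independent drives", {
  rec <- make_coupled_trial(coupling_spec(direction = "none", seed = 23))
  d1 <- attr(rec, "drive_eeg")
  d2 <- attr(rec, "drive_emg")[seq(1, length(attr(rec, "drive_emg")), 4)]
  expect_lt(abs(cor(d1, d2)), 0.1)
})

test_that("cohort designs expand to the right trial count with derived seeds", {
  dsg <- cohort_design(n_per_group = 10, trials_per_task = 7, seed = 2)
  co <- make_cohort(dsg, materialize = FALSE)
  expect_equal(nrow(co$design), 420)  # 10 x 2 groups x 3 tasks x 7 trials
  expect_equal(length(co$trials), 420)
  expect_false(anyDuplicated(co$design$seed) > 0)
  expect_identical(make_cohort(dsg, materialize = FALSE)$design, co$design)
})

test_that("band effects multiply the right trials' gains and labels are validated", {
  fx <- tibble::tibble(group = "amputee", task = "EC", band = "alpha",
                       direction = "efferent", gain = 2)
  dsg <- cohort_design(n_per_group = 2, trials_per_task = 1, band_effects = fx, seed = 3)
  co <- make_cohort(dsg, materialize = FALSE)
  hit <- co$design$group == "amputee" & co$design$task == "EC"
  expect_true(all(co$design$gain[hit] == 2))
  expect_true(all(co$design$gain[!hit] == 1))
  expect_true(all(co$design$gain2 == 1))  # alpha effect leaves the beta component alone
  sp <- co$trials[[which(hit)[1]]]
  expect_equal(sp$gain, 2)

  bad <- tibble::tibble(group = "martian", task = "EC", band = "alpha",
                        direction = "efferent", gain = 2)
  expect_error(cohort_design(band_effects = bad), "unknown labels")
  expect_error(cohort_design(trials_per_task = 0), "trials_per_task")
})

test_that("materialized cohorts contain generated recordings", {
  dsg <- cohort_design(n_per_group = 1, trials_per_task = 1,
                       base_spec = coupling_spec(duration_s = 2, ecg_bpm = 0), seed = 4)
  co <- make_cohort(dsg)
  expect_true(all(vapply(co$trials, inherits, logical(1), "cmc_recording")))
})
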