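#' Multichannel EEG/EMG trial container
#'
#' Holds one trial as two time-by-channel matrices (microvolts), one per
#' modality, each with its own sampling rate -- EEG and EMG are typically
#' acquired at different rates until both are downsampled to 250 Hz.
#'
#' @param eeg Numeric matrix, time x EEG channels, with column names.
#' @param emg Numeric matrix, time x EMG channels, with column names.
#' @param fs_eeg,fs_emg Sampling rates, Hz.
#' @param meta One-row tibble of trial metadata (participant, task, trial).
#' @return Object of class `cmc_recording`.
#' @export
recording <- function(eeg, emg, fs_eeg, fs_emg, meta = tibble()) {
  eeg <- as.matrix(eeg); emg <- as.matrix(emg)
  assert_field(!is.null(colnames(eeg)) && !anyDuplicated(colnames(eeg)),
               "eeg", "columns must have unique labels")
  assert_field(!is.null(colnames(emg)) && !anyDuplicated(colnames(emg)),
               "emg", "columns must have unique labels")
  assert_field(fs_eeg > 0 && fs_emg > 0, "fs", "sampling rates must be positive")
  assert_field(abs(nrow(eeg) / fs_eeg - nrow(emg) / fs_emg) < 1 / fs_eeg,
               "emg", "EEG and EMG must cover the same duration")
  structure(list(eeg = eeg, emg = emg, fs_eeg = fs_eeg, fs_emg = fs_emg,
                 meta = meta),
            class = "cmc_recording")
}

#' @export
print.cmc_recording <- function(x, ...) {
  cat(sprintf("<cmc_recording> %.3g s | EEG: %d ch @ %g Hz [%s] | EMG: %d ch @ %g Hz [%s]\n",
              nrow(x$eeg) / x$fs_eeg, ncol(x$eeg), x$fs_eeg,
              paste(colnames(x$eeg), collapse = ", "),
              ncol(x$emg), x$fs_emg,
              paste(colnames(x$emg), collapse = ", ")))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec A [recording()].
#' @return Duration, s.
#' @export
recording_duration <- function(rec) {
  nrow(rec$eeg) / rec$fs_eeg
}
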