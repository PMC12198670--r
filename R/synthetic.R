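#' Specification of one synthetic coupled EEG/EMG trial
#'
#' Emulates the quiet-standing recording protocol: a 30-s trial with EEG at
#' 500 Hz and bipolar EMG at 2000 Hz, a band-limited common cortical drive
#' transmitted to the muscle with a directional delay, additive channel noise,
#' optional 50-Hz line interference and optional ECG contamination of the EMG.
#'
#' @param duration_s Trial duration, s.
#' @param fs_eeg,fs_emg Sampling rates, Hz (`fs_emg` must be an integer
#'   multiple of `fs_eeg`).
#' @param coupling_center_hz Center of the (primary) coupled band, Hz.
#' @param coupling_bandwidth_hz Half-width of the coupled band, Hz (the drive
#'   occupies `center - bw` to `center + bw`).
#' @param coupling2_center_hz Center of a secondary coupled band, Hz (0
#'   disables). By default a beta-band component accompanies the alpha one,
#'   since quiet-standing CMC is observed in both analysed bands.
#' @param coupling2_bandwidth_hz Half-width of the secondary band, Hz.
#' @param coupling2_weight Amplitude of the secondary drive relative to the
#'   primary.
#' @param delay_ms Transmission delay, ms (>= 0). Positive efferent delay
#'   means the cortex leads the muscle.
#' @param direction `"efferent"` (EEG leads), `"afferent"` (EMG leads) or
#'   `"none"` (independent drives; no coupling).
#' @param snr_db Drive-to-noise ratio per channel, dB (broadband; the
#'   in-band ratio is higher since the drive is narrow-band). The default
#'   -6 dB, together with the default `emg_coupling`, produces band-mean
#'   coherences around 0.4-0.6 -- comfortably above the surrogate null yet
#'   far from ceiling, the regime in which gain effects remain visible.
#'   `-Inf` yields pure noise channels.
#' @param line_hz Line interference frequency, Hz; 0 disables.
#' @param emg_coupling Amplitude of the drive copy mixed into the EMG,
#'   relative to the EEG drive amplitude. Values below 1 make the muscle side
#'   the coherence-limiting side, so transmission-gain effects act through it.
#' @param ecg_bpm Heart rate of the ECG contamination, beats/min; 0 disables.
#' @param ecg_amplitude ECG peak amplitude relative to the EMG RMS.
#' @param gain Coupling gain multiplier of the primary component (used by
#'   cohort effects).
#' @param gain2 Coupling gain multiplier of the secondary component.
#' @param seed Integer seed; the trial is a deterministic function of the spec.
#' @return Object of class `coupling_spec`.
#' @export
coupling_spec <- function(duration_s = 30, fs_eeg = 500, fs_emg = 2000,
                          coupling_center_hz = 10, coupling_bandwidth_hz = 2,
                          coupling2_center_hz = 20, coupling2_bandwidth_hz = 2,
                          coupling2_weight = 1,
                          delay_ms = 24,
                          direction = c("efferent", "afferent", "none"),
                          snr_db = -6, emg_coupling = 0.3,
                          line_hz = 50, ecg_bpm = 70,
                          ecg_amplitude = 2, gain = 1, gain2 = 1, seed = 1) {
  direction <- match.arg(direction)
  assert_field(duration_s > 0, "duration_s", "must be positive")
  assert_field(fs_emg >= fs_eeg, "fs_emg", "must be >= fs_eeg")
  assert_field(fs_emg %% fs_eeg == 0, "fs_emg", "must be an integer multiple of fs_eeg")
  assert_field(fs_eeg >= 2 * (coupling_center_hz + coupling_bandwidth_hz),
               "fs_eeg", "must be >= 2 * (coupling_center_hz + coupling_bandwidth_hz)")
  assert_field(delay_ms >= 0, "delay_ms", "must be >= 0")
  assert_field(coupling_bandwidth_hz > 0, "coupling_bandwidth_hz", "must be positive")
  assert_field(line_hz >= 0, "line_hz", "must be >= 0")
  assert_field(ecg_bpm >= 0, "ecg_bpm", "must be >= 0")
  assert_field(gain > 0, "gain", "must be positive")
  assert_field(gain2 > 0, "gain2", "must be positive")
  assert_field(emg_coupling > 0, "emg_coupling", "must be positive")
  if (coupling2_center_hz > 0) {
    assert_field(fs_eeg >= 2 * (coupling2_center_hz + coupling2_bandwidth_hz),
                 "coupling2_center_hz", "secondary band must respect Nyquist")
  }
  structure(
    list(duration_s = duration_s, fs_eeg = fs_eeg, fs_emg = fs_emg,
         coupling_center_hz = coupling_center_hz,
         coupling_bandwidth_hz = coupling_bandwidth_hz,
         coupling2_center_hz = coupling2_center_hz,
         coupling2_bandwidth_hz = coupling2_bandwidth_hz,
         coupling2_weight = coupling2_weight,
         delay_ms = delay_ms, direction = direction, snr_db = snr_db,
         emg_coupling = emg_coupling,
         line_hz = line_hz, ecg_bpm = ecg_bpm, ecg_amplitude = ecg_amplitude,
         gain = gain, gain2 = gain2, seed = as.integer(seed)),
    class = "coupling_spec"
  )
}

# band-limited unit-variance Gaussian drive at fs, length n (+pad for
# delays); zero-phase Butterworth band-pass applied spectrally
make_drive <- function(n, fs, center, bw) {
  lo <- max(center - bw, 0.1)
  hi <- min(center + bw, fs / 2 * 0.95)
  bf <- signal::butter(2, c(lo, hi) / (fs / 2), type = "pass")
  m <- stats::nextn(n, c(2, 3, 5))       # FFT-friendly length, then truncate
  R <- Mod(iir_response(bf, m))^2
  d <- Re(fft(fft(rnorm(m)) * R, inverse = TRUE))[seq_len(n)] / m
  d / sd(d)
}

# QRS-like pulse: sum of three Gaussians (small Q dip, tall R, S dip)
qrs_template <- function(fs, width_s = 0.1) {
  t <- seq(-width_s, width_s, by = 1 / fs)
  g <- function(mu, sig, a) a * exp(-((t - mu)^2) / (2 * sig^2))
  g(-0.025, 0.008, -0.25) + g(0, 0.012, 1) + g(0.03, 0.01, -0.35)
}

# periodic ECG-like pulse train with +/-10% beat-to-beat amplitude jitter
make_ecg <- function(n, fs, bpm) {
  period <- 60 / bpm
  tmpl <- qrs_template(fs)
  half <- (length(tmpl) - 1L) %/% 2L
  beats <- seq(period / 2, n / fs, by = period)
  x <- numeric(n)
  for (bt in beats) {
    i0 <- round(bt * fs)
    amp <- 1 + runif(1, -0.1, 0.1)
    idx <- (i0 - half):(i0 + half)
    ok <- idx >= 1 & idx <= n
    x[idx[ok]] <- x[idx[ok]] + amp * tmpl[ok]
  }
  attr(x, "beat_samples") <- round(beats * fs)
  x
}

#' Generate one synthetic coupled EEG/EMG trial
#'
#' The cortical drive is band-limited Gaussian noise. Each EEG channel is the
#' drive plus independent Gaussian noise at `snr_db`. Each EMG channel is an
#' independent broadband carrier amplitude-modulated by the (delayed) drive
#' plus an additive scaled copy of the delayed drive -- the additive copy is
#' what carries genuine narrow-band EEG-EMG coherence -- plus channel noise,
#' optional line interference and an optional ECG-like pulse train. All EMG
#' channels share the cortical drive but have independent carriers, mimicking
#' a common central drive to several muscles.
#'
#' In addition to the motor-cortex channels that receive the drive, the EEG
#' block contains background channels (pure noise, like the non-motor sites
#' of a full cap): with them, the common average reference subtracts only a
#' small fraction of the common drive instead of cancelling it, as on a real
#' multi-channel montage.
#'
#' @param spec A [coupling_spec()].
#' @param eeg_labels,emg_labels Channel labels (10-20 / SENIAM-style).
#' @param background_labels Labels of drive-free EEG channels.
#' @return A [recording()] with ground-truth attributes `drive_eeg`,
#'   `drive_emg` (the band-limited drives actually mixed into each modality)
#'   and `ecg_beat_samples` (EMG-rate sample indices of the simulated beats,
#'   or `NULL`).
#' @export
make_coupled_trial <- function(spec,
                               eeg_labels = c("FC1", "Cz", "C3"),
                               emg_labels = c("ExO", "ES"),
                               background_labels = c("F3", "F4", "P3", "P4", "O1", "O2")) {
  stopifnot(inherits(spec, "coupling_spec"))
  with_seed_if(spec$seed, {
    n_emg <- round(spec$duration_s * spec$fs_emg)
    n_eeg <- round(spec$duration_s * spec$fs_eeg)
    dec <- spec$fs_emg / spec$fs_eeg
    delay <- round(spec$delay_ms / 1000 * spec$fs_emg)
    margin <- delay + round(0.5 * spec$fs_emg)

    w2 <- if (spec$coupling2_center_hz > 0) spec$coupling2_weight else 0
    base <- seq.int(margin + 1L, margin + n_emg)
    component <- function(center, bw) {
      drv <- make_drive(n_emg + 2L * margin, spec$fs_emg, center, bw)
      if (spec$direction == "efferent") {
        list(eeg = drv[base], emg = drv[base - delay])
      } else if (spec$direction == "afferent") {
        list(eeg = drv[base - delay], emg = drv[base])
      } else {
        list(eeg = drv[base], emg = make_drive(n_emg, spec$fs_emg, center, bw))
      }
    }
    c1 <- component(spec$coupling_center_hz, spec$coupling_bandwidth_hz)
    c2 <- if (w2 > 0) component(spec$coupling2_center_hz, spec$coupling2_bandwidth_hz)
          else list(eeg = 0, emg = 0)
    s0 <- sqrt(1 + w2^2)                 # combined drive sd (independent bands)
    d_eeg <- (c1$eeg + w2 * c2$eeg) / s0
    # transmission gains act per band on the muscle side only
    d_emg <- (spec$gain * c1$emg + spec$gain2 * w2 * c2$emg) / s0

    amp <- 10^(spec$snr_db / 20)        # drive amplitude relative to unit noise
    couple <- if (spec$direction == "none") 0 else 1

    d_eeg_ds <- d_eeg[seq.int(1L, n_emg, by = dec)]
    eeg <- vapply(seq_along(eeg_labels), function(k) {
      10 * (amp * d_eeg_ds + rnorm(n_eeg))
    }, numeric(n_eeg))
    if (length(background_labels)) {
      bg <- vapply(seq_along(background_labels), function(k) {
        10 * rnorm(n_eeg)
      }, numeric(n_eeg))
      eeg <- cbind(eeg, bg)
    }
    colnames(eeg) <- c(eeg_labels, background_labels)

    t_emg <- (seq_len(n_emg) - 1L) / spec$fs_emg
    ecg <- NULL
    emg <- vapply(seq_along(emg_labels), function(k) {
      carrier <- rnorm(n_emg)
      phys <- carrier * (1 + 0.5 * couple * pmin(abs(d_emg), 3)) +
        couple * spec$emg_coupling * amp * d_emg
      ch <- phys + rnorm(n_emg)          # channel noise (unit sd)
      if (spec$line_hz > 0) {
        ch <- ch + 2 * sin(2 * pi * spec$line_hz * t_emg + runif(1, 0, 2 * pi))
      }
      ch
    }, numeric(n_emg))
    colnames(emg) <- emg_labels
    if (spec$ecg_bpm > 0) {
      ecg <- make_ecg(n_emg, spec$fs_emg, spec$ecg_bpm)
      emg_rms <- sqrt(mean(emg[, 1]^2))
      emg <- emg + spec$ecg_amplitude * emg_rms * as.numeric(ecg)
    }
    emg <- 20 * emg

    rec <- recording(eeg = eeg, emg = emg, fs_eeg = spec$fs_eeg,
                     fs_emg = spec$fs_emg)
    attr(rec, "drive_eeg") <- d_eeg_ds
    attr(rec, "drive_emg") <- d_emg
    attr(rec, "ecg_beat_samples") <- if (!is.null(ecg)) attr(ecg, "beat_samples")
    rec
  })
}

#' Two-group cohort design
#'
#' Mirrors the study layout: two groups, three standing tasks (eyes open,
#' eyes closed, dual task), a fixed number of trials per task per participant.
#' `band_effects` injects group/task-specific coupling-gain multipliers.
#'
#' @param n_per_group Participants per group.
#' @param groups Two group labels.
#' @param tasks Task labels.
#' @param trials_per_task Trials per task per participant (default 7).
#' @param band_effects Tibble with columns `group`, `task`, `band`,
#'   `direction`, `gain`; a trial whose (group, task) matches a row and whose
#'   coupling band and direction match receives that gain multiplier.
#' @param base_spec The [coupling_spec()] shared by all trials.
#' @param seed Master seed; per-trial seeds are derived deterministically.
#' @return Object of class `cohort_design`.
#' @export
cohort_design <- function(n_per_group = 10,
                          groups = c("amputee", "control"),
                          tasks = c("EO", "EC", "DT"),
                          trials_per_task = 7,
                          band_effects = NULL,
                          base_spec = coupling_spec(),
                          seed = 1) {
  assert_field(length(groups) == 2, "groups", "must have exactly 2 labels")
  assert_field(trials_per_task >= 1, "trials_per_task", "must be >= 1")
  assert_field(n_per_group >= 1, "n_per_group", "must be >= 1")
  if (!is.null(band_effects)) {
    need <- c("group", "task", "band", "direction", "gain")
    assert_field(all(need %in% names(band_effects)), "band_effects",
                 paste("must have columns", paste(need, collapse = ", ")))
    bad_g <- setdiff(band_effects$group, groups)
    bad_t <- setdiff(band_effects$task, tasks)
    if (length(bad_g) || length(bad_t)) {
      abort(sprintf("band_effects references unknown labels: %s",
                    paste(c(bad_g, bad_t), collapse = ", ")),
            class = "cmcwave_validation_error")
    }
    assert_field(all(band_effects$gain > 0), "band_effects", "gains must be positive")
  }
  structure(
    list(n_per_group = as.integer(n_per_group), groups = groups, tasks = tasks,
         trials_per_task = as.integer(trials_per_task),
         band_effects = band_effects, base_spec = base_spec,
         seed = as.integer(seed)),
    class = "cohort_design"
  )
}

# which band does the base spec's coupling center fall in?
coupling_band <- function(spec, bands = cmc_bands()) {
  hit <- bands$band[spec$coupling_center_hz >= bands$lo &
                    spec$coupling_center_hz <= bands$hi]
  if (length(hit)) hit[1] else NA_character_
}

#' Generate a synthetic two-group cohort
#'
#' @param design A [cohort_design()].
#' @param materialize If `TRUE` (default) the recordings are generated and
#'   returned; if `FALSE` only the per-trial [coupling_spec()]s are returned
#'   (the pipeline generates trials lazily to bound memory).
#' @return List with `design` (tidy tibble: participant, group, task, trial,
#'   gain, seed) and `trials` (named list of recordings or coupling specs,
#'   keyed `participant_task_trial`).
#' @export
make_cohort <- function(design, materialize = TRUE) {
  stopifnot(inherits(design, "cohort_design"))
  tab <- tidyr::expand_grid(
    group = design$groups,
    subject = seq_len(design$n_per_group),
    task = design$tasks,
    trial = seq_len(design$trials_per_task)
  ) |>
    mutate(participant = sprintf("%s%02d", substr(.data$group, 1, 1), .data$subject)) |>
    select("participant", "group", "task", "trial")
  tab$seed <- derive_seeds(design$seed, nrow(tab))

  base <- design$base_spec
  band1 <- coupling_band(base)
  band2 <- if (base$coupling2_center_hz > 0) {
    coupling_band(list(coupling_center_hz = base$coupling2_center_hz))
  } else NA_character_
  tab$gain <- base$gain
  tab$gain2 <- base$gain2
  if (!is.null(design$band_effects)) {
    fx <- design$band_effects
    for (i in seq_len(nrow(fx))) {
      hit <- tab$group == fx$group[i] & tab$task == fx$task[i] &
        fx$direction[i] == base$direction
      if (identical(fx$band[i], band1)) {
        tab$gain[hit] <- tab$gain[hit] * fx$gain[i]
      } else if (identical(fx$band[i], band2)) {
        tab$gain2[hit] <- tab$gain2[hit] * fx$gain[i]
      }
    }
  }

  specs <- purrr::pmap(tab, function(participant, group, task, trial, seed, gain, gain2) {
    sp <- base
    sp$seed <- seed
    sp$gain <- gain
    sp$gain2 <- gain2
    sp
  })
  names(specs) <- sprintf("%s_%s_%d", tab$participant, tab$task, tab$trial)
  trials <- if (materialize) purrr::map(specs, make_coupled_trial) else specs
  list(design = tab, trials = trials)
}
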