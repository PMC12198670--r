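#' Analysis configuration for a full study run
#'
#' Gathers every stage's parameters. Defaults reproduce the standing-CMC
#' protocol: Cauchy bank (scale 12, j = 1..30), 8 x 1.984-s windows,
#' alpha/beta bands analysed, 100 AAFT surrogates with the median statistic,
#' +/-128-ms lag scan with 16-ms smoothing, PERMANOVA with 5000 permutations
#' and participant strata.
#'
#' @param bank A [wavelet_bank()].
#' @param wincfg A [windowing_config()] for the 16-s analysis segment.
#' @param preprocess A [preprocess_config()].
#' @param surrogate A [surrogate_config()].
#' @param bands_used Character vector of band names entering the directional
#'   and multivariate analysis.
#' @param eeg_channels EEG channels whose pairs are analysed (`NULL` = all);
#'   defaults to the motor-cortex montage. Channels excluded here still
#'   contribute to the common average reference.
#' @param emg_channels EMG channels analysed (`NULL` = all).
#' @param max_lag_ms Lag-scan range, ms.
#' @param smooth_ms Lag-profile smoothing span, ms.
#' @param n_perm PERMANOVA permutations.
#' @param strata `"participant"` or `NULL` (free permutation).
#' @param compute_psd Also compute per-channel EEG power spectra.
#' @param compute_nmds Also compute NMDS embeddings per direction.
#' @param seed Master analysis seed (surrogates, permutations, NMDS).
#' @return Object of class `analysis_config`.
#' @export
analysis_config <- function(bank = wavelet_bank(),
                            wincfg = windowing_config(),
                            preprocess = preprocess_config(),
                            surrogate = surrogate_config(),
                            bands_used = c("alpha", "beta"),
                            eeg_channels = c("FC1", "Cz", "C3"),
                            emg_channels = NULL,
                            max_lag_ms = 128, smooth_ms = 16,
                            n_perm = 5000, strata = "participant",
                            compute_psd = TRUE, compute_nmds = TRUE,
                            seed = 1) {
  structure(list(bank = bank, wincfg = wincfg, preprocess = preprocess,
                 surrogate = surrogate, bands_used = bands_used,
                 eeg_channels = eeg_channels, emg_channels = emg_channels,
                 max_lag_ms = max_lag_ms, smooth_ms = smooth_ms,
                 n_perm = n_perm, strata = strata,
                 compute_psd = compute_psd, compute_nmds = compute_nmds,
                 seed = as.integer(seed)),
            class = "analysis_config")
}

# preprocess one trial (recording or coupling_spec) and split into segments
prepare_trial <- function(trial, cfg) {
  rec <- if (inherits(trial, "coupling_spec")) make_coupled_trial(trial) else trial
  pre <- preprocess_recording(rec, cfg$preprocess,
                              remove_ecg_artifacts = TRUE,
                              car = ncol(rec$eeg) >= 2L)
  segment_trial(pre)
}

#' Analyse one prepared trial pair-by-pair
#'
#' Computes, for every EEG x EMG pair and analysed band: the peak coherence
#' frequency on the 4-s segment and the band-mean coherence on the 16-s
#' analysis segment (its first `wincfg$total_samples` samples, the span a
#' maximal lag shift leaves).
#'
#' @param segments List with `peak` and `analysis` recordings (from
#'   [segment_trial()]).
#' @param cfg An [analysis_config()].
#' @return Tibble with one row per pair x band: `eeg`, `emg`, `band`,
#'   `peak_cf`, `band_mean`.
#' @export
trial_band_table <- function(segments, cfg = analysis_config()) {
  bands <- cmc_bands()
  used <- bands[bands$band %in% cfg$bands_used, ]
  span_bank <- bank_subset(cfg$bank, min(used$lo), max(used$hi))
  peak_w <- peak_windowing_config(cfg$wincfg$fs)
  span <- cfg$wincfg$total_samples
  eeg_ch <- cfg$eeg_channels %||% colnames(segments$peak$eeg)
  eeg_ch <- intersect(eeg_ch, colnames(segments$peak$eeg))
  emg_ch <- cfg$emg_channels %||% colnames(segments$peak$emg)
  emg_ch <- intersect(emg_ch, colnames(segments$peak$emg))
  purrr::map_dfr(eeg_ch, function(ei) {
    purrr::map_dfr(emg_ch, function(mi) {
      pk <- wavelet_coherence(segments$peak$eeg[seq_len(peak_w$total_samples), ei],
                              segments$peak$emg[seq_len(peak_w$total_samples), mi],
                              span_bank, peak_w)
      an <- wavelet_coherence(segments$analysis$eeg[seq_len(span), ei],
                              segments$analysis$emg[seq_len(span), mi],
                              span_bank, cfg$wincfg)
      purrr::map_dfr(seq_len(nrow(used)), function(b) {
        tibble(eeg = ei, emg = mi, band = used$band[b],
               peak_cf = band_peak_frequency(pk, c(used$lo[b], used$hi[b])),
               band_mean = band_mean(an, c(used$lo[b], used$hi[b])))
      })
    })
  })
}

#' Run the full study pipeline on a synthetic (or loaded) cohort
#'
#' Stages, in order: preprocess and segment every trial; per-trial, per-pair
#' band table (peak cfs from the 4-s segment, band means from the 16-s
#' segment); AAFT surrogate thresholds and significance mask; participant
#' peak frequencies (mean of per-trial argmax cfs, snapped to the bank);
#' lag-scanned directional CMC per retained trial; optional EEG power
#' spectra; six-dimensional profiles per direction; PERMANOVA, task-wise
#' group contrasts and optional NMDS per direction.
#'
#' @param cohort List with `design` and `trials` as returned by
#'   [make_cohort()] (trials may be recordings or coupling specs).
#' @param cfg An [analysis_config()].
#' @return List of result tables (see Details in the vignette): `band_table`,
#'   `mask`, `peak_cfs`, `cmc_table`, `profiles`, `permanova`, `pairwise`,
#'   `nmds`, `psd`.
#' @export
analyze_cohort <- function(cohort, cfg = analysis_config()) {
  design <- cohort$design
  keys <- sprintf("%s_%s_%d", design$participant, design$task, design$trial)
  stopifnot(all(keys %in% names(cohort$trials)))
  span <- cfg$wincfg$total_samples

  seeds <- derive_seeds(cfg$seed, nrow(design) + 3L)
  stat_seed <- seeds[nrow(design) + 1L]
  nmds_seed <- seeds[nrow(design) + 2L]

  per_trial <- purrr::map(seq_len(nrow(design)), function(i) {
    segs <- prepare_trial(cohort$trials[[keys[i]]], cfg)
    bt <- trial_band_table_fast(segs, cfg) |>
      mutate(participant = design$participant[i], group = design$group[i],
             task = design$task[i], trial = design$trial[i])
    bt$threshold <- trial_thresholds_fast(segs, bt, cfg, seeds[i])
    psd <- NULL
    if (cfg$compute_psd) {
      psd_ch <- intersect(cfg$eeg_channels %||% colnames(segs$analysis$eeg),
                          colnames(segs$analysis$eeg))
      psd <- purrr::map_dfr(psd_ch, function(ch) {
        sp <- psd_boxcar(segs$analysis$eeg[, ch], segs$analysis$fs_eeg)
        tibble(participant = design$participant[i], group = design$group[i],
               task = design$task[i], trial = design$trial[i], channel = ch,
               freq = sp$freq, power = sp$power)
      })
    }
    list(band_table = bt, segments = segs, psd = psd)
  })

  band_table <- purrr::map_dfr(per_trial, "band_table")
  mask <- band_table |>
    mutate(retained = .data$band_mean > .data$threshold)
  class(mask) <- c("significance_mask", class(mask))

  # participant-level peak cf: average of per-trial, per-pair argmax cfs
  peak_cfs <- band_table |>
    group_by(.data$participant, .data$band) |>
    summarise(peak_cf = snap_to_bank(mean(.data$peak_cf), cfg$bank),
              .groups = "drop")

  max_lag <- as.integer(round(cfg$max_lag_ms / 1000 * cfg$wincfg$fs))
  lag_ms <- seq.int(-max_lag, max_lag) * 1000 / cfg$wincfg$fs
  cmc_table <- purrr::map_dfr(seq_len(nrow(design)), function(i) {
    segs <- per_trial[[i]]$segments
    bt <- per_trial[[i]]$band_table
    pcfs <- peak_cfs[peak_cfs$participant == design$participant[i], ]
    pcf_of_band <- as.list(stats::setNames(pcfs$peak_cf, pcfs$band))
    profs <- trial_lag_scan_fast(segs, bt, pcf_of_band, cfg, max_lag)
    purrr::map_dfr(seq_len(nrow(bt)), function(r) {
      prof <- tibble(lag_ms = lag_ms, coherence = profs[[r]])
      class(prof) <- c("lag_profile", class(prof))
      attr(prof, "peak_cf") <- pcf_of_band[[bt$band[r]]]
      est <- estimate_directional_cmc(smooth_lag_profile(prof, cfg$smooth_ms))
      tibble(participant = design$participant[i], group = design$group[i],
             task = design$task[i], trial = design$trial[i],
             eeg = bt$eeg[r], emg = bt$emg[r], band = bt$band[r]) |>
        dplyr::bind_cols(est)
    })
  })

  profiles <- purrr::map(c(afferent = "afferent", efferent = "efferent"),
    function(dir) {
      assemble_profiles(cmc_table, mask) |>
        filter(.data$direction == dir)
    })

  stats <- purrr::map(profiles, function(pf) {
    ok <- !pf$missing
    if (sum(ok) < 4 || length(unique(pf$group[ok])) < 2) return(NULL)
    # an unbalanced design (all trials of a cell masked) is reported, not fatal
    tryCatch(cmc_permanova(pf, n_perm = cfg$n_perm, seed = stat_seed,
                           strata = cfg$strata),
             cmcwave_validation_error = function(e) {
               warning(conditionMessage(e), call. = FALSE)
               NULL
             })
  })
  pairwise <- purrr::map(profiles, function(pf) {
    ok <- !pf$missing
    if (sum(ok) < 4 || length(unique(pf$group[ok])) < 2) return(NULL)
    tryCatch(pairwise_group_by_task(pf, n_perm = cfg$n_perm, seed = stat_seed),
             cmcwave_validation_error = function(e) NULL)
  })
  nmds <- if (cfg$compute_nmds) {
    purrr::map(profiles, function(pf) {
      pf2 <- filter(pf, !.data$missing)
      if (nrow(pf2) < 4) return(NULL)
      cmc_nmds(pf2, seed = nmds_seed)
    })
  } else NULL

  psd <- if (cfg$compute_psd) purrr::map_dfr(per_trial, "psd") else NULL

  list(design = design, band_table = band_table, mask = mask,
       peak_cfs = peak_cfs, cmc_table = cmc_table, profiles = profiles,
       permanova = stats, pairwise = pairwise, nmds = nmds, psd = psd)
}

#' Run a complete study from one configuration
#'
#' Accepts either a config list or the path to a YAML file with sections
#' `cohort` (arguments of [cohort_design()]; `band_effects` as a list of
#' rows), `analysis` (arguments of [analysis_config()] with plain scalar
#' fields for the sub-configs) and `out_dir`/`seed`. Generates the synthetic
#' cohort, runs [analyze_cohort()], and -- when `out_dir` is set -- writes
#' every intermediate table as CSV plus a provenance manifest (config hash,
#' seeds, package version) as JSON.
#'
#' @param config List or YAML path.
#' @return The [analyze_cohort()] result bundle (invisibly when writing).
#' @export
run_study <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  known <- c("cohort", "analysis", "out_dir", "seed")
  unknown <- setdiff(names(config), known)
  if (length(unknown)) {
    abort(sprintf("unknown config section(s): %s", paste(unknown, collapse = ", ")),
          class = "cmcwave_validation_error")
  }
  if (is.null(config$cohort)) {
    abort("config must contain a `cohort` section", class = "cmcwave_validation_error")
  }
  seed <- config$seed %||% 1L

  ch <- config$cohort
  base_args <- ch$base_spec %||% list()
  base <- do.call(coupling_spec, base_args)
  fx <- if (!is.null(ch$band_effects)) dplyr::bind_rows(ch$band_effects) else NULL
  design <- cohort_design(
    n_per_group = ch$n_per_group %||% 10,
    groups = ch$groups %||% c("amputee", "control"),
    tasks = ch$tasks %||% c("EO", "EC", "DT"),
    trials_per_task = ch$trials_per_task %||% 7,
    band_effects = fx, base_spec = base, seed = seed
  )

  an <- config$analysis %||% list()
  cfg <- analysis_config(
    bank = do.call(wavelet_bank, an$bank %||% list()),
    wincfg = do.call(windowing_config, an$windowing %||% list()),
    preprocess = do.call(preprocess_config, an$preprocess %||% list()),
    surrogate = do.call(surrogate_config, an$surrogate %||% list()),
    bands_used = an$bands_used %||% c("alpha", "beta"),
    eeg_channels = an$eeg_channels %||% c("FC1", "Cz", "C3"),
    emg_channels = an$emg_channels %||% NULL,
    max_lag_ms = an$max_lag_ms %||% 128,
    smooth_ms = an$smooth_ms %||% 16,
    n_perm = an$n_perm %||% 5000,
    strata = an$strata %||% "participant",
    compute_psd = an$compute_psd %||% TRUE,
    compute_nmds = an$compute_nmds %||% TRUE,
    seed = seed
  )

  cohort <- make_cohort(design, materialize = FALSE)
  res <- analyze_cohort(cohort, cfg)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(x, name) {
      if (!is.null(x) && is.data.frame(x)) {
        readr::write_csv(as_tibble(x), file.path(config$out_dir, paste0(name, ".csv")))
      }
    }
    wr(res$design, "design"); wr(res$band_table, "band_table")
    wr(as_tibble(res$mask), "significance_mask"); wr(res$peak_cfs, "peak_cfs")
    wr(res$cmc_table, "directional_cmc"); wr(res$psd, "psd")
    for (dir in names(res$profiles)) {
      wr(as_tibble(res$profiles[[dir]]), paste0("profiles_", dir))
      if (!is.null(res$permanova[[dir]])) {
        wr(tidy(res$permanova[[dir]]), paste0("permanova_", dir))
      }
      if (!is.null(res$pairwise[[dir]])) {
        wr(res$pairwise[[dir]], paste0("pairwise_", dir))
      }
      if (!is.null(res$nmds) && !is.null(res$nmds[[dir]])) {
        wr(tidy(res$nmds[[dir]]), paste0("nmds_", dir))
      }
    }
    manifest <- list(
      package_version = as.character(utils::packageVersion("cmcwave")),
      seed = seed,
      config_hash = rlang::hash(config),
      created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    )
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    return(invisible(res))
  }
  res
}
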