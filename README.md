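# cmcwave

Directional corticomuscular coherence (CMC) between EEG and surface EMG
during quiet upright standing, implemented as a tidyverse-style R package.

## The problem

During standing, cortex and muscles exchange oscillatory activity in both
directions: efferent drive (cortex leads muscle) and afferent feedback
(muscle leads cortex). Quantifying this coupling — which frequency bands are
coherent, in which direction, and with what transmission delay — requires a
multi-stage pipeline whose pieces are individually standard but whose
combination is bespoke. `cmcwave` implements that pipeline end to end, for
researchers in motor control and neurorehabilitation who want to run it on
their own EEG/EMG recordings or to study its behaviour on simulated data
with known ground truth.

## The method

* **Cauchy wavelet bank.** Spectral estimation uses complex Cauchy wavelets
  defined in the frequency domain by
  `F(f) = (f/cf)^mode * exp((1 - f/cf) * mode)` with `mode = cf * scale`,
  with center frequencies `cf_j = (1/scale) * (j + q)^r`
  (scale 12, q 1.45, r 1.959, j = 1..30, spanning ~0.5–72 Hz).
* **Windowed wavelet coherence.** Signals are analysed in eight
  non-overlapping 1.984-s windows (0.504-Hz resolution); per window the
  cross- and auto-spectra are time-averaged before normalization, and the
  moduli are averaged across windows, giving coherence in [0, 1] per cf.
* **AAFT surrogate significance.** The null level of each trial's band-mean
  coherence is the median of 100 amplitude-adjusted Fourier-transform
  surrogate pairs; only trials and bands above the threshold enter the
  directional analysis.
* **Lag-scanned directionality.** EEG and EMG are shifted against each other
  up to ±128 ms on a fixed 15.872-s span; the coherence at the per-band peak
  frequency, smoothed over 16 ms, peaks at the transmission delay. Positive
  lags are efferent (EEG leads), negative afferent.
* **Multivariate group statistics.** Six-dimensional CMC profiles
  (3 EEG × 2 EMG electrodes) per participant × task × band × direction are
  compared with altGower distances, PERMANOVA (5000 permutations,
  participant strata), task-wise group contrasts, and NMDS embeddings.
* **Synthetic cohorts.** A generator produces coupled EEG/EMG trials with a
  known coupling band, direction, delay, SNR, 50-Hz line interference and
  ECG contamination, plus two-group cohorts with configurable gain effects,
  so every stage is testable without any recordings.

## Worked example

Generate one 30-s trial with an efferent 24-ms delay and a 10-Hz coupling,
preprocess it (notch, band-pass, trimming, ECG removal, common average
reference, downsampling to 250 Hz), and estimate the directional CMC:

```r
library(cmcwave)

spec <- coupling_spec(delay_ms = 24, direction = "efferent",
                      snr_db = 10, seed = 42)
trial <- make_coupled_trial(spec)
trial
#> <cmc_recording> 30 s | EEG: 9 ch @ 500 Hz [FC1, Cz, C3, F3, F4, P3, P4, O1, O2] |
#>                       EMG: 2 ch @ 2000 Hz [ExO, ES]

segs <- segment_trial(preprocess_recording(trial))

# peak coherence frequency inside the beta band, from the 4-s segment
pk <- wavelet_coherence(segs$peak$eeg[1:992, "Cz"], segs$peak$emg[1:992, "ExO"],
                        wavelet_bank(), windowing_config(n_windows = 2))
band_peak_frequency(pk, "beta")
#> [1] 20.10424

# band-mean coherence on the 16-s segment vs its AAFT surrogate threshold
cs <- wavelet_coherence(segs$analysis$eeg[1:3968, "Cz"],
                        segs$analysis$emg[1:3968, "ExO"])
band_mean(cs, "alpha")
#> [1] 0.93
coherence_threshold(segs$analysis$eeg[1:3968, "Cz"],
                    segs$analysis$emg[1:3968, "ExO"], "alpha",
                    cfg = surrogate_config(n_surrogates = 100, seed = 1))
#> [1] 0.447

# lag-scanned directional estimate at the beta peak frequency
directional_cmc(segs$analysis$eeg[, "Cz"], segs$analysis$emg[, "ExO"],
                peak_cf = band_peak_frequency(pk, "beta"))
#>   afferent_cmc afferent_delay_ms efferent_cmc efferent_delay_ms dominant_direction
#> 1         0.93                 4        0.936                20           efferent
```

The alpha-band coherence (0.93) is far above its surrogate threshold
(0.447), so the trial would be retained. The dominant direction is correctly
efferent; the single-trial delay estimate (20 ms here, true 24 ms) carries
the sampling variability inherent to locating the maximum of a smooth lag
profile — across 50 simulated trials the median absolute error is at most
one 4-ms sample (see the acceptance tests).

A whole synthetic study — cohort generation, preprocessing, significance
masking, directional CMC, profiles, PERMANOVA and NMDS — runs from one
config:

```r
res <- run_study(list(
  cohort = list(n_per_group = 4, trials_per_task = 2),
  analysis = list(surrogate = list(n_surrogates = 25), n_perm = 999),
  seed = 1, out_dir = "results/demo"
))
tidy(res$permanova$efferent)
```

Result objects are tibbles (or carry `tidy()`/`glance()` methods) and have
`autoplot()` methods for coherence spectra, lag profiles, power spectra and
NMDS embeddings.

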