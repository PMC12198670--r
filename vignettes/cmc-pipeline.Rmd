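---
title: "Directional corticomuscular coherence: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Directional corticomuscular coherence: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the science it implements: the
estimators, the parameters that matter, what the synthetic-data generator
does and does not emulate, and the design decisions taken where more than
one reasonable reading existed.

## The estimation pipeline

The pipeline quantifies corticomuscular coherence (CMC) between EEG and
bipolar surface EMG recorded during quiet standing, separately for the
efferent (cortex-to-muscle) and afferent (muscle-to-cortex) pathway:

1. **Pre-processing** (`preprocess_recording()`): a second-order Butterworth
   50-Hz notch (49–51 Hz), a 1-Hz high-pass and a 100-Hz low-pass; 5 s
   trimmed from each end of a 30-s trial; ECG template subtraction from EMG;
   common average reference (CAR) across EEG channels; decimation to 250 Hz.
2. **Segmentation** (`segment_trial()`): the first 4 s locate per-band peak
   coherence frequencies without biasing the analysis; the remaining 16 s
   carry the significance and directionality computations.
3. **Wavelet coherence** (`wavelet_coherence()`): windowed coherence per
   center frequency from the complex Cauchy bank.
4. **Significance** (`coherence_threshold()`): AAFT-surrogate null per trial,
   pair and band; only exceeding trials/bands are retained.
5. **Directionality** (`directional_cmc()`): lag-scanned coherence at the
   per-band peak frequency, ±128 ms, yielding per-side CMC and delay.
6. **Group statistics** (`cmc_permanova()`, `pairwise_group_by_task()`,
   `cmc_nmds()`): altGower distances on six-dimensional CMC profiles,
   distance-based ANOVA with permutation inference, NMDS display.

## The wavelet family

The bank (`wavelet_bank()`) consists of complex Cauchy wavelets specified in
the frequency domain,

$$F_\psi(f) = \left(\frac{f}{cf}\right)^{mode}
  e^{(1 - f/cf)\,mode}, \qquad mode = cf \cdot scale,$$

with center frequencies $cf_j = (1/scale)(j + q)^r$. The defaults
(scale 12, $q = 1.45$, $r = 1.959$, $j = 1..30$) give 30 center
frequencies from 0.48 to 71.6 Hz. Two notes:

* With these parameters the 29th cf is 67.2 Hz and the 30th 71.6 Hz; an
  index convention that stops at $j = 29$ would end near 67 Hz. Both the
  range and the parameters are configurable; the default keeps $j = 1..30$.
* The gain is evaluated in log space (`wavelet_filter()`); $mode$ exceeds
  800 at the top of the bank and the naive power expression overflows.

The transform is one-sided (analytic): the gain is applied to non-negative
frequencies only, so coefficients are complex with a meaningful phase, which
the coherency requires. Windows are zero-padded symmetrically to the next
power of two at least twice the window length, and only the unpadded span
contributes to within-window averages (padded tails would bias the
auto-spectra downward).

## The coherence estimator

The printed form of the wavelet coherency is a per-sample ratio whose
modulus is identically 1. The implemented estimator therefore
time-averages the cross- and auto-spectra within each window before forming
the ratio,

$$C_w(cf) = \frac{\left|\sum_t W_x \bar W_y\right|}
 {\sqrt{\sum_t |W_x|^2}\sqrt{\sum_t |W_y|^2}},$$

and reports the mean of $C_w$ over the eight windows. Two consequences are
worth knowing:

* Because moduli are averaged across windows, the independent-noise bias
  level does not shrink with the number of windows — it shrinks with the
  window length (more in-window averaging). The surrogate threshold absorbs
  this bias, which is why significance is assessed against AAFT surrogates
  of the same length and windowing rather than an analytic null.
* The default windowing — eight windows of 496 samples (1.984 s) at
  250 Hz — is chosen so that the 15.872-s span divides evenly and the
  spectral resolution is $1/1.984 = 0.504$ Hz.

## Significance thresholds

`aaft()` builds amplitude-adjusted Fourier-transform surrogates: ranks of
the signal are imposed on Gaussian noise, that series is phase-randomized
with Hermitian symmetry, and the original sorted values are mapped back onto
the result's ranks. The sorted values of the surrogate equal the original
exactly; all temporal and cross-signal structure is destroyed. The threshold
is a summary of the band-mean coherences of `n_surrogates` (default 100)
independently surrogated pairs. The default statistic is the median — read
as "the trial's coherence must beat the typical chance coherence" — which
by construction retains ~50% of genuinely uncoupled trials; a percentile
statistic (e.g. 95) is available for a conventional test-like threshold.
"Median surrogate" is implemented as the median of the surrogate coherence
values, not a pointwise-median signal (which would destroy amplitude
conservation and has no coherence interpretation).

Inside the cohort pipeline, surrogates are generated once per channel within
a trial and shared across that trial's electrode pairs; each pair still sees
`n_surrogates` valid independent null pairs, at a fraction of the cost. The
standalone `coherence_threshold()` surrogates each pair independently.

## Transmission delay and direction

The lag scan (`lagged_coherence()`) shifts EEG against EMG in single-sample
steps (4 ms) up to ±128 ms. At every lag the windowed coherence at the
per-band peak frequency is recomputed on a fixed 3968-sample span, so values
are comparable across lags. Positive lags mean the EEG precedes the EMG
(efferent side). A 16-ms (5-point) centered moving average smooths the
profile; per side, the delay is the coherence-maximizing lag and the CMC the
coherence there. Ties resolve to the smallest absolute lag.

An honest caveat: a wavelet at cf has a coherence time of roughly
$1/\mathrm{bandwidth}$ — hundreds of milliseconds — so the lag profile's
peak is intrinsically broad and single-trial delay estimates scatter by
several samples even at favorable SNR (the method's published per-trial
spreads are on the order of ±13 ms). Higher-frequency peaks (beta rather
than alpha) have wider absolute bandwidth and localize delays better; the
parameter-recovery tests therefore estimate delays at the beta-band peak,
where the median absolute error stays within one 4-ms sample at a 10-dB
broadband SNR.

## ECG removal

ECG contamination of trunk EMG is removed by beat detection in wavelet
intensity space followed by template subtraction (`remove_ecg()`). Beat
detection uses a small bank at the EMG-intensity wavelet scale (0.3; cfs
~7, 19, 38 Hz) whose ~25-ms temporal support matches a QRS complex — the
narrow-band coherence bank (scale 12) would smear a beat over seconds and
cannot localize it. The summed intensity is smoothed over 25 ms; peaks above
`median + 0.25 (max − median)`, separated by a 300-ms refractory period and
refined to the strongest deflection at the full rate, are taken as beats. A
smoothed ensemble-average template is subtracted per beat with a
least-squares scale. With fewer than three detected beats the channel is
returned unchanged — on ECG-free signals the subtraction perturbs the RMS
by well under 2%.

## Group statistics

Directional CMC values are averaged over the retained trials into
six-dimensional profiles (3 EEG × 2 EMG electrodes) per
participant × task × band × direction. Dissimilarity is altGower — the mean
absolute difference across dimensions, without range normalization
(coherences are positive, so double-zero handling is moot). PERMANOVA
partitions the squared distances with sequential sums of squares in the
order band, task, group, then interactions, via `vegan::adonis2`.

The repeated-measures structure is honoured by restricting permutations to
exchanges within participant. Under this restriction the purely
between-participant `group` main effect has a degenerate permutation
distribution (group labels are never exchanged) — its omnibus p-value is not
interpretable, while task, band and all interactions involving them are
tested validly. The task-wise group contrasts
(`pairwise_group_by_task()`) therefore use free permutations, group being
the only factor there. No multiplicity adjustment is applied to the three
task-wise contrasts. NMDS uses Kruskal stress-1 minimization with monotone
regression and random restarts (`vegan::metaMDS` machinery).

## The synthetic generator

`make_coupled_trial()` emulates the recording protocol: 30-s trials, EEG at
500 Hz, bipolar EMG at 2000 Hz, seven trials per task in per-participant
blocks of three tasks (eyes open, eyes closed, dual task). The cortical
drive is band-limited Gaussian noise; by default it has an alpha (10 ± 2 Hz)
and a beta (20 ± 2 Hz) component, mirroring the observation that standing
CMC is significant in both analysed bands. Each EEG motor channel is drive
plus independent noise; six background channels (pure noise) stand in for
the non-motor sites of a full cap so that the common average reference
subtracts only a small fraction of the common drive, as on a real montage.
Each EMG channel is an independent broadband carrier, amplitude-modulated by
the delayed drive, plus an additive scaled copy of the delayed drive — the
additive copy is what carries genuine narrow-band coherence, which envelope
modulation alone would not — plus channel noise, a 50-Hz line component and
an ECG-like pulse train (QRS-shaped sum of Gaussians, ±10% beat-to-beat
amplitude jitter). The drive copies, not the cortical signal, receive the
per-band transmission gains, so cohort effects act on the muscle side.

The default broadband SNR of −6 dB with an EMG-side coupling amplitude
(`emg_coupling`) of 0.3 is chosen so that band-mean coherences fall around
0.4–0.6: comfortably above the surrogate null (~0.35–0.40 at this
windowing) yet far from the ceiling. The sub-unit EMG coupling makes the
muscle side the coherence-limiting side, so per-band transmission gains —
the quantity cohort effects act on — move the coherence visibly; were both
sides strong, coherence would saturate and gain effects would vanish into
the ceiling. Delay-recovery and direction tests instead use
`emg_coupling = 1` and an SNR of 10 dB: full transmission strength is the
condition under which the lag estimator itself is validated.

What the generator does **not** emulate: volume conduction and realistic
EEG topographies, postural sway biomechanics, non-stationary muscle
activation, real ECG morphology, electrode artifacts. Passing tests
therefore demonstrate that the estimators recover known coupling structure
under realistic noise, sampling and contamination — not that the pipeline is
robust to every artifact class of real recordings.

## Problem sizes in the tests

The test suite exercises the statistics at desk scale, as the package's own
choice of simulation size: delay recovery uses 50 trials per delay
condition; surrogate-threshold calibration uses 250 independent-noise pairs
with 100 surrogates each; PERMANOVA type-I calibration uses 500 null
profile cohorts at 499 permutations (scaled down from the study's 5000);
end-to-end detection uses 50 cohorts of 4 participants per group with one
trial per task, eight surrogates and 199 permutations, with a coupling-gain
ratio of 2.5 for the affected group × task cell. The full study design
(10 per group × 3 tasks × 7 trials, 100 surrogates, 5000 permutations)
runs with the same code by changing the config.

## Numerical choices

* Zero-phase filtering is implemented spectrally as multiplication by the
  cascade's squared magnitude response — the exact transfer function of
  forward–backward application — with circular boundary; edge transients
  fall inside the trimmed 5-s margins. Single-pass causal filtering is
  available via `zero_phase = FALSE`.
* The inverse wavelet transform restricted to a window's unpadded span is
  evaluated on the gain's support bins only (the gain decays to below
  1e−14 of its peak outside a narrow band), either as a small matrix
  product or through its Gram matrix; both are exactly equivalent to the
  full-length inverse FFT and are covered by equivalence tests against the
  reference implementation.
* Coherence values are clipped to 1 from above to absorb last-ulp float
  excursions; windows with zero power contribute zero coherence.
* Peak-frequency ties resolve to the lowest cf in the band; lag-profile
  ties to the smallest absolute lag. Per-participant peak frequencies are
  the mean of per-trial argmax frequencies, snapped to the nearest bank cf
  (the alternative — argmax of the trial-averaged spectrum — is a
  one-liner on the exported tables).
* EDF export quantizes to 16 bits with a per-channel symmetric physical
  range; the round-trip error is bounded by one quantization step.

## Known limitations

* Single-trial delay estimates at low peak frequencies are imprecise by
  construction (broad lag profiles); interpret delays at the cohort level.
* The within-participant permutation scheme leaves the group main effect
  untestable in the omnibus model; use the task-wise contrasts for group
  inference.
* The ECG detector's threshold is tuned for contamination that clearly
  exceeds the EMG background (peak amplitude of the order of the EMG RMS
  or more); faint contamination is left in place rather than risking
  template subtraction of genuine EMG.
* ICA-based artifact removal is out of scope; ocular and movement artifacts
  must be handled upstream for real recordings.
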