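Package: cmcwave
Title: Directional Corticomuscular Coherence from EEG and EMG with Cauchy Wavelets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying directional corticomuscular coherence (CMC)
    between EEG and surface EMG recorded during quiet upright standing. Implements
    a non-linearly scaled complex Cauchy wavelet bank and frequency-domain
    continuous wavelet transform, windowed wavelet coherence, amplitude-adjusted
    Fourier transform (AAFT) surrogate significance thresholds, lag-scanned
    estimation of afferent and efferent transmission delays, power spectral
    density summaries, and multivariate group statistics (altGower distances,
    PERMANOVA with participant strata, nonmetric multidimensional scaling) on
    six-dimensional CMC profiles. Includes a synthetic coupled EEG/EMG trial and
    cohort generator with known coupling band, direction, delay, line noise and
    ECG contamination so the full pipeline can be exercised against ground truth,
    plus EDF and delimited-text signal I/O and a single-config study runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    vegan,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
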