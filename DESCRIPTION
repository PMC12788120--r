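Package: tremorband
Title: Task-Based Low-Frequency Tremor Profiling from Surface EMG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for profiling low-frequency (tremor-band)
    activity in protocol-annotated surface electromyography recordings of
    antagonistic forearm muscles. Provides a seeded synthetic cohort simulator
    (amplitude-modulated band-limited noise with task-specific tremor bursts),
    maximum-voluntary-contraction normalisation, full-wave rectification and
    zero-phase 10th-order Butterworth low-pass filtering at 14 Hz,
    FFT amplitude spectra and Gaussian-window short-time Fourier transform
    spectrograms with task-adaptive window lengths, per-frame dominant-frequency
    extraction, partition of observations into the five clinical tremor
    frequency bands (noise, rest, action, postural, normal), and a
    nonparametric statistical battery (Lilliefors-corrected Kolmogorov-Smirnov
    normality, Kruskal-Wallis with epsilon-squared effect sizes, and Dunn's
    pairwise comparisons with Bonferroni adjustment) emitting
    SPSS-dialect comparison tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    Rcpp,
    generics,
    ggplot2,
    jsonlite,
    nortest,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
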