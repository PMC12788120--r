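---
title: "Methods: task-based low-frequency tremor profiling from surface EMG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: task-based low-frequency tremor profiling from surface EMG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tremorband)
```

## The problem

Tremor in movement disorders is conventionally rated by visual observation
during standardised upper-limb tasks. Surface electromyography (sEMG) of
the forearm extensors offers an objective alternative: rhythmic bursting
of the muscle appears as low-frequency amplitude modulation of the
20--450 Hz sEMG carrier, and the modulation frequency falls into clinically
meaningful bands (rest tremor 3.5--6 Hz, action tremor 6--9 Hz, postural
tremor 9--12 Hz). `tremorband` implements the full analysis chain from
protocol-annotated two-channel forearm recordings to nonparametric
task-comparison tables: MVC normalisation, rectification, low-pass envelope
extraction, Gaussian-window STFT, per-frame dominant-frequency profiling,
band partition, and a Kruskal--Wallis / Dunn statistical battery. Because
raw clinical recordings of this kind are rarely shareable, the package also
ships a seeded synthetic cohort generator so the entire chain is testable
and reproducible from code alone.

## The synthetic signal model

`generate_subject()` produces amplitude-modulated band-limited noise, the
standard phenomenological model of bursting sEMG:

* **Carrier** -- zero-mean Gaussian noise confined exactly to 20--450 Hz,
  synthesised in the frequency domain, unit RMS. This emulates the
  interference pattern of many motor units; no motor-unit-level biophysics
  is attempted.
* **Envelope** -- `activation_level x amp_scale x modulation`, in fractions
  of MVC. For tremor tasks the modulation is
  `(1 - depth) + depth * max(0, sin(2 pi f t))`, a half-rectified sinusoid:
  bursts at the tremor frequency `f` separated by quiescence, with `depth`
  the modulation index in [0, 1]. Non-tremor tasks instead carry a slow
  (< 0.5 Hz) stochastic activation drift of 15% relative amplitude, so
  baseline segments are low-level, broadband and non-stationary rather
  than exactly constant.
* **Per-subject variability** -- a lognormal amplitude factor
  (`subject_amp_sd = 0.25` on the log scale) and a normal shift of every
  injected tremor frequency (`tremor_freq_jitter_sd = 0.3` Hz), drawn once
  per subject from a private RNG stream (`cohort seed + subject index`),
  so enlarging a cohort never perturbs existing subjects.
* **Nuisance terms** -- 50 Hz mains hum (Irish/EU grid; 2% of clean-signal
  RMS) and white measurement noise (10% of clean-signal RMS).
* The two channels (extensor carpi ulnaris / radialis) share the task's
  burst timing but have independent carriers and noise.

The default nine-segment protocol places a 240 s baseline (task 0) and
post-baseline (task 8) around seven short motor tasks of 12 s each, with
2 s unmarked rest gaps. Finger tapping (task 3) carries a strong 5 Hz
rest-band rhythm (`depth = 0.8`); the kinetic reach (task 5) and postural
hold (task 7) carry milder 7 and 10 Hz components; pronation--supination
(task 6) is the low, stable reference; the object grip (task 4) is
generated at full activation and serves as the MVC calibration source.
Where the underlying study protocol leaves per-task durations and effect
parameters unstated, these defaults were chosen once as physiologically
plausible values that reproduce the qualitative band structure the
analysis expects (strong rest-band activity under finger tapping, minimal
and stable activity under pronation--supination and at baseline); they are
configurable but the defaults are not tuned per analysis.

What the generator deliberately does **not** emulate: motor-unit
recruitment and firing statistics, electrode-skin impedance drift,
movement artefacts, inter-channel crosstalk, fatigue-induced spectral
compression, and pathological tremor waveforms. Passing tests therefore
demonstrate that the pipeline recovers the structure this model injects --
not that it is robust to every artefact of clinical recordings.

## Pre-processing chain

The stage order is fixed and asserted via monotone processing flags:
segment → trim → normalise → rectify → filter → combine.

* **Segmentation** uses 0-based half-open sample intervals; samples
  between task markers are discarded.
* **Baseline trimming** keeps the central 3 minutes of each baseline,
  discarding equal head/tail excess (odd excess: the extra sample comes
  off the head). This removes settling-in and anticipation effects at the
  segment edges.
* **MVC normalisation** divides each channel by that channel's maximum
  voluntary contraction, estimated from the grip task as the maximum of a
  100 ms moving RMS of the rectified signal. The estimator is a design
  choice (only the source task is externally fixed); a robust 99th-percentile
  alternative is available via `estimator = "quantile"`. Per-channel
  normalisation makes the two electrodes' differing pick-up comparable and
  removes between-subject amplitude scale by construction.
* **Rectification before filtering.** A 14 Hz low-pass applied directly to
  raw sEMG would retain almost nothing, since sEMG power lives at
  20--450 Hz. Full-wave rectification demodulates burst rhythmicity into
  the 0--14 Hz envelope band, which is what the low-pass then isolates.
  Rectification is on by default and can be disabled
  (`do_rectify = FALSE`) for sensitivity analyses.
* **Filtering** uses a 10th-order digital Butterworth low-pass with the
  half-power point placed exactly at 14 Hz (cutoff prewarped before the
  bilinear transform). The filter is designed and applied as cascaded
  second-order sections: at this order and normalised cutoff
  (14/1024) the expanded transfer-function polynomial is numerically
  ill-conditioned, while the biquad cascade is stable. Application is
  zero-phase (forward--backward, odd-reflection edge padding, steady-state
  section initialisation), preserving burst timing for spectrograms; the
  stated order-10 design describes the single-pass filter. Segments
  shorter than three effective impulse lengths (about 0.4 s at 2048 Hz)
  are rejected rather than silently transients-dominated.
* **Combined trace.** After filtering, the mean of the two normalised
  channels is added as `ch_combined` and used as the default analysis
  trace; per-channel analyses remain available.

## Spectral analysis

`amplitude_spectrum()` uses the sinusoid amplitude convention (2/N scaling
off DC) so spectral peaks read directly in fraction-of-MVC units.

The STFT uses a Gaussian window whose length adapts to the task duration:
`nperseg` is the smallest power of two reaching a target frequency
resolution of 0.25 Hz (8192 samples at 2048 Hz), capped at the largest
power of two that fits the segment -- long baselines get full-resolution
windows, short motor tasks the longest window they can carry. The Gaussian
standard deviation is `nperseg/6` samples and frames overlap by half. The
0.25 Hz target matches the ±0.25 Hz recovery tolerance used in
validation; all three values are configurable.

Each frame is constant-detrended (window-weighted mean removed) before
windowing. This matters: rectification leaves a large positive mean, and
with a Gaussian window of this width the DC component would otherwise leak
into the first few bins and dominate every frame's low-frequency range.

**Observation extraction.** Rhythm "occurrence" is operationalised as one
observation per STFT frame: the dominant frequency is the argmax bin over
(0, 14] Hz -- DC excluded so the rectification mean cannot win -- and the
observation's magnitude is that bin's value. Frames whose peak is below
3x the median magnitude of the frame's 0--14 Hz band are dropped as
carrying no confident rhythmic component. This is the simplest rule
consistent with reading dominant ridges off a spectrogram; the gate
multiplier is configurable.

## Frequency bands

Five bands partition the nonnegative axis: noise [0, 3.5), rest [3.5, 6),
action [6, 9), postural [9, 12], normal (12, Inf). Published clinical band
tables often quote boundaries to one decimal ("up to 5.9", "from 6.0"),
leaving the continuum between undefined; the package resolves interior
boundaries as half-open intervals meeting at 6 and 9 Hz. The
postural/normal boundary is taken inclusive on the postural side (an
explicit "up to and including 12" beats an implicit "12+"). Noise and
normal rows are retained in the band table but flagged
`analyzed = FALSE`: sub-3.5 Hz content is dominated by drift and movement
artefact and the 12+ Hz range shows minimal task discrimination, so both
are excluded from the primary inferential battery while remaining
available for descriptive reporting.

## Statistical battery

Per analysed band x measure (frequency, magnitude):

* **Normality screen** -- one-sample Kolmogorov--Smirnov per task with the
  Lilliefors correction, since the reference normal's parameters are
  estimated from the sample. (Frame-level magnitude data are effectively
  never normal; the screen motivates the nonparametric battery.)
* **Omnibus** -- tie-corrected Kruskal--Wallis H across tasks with the
  epsilon-squared effect size `H (N+1) / (N^2 - 1)`, which spans 0 to 1
  (1 is attained when H reaches its maximum N - 1, e.g. N fully ordered
  singleton groups).
* **Pairwise** -- Dunn's test on the pooled ranking: mean-rank difference,
  tie-corrected standard error, standardised z, two-sided normal p, and
  Bonferroni-adjusted p (multiplied by the number of pairs, capped at 1).
  These are exactly the columns of SPSS-style pairwise comparison output,
  and `spss_pairwise_table()` renders them under those column names.

Two analysis units are supported. The default pools all retained frames
(`unit = "frame"`), matching how task-comparison tables of this kind are
usually built; but pooled frames pseudo-replicate -- overlapping frames
within a subject-task are correlated, and all of a subject's observations
share one MVC divisor. `unit = "subject"` collapses to per-subject medians
first and is the robust choice when calibrated error rates matter.

A consequence worth stating plainly: under a task-null with realistic
between-subject variability, the pooled rank test is *conservative* --
subject physiology acts as a blocking factor, so within-subject task
contrasts are diluted by between-subject rank spread. The package's
α-calibration is therefore verified on single-subject null recordings,
where ranks are invariant to the common MVC scale and task-label
exchangeability genuinely holds (measured type-I rate 0.05 at α = 0.05
over 100 seeded runs). For confirmatory multi-subject inference a blocked
test (e.g. Friedman) would be the statistically stricter tool; it is out
of scope here because the battery mirrors the pooled-comparison table
format.

## Numerical and validation choices

* All randomness flows from one integer seed; per-subject streams are
  split deterministically. Every generated sample is bit-reproducible.
* Ties in ranking are handled by midranks with the `t^3 - t` correction in
  both H and the Dunn standard error; degenerate all-equal inputs return
  H = 0, p = 1 rather than erroring.
* Frame argmax ties (exactly equal magnitudes) resolve to the lowest
  frequency bin, as `which.max` does; with continuous data these have
  probability zero.
* Validation problem sizes: the finger-tapping vs baseline significance
  check runs 12-subject cohorts over 20 seeds; tremor-frequency recovery
  runs 50 seeded single-subject recordings (recovery within ±0.25 Hz
  required in ≥ 90%); α-calibration runs 100 seeded null recordings.
  These sizes give stable pass/fail behaviour for a stochastic pipeline
  while keeping a full validation run in the minutes range on one core.

## Worked example

A small end-to-end run (2 subjects, short baselines so the example is
quick; real analyses should keep the 240 s default):

```{r example, eval = FALSE}
proto <- build_default_protocol()
proto$duration[proto$task_id %in% c(0, 8)] <- 30

config <- run_config(
  n_subjects = 2, seed = 1, protocol = proto,
  output_dir = "tremorband_demo"
)
manifest <- run_pipeline(config)
manifest

battery_pairwise <- readr::read_csv(
  file.path("tremorband_demo", "pairwise.csv")
)
dplyr::filter(battery_pairwise, band == "rest", measure == "magnitude")
```

## Known limitations

* The generator is a phenomenological envelope model; conclusions about
  real recordings require real recordings.
* Dunn + Bonferroni is one defensible post-hoc convention among several
  (Conover--Iman, Holm adjustment); the column format, not optimality,
  fixed the choice.
* The pooled battery's conservatism under subject heterogeneity
  (discussed above) means frame-level p-values should be read as
  descriptive orderings rather than calibrated error statements.
* Channel coherence, wavelet/Hilbert alternatives, artefact rejection and
  notch filtering are intentionally out of scope.
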