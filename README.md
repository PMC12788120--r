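# tremorband

Task-based low-frequency tremor profiling from surface electromyography
(sEMG), for researchers quantifying upper-limb motor behaviour during
standardised clinical task protocols (e.g. MDS-UPDRS-style batteries).
The package turns protocol-annotated two-channel forearm recordings into
nonparametric task-comparison tables over the clinical tremor frequency
bands, and ships a seeded synthetic cohort simulator so the whole chain is
reproducible from code alone.

## What it computes

Muscle bursting appears in sEMG as low-frequency amplitude modulation of
the 20–450 Hz carrier. The pipeline extracts and profiles that modulation:

1. **Pre-processing** — split the recording at task markers; trim both
   baselines to their central 3 min; normalise each channel by its maximum
   voluntary contraction, MVC (max of a 100 ms moving RMS of the rectified
   grip-task signal); full-wave rectify; apply a zero-phase 10th-order
   Butterworth low-pass with half-power at 14 Hz, |H(14 Hz)|² = ½,
   designed and run as cascaded second-order sections; average the two
   channels into the combined analysis trace.
2. **Spectral analysis** — FFT amplitude spectra, and Gaussian-window STFT
   spectrograms whose window length adapts to task duration (smallest
   power of two reaching 0.25 Hz resolution, capped at the segment).
   Each frame contributes one observation: its dominant frequency
   f\* = argmax over (0, 14] Hz and magnitude M(f\*), gated at 3× the
   frame's median band magnitude.
3. **Band profiling** — observations partitioned into noise [0, 3.5),
   rest [3.5, 6), action [6, 9), postural [9, 12] and normal (12, ∞) Hz;
   rest/action/postural form the analysis set.
4. **Statistics** — per band × measure (frequency, magnitude): Lilliefors
   Kolmogorov–Smirnov normality per task; Kruskal–Wallis omnibus H with
   effect size ε² = H(N+1)/(N²−1); Dunn pairwise comparisons
   (mean-rank difference, tie-corrected SE, z, two-sided p, Bonferroni-
   adjusted p) rendered in SPSS-style columns.

The simulator generates amplitude-modulated band-limited noise: a
20–450 Hz unit-RMS carrier times an activation envelope
`a · s · [(1−d) + d · max(0, sin 2πft)]` (activation `a`, subject scale
`s`, modulation depth `d`, tremor frequency `f`), plus 50 Hz hum and
measurement noise. Finger tapping (task 3) injects a strong 5 Hz rest-band
rhythm; pronation–supination (task 6) is the low stable reference; the
grip task (task 4) is the MVC source.

## Worked example

```r
library(tremorband)

cfg <- run_config(n_subjects = 6, seed = 1, output_dir = "demo_run")
manifest <- run_pipeline(cfg)
manifest
#> <run_manifest> 6 recordings, 54 segments, 1024 observations -> 7 output files

pw <- readr::read_csv(file.path("demo_run", "pairwise_magnitude_spss.csv"))
subset(pw, Group == "Rest" & `Sample 1-Sample 2` %in% c("0-3", "0-8", "3-8"))
#>   Group Sample 1-Sample 2 Test Statistic Std. Error Std. Test Statistic
#> 1  Rest               0-3          -20.0      5.762             -3.4712
#> 2  Rest               0-8           -3.5      8.267             -0.4234
#> 3  Rest               3-8           16.5      6.554              2.5174
#>        Sig. Adj. Sig.
#> 1 0.0005181  0.001554
#> 2 0.6720342  1.000000
#> 3 0.0118236  0.035471
```

Reading the table: in the rest band (3.5–6 Hz), finger tapping (task 3)
separates sharply from both baseline (task 0) and post-baseline (task 8)
in magnitude — the mean-rank differences of −20.0 and 16.5 standardise to
|z| > 2.5 with Bonferroni-adjusted p < 0.05 — while the two baselines do
not differ from each other (p = 0.67), the consistency that justifies
using them as reference states. The corresponding omnibus test prints
H = 16.76 on 2 df, p = 2.3e-4, ε² = 0.47 for rest-band magnitude.

`autoplot()` methods render spectrogram heat maps and pairwise z-value
summaries; `render_reports("demo_run")` writes band figures and a Markdown
summary. A thin CLI wrapper lives at `inst/cli/tremorband.R`
(`simulate`, `run-all`, `report`).

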