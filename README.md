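# audiencesync

Tools for quantifying collective neural engagement in audiences of live,
naturalistic performances from multi-subject mobile EEG — and for asking
*what on stage drives it*.

When a group of people watch the same performance, slow (delta-band)
components of their EEG become weakly but measurably correlated.
`audiencesync` implements the full analysis chain around that phenomenon
for researchers working with multi-device ("hyperscanning") audience
recordings:

* **Correlated-components ISC.** Channel weight vectors `v` maximizing the
  ratio of pooled between-subject to within-subject covariance, via the
  generalized eigenproblem `Rb v = mu (Rw + lambda tr(Rw)/D I) v`, with
  `ISC_i = v' Rb v / ((N-1) v' Rw v)` so that N identical subjects score
  exactly 1. Time-resolved ISC uses 5 s windows with 80% overlap and fixed
  global weights; forward models (scalp topographies) are
  `A = Rw W (W' Rw W)^-1`.
* **Surrogate and cluster statistics.** Circular-shift surrogate nulls
  (independent uniform rotations per subject), per-window 95th-percentile
  thresholds, and cluster-size correction over time-adjacent windows and
  neighbouring frequency bands; plus a tiled resting-state baseline
  contrast (paired Wilcoxon per 2.5 min segment, BH-FDR).
* **Phase-locking value.** `PLV = |(1/T) sum_t exp(i(theta_j - theta_k))|`
  on Hilbert phases of band-passed data, per subject pair, electrode, and
  5 s window.
* **Welch band power.** 1 s Hann segments, 20% overlap, channel- then
  bin-averaged, with a 4 SD outlier filter.
* **Performance features at 1 Hz.** Audio RMS energy and a pulse-clarity
  (beat-strength) index, wrist-accelerometer magnitude, dancer distance,
  stage luminance, windowed continuous ratings, and audience respiration
  synchrony through the same ISC machinery.
* **Granger coupling.** Augmented Dickey-Fuller stationarity screening,
  then pairwise nested-OLS F tests from each feature to the synchrony time
  course over lags 1-15 s, BH-FDR over the whole predictor-by-lag grid,
  with the identical scan against surrogate synchrony as a negative
  control.
* **Synthetic audience generator.** A seed-deterministic simulator with
  known ground truth (shared band-limited source, slow engagement gain,
  spatially correlated noise, artifact bursts, device clock offsets with
  photoresistor blackout traces, a feature with a planted lagged influence
  on the gain) so every stage is testable without recorded audience data.

The methods vignette (`vignettes/audience-synchrony-methods.Rmd`) documents
the models, parameter choices, and limitations in detail.

## Worked example

Simulate a small audience with a shared delta-band source, fit the
correlated components, and check the time-resolved synchrony against its
circular-shift null:

```r
library(audiencesync)

cfg <- sim_config(n_subjects = 8, n_channels = 8, duration = 180,
                  snr = 0.1, artifact_rate = 0, device_offsets = rep(0, 8),
                  seed = 42)
sim  <- simulate_audience(cfg)
gd   <- group_map(sim$group, bandpass_filter, band = canonical_bands()$delta)
grid <- window_grid(180)

model <- fit_cca_group(gd, n_components = 3)
model
#> <cca_model: 8 channels, 3 components, N = 8>
#>   ISC: 0.1349 0.01457 0.005468

round(explained_covariance(model), 2)
#> [1] 87.07  9.40  3.53  0.00  0.00  0.00  0.00  0.00

tc <- isc_timecourse(gd, model, grid)
tc
#> <isc_series: C1 delta, 176 windows, median 0.1030>

nd <- null_isc_distribution(gd, grid, iterations = 200, seed = 42)
mean(tc$values > null_threshold(nd))
#> [1] 0.3977273
```

The first correlated component captures the planted shared source: its ISC
(0.135) dwarfs the remaining components and accounts for 87% of the group
covariance, and 40% of the 5 s windows exceed the per-window 95th
percentile of 200 circular-shift surrogates — against the 5% expected if
the audience were unsynchronized.

## The analysis workflow

`analysis/` contains numbered drivers that walk one synthetic "performance
evening" (16 subjects x 32 channels, 5 min at 250 Hz, seed-deterministic)
through the whole pipeline, writing tidy CSV tables under `results/`:

| script | what it does |
|---|---|
| `01_simulate.R` | generate the audience, photoresistor, feature, and respiration data; record ground truth |
| `02_preprocess_align.R` | blackout alignment, band-pass, 4 SD outlier zeroing, average reference |
| `03_isc_surrogate.R` | correlated components per band, windowed ISC, surrogate null, cluster correction |
| `04_features.R` | 1 Hz feature series, respiration synchrony, spectral centroids |
| `05_granger.R` | ADF screen and feature -> synchrony Granger scan, plus the surrogate-outcome control |
| `06_plv_power.R` | section PLV (low- vs high-engagement) and Welch band power |

Run them in order from the repository root:
`for s in analysis/0*.R; do Rscript "$s"; done`

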