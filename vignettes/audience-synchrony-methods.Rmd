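---
title: "Audience inter-brain synchrony: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Audience inter-brain synchrony: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(audiencesync)
```

# The scientific problem

When many people watch the same live performance, slow components of their
EEG become weakly correlated: a group-level signature of shared attentional
engagement. `audiencesync` implements the full analysis chain for
quantifying this *inter-subject correlation* (ISC) in a naturalistic,
multi-device recording setting and for relating its time course to what was
happening on stage:

1. multi-device temporal alignment from photoresistor blackout traces;
2. band-limited preprocessing (Butterworth band-pass, 4 SD outlier zeroing,
   common average reference, polyphase-free zero-phase downsampling);
3. correlated-components ISC with time-resolved 5 s / 80%-overlap windows;
4. circular-shift surrogate nulls with cluster-based multiple-comparison
   correction and a tiled resting-state baseline contrast;
5. continuous performance features on a common 1 Hz grid;
6. stationarity-screened pairwise Granger-causality scans from features to
   the synchrony course;
7. pairwise phase-locking values (PLV) and Welch band power for section and
   context contrasts.

Because raw audience EEG is not shipped with the package, a synthetic
generator with known ground truth stands in for it; every downstream stage
is tested against that ground truth.

# The correlated-components model

For subjects $k, l$ let $R_{kl}$ be the channel cross-covariance over a
span. With $R_w = \sum_k R_{kk}$ (pooled within-subject) and
$R_b = \sum_{k \ne l} R_{kl}$ (pooled between-subject, symmetrized), the
component weights $v$ maximize the ratio of between- to within-subject
covariance, solved as the generalized eigenproblem

$$R_b\, v = \mu \left(R_w + \lambda \tfrac{\mathrm{tr} R_w}{D} I\right) v,
\qquad
\mathrm{ISC}_i = \frac{v_i^\top R_b v_i}{(N-1)\, v_i^\top R_w v_i}.$$

Key conventions, each of which was a genuinely open choice:

* **$(N-1)$ normalization.** $N$ identical subjects have
  $R_b = (N-1) R_w$, so the first component's ISC is exactly 1; independent
  subjects give ISC near 0. This fixes the otherwise arbitrary scale of
  "synchrony values".
* **Global weights, window-local covariances.** The time-resolved course
  evaluates the ratio with $R_w(w), R_b(w)$ from each 5 s window but the
  weights fitted once on the whole recording. Refitting inside 5 s windows
  (1250 samples, 32 channels) is unstable and was rejected.
* **Shrinkage $\lambda = 0.1$** (diagonal loading relative to the mean
  eigenvalue of $R_w$). Window covariances are rank-deficient without it.
  The loading is isotropic, so the regularized fit is deliberately *not*
  invariant to per-channel rescaling; the exact fit ($\lambda = 0$) is, and
  the tests check invariance there.
* **Windows** are half-open $[t, t+5)$ at sample resolution, timestamped by
  their start, with a 1 s hop (80% overlap); a 60 s recording yields 56
  windows. Windows with more than half their samples masked yield `NA`
  rather than a biased value.
* **Explained covariance** is reported as
  $100 \cdot \max(\mathrm{ISC}_i, 0) / \sum_j \max(\mathrm{ISC}_j, 0)$ over
  the full component set — a declared convention for a quantity whose exact
  formula is not fixed by the field.
* **Masked samples** (artifact zeroing) are excluded pairwise from
  cross-covariances, with means removed per span; a sample is unusable when
  any channel was zeroed there.

# Surrogate statistics and cluster correction

The null model rotates each subject's whole multichannel record by an
independent uniform offset in $[30\,\mathrm{s}, T-30\,\mathrm{s}]$
(circular shift), destroying alignment across subjects while preserving all
within-subject structure. The 30 s guard keeps draws away from the identity;
the offset law itself is a convention, as only its support matters under
exchangeability. Per window, the 95th percentile of the surrogate ISC draws
is the significance threshold.

With a finite number $K$ of surrogates the choice of percentile estimator
matters: the interpolated order statistic at $p(K+1)$ (quantile type 6) has
exceedance probability exactly $1-p$ under exchangeability, whereas the
default type-7 estimator is anti-conservative (about 5.45% at $K = 200$).
The package uses type 6; at the full-scale $K = 1000$ the difference is
immaterial.

One engineering note: the surrogate loop refits the components hundreds of
times. Each refit uses the pooled covariances with zeroed samples entering
as zeros rather than being excluded pairwise (`exclude_masked = FALSE`): at
the sub-percent masked fractions the pipeline produces, the two versions of
the covariances differ by well under 1%, far below surrogate variability,
while the pairwise-excluded pass costs $O(N^2 D^2 T)$ per fit. The single
fit of the *true* model keeps exact pairwise exclusion, and all windowed
statistics keep their pairwise mask handling in every case.

Cluster correction groups supra-threshold windows that are adjacent in time
within a band or coincident in neighbouring bands (bands ordered delta,
theta, alpha, beta), measures clusters by their size in windows (not summed
height), and compares each against the 95th percentile of the per-iteration
largest-cluster sizes. Sampling variance matters when interpreting the
pointwise rate: overlapping 5 s windows at a 1 s hop are strongly
correlated, so a 600-window recording has roughly 120 effectively
independent windows and a single dataset's exceedance fraction fluctuates
with SD near 2 percentage points. Calibration is therefore asserted tightly
on the *mean* over 200 independent null replicates and only loosely on any
single dataset.

The resting-state baseline tiles a short pre-performance recording
end-to-end (no taper; seam-spanning windows kept, matching naive tiling) to
the performance length, computes ISC through the identical pipeline, and
compares each 2.5 min performance segment against its resting counterpart
with a paired Wilcoxon signed-rank test across windows (pairing by window
index; exact null below 25 informative pairs, normal approximation with
continuity correction above), BH-FDR corrected across segments.

# Phase locking and band power

Instantaneous phase is the angle of the analytic signal (frequency-domain
Hilbert transform) of band-passed data. The windowed phase-locking value is
the modulus of the mean unit phasor of the phase difference,
$\mathrm{PLV} = |\tfrac1T \sum_t e^{i(\theta_j - \theta_k)}|$: the modulus
makes the statistic real and confines it to $[0, 1]$, with 1 for perfectly
locked (including constant-offset) phases and exactly 0 when the phase
difference sweeps a complete set of roots of unity. The default grid is 5 s
windows with 4 s overlap; a non-overlapping switch reproduces 36 windows
per 3 min section. Six analysis electrodes are grouped as central
(C3, C4, Cz) and occipital (O1, Oz, O2).

Welch band power uses 1 s Hann segments (250 samples at 250 Hz) with 20%
overlap, mean removed per segment, one-sided scaling such that the PSD
integrates to the signal variance; power is averaged across channels and
then across band bins, and subject rows beyond 4 SD of the mean power are
dropped. Note that a single outlier among $n$ rows can reach at most
$(n-1)/\sqrt{n}$ contaminated SDs, so the 4 SD rule only ever fires in
sufficiently large tables — the filter is a guard against gross hardware
failures, not a small-sample trimmer.

# Granger coupling of features to synchrony

Every predictor (and the outcome, informatively) passes an augmented
Dickey-Fuller screen: constant-only regression, augmentation order chosen
by AIC up to $\lfloor 12 (n/100)^{1/4} \rfloor$, p-value interpolated from
the standard constant-case Dickey-Fuller quantile table over both sample
size and level. A non-stationary predictor is refused unless explicitly
first-differenced (as stage lighting is in practice). The unit-root test is
implemented in the package because no unit-root package is part of its
dependency set; it was checked against an independent reference
implementation during development.

The scan runs a pairwise nested-OLS F test per (predictor, lag) cell over
lags 1-15 s — restricted model: outcome on its own lags $1..p$;
unrestricted: plus predictor lags $1..p$; $F$ with $(p,\; n - 2p - 1)$
degrees of freedom — and reports every lag separately rather than selecting
an order, with BH-FDR over the whole predictor-by-lag grid (the declared
family, per outcome and performance). A univariate-per-feature approach is
intentional: the features live on qualitatively different timescales, and a
joint autoregressive model would force a single lag structure on all of
them. The same scan applied to a circular-shift surrogate outcome is the
negative control.

# What the generator emulates — and what it does not

`simulate_audience()` produces, per subject,
$X_k(t) = g(t)\,\mathrm{snr}\, m_k s(t) + \varepsilon_k(t) + \text{artifacts}$:

* a **shared source** $s(t)$: white noise passed through the same 5th-order
  Butterworth band-pass used in preprocessing (spectral consistency with the
  analysis band), unit variance;
* an **engagement gain** $g(t) \in [0,1]$ at 1 Hz: a smoothed random walk
  with ~180 s correlation length (matching the 2.5-3 min granularity of a
  choreographed piece), linearly interpolated to the sample rate;
* **mixing vectors** $m_k$: a common random topography plus per-subject
  jitter, unit norm;
* **spatially correlated noise**: unit variance with inter-channel
  correlation 0.3 via a compound-symmetry Cholesky factor — an exact
  version of "about 0.3 correlation, mimicking volume conduction";
* **artifact bursts**: 200 ms boxcars at 8 channel-SDs on random channel
  subsets, 2 per minute, exercising the outlier-zeroing stage;
* **device clock offsets** (default uniform in ±0.25 s) plus photoresistor
  traces whose blackout ramp encodes each offset;
* **respiration traces** sharing a slow ~0.25 Hz rhythm.

When `coupling_beta > 0`, the gain's fast component is driven by a white
1 Hz feature $f$ delayed by `coupling_lag`:
$g = \mathrm{rescale}(\mathrm{base} + \beta f(t - \ell) + \eta)$. The
coupled feature is white by design: a temporally smooth feature would make
every lag below the planted one informative (its own past predicts its
future), and the minimal significant Granger lag would no longer identify
$\ell$. Conversely, note that the 5 s analysis windows smear the planted
lag when the scan targets the *windowed ISC* rather than the gain: the
window value at start $t$ reflects $f(t-\ell) \ldots f(t-\ell+4)$, so lags
shorter than $\ell$ also become informative. Lag-recovery properties are
therefore stated against the 1 Hz gain, and the windowed-ISC route is
expected to recover the coupling with a minimal lag at or below $\ell$.

Defaults describe the emulated study conditions: 20 subjects, 32 channels,
250 Hz, 10 min, snr 1, seed-derived substreams for every draw (bit-identical
output for a fixed seed; all derived seeds stay below $2^{31}$).

A note on the meaning of `snr`: it is the *broadband* shared-to-noise
amplitude ratio. Band-passing to delta keeps the entire shared source but
only ~2% of the unit-variance noise power, so the **in-band** signal-to-noise
ratio is roughly $50\,\mathrm{snr}^2$: `snr = 1` is a strong-synchrony
regime (first-component ISC near 0.9), useful for exercising the machinery,
while `snr` in the 0.03–0.1 range produces the few-percent delta-band ISC
magnitudes typical of real audiences. The worked examples and the
`analysis/` evening use `snr = 0.1` (moderate regime: ISC$_1 \approx$ 0.13
with the pipeline's windows clearly separated from the surrogate band);
null-calibration checks use `snr = 0`.

What the generator does **not** emulate: biophysical head geometry, eye or
movement artifacts with realistic spectra, non-stationary noise, electrode
drift or contact loss, inter-individual latency differences, or any audio
synthesis (audio features are simulated at series level). Passing tests
demonstrate the *statistical machinery* — normalization identities, null
calibration, lag recovery, monotonicity in effect strength — not
performance on real scalp data.

# Numerical and degenerate-input choices

* Band-pass, high-/low-pass and anti-alias filters are zero-phase
  (forward-backward Butterworth); ISC and PLV are phase-sensitive, so
  one-sided filtering would bias them. The effective order doubling is
  accepted.
* Outlier zeroing runs *after* band-passing (zeroing last avoids smearing
  zeros through the filter); channel mean and SD come from the channel's
  currently unmasked samples, so the operation is stable under repetition
  on its own output. Constant channels are left untouched with a warning.
* Downsampling is zero-phase anti-aliased interpolation (8th-order
  Butterworth at 0.45 of the target rate); upsampling is refused.
* The blackout onset detector localizes coarsely by a sliding-window slope
  deviation, refines by minimizing the two-segment least-squares residual,
  and polishes to sub-sample precision by intersecting lines fitted well
  inside each segment; detection is accepted only if the two-segment fit
  reduces the single-line residual by at least 20% (tunable), otherwise a
  no-change-point error is raised. The fit window (0.4 s per side) must stay
  shorter than the blackout ramp.
* Savitzky-Golay polynomial order for respiration smoothing is 3; the
  respiration outlier rule is a 0.5 s rolling median with a 4
  robust-SD(MAD) deviation threshold and nearest-good-neighbour averaging.
* Degenerate inputs error loudly: fewer than 2 subjects or channels where
  required, bands at or above Nyquist, surrogate shifts on recordings
  shorter than 120 s, all-nonpositive component ISCs in the explained-
  covariance composition, alignment shifts above 10% of the duration.

# Problem sizes used by the tests and scripts

The package's own test and script runs use desk-scale versions of the study
conditions, chosen so the full suite exercises every stage at meaningful
statistical resolution: the single-dataset null-band check runs 8 subjects,
8 channels, 10 min at 250 Hz with 200 surrogates; the calibration study
runs 200 independent null replicates (6 subjects, 4 channels, 50 Hz, 240 s,
200 surrogates each); Granger calibration uses 100 replicates of a
6-predictor-by-15-lag grid at n = 600; the analysis scripts run one full
16-subject, 32-channel, 5 min evening with 200 surrogates. The surrogate
count is the one knob scaled down from the full-scale 1000; the
order-statistic threshold correction above keeps the smaller count
calibrated.

# Known limitations

* The pulse-clarity feature is a simplified autocorrelation beat-strength
  index; parity with established music-information-retrieval estimators is
  explicitly out of scope.
* ICA-based artifact rejection is out of scope (a manual step in practice);
  the artifact path here is the 4 SD zeroing stage only.
* The ADF p-value interpolates between tabulated quantiles (exact at the
  table's probability points, linear between them); this is the same
  approach long used by standard R unit-root tests and is amply accurate
  for a 0.05 screen.
* Mixed-effects modelling of PLV/power tables and questionnaire statistics
  are downstream of the exported tidy tables and not implemented here.
* Granger F tests on the windowed synchrony course inherit its strong
  autocorrelation (5 s windows at a 1 s hop impose a moving-average
  structure), which makes uncorrected cell-level tests somewhat
  anticonservative; the scan against the circular-shift surrogate outcome
  is the empirical control for this, and short recordings can show more
  surrogate than true detections. At desk scale (a few hundred windows,
  weak sources) the windowed-ISC route may miss a planted coupling that the
  1 Hz latent-gain series recovers cleanly; lag-recovery guarantees are
  stated at the series level.
* Clock *drift* (slow divergence after alignment) is not corrected; only
  constant offsets are.
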