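---
title: "Methods: HRV characterization and prediction of PSH episodes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: HRV characterization and prediction of PSH episodes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pshhrv)
```

## The analysis problem

Paroxysmal sympathetic hyperactivity (PSH) produces episodic surges of
heart rate, blood pressure, sweating, and posturing in patients with severe
brain injury. Because episodes are unpredictable, the question this
pipeline addresses is whether the autonomic signature of an impending or
ongoing episode is readable from the tachogram — the sequence of RR
(inter-beat) intervals — and whether that signature can be classified
against control events in which heart rate also rises (noPSH) but no storm
occurs.

Each episode is analyzed over three adjacent 600-s windows around the
clinically annotated onset: `Pre20` = [onset − 1200, onset − 600), `Pre10`
= [onset − 600, onset), and `Event` = [onset, onset + 600). Ten minutes is
the shortest window that still admits a usable number of very-low-frequency
oscillations (the VLF floor of 0.0033 Hz corresponds to a 300-s period);
the estimator variance at that floor is correspondingly high, and we treat
VLF quantities from 600-s windows as noisier than LF/HF ones rather than
pretending otherwise.

## Preprocessing

R peaks are detected with the classic Pan–Tompkins cascade: 5–15 Hz
band-pass (2nd-order Butterworth, zero-phase `filtfilt`), five-point
derivative, squaring, 150-ms moving-window integration, adaptive dual
thresholds with a search-back pass at half threshold, a 200-ms refractory
period, and refinement of each fiducial mark to the raw-signal maximum
within ±25 ms. One implementation detail matters: the integrated envelope
carries side lobes around each QRS complex, so candidate maxima are
non-maximum-suppressed inside the refractory window before thresholding;
otherwise a shoulder lobe can fire first and the refractory period then
masks the true peak.

Artifact handling is a local-median rule: an interval deviating from the
running median of 11 intervals by more than 25% (configurable) is flagged
and replaced by cubic-spline interpolation over accepted neighbours; each
corrected run is rescaled so the spanned duration is preserved, which keeps
beat count and total duration invariant. The 25% threshold is a standard,
auditable choice — the thresholds used by commercial HRV software are not
published. Series with more than 20% flagged intervals are marked
low-quality but still processed. Interpolation is the default; an
`exclude` mode flags without replacing, for users who prefer to drop
ectopic intervals from time-domain summaries.

Respiratory rate is estimated from ECG-derived respiration (EDR): the
per-beat R-wave amplitude series, spline-resampled to 4 Hz, whose dominant
spectral peak in 0.1–0.7 Hz is reported in breaths/min. R-amplitude
modulation is one of several published EDR schemes; it is recorded in the
output's method field so downstream users know which one they got.

## Spectral measures

The tachogram is cubic-spline resampled to a uniform 4 Hz grid and
quadratically detrended before spectral analysis; the quadratic removes
slow nonstationary drift that would otherwise leak into the VLF band.
Welch's method uses 150-s segments — Hann-tapered, 50% overlap, choices
exposed in the function signature since only the window length is a fixed
design input — giving a frequency resolution of 1/150 Hz and 7 averaged
segments per 600-s window. The density is one-sided and normalized so its
integral recovers the variance (verified by a Parseval test). Band powers
integrate the density over VLF 0.0033–0.04, LF 0.04–0.15, and HF
0.15–0.5 Hz with linear interpolation at the band edges, so adjacent bands
partition the spectrum without double counting. Natural logs of the powers
are the analysis variables (raw band powers are strongly right-skewed); a
power below 1e-12 ms² is numerical dust from an effectively constant
window and its log is reported missing rather than −∞, so degenerate
windows drop out of downstream statistics instead of propagating
infinities.

Two time-domain conventions are worth stating. "Max HR" is defined as the
maximum of the 10-s rolling-mean heart rate, which suppresses single-beat
spikes; the raw per-beat maximum is also reported. SDNN uses the
population standard deviation (divide by n).

## Multiscale entropy

Sample entropy SampEn(m = 2, r = 0.2·SD) is computed on coarse-grained
versions of the beat-domain RR series at scales 1–10, and the complexity
indices are the sums over scales 1–5 (CI_s) and 6–10 (CI_l). Three
conventions are deliberate:

- The tolerance r is fixed from the scale-1 series and reused at every
  scale (the original multiscale-entropy convention). Per-scale
  renormalization is available behind a flag because it changes results
  materially: with a fixed r, the variance loss under coarse-graining is
  part of the signal.
- Entropy runs on the artifact-corrected beat-domain series, not the 4 Hz
  interpolated grid — spline interpolation manufactures regularity and
  inflates apparent predictability.
- Undefined SampEn (no template matches) is reported missing, never capped.

A 600-s window at 90–120 b/min yields 900–1200 intervals, so scale 10
operates on ~100 points; that is above the m + 2 floor but short, and the
per-scale minimum lengths are warned about rather than silently accepted.

## Wavelet band-power trends

Gradual power changes over the full 1800-s episode are measured with an
analytic Morlet continuous wavelet transform, computed in the Fourier
domain with center-frequency parameter ω₀ = 6 (the standard choice; it is
exposed in the signature) and 12 voices per octave over 0.0033–0.5 Hz.
Power is normalized as a spectral density such that the time-averaged
integral over frequency recovers the series variance (reconstruction
constant C_δ = 0.776 for ω₀ = 6); RR values are converted from ms to s
first, so densities are in s²/Hz — multiply by 10⁶ for the ms²/Hz used by
the Welch module. Band-power time courses are per-time trapezoidal
integrals over the band.

Each band's time course is regressed on time (seconds) by ordinary least
squares, reporting intercept and slope with standard errors, the model
F-ratio, the slope p-value, R², and a 95% CI from the t distribution with
n − 2 degrees of freedom. Two caveats are intentional. First, the 4-Hz
power samples are strongly serially correlated, and the plain OLS
inference ignores that, exactly as the regression-table convention this
mirrors does; the fitted slope is unbiased but the nominal SEs are
optimistic for real wavelet power. (The CI-coverage test in the suite
injects *independent* noise, so it validates the OLS machinery, not a
claim about serial correlation.) Second, samples inside the cone of
influence are excluded from trend fits by default — for the VLF band the
cone removes roughly the first and last 400 s — and a flag restores the
naive full-window fit.

## The synthetic-episode generator

The generator is the package's stand-in for patient recordings and defines
the study conditions the tests run under. Beat times come from
integrate-and-fire over an instantaneous-rate function (a beat fires at
each integer crossing of the integrated rate), which keeps beat times, RR
intervals, and ECG placement mutually consistent. The instantaneous RR is:

- a baseline ramp: heart rate follows a sigmoid transition at onset with a
  60-s time constant — PSH episodes ramp from 97 to 123 b/min, controls
  from 95 to 100 b/min, matching the observed group means — so the Pre10
  window carries partial pre-onset signal;
- one band-limited oscillator per VLF/LF/HF band with a linearly decaying
  amplitude envelope (clipped at zero). Default initial amplitudes are
  40/30/25 ms; PSH decay slopes are steeper than noPSH in every band, with
  HF losing relatively more than LF — the sign-and-ordering structure of
  the observed regression table. The magnitudes are modeling choices, not
  claims about patients;
- oscillator phase drift: each oscillator's phase performs Brownian motion
  whose rate (`phase_jitter`) is low in PSH (0.25) and higher in controls
  (0.55). This is the generative counterpart of the rigid, low-complexity
  autonomic output of a storm; a pure additive-noise contrast turned out
  to produce the *wrong* long-scale entropy ordering (deterministic
  sinusoids plus relatively more noise make PSH look more complex at long
  scales), whereas phase rigidity lowers PSH entropy across all ten
  scales, as required;
- additive modulation noise: a white/1-f mixture (`noise_mix`, PSH 0.10 vs
  noPSH 0.80; total SD 6 vs 15 ms). The white fraction drives short-scale
  entropy specifically, making CI_s the dominant discriminator, which is
  the structure the classifier ablation is expected to show.

Cohorts draw per-episode parameters around these defaults: a shared
lognormal amplitude factor (σ = 0.45) plus band-specific factors
(σ = 0.25), heart-rate jitter of 4 b/min, and mild jitter on the noise
parameters. The shared amplitude factor models episode-to-episode
variation in overall autonomic tone and makes the spectral features
mutually redundant — deliberately, so that classification accuracy is high
but not trivially saturated, in the moderate-effect-size regime the
observed cohort statistics imply (between-condition effect sizes around
r² ≈ 0.5 for CI_s).

What the generator does *not* emulate: ectopic beats and device artifacts
(tests construct those explicitly), respiratory sinus arrhythmia coupled
to an actual respiration signal, blood-pressure or temperature channels,
circadian structure, and any patient-specific tachogram morphology.
Passing tests therefore demonstrate that the pipeline measures what it
claims on signals with known ground truth — not that real PSH episodes are
classifiable at the same accuracy.

## Statistics and scoring

Group comparisons use two-sided t-tests (paired within condition across
windows, independent between conditions), preceded by Shapiro–Wilk
normality screening; non-normal results are flagged but still reported, and
the effect size is r² = t²/(t² + df). The significance threshold is
Bonferroni-corrected at 0.05/44 ≈ 0.001 for the default battery; the
divisor is configurable since the enumeration of planned comparisons
belongs to the study design, not the package.

PSH-AM scoring combines the six-item Clinical Features Scale (0–3 each;
a total above 13 flags severe features) with the eleven-item binary
Diagnosis Likelihood Tool. The published "probable" band is 19–21;
because an instrument's higher scores cannot make the diagnosis less
likely, the category is implemented as combined ≥ 19, with 8–18 "possible"
and below 8 "unlikely".

## Classifier

Features are the log band powers, LF/HF ratio, SDNN, and the two
complexity indices; a seeded 500-tree random forest ranks them by impurity
importance, and the default subset covers 80% of cumulative importance.
The reference outcome on synthetic cohorts — log VLF and HF power plus the
complexity indices — matches the feature set the pipeline is designed
around. Etiology can be carried as an optional one-hot feature but is
excluded by default.

The RBF-SVM hyperparameters are searched on a 10 × 10 log-spaced grid over
C ∈ [0.5, 10] and γ ∈ [0.01, 10] (100 models; a seeded random search over
the same ranges is available, since a reported best configuration need not
sit on a round grid). Each configuration is scored by stratified tenfold
cross-validation with standardization parameters estimated on the training
folds only; out-of-fold predictions are pooled into one confusion matrix
(fold-averaged metrics are available by flag). "Best" means maximal
validation balanced accuracy, ties broken toward smaller C then smaller γ.
Tuning runs on Event windows only; the frozen configuration is then applied
to Pre10 and Pre20, avoiding per-window adaptation. Ablation refits the
cross-validation with each feature removed and reports misclassification
and balanced-accuracy deltas overall and per class.

Known inconsistency, documented rather than forced: a balanced 24/24
design with sensitivity 100% and specificity 33% gives balanced accuracy
66.5%, not the 68% sometimes quoted for the Pre20 window, and the
corresponding F1 cannot be 67% either; `compute_metrics()` follows the
algebraic definitions.

## Problem sizes and determinism

The validation suite runs cohorts of 24 + 24 episodes of 1800 s (the study
design size), 20-replicate noise ensembles for the entropy and Parseval
properties, 30 mixed signals for the wavelet/Welch cross-check, 100 seeded
runs for CI coverage, and 20 ECG replicates at 10 dB for detection — sizes
chosen so each property is tested at the scale the pipeline targets while
the whole suite stays comfortably runnable on a laptop. Every stochastic
step is seeded: a spec plus seed reproduces beat times bitwise, and the
cohort manifest records per-episode seeds so any feature table can be
regenerated exactly.
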