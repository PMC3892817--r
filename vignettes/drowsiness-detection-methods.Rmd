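---
title: "Detecting driver drowsiness from PPG-derived HRV: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting driver drowsiness from PPG-derived HRV: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drowsyhrv)
```

## The problem and the signal model

A photoplethysmogram (PPG) records blood-volume pulses optically; each pulse
peak marks a heartbeat. The pulse-to-pulse (P-P) interval series is the HRV
signal, and its spectral composition indexes autonomic balance: power in the
low-frequency band (LF, 0.04–0.15 Hz) mixes sympathetic and parasympathetic
drive, power in the high-frequency band (HF, 0.15–0.4 Hz) is respiratory
vagal modulation, and LF/HF is the classical sympathovagal index. Alert
driving produces an approximately stationary tachogram; drowsy driving —
especially a driver fighting sleep — produces slow drifts and time-varying
oscillation amplitudes. Stationary spectral indices average over those
dynamics; wavelet-domain statistics keep them. This package implements both
feature families over the identical preprocessing chain so they can be
compared fairly, and classifies windows with an SVM under leave-one-out
validation.

## Preprocessing

**Differencing.** The record is first differenced,
`v(x) = (y(x) − y(x−1))/Δt`. This is deliberately crude: it exactly removes
constant offsets, turns linear baseline drifts into constants, and converts
step artifacts (grip changes on a steering-wheel sensor) into single-sample
spikes that the subsequent smoothing absorbs. Beat timing is preserved
because the steep systolic rise dominates the differential.

**Peak detection.** No detector algorithm is canonical for PPG, so the
package uses a deliberately parameter-light one: moving-average smoothing
(0.1 s) of the differential, local maxima above an adaptive threshold — half
the 75th percentile of the positive smoothed values, computed over 5-s
blocks so the threshold tracks slow amplitude changes — a 0.3 s refractory
period (capping heart rate at 200 bpm, well above anything seen at the
wheel), and refinement of each detection to the nearest raw-signal maximum
within ±0.15 s so reported beat times coincide with waveform peaks. Both the
differential-domain (default) and raw-domain searches are available. On
artifact-free synthetic records the round trip recovers every beat within
one sample at 40 Hz; this is pinned in the test suite.

**Interval validity.** Intervals outside (0.3, 2.0) s, or differing from the
previous valid interval by more than 75%, are dropped before resampling.
Differencing only suppresses waveform-level artifacts; missed or spurious
beats produce interval outliers that a cubic spline would amplify into large
excursions, so they must be filtered at this stage.

**Resampling.** The surviving intervals, each anchored at the time of the
second beat of its pair (the instant the interval becomes observable), are
interpolated by a natural cubic spline and evaluated on a uniform 7 Hz grid
from the first to the last knot — interpolation only, never extrapolation.
7 Hz comfortably oversamples the 0–0.4 Hz band of interest while giving the
8-level dyadic decomposition sensible band edges. Windows (60/120/180 s) are
cut on the resampled grid, non-overlapping by default.

## Spectral features

The PSD is FFT-based: mean removal, Hann taper, one-sided scaling such that
the integral of the density equals the window variance (Parseval; verified
in tests to 5%, the residual being taper-weighting noise). One-minute
windows use a single periodogram — at 60 s there is no room to average —
while windows of two minutes or more use Welch averaging (64-s segments, 50%
overlap) to reduce estimator variance. Band powers integrate the density by
the trapezoid rule over the closed VLF/LF/HF intervals, with interpolation
at the exact band edges. LF/HF is reported as `NA` when HF power is zero —
an undefined ratio, never infinity — and such windows are excluded
downstream.

## Wavelet features

The tachogram window is decomposed to 8 levels with the order-3 Symlet, a
near-symmetric orthogonal wavelet whose moderate support (6 taps) suits
420-sample windows. Detail level *n* spans `(fs/2^(n+1), fs/2^n)` Hz; at
7 Hz, D5 (0.11–0.22 Hz) and D4 (0.22–0.44 Hz) cover HF, D6–D7 cover LF, and
A8 (below ~0.014 Hz) carries the slow trend that distinguishes a drifting,
drowsy tachogram. Per coefficient set (D1..D8, A8) four statistics are
extracted, plus the multiscale slope for the seven adjacent detail pairs —
43 features:

* **Shannon entropy**, unnormalized: `−Σ c² log₂ c²` with `0·log 0 = 0`.
  The unnormalized form is intentional — it scales with level energy and
  reaches magnitudes of order 10⁴ bit on realistic windows, which is what
  makes it sensitive to the energy redistribution drowsiness causes. (A
  probability-normalized entropy would be bounded by log₂ of the
  coefficient count, ≈ 9 bit, and blind to energy.) Note the signed sum:
  coefficients with `c² > 1` contribute negatively, so windows with a large
  slow trend drive entropy_A8 strongly negative. Separability, not sign, is
  what the classifier consumes.
* **Mean, variance, kurtosis** — sample mean, unbiased variance, and
  kurtosis as the standardized fourth moment (non-excess; a Gaussian level
  reads ≈ 3). Degenerate zero-variance levels impute kurtosis 3 and β 0
  with a warning; on real-like data a degenerate level means an upstream
  failure, and the warning is the signal.
* **Multiscale β** — `log₂ var(D_{j+1}) − log₂ var(D_j)`, the local slope of
  log-variance across one dyadic scale step, a spectral-exponent surrogate.
  It is defined behind a single function so an alternative estimator can be
  swapped in; being a log variance ratio it is exactly scale invariant.

Features are computed on the decomposition coefficients themselves, not on
per-band reconstructions.

**Boundary handling.** Two modes are implemented. `symmetric` (default)
half-sample-reflects the signal at each end; it is robust for short windows
but the reflected samples make boundary coefficients slightly redundant, so
level energies need not sum exactly to the input energy. `periodic` is the
critically sampled periodized transform: exactly orthogonal (energy
conserved to machine precision, tested at 1e-6) but requiring the length to
be divisible by 2^level, which a 420-sample window is not. Tests pin the
symmetric mode for feature values and perfect reconstruction (round-trip
error below 1e-8 relative), and the periodic mode for orthogonality. The
approximation band is treated as the residual low band below the D8 edge.

## Feature selection and classification

Each feature is scored by the area under its empirical ROC curve, computed
by the rank-sum identity (ties credited one half) with drowsy as the
positive class everywhere. Areas of 1.0 *and* 0.0 both mean perfect
separation — only the direction differs — so features are ranked by
`|area − 0.5|`, with areas ≥ 0.7 or ≤ 0.3 flagged acceptable. Independent
two-sample t-tests (pooled variance by default, Welch available) accompany
the ranking; no multiple-testing correction is applied by default, matching
the per-feature selection protocol, with Benjamini–Hochberg available as an
option.

The classifier is a soft-margin SVM (linear and RBF kernels) over the grid
`C, γ ∈ {10, 1, 0.1}`. Features are z-scored with statistics learned from
the training fold only — entropy (~10⁴) and LF/HF (~1) differ by four orders
of magnitude, and an unscaled RBF kernel would collapse. Leave-one-out
validation holds each window out of both the standardization and the fit.
The backend solver is libsvm (via e1071); the contract is the dual solution
itself — multipliers in `[0, C]`, `Σ λᵢyᵢ = 0`, checked after every fit —
and the test suite cross-checks decision values against an independent
interior-point QP solution on small instances. A decision value of exactly
zero maps to drowsy: the fail-safe direction for a safety system. Grid cells
are compared by LOO accuracy, ties broken toward the linear kernel, then
smaller C.

## The synthetic-data generator

Real drowsy-driving recordings are scarce and private, so the generator
defines the study conditions under which this package is validated:

* Instantaneous IBI = mean + sinusoids at representative band frequencies
  (VLF 0.02 Hz, LF 0.1 Hz, HF 0.3 Hz) + optional white beat-level jitter;
  beats are placed by forward integration. Defaults: mean IBI 0.85 s
  (~70 bpm), LF and HF amplitudes 0.03 s (LF/HF ≈ 1, a neutral alert
  balance), VLF 0.01 s, jitter 0.01 s for subject simulation — ordinary
  resting-HRV magnitudes.
* The **drowsy regime** is nonstationary by construction: across a session
  the LF modulation amplitude ramps from 0.5× to 1.5× its nominal value and
  the mean IBI drifts up by 0.15 s (heart rate slowing as vagal tone rises).
  The time-averaged LF amplitude equals the alert value, so a stationary
  LF/HF estimate is only weakly informative, while the within- and
  across-window drift is exactly what the A8/D8 statistics capture — the
  contrast the package exists to measure.
* PPG rendering places an asymmetric raised-cosine pulse (0.1 s rise,
  0.25 s decay, peak on the beat time) per beat, plus sinusoidal baseline
  wander and sparse step/ramp motion artifacts — the disturbance classes a
  first-order differential handles. The first beat is placed 0.5 s into the
  record so no pulse is truncated.
* PERCLOS labels are drawn uniformly within the calibrated bands
  (alert [0, 30%), drowsy [30%, 40%]); 30% maps to drowsy (fail-safe) and
  values above 40% are excluded as outside the protocol's range.

What the generator does **not** emulate: realistic pulse morphology
(dicrotic notches), respiration–heart-rate coupling beyond a fixed HF tone,
ectopy, or sensor-specific noise spectra. Artifact severity is a free knob,
not calibrated to any recording. Passing tests therefore demonstrate
algorithmic correctness and the directional wavelet-vs-LF/HF contrast under
controlled nonstationarity — not field performance on real drivers.

## Problem sizes and numerical choices

The validation experiments use 4 simulated subjects × (10 alert + 10 drowsy)
1-min windows, mirroring the 20-sample-per-subject design the LOO protocol
expects, and the directional comparison is repeated over 20 seeds with a
sign test. These sizes keep the full suite comfortably fast while giving the
sign test resolving power. Other fixed choices: natural spline boundary
conditions (configurable to `fmm`); detection threshold floor of 1e-3 of the
global maximum to keep flat blocks silent; interval anchor at the second
beat of each pair; windows cut on the resampled grid for reproducible
lengths.

## Known limitations

* ROC areas and LOO metrics on 20-window subjects are coarse (multiples of
  1/100 and 1/20); small differences between feature sets are not
  interpretable at this scale.
* The LF/HF route on 1-min windows uses a single periodogram; its variance
  is high by construction, which is part of why the standard protocol
  prescribes 2-min windows for LF/HF.
* The entropy's sign convention (signed, unnormalized) means comparisons
  across preprocessing scales are meaningless; features must come from the
  same pipeline configuration — the manifest written by `run_experiment()`
  records that configuration in full.
* No confidence intervals on ROC areas and no probabilistic SVM outputs;
  the pipeline reports point metrics per the validation protocol.
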