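---
title: "wristpa: methods, models and design choices"
author: "wristpa authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{wristpa: methods, models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

Wrist-worn tri-axial accelerometers record acceleration in units of g
(1 g = 9.81 m/s²) continuously over multiple days. Turning those raw
streams into interpretable physical-activity measures for clinical group
comparisons — here, the actigraphy design used to characterise movement
in late-life depression — requires a chain of conventions: the device
must be calibrated to local gravity, resampled to a common rate,
gravity must be removed, non-wear must be found and excluded, days must
be qualified, and per-minute signal characteristics must be aggregated
into each participant's circadian "average day" before any statistics
are run. `wristpa` implements that chain end to end, plus a synthetic
cohort generator with known ground truth so every stage can be
validated by recovery rather than by eye.

## Pre-processing model

**Autocalibration.** A still device measures pure gravity, so
still-window mean accelerations must lie on the unit sphere. We detect
stillness in consecutive non-overlapping 10 s windows whose per-axis
standard deviation is below 13 mg (the same constant as the wear-time
rule, which keeps the pipeline's thresholds coherent), then iterate a
per-axis ordinary least-squares fit of the corrected window means onto
their projections on the unit sphere, to a relative parameter change
below 1e-9 (at most 1000 iterations). The sensor model is
`measured = gain * a + offset` per axis; the fit therefore reports
`gain` and `offset` such that `corrected = (measured - offset) / gain`.
Two guards make the fit trustworthy: a sphere-sampling requirement
(each axis's still means must reach beyond ±300 mg, otherwise the
geometry cannot separate gain from offset) and a residual-error
criterion (mean absolute deviation of corrected still magnitudes from
1 g must fall below 10 mg). A recording that fails either is flagged
`success = FALSE` and is excluded downstream rather than silently
passed through — mirroring how studies drop recordings with calibration
failure.

**Resampling.** Device clocks jitter and rates differ, so each axis is
interpolated onto an exact uniform 50 Hz grid with a cubic
interpolating spline using not-a-knot boundary conditions. We chose a
true interpolating cubic spline (rather than a local scheme such as
Catmull–Rom) because it reproduces polynomial signals up to degree 3
exactly, which gives the resampler a sharp, testable contract; local
tangent schemes only reproduce quadratics. Gaps larger than 1 s are
never interpolated across: grid samples inside them are missing, and
downstream stages propagate that missingness (never zero-fill).

**Gravity removal.** The Euclidean magnitude of the calibrated 50 Hz
signal is band-pass filtered with a zero-phase (forward–backward)
4th-order Butterworth filter, corner frequencies 0.2 and 15 Hz. The
magnitude-then-filter order follows the pipeline's step ordering;
zero-phase application preserves minute alignment. Order 4 is the
conventional actigraphy choice. The first and last 5 s of every
contiguous filtered span are flagged unreliable (filter edge
transients) and excluded from minute features. The filter is applied
with reflection padding and steady-state initial conditions, so a
constant input yields a numerically zero output rather than a startup
transient; on a constant 1 g input the residual is below 10⁻¹¹ mg.

**Changeover merging.** When a participant's recording is split across
two devices (battery swap mid-week), each device is calibrated
separately, corrected, and the two recordings are placed on one clock.
The swap gap (typically under a minute) remains missing samples.
Pairs that overlap, belong to different participants, or are separated
by an hour or more are refused.

## Wear time and day qualification

Each 30-minute segment, aligned to local midnight, is wear-time when
the standard deviation of its available band-passed magnitude strictly
exceeds 13 mg. Midnight alignment makes day accounting exact (48
segments per day; each segment covers exactly 30 feature minutes).
Segments with under half their samples present are classified from what
is available but flagged. A calendar day qualifies when (i) worn
minutes strictly exceed 720 — the literal reading of "more than half
the day" — (ii) the device calibration succeeded, and (iii)
malfunction is ruled out; malfunction is an input flag from file
integrity checking, not inferred from the signal. Partial first/last
days normally fail (i) and are reported with reason `partial_day`.
Compliance is worn time over total time on included days.

## Per-minute features

For each minute with at least 1500 valid samples (half a minute at
50 Hz) inside worn segments:

* **activity** (mg): mean of |m|, the absolute band-passed magnitude.
  The band-passed signal is signed and its plain mean telescopes to
  zero; rectification preserves the interpretation "how much the device
  accelerated".
* **jerk** (mg/s): mean absolute five-sample least-squares slope,
  `d_t = (2 m_{t+2} + m_{t+1} - m_{t-1} - 2 m_{t-2}) / (10 Δt)` with
  Δt = 0.02 s. Sudden ("quick") movements give high jerk; the absolute
  value again prevents telescoping.
* **entropy** (bits): Shannon entropy of the minute's magnitude
  histogram over 64 fixed bins of width 15.625 mg spanning
  [−500, 500) mg, out-of-range values clamped to the edge bins, empty
  bins contributing zero. Fixed global bins make entropy comparable
  across minutes and participants and bound it at 6 bits; the
  discretisation and base are package conventions, since entropy
  estimators for this purpose are not standardised in the actigraphy
  literature. Low entropy: stationary or repetitive movement; high:
  unpredictable, gesture-like movement.

Minutes below the sample threshold are missing rather than estimated —
estimates from fragments at wear boundaries would be high-variance.

The **average day** is the 1440-vector of per-minute-of-day means of
each feature across included days, excluding non-wear; a minute of day
with no contributing days is missing. Window means are unweighted means
over night (00:00–06:00), daytime (06:00–24:00), morning
(06:00–12:00), or the whole day (the quantity used in group tests).

## Statistical layer

Confounds (age, BMI, pre-morbid IQ) are removed from participant-level
summaries by pooled ordinary least squares: the measure is regressed on
an intercept plus confounds across both groups together, and the
residuals plus the grand mean are retained. Pooling preserves the group
contrast while removing confound slopes; residualizing per group would
also remove part of the group effect. One property of this
residualize-then-test procedure deserves emphasis: when the confounds
themselves differ between groups, the confound regression absorbs the
share of the group contrast that is collinear with them, so the
subsequent t test is attenuated relative to a joint
analysis-of-covariance fit. That is inherent to the procedure (which
follows the field's reporting convention), not an implementation
artefact; the simulator's default covariate model draws confounds from
the same distribution in both arms, so its planted effects are not
attenuated this way. Group differences use the
classical pooled-variance two-tailed t test with n₁+n₂−2 degrees of
freedom (not Welch — matching the reporting convention of studies whose
df equal n₁+n₂−2). Partial correlations between activity summaries and
clinical scores residualize both variables on an intercept plus age,
BMI, IQ and sex, correlate the residuals, and compute two-tailed p from
`t = r sqrt((n-k-2)/(1-r²))`; they are computed within group, with
listwise deletion per pair and the effective n reported. No
multiple-testing correction is applied (the correlation analysis is
exploratory by design and flagged as such in the output). Z composites
standardize patient raw scores against the control mean and SD per
test, negate lower-is-better scores (times, latencies, error counts)
so that higher always means better, impute missing raw values with the
group mean, and average tests into five conceptual domains plus a grand
mean.

## What the simulator emulates

Ground truth per participant is the minute-of-day intensity profile
λ(m), in mg of dynamic-acceleration SD:

* a raised-cosine day envelope (night baseline 3 mg, day baseline
  15 mg, rise 06:00–07:30, fall 21:30–23:00);
* Gaussian bumps at 09:00, 15:00 and 20:00 (heights 80, 50, 30 mg;
  widths 80, 75, 60 min) giving morning, afternoon and evening
  activity peaks; the case group's morning bump is scaled by
  1 − δ (default δ = 0.3);
* sporadic movement bursts (probability 0.25 per minute, +60 mg)
  wherever the envelope is below 0.6 — sleep movements and
  evening/morning fidgeting. These matter: they are what keeps
  genuinely worn low-activity segments above the 13 mg wear threshold,
  exactly as restless real wrists do;
* a per-subject log-normal activity scale (σ = 0.06). This is
  deliberately below realistic between-person variability: the
  simulator is a recovery testbed whose planted effects must be
  detectable at small synthetic cohort sizes, not an estimate of any
  real cohort's spread.

The measured signal is `gain ∘ (g(t) + d(t)) + offset + noise` per
axis: `g(t)` a unit gravity vector performing a 0.5°/s random walk on
the sphere while worn (frozen during non-wear) with sporadic posture
jumps (probability 0.03 per minute, 45° SD) that sweep orientation
coverage for calibration; `d(t)` isotropic Gaussian noise with
per-axis SD λ so that the magnitude — which to first order sees only
the component of `d` along gravity — has SD λ; during movement bouts
(λ > 50 mg) a 2 Hz arm-swing sinusoid along a fixed random axis
carries a 15% variance share in expectation over orientations
(amplitude λ√(6w), using E[(u·ĝ)²] = 1/3). Sensor noise (2 mg per
axis) is folded into the Gaussian draw before the gain is applied;
the gain perturbs it by at most ~1%, far below every threshold in the
pipeline. Timestamps carry multiplicative jitter (SD 10⁻⁴) at a native
30 Hz rate. Non-wear bouts (one per day with probability 0.9, mean
150 min, during 08:00–19:00) zero the dynamics and freeze orientation.
Recordings span the configured full days plus short partial first/last
days that the half-day rule later excludes; recordings of four or more
days are split into two device files (independent gain/offset errors)
at a mid-week noon changeover with a 30 s gap, shorter recordings fit
one battery and stay on one device.

Outcome scores (IADL-, SF-36-, PAL-, MADRS-like) are linear in true
daytime intensity and the confounds, with Gaussian noise. The slope on
intensity is solved in closed form per group from the target partial
correlation ρ (defaults +0.60, +0.65, +0.40, −0.37) using the
within-group sample SD of the planted daytime means, so the planted ρ
is carried exactly by construction.

**What passing tests do not show.** The simulator has no biomechanics
(no gait, posture transitions or tremor spectra), no temperature-driven
calibration drift, no device idle-sleep dropout, no sleep staging, and
minute-constant truth within each minute. Recovery on this testbed
therefore validates the pipeline's arithmetic, conventions and
statistical calibration — not the clinical sensitivity of the features
on real wrists.

## Numerical choices and degenerate inputs

Interpolation uses not-a-knot boundary conditions (exact through cubic
polynomials); queries are evaluated with per-interval Horner
coefficients. The zero-phase filter uses odd-reflection padding and
per-unit-input steady-state initial conditions. Wear truth in the
validation study is defined at the segment level (a segment is truly
non-worn only when fully inside a scripted bout) because the
classifier's decision unit is the 30-minute segment and partially
covered segments are not unambiguous targets under any threshold.
A segment whose SD equals the threshold exactly is non-wear (strict
inequality). Rank-deficient confound matrices abort with the collinear
columns named; zero pooled variance and zero control SD are errors, not
NaNs; partial correlations with (numerically) zero residual variance
are flagged degenerate and return NA. Identical configuration and seed
reproduce byte-identical outputs, including written files.

## Validation study sizes

The package's validation suite uses: ten replicate cohorts of 10
participants per arm with two recording days and δ = 0.5 for
effect-detection and localization; a 10-participant cohort for
segment-level wear scoring; one two-day recording with planted offsets
(≤50 mg) and gain errors (≤2%) for calibration recovery; and 200
truth-level replicates at 29 per arm for partial-ρ recovery and null
calibration of the group test. These sizes were chosen so each planted
effect is comfortably inside the pipeline's operating range while the
whole suite stays convenient to run on a laptop; `morning_effect_study()`
and friends accept larger sizes for users who want tighter Monte-Carlo
error.

## Known limitations

Entropy and jerk depend on package conventions (binning, rectification)
that published studies rarely specify; absolute values of those
features are comparable within analyses run by this package, not across
implementations. The autocalibration offset is not temperature
compensated. Wear detection inherits the known weakness of
SD-threshold rules: a perfectly still worn wrist for a full segment is
indistinguishable from non-wear. The statistical layer implements
exploratory, uncorrected inference by design; users requiring
familywise control should adjust the reported p values themselves.
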