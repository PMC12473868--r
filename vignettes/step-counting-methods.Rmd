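---
title: "Step counting in impaired gait: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Step counting in impaired gait: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adlsteps)
```

## The problem

People with neurological conditions (stroke, Parkinson's disease, spinal
cord injury) walk slowly, in short irregular bouts, often asymmetrically and
with shuffling steps — weight transfers without spatial displacement of the
foot. Step counters developed on able-bodied walkers miss much of this
activity, especially during unscripted activities of daily living (ADL)
where steps occur outside structured walking bouts. `adlsteps` implements a
complete development-and-evaluation chain for population-specific step
counting from body-worn triaxial accelerometers (100 Hz, ±8 g), and the
statistics used to compare sensing/analysis configurations and algorithms on
small clinical samples.

A *step* throughout the package is the moment of reloading a foot after a
weight transfer, whether walking or shuffling; the two types are annotated
separately but always counted together.

## The analysis pipeline

The window-based regression approach treats step counting as supervised
learning on short signal segments:

1. **Axis assignment** (`assign_axes()`): the vertical axis is the channel
   with the largest absolute mean acceleration (gravity marks the vertical;
   the sign makes the corrected mean positive), the anteroposterior axis is
   the remaining channel most correlated with it. This happens *before*
   band-pass filtering, which would remove the gravity cue. Assignment uses
   whole-recording means because mounting orientation is fixed per session.
   With zero-variance channels the lowest-index non-vertical channel is the
   deterministic fallback.
2. **Filtering** (`apply_filter()`): three fixed 5th-order Butterworth
   designs applied forward-backward (zero phase): wide (low-pass 15 Hz),
   medium (band-pass 0.2–5 Hz) and narrow (band-pass 0.5–3 Hz). Gait energy
   sits mostly below 5 Hz with the fundamental below 3 Hz; the wide band
   keeps impact transients. Signals are odd-reflection padded by three
   periods of the lowest band edge so filter transients stay out of the
   returned samples.
3. **Windowing** (`make_windows()`): sliding windows of 0.5, 2 or 5 s with
   50% overlap, starting at time zero. Window labels count annotated events
   in the half-open interval [start, end), so boundary events are never
   double-counted by a tiling grid. Windows intersecting an excluded
   interval (e.g. video occlusion in the reference workflow) are dropped
   entirely — partially observed windows would carry corrupted labels.
4. **Features** (`extract_features()`): per axis, time-domain (mean, SD,
   number of peaks, range, RMS, IQR), frequency-domain (spectral energy,
   dominant frequency and its magnitude, spectral entropy) and an
   autocorrelation peak; across axes, the maximum normalized
   cross-correlation within ±1 s and its lag. Peaks are local maxima with
   prominence at least 0.1 × window SD and 0.25 s minimum separation — a
   4 steps/s ceiling above the ~3 Hz gait fundamental. Spectra use a Hann
   taper on the de-meaned window; without the taper, leakage on 0.5–2 s
   windows corrupts dominant-frequency estimates. The registry marks
   features beyond the core literature examples as "extended"; they stand in
   for the fuller feature appendices of published pipelines.
5. **Regression** (`train_and_score()`): five regressor types (GB, kNN, MLP,
   RF, SVR) with fixed library-default hyperparameters, so the comparison is
   about the sensing/analysis configuration rather than tuning. Features are
   standardized with training-fold statistics only. Scores are window-level
   RMSE divided by the window length (steps/s, "RMSE scaled to 1 s") and
   summarized by the median over leave-one-subject-out (LOSO) folds; LOSO
   simulates deployment to unseen patients, which matters because
   inter-subject variability dominates in clinical populations.
6. **Totals** (`aggregate_window_totals()`): per-window predictions are
   clipped at zero and summed with weight 0.5 under 50% overlap (every time
   point is covered twice), plus 0.25 × (first + last window) for the
   single-counted half-windows at the edges. The rule is exact when
   predictions are locally constant; no published aggregation convention
   exists for overlapped windows, so the unbiased choice was adopted.

## The configuration GLM

`run_config_grid()` scores every (location, filter band, window length,
regressor) cell; `fit_config_glm()` models the scores with a gamma GLM and
log link — the natural family for positive, right-skewed RMSE outcomes — with
main effects only (a 210-cell grid cannot support interactions).
Exponentiated coefficients are multiplicative RMSE changes against the
reference configuration (waist, wide band, medium window, GB). Short-window
(0.5 s) scores must be excluded before fitting: their RMSE distribution is
bimodal and much larger, grossly violating the gamma assumption; the
function refuses them.

Inference uses Wald intervals with a deviance-based dispersion estimate.
Model fit is checked by mapping each observation through its fitted gamma
CDF to a quantile residual and testing against the standard normal with a
Kolmogorov–Smirnov test (`residual_fit_test()`); quantile residuals are the
defensible residual type for gamma GLMs. Because the mean structure and
dispersion are estimated from the same data, the check is conservative —
under the true model the p-values concentrate above 0.5 rather than being
exactly uniform — which the test suite asserts as such.

`importance_report()` expresses each parameter's influence as the predicted
RMSE of its worst level relative to its best (reference included at effect
1.0). `select_optimal_config()` retains the reference level unless another
level is significantly better (p < 0.05 *and* effect size < 1), mirroring a
pre-registered retention rule: a nominally better but non-significant level
(e.g. RF vs GB) does not displace the reference.

```{r glm-example}
ex <- example_config_effects()
importance_report(ex)
select_optimal_config(ex)
```

## Baseline counters

Two transparent able-bodied baselines are implemented in full:

* **TCA** (`tca_count()`): upward crossings of a 0.3 m/s² threshold by the
  gravity-referenced vector magnitude (|a| − g), with a 0.25 s refractory
  period. The gravity reference is a declared interpretation: a 0.3 m/s²
  threshold on the raw magnitude (~9.81 m/s² at rest) would fire
  continuously. Greedy earliest-first suppression makes the count monotone
  non-increasing in the threshold.
* **CWT** (`cwt_count()`): an analytic Morlet transform (ω₀ = 6) of the
  vertical channel over 12 scales spanning 0.5–3 Hz, normalized so a unit
  sinusoid at a scale's centre frequency gives unit coefficient magnitude.
  Each non-overlapping 5 s segment selects its dominant scale (the
  adaptation to walking speed); prominent peaks of the coefficient series at
  that scale are steps. The absolute prominence floor (0.15 m/s²) keeps the
  counter silent on the noise floor. The transform is implemented in the
  Fourier domain inside the package.

Pre-trained external counters (SKDH for the lower back, OxWearables for the
wrist) are represented by an adapter contract: they appear in the algorithm
registry, and calling them without registering an implementation raises an
explicit "external counter not installed" error — they are never silently
substituted.

## The synthetic cohort generator

The study conditions the package targets are not distributable as raw data,
so `simulate_session()` generates annotated recordings with the statistical
structure the analysis assumes: gravity on the location-specific vertical
axis; a cadence-locked base oscillation during bouts plus a damped-sinusoid
heel-strike transient per step (an 8 Hz carrier puts part of the impact
energy above 5 Hz while the base stays below 3 Hz); shuffling steps at 40%
vertical amplitude with no anteroposterior signature; smooth 1–5 s non-step
movement bursts (tripled at the wrists); white noise; and ±8 g clipping.
Step impulse amplitudes attenuate from ankle (gain 1.0) and waist (0.85)
down to the wrists (~0.3), which also carry the most artifact energy — the
plausibility ordering for signal strength versus distance from the feet. No
per-location statistics were available to calibrate against, so these gains
are design choices, stated once and not revisited.

`default_cohort_profiles()` builds seven heterogeneous subjects whose
bout/rest structure targets a cohort-mean overall rate of 0.37 steps/s
(within-bout cadences 0.8–1.4 steps/s, overall rates 0.22–0.52 steps/s,
shuffle fractions 5–25%, asymmetry 0.55–0.95), so a 35-minute session
accumulates ~775 steps on average with wide between-subject spread. All
randomness flows from one master seed through per-subject and per-location
streams, so a cohort is reproducible regardless of generation order or the
location subset requested.

What the generator does *not* emulate: biomechanically realistic waveforms,
walking aids, turning, stairs, sensor detachment, or the specific
misdetection patterns of real impaired gait. One practical consequence: on
these clean, strong impulse trains the TCA and CWT baselines tend to
*over*count (each heel-strike transient can cross the threshold more than
once), whereas on real impaired-gait data all algorithms undercount. Tests
and acceptance checks therefore assert the *ordering* — the trained
configuration beats both baselines — and the package's arithmetic identities,
not the clinical error magnitudes, which are not reproducible without the
original recordings.

## Numerical and degenerate-input choices

* Window event counting is half-open; exclusion intersections are open-ended
  (`start < excluded_end` and `end > excluded_start`).
* Constant windows yield SD 0, zero peaks, zero DC-excluded spectral energy,
  and flagged (0) correlation features; NaN inputs are errors, never imputed.
* Zero-variance channels in axis assignment fall back to the lowest-index
  non-vertical channel.
* A saturated or exactly-constant GLM fit reports point estimates with NA
  p-values rather than NaN inference, and the residual fit test refuses
  zero-deviance fits.
* Gamma simulation uses dispersion = 1/shape so the simulated mean equals
  the model mean exactly.
* `wilcoxon_min_p(n) = 2 × 0.5^n` (capped at 1), the exact two-sided
  sign-rank floor when all differences share a sign; at n = 7 this is
  0.0156, which cannot survive multiplicity correction — the reason the
  package reports the Friedman test without post hoc pairwise tests.

## Problem sizes used in the tests and acceptance script

The unit and property tests run on seconds-to-minutes of synthetic signal;
the acceptance checks use a 7-subject cohort (6-minute sessions in the test
suite, 35-minute sessions in `scripts/acceptance.R`, both at 100 Hz, waist
location), 200 and 100 replicate GLM calibration grids of 36 cells, and the
worked effect-size table for the exact reporting arithmetic. These sizes
were chosen so the whole chain demonstrates its properties at full fidelity
— sampling rate, window geometry and cohort size are never scaled down, only
session length and the grid extent are.

## Known limitations

* Grid scoring with all 315 configurations on full-length cohorts is
  computationally heavy in plain R; reduced grids (fewer locations/filters)
  demonstrate the machinery, and the GLM arithmetic is validated against
  simulated grids with known coefficients instead.
* The GLM reports per-level Wald p-values without multiple-testing
  correction, matching the flat 0.05 convention it reproduces.
* MAPE is summarized by median and IQR despite its name; the mean is also
  returned.
* The affine video-to-sensor time map assumes linear clock drift between the
  two anchors.
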