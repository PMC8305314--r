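---
title: "From phone accelerometer traces to approach–avoidance measures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From phone accelerometer traces to approach–avoidance measures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maatkit)
```

## The task and the raw signal

In the mobile Approach–Avoidance Task (mAAT) a participant holds their phone,
sees an image, and either pulls the phone toward their face or pushes it away
as instructed. The phone records timestamped 3-axis acceleration (and, on
some devices, rotational rate) throughout each trial. A trial starts with the
phone at rest, shows a fixation cross, then the stimulus; the participant has
2 s to respond and then immediately returns the phone to the starting
position. Everything `maatkit` computes — reaction time, movement distance,
movement direction — must be recovered from that raw trace.

Two behavioural measures are extracted per trial:

* **mAAT RT** — time from stimulus onset to the onset of phone motion, where
  motion onset is the first acceleration-magnitude sample strictly above
  `max(0.8, 0.3 · a_max)` m/s², with `a_max` the maximum magnitude inside
  that trial's 2 s response window. The 0.8 m/s² floor keeps tremor and
  sensor noise from triggering onsets; the 30% fraction adapts the threshold
  to the vigour of the movement. `a_max` is computed per trial, not per
  block: the trial is the behavioural unit and the threshold should adapt to
  the current response.
* **mAAT distance** — how far the phone moved during the outward stroke,
  obtained by double integration of the movement-axis acceleration
  (details below). It is a movement-vigour measure intended to track
  stimulus arousal, complementing the RT, which tracks approach–avoidance
  motivation.

Trials with RT < 200 ms are discarded as anticipations (`too_fast`, the
whole trial including its distance); RT > 2000 ms or no threshold crossing
is a no-reaction; participants with less than 75% valid trials are excluded
(exactly 75% is included, because the exclusion rule is "less than 75%").

## Signal preparation

Phone accelerometers sample irregularly and, unless the device exposes a
linear accelerometer, include gravity. The preparation chain is:

1. **Rest baseline** — per-axis mean over the 0.3 s before stimulus onset.
   The trial design guarantees the phone is at rest there, so the baseline
   is the gravity vector in the device frame (norm ≈ 9.81 m/s²), or ≈ 0 for
   linear accelerometers.
2. **Gravity removal** — subtract the constant baseline. Gravity is treated
   as constant per trial rather than orientation-tracked: strokes last well
   under a second, the magnitude-based onset rule is rotation-robust, and
   full sensor fusion would add model risk without serving any downstream
   quantity. Gyroscope channels are carried through but unused.
3. **Uniform resampling** — linear interpolation onto a grid at
   `resample_rate_hz` (default 100 Hz, the typical phone rate). Linear
   rather than spline interpolation: no overshoot at the sharp movement
   onset. A sub-step remainder at the trace tail is dropped so the grid is
   exactly uniform for the integrators.
4. **Low-pass filtering** — zero-phase Butterworth (applied forward and
   backward, 4th-order response) at `lowpass_hz` (default 20 Hz,
   configurable off). Zero-phase matters: a causal filter would shift the
   onset and bias every RT. 20 Hz is far above the ≈ 3–10 Hz content of a
   sub-second reaching stroke and far below the noise floor it suppresses.

Whether the original processing chain filters before thresholding is not
documented anywhere we know of; the default here is this package's own
choice and `lowpass_hz = NULL` switches it off for comparisons.

## Distance by double integration

The distance definition in circulation for the mAAT — "derived from the
magnitude and the duration of the acceleration" — does not pin down a
formula. This package therefore *declares* its interpretation:

* velocity = cumulative trapezoidal integral of the z-axis (movement-axis)
  acceleration from the detected onset, with v(onset) = 0 (the phone is at
  rest between trials);
* the **outward segment** ends at the first zero crossing of that velocity
  after its peak, capped at 1 s after onset;
* distance = |cumulative integral of velocity| at the segment end.

The return stroke must be excluded: participants return the phone
immediately, so integrating the whole trial would cancel the displacement to
≈ 0 by design. Restricting integration to the sub-second outward stroke also
keeps accelerometer drift second-order, which is why no further drift
correction is applied. The outward direction is taken from the first
substantial velocity excursion (first crossing of 25% of the peak speed)
rather than the global speed maximum, which can sit on the return stroke.
Movement direction is classified from the sign of the net z displacement
(+z points out of the screen toward the face, so positive = pull); |net
displacement| ≤ 1 cm is `undetermined`.

Numerical behaviour: trapezoidal double integration converges as O(Δt²); the
test suite verifies the error against closed-form constant-acceleration and
minimum-jerk displacements at 100 Hz (< 1%) and confirms the error ratio ≈ 4
when the step halves.

## The statistical layer

Valid trials are averaged into participant × category × direction cells, the
unit of analysis. On cells the package computes:

* **RT score** = push − pull (per participant and category; positive =
  approach motivation) and **distance score** = mean(pull, push);
* **2×2 within-subject ANOVAs** (category pair × direction) on mean RT and
  mean distance. With 2-level factors sphericity is trivial and each effect
  is tested against its own effect-by-subject interaction with df (1, n−1).
  Sums of squares are computed directly from the cell-mean decomposition;
  the interaction F is algebraically the squared paired t on each
  participant's difference of differences, and the tests verify both that
  identity and agreement with `aov()` error strata. Participants with
  incomplete cells are dropped listwise (classical RM-ANOVA needs complete
  cells) with a message. F, df, p and partial eta squared are reported for
  auditability even where only p-values are conventionally quoted.
* **Wilcoxon signed-rank tests** for paired rating comparisons: zero
  differences dropped, mid-ranks for ties, W = min(W+, W−), exact null
  distribution (shift-algorithm convolution) for n ≤ 15 and the normal
  approximation with continuity correction and tie-corrected variance
  above. Exact-vs-approximate and tie handling are declared choices — the
  field's software defaults vary and published reports rarely say which was
  used.
* **Pearson correlations** (via `stats::cor.test`) of RT scores with rated
  valence/wanting per category and of food-neophobia scores with
  Asian-food responses, reporting r, R² and the t-based two-sided p.

All tests are two-sided at α = 0.05 with no multiplicity correction,
matching standard practice for this design. Trials whose observed direction
contradicts the instruction remain valid but are flagged
(`direction_match`): no published exclusion rule exists for them, so the
package flags rather than invents one.

## The simulator and what passing tests mean

`simulate_trace()` emulates one recorded trial: rest with gravity and
Gaussian sensor noise, a minimum-jerk outward stroke along z after a planted
latency, an optional mirrored return stroke, sampling-timestamp jitter. The
minimum-jerk model `x(τ) = D(10τ³ − 15τ⁴ + 6τ⁵)` is the standard description
of point-to-point human reaching and has closed-form derivatives, so every
planted trace comes with exact ground truth (peak |a| = (10/√3)·D/T²).

`simulate_experiment()` plants a whole study: 4 stimulus categories × 2
directions × 20 trials per cell (10 images per category per half, each shown
twice per direction) — 160 experimental trials per participant. Trial RT =
base (650 ms) ± half the congruency effect (30 ms default, congruent =
pull-palatable/dutch, push-unpalatable/asian) + Gaussian noise (sd 100 ms,
truncated at 50 ms); the symmetric ± split keeps direction marginals equal
so main effects and the interaction are separately testable. Stroke
amplitude scales with planted category arousal (unpalatable > dutch > asian
> palatable ordering on the planted rating profile), and emitted ratings
follow the expected valence/wanting/arousal orderings with a planted
negative neophobia–Asian-valence relation. Defaults for what no one
publishes (stroke amplitude ≈ 0.25 m, duration 0.3 s — a brisk, flick-like
stroke; noise sd 0.05 m/s²; 1 ms timestamp jitter) were fixed once as
realistic values for a hand-held phone movement.

With `traces = FALSE` the planted per-trial metrics are returned directly
(the planted-metrics fast path). Power and calibration studies use this
path: they exercise aggregation and inference, for which trace synthesis
adds runtime but no information.

The simulator is also a statement of what the tests do *not* show: it plants
compliant participants (no wrong-direction movements), stationary gravity,
white noise and a single stroke shape. Real phone data contain orientation
drift, coloured noise, hesitations and double strokes; passing recovery
tests on simulated data validates the algorithmic chain, not robustness to
every field artefact.

## Known limitations and numerical choices

* **Detection lag.** On a smooth acceleration ramp the threshold is crossed
  ~0.032·T after true movement onset (≈ 10 ms for a 0.3 s stroke), and
  first-sample-above discretisation adds up to one sample. Detected RTs are
  therefore biased late by ~10–20 ms at 100 Hz. This is inherent to the
  published threshold rule, affects all trials alike, and cancels in the
  push-minus-pull score.
* **Distance underestimation.** Because v = 0 is imposed at the *detected*
  (late) onset, the velocity already accumulated during the lag is lost,
  giving a systematic ≈ 5–10% underestimate of the planted displacement
  end-to-end (the integrator alone is < 1% off given the true onset).
  Condition *contrasts* are preserved since the bias is common to all
  conditions.
* **Ties and edge cases.** Onset tie-breaks are first-sample-strictly-above
  (deterministic); degenerate ANOVA inputs (all cells equal) return F = 0,
  p = 1; all-zero Wilcoxon differences are flagged degenerate; zero-variance
  correlations error.
* **Problem sizes.** The checks behind the recovery claims use 500 simulated
  trials for RT recovery, 200 replicate experiments (n = 40) for interaction
  power and 500 for null calibration, sizes at which the binomial
  uncertainty of the reported rates is ~1–3 percentage points.

## Session info

```{r}
sessionInfo()
```
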