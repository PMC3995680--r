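---
title: "Gravity-removal activity classification and METs calibration: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gravity-removal activity classification and METs calibration: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grpaca)
```

## The measurement model

A waist-worn triaxial accelerometer samples acceleration at 32 Hz on three
axes (vertical x, anteroposterior y, mediolateral z), in milli-g
(1 G = 1000 mg), within ±6000 mg at 3 mg resolution. The signal is a
superposition of three components:

1. **gravity**, a 1000 mg vector whose direction in the device frame encodes
   trunk posture;
2. **dynamic movement**, gait and limb motion, concentrated above ~1.5 Hz;
3. **sensor noise**.

During locomotion the posture term is nearly constant; during lifestyle
activities it drifts at well below 1 Hz as the trunk tilts. This frequency
separation is the core assumption of the method: a high-pass filter at
0.7 Hz removes gravity and posture change but passes gait essentially
untouched.

## Epoch features

Each 10-s epoch (320 samples; half-open intervals from sample 0, trailing
partial epoch discarded) is summarized by the epoch mean of the per-sample
vector magnitude in mg, computed two ways:

- **FSA** on the signal after a second-order Butterworth high-pass at
  0.7 Hz applied per axis — movement only;
- **USA** on the unfiltered signal after per-axis, per-epoch mean
  subtraction — movement *plus* within-epoch posture change (static gravity
  cancels in the mean, slow reorientation does not).

The summary statistic is deliberately the *mean* of the per-sample vector
norms rather than their sum: back-solving the packaged locomotive equation
at jogging intensity (≈6.4 METs) gives SA ≈ 1100 mg, the scale of a mean,
not of a 320-sample sum. A `sa_stat = "sum"` option exists in
`epoching_spec()` for sensitivity analysis. Likewise the USA definition —
mean subtraction, vector-norm-first — is the one under which movement-free
epochs give SA near 0 and the packaged intercepts (≈1.2 METs) make sense; a
`raw_with_gravity` mode is available but with full gravity retained every
epoch's ratio would dwarf the classification cut-offs.

## Classification

For an epoch with FSA at or above the movement floor (3 mg, the device
resolution), the USA/FSA ratio decides the class: ratio ≥ threshold ⇒
nonlocomotive, otherwise locomotive. Epochs under the floor are
movement-free (sedentary) and classified nonlocomotive with an undefined
ratio. Bouts are decided by majority vote over their epochs.

Tie-breaks are fixed once and documented:

- ratio exactly at the threshold ⇒ nonlocomotive, reserving the locomotive
  branch (steeper response, lower intercept) for unambiguous gait;
- an exact epoch-vote tie ⇒ nonlocomotive, for the same reason;
- in the threshold sweep, ties in total rate break toward the smallest
  threshold.

The packaged cut-off is 1.12 for children and 1.16 for the adult preset.
`optimize_threshold()` re-derives a cut-off from labeled bouts by evaluating
the discrimination table over a grid (default 1.00–1.50 by 0.01) and
maximizing the *unweighted mean of per-activity rates* — the semantics of a
"total discrimination" row, which weights rare and common tasks equally —
rather than pooled accuracy (available via `unit = "epoch"`). Note a
consequence of the smallest-maximizer tie-break: when the two ratio
distributions are separated by a gap, the selected threshold sits at the
bottom of the 100% plateau, just above the locomotive distribution.

## Filtering numerics

The filter is designed with `signal::butter` (order 2, 0.7/16 normalized
cut-off, high-pass). Application is a causal single pass per axis — the
device filters in real time — with the internal state initialized to the
steady-state response to the first sample: for a high-pass filter the
steady-state output under constant input is zero, so direct-form
initialization with past inputs equal to the first sample and past outputs
zero removes the startup transient exactly. A zero-phase forward–backward
mode (`mode = "zero_phase"`) is provided for offline analysis.

One discrete-sampling caveat is worth recording: at 4 Hz and 32 Hz there are
only 8 samples per cycle, so the epoch mean of a rectified sinusoid depends
on where the sample grid sits relative to the nodes (it ranges about ±3–5%
around the continuous value 2A/π). The closed-form feature checks in the
test suite therefore use the zero-phase mode and a node-avoiding phase; the
causal mode's phase lag would otherwise re-align the grid unfavorably. This
is a property of coarse sampling, not of the filter.

## Energetics and the METs definition

Reference energy expenditure is the abbreviated Weir equation,
EE (kcal/min) = 3.941·VO2 + 1.106·VCO2 with gases in L/min. METs are
defined as activity EE divided by the subject's *measured seated* resting
EE — not the 3.5 mL O2/kg/min convention, which is provided separately
(`mets_conventional()`) and is never the default. The respiratory quotient
is sanity-checked into (0.6, 1.3) with a warning, not an error.

## Branch models and fitting

Each branch is linear in FSA, optionally with weight, age and sex
(0 = boy, 1 = girl) covariates. The SA entering both prediction and fitting
is FSA: the gravity-removed feature is the one whose zero corresponds to a
movement-free epoch, which is what the ≈1.2 METs intercepts describe.
Fitting is ordinary least squares (`stats::lm`) with an *explicit* covariate
set — stepwise selection is deliberately not implemented, since it is a
routine procedure and irreproducible without the original data. Reported
R² is adjusted when covariates are present; RMSE is the residual standard
error with denominator n − p − 1. The fitting default is one row per
subject × activity (bout-mean FSA), with epoch-level rows as an option.
Predictions are floored at 0.1 METs with a flag rather than returning
non-physical extrapolations.

The stratified development/cross-validation split allocates a rounded
fraction within each sex × age-band stratum (bands 6–9 and 10–12 years);
with the study's strata (boys 15 + 27, girls 14 + 12) and fraction 48/68 it
reproduces a 48/20 allocation deterministically for any seed.

## The synthetic generator

No raw device or participant data are available, so every stage is exercised
on synthetic data whose statistical structure matches what the method
assumes:

- **waveforms**: gravity of fixed 1000 mg magnitude, rotating in the x–z
  plane as a sinusoidal tilt (frequency below 0.7 Hz, peak-to-peak range per
  task); a dynamic component with a fundamental plus one half-amplitude
  harmonic on the vertical axis and 30% side components (locomotive
  fundamentals ≥ 1.5 Hz; nonlocomotive movement frequency drawn from
  1.2–2.8 Hz per bout); white Gaussian noise; optional 3 mg quantization;
- **cohort**: 68 children in the study's four strata; weight and height
  linear in age with sex-specific offsets, seated RMR ≈ 0.022 kcal/min per
  kg; per-bout intensity jitter (±15% on amplitude and tilt); measured METs
  drawn as the planted branch response to the bout-mean FSA plus
  Normal(0, 0.65) noise (0.65 METs being the scale of the published
  residual error); VO2/VCO2 back-computed through Weir with RQ uniform in
  (0.80, 0.95), so calorimetry inverts exactly to the generating METs.

Default bout length is 60 s (six epochs) — long enough for stable bout
statistics while keeping a full 68-subject, 748-bout cohort cheap to
generate (a few seconds); the steady-state durations in a live protocol
would be 2–3 minutes.

Task geometry was calibrated once, at design time, to the regime the method
targets: strong dynamic amplitude and near-zero tilt for gait tasks (ratios
near 1), large slow tilt for lifestyle tasks (ratios well above 1.2), with
the two deliberately hardest tasks nearest the boundary — stair descent
(moderate gait, 20° sway, bout ratios centred ≈ 1.08 with a small tail
crossing 1.12) and ball throwing (weakest tilt among lifestyle tasks,
ratios ≥ ≈ 1.18). The designed separatrix between the class ratio
distributions is ≈ 1.15, so a data-driven sweep on a default cohort selects
a cut-off within a few hundredths of it, and discrimination at the 1.12
cut-off lands just under 100% with the stair and throwing tasks providing
the rare errors. Giving the gait tasks modest postural sway (5–20°
peak-to-peak) was a deliberate choice over perfectly rigid gait: it is both
more physical and the only way a grid sweep with a smallest-maximizer
tie-break can land near the designed separatrix rather than collapsing to
the bottom of the grid.

What the generator does **not** emulate: biomechanically realistic gait
(impact transients, asymmetry, harmonics beyond the second), colored device
noise, wear-time artifacts, non-steady-state metabolism, and the
between-task heteroscedasticity of real METs residuals (the generator's
residual SD is constant across tasks). Passing the recovery tests therefore
shows the *machinery* is correct under the stated statistical structure,
not that the packaged equations generalize to any particular free-living
population.

## Reproducibility

All randomness flows from explicit seeds: `simulate_signal()` and the split
accept one directly, and `simulate_cohort()` drives everything from a single
spec-level seed through one sequential RNG stream (saving and restoring the
caller's RNG state). Rerunning any command on the same inputs and seed
produces byte-identical outputs.

## Known limitations

- The on-device USA computation is not publicly specified; per-axis epoch
  mean subtraction is this package's documented realization, with
  alternatives behind flags.
- Per-bout scoring of discrimination tables is the default; whether
  published per-activity rates were bout- or epoch-scored is not knowable,
  so both are implemented.
- Percentage-difference SDs in agreement tables are per-subject quantities
  and cannot be reconstructed from group means; on real group-level
  summaries only the mean-difference arithmetic is checkable.
- Significance testing (paired tests, ANOVA) is intentionally out of scope;
  the agreement tables are descriptive.
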