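---
title: "Models and measurement pipelines in chemosignal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and measurement pipelines in chemosignal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemosignal)
```

`chemosignal` implements the three quantitative readouts used to study
repellent (negative) chemotaxis of *Escherichia coli* toward oxidizing
environments: flagellar-motor rotation statistics from the bead assay,
CheA kinase activity from three-cube E-FRET imaging, and the vertical
distribution of cells inside swarm colonies from defocused diffraction
rings. Because such experiments rarely deposit raw recordings, every
pipeline ships with a seeded forward model producing ground-truthed
synthetic inputs, so each estimator can be validated end to end.

## Motor rotation: the bead assay

A polystyrene bead attached to a sheared flagellar stub orbits with the
motor. The motor alternates between counterclockwise (CCW, the default
"run" state) and clockwise (CW, "tumble"); the direction of rotation
reports on CheA activity.

### Forward model

`switching_model()` is the minimal two-state continuous-time Markov
process: exponential dwell times with rates $a$ (CCW$\to$CW) and $b$
(CW$\to$CCW). Its stationary properties are

$$\mathrm{CW\ bias} = \frac{a}{a+b}, \qquad
  \mathrm{reversal\ rate} = \frac{2ab}{a+b}.$$

The published observables of each condition (reversal rates of about 39
per minute at baseline and about 65 per minute under a saturating
oxidant; a roughly one-minute adaptation; a biphasic aminoglycoside
response with a repellent phase starting about six minutes after
addition) are mapped to $(a, b)$ by inverting these two relations —
`rates_from_statistics()`. Reversal rates are typically reported without
accompanying CW-bias values, so the presets fix the bias at
field-plausible levels: 0.15 at baseline ("predominantly CCW"), 0.35 in
the repellent phase, 0.08 in the attractant phase. Stimuli are windowed
rate overrides; within a window the rates relax back toward baseline with
a single-exponential adaptation constant (default 60 s). The true
kinetics linking stimulus to switching rates are not known; this shape is
a documented placeholder, and the sampler stays exact under it by
thinning against the per-state rate envelope.

`simulate_motor_trace()` discretizes the exact jump path at the frame
rate, integrates the bead angle at $\pm 2\pi\,\text{speed}$ rad/s by
state, and adds isotropic Gaussian localization noise (default 0.02 µm on
a 0.25 µm orbit). Pauses can be inserted at switches with a fixed dwell
(off by default). The exact path travels with the output, so the
ground-truth reversal count ("jump-chain oracle") is always available.

### Estimators

* `estimate_rotation()`: orbit center by a 1-s running centroid, angle by
  `atan2` with unwrapping, angular velocity by central difference. The
  assay's sign convention is applied last: CW positive, CCW negative.
  Screen-coordinate data (y axis down) flip chirality via `image_y_down`.
* `classify_direction()`: threshold at `pause_threshold_hz` (default
  2 Hz) into CW/CCW/PAUSE, then a debounce that merges runs shorter than
  `min_dwell_s` (default 10 ms) into the flanking state. The debounce is
  what keeps localization noise from manufacturing reversals; its cost is
  that direction dwells shorter than roughly one debounce window are
  invisible, a bias of a few tenths of a percent of events at the preset
  rates.
* `compute_cw_bias()` is the CW fraction of direction-labelled frames
  (pauses excluded from numerator and denominator);
  `smooth_cw_bias()` applies the standard 30-s running average, centered
  (the convention when none is stated), with truncated windows at the
  edges.
* `count_reversals()` counts debounced CW/CCW transitions; transitions
  bridged by a pause count once, a pause-and-return counts zero. Rates
  are reported per minute. Note that in this assay literature "rpm" means
  reversals, not revolutions, per minute; the package always says
  `reversals_per_min`.
* `compare_pre_post()` is the classical equal-variance Student's t-test
  across motors (Welch via `var_equal = FALSE`), reporting means ± SEM.

Working at 1,000 frames/s, the camera rate of the real assay, is
supported but unnecessary for simulated data: the tests and examples run
at 250 frames/s with a 25 Hz orbit (ten samples per revolution), where
reversal counts are invariant to further subsampling down to 100 frames/s
on clean traces. The packaged validation uses 200 motors of 10 minutes
each, recovering the oracle's reversal count and the stationary CW bias
within three standard errors, with rate doubling reproduced and bias
invariant.

## Kinase activity: three-cube E-FRET

FRET between CheZ-mYFP and CheY-mRFP reports on CheY-P levels and hence
CheA activity; higher kinase activity gives more FRET (the default
`direction = "high_fret_on"`, configurable). Three channels are
measured: donor-excited donor emission (IDD), donor-excited acceptor
emission (IDA), and acceptor-excited acceptor emission (IAA). The
apparent efficiency is

$$E_{app} = \frac{I_{DA} - a I_{AA} - d I_{DD}}
                 {I_{DA} - a I_{AA} + (G - d) I_{DD}},$$

with bleed-through constants $a$, $d$ and gauge factor $G$.

### Forward model

`simulate_fret_experiment()` builds $E(t) = E_{min} + (E_{max} -
E_{min})\,\mathrm{activity}(t)$ from a step/adapt/undershoot activity
trajectory (`kinase_step_model()`: jump to a peak on addition,
exponential adaptation back to baseline, undershoot on removal,
saturating windows pinned at 0 or 1), applies per-fluorophore
bi-exponential bleaching, and composes the channels so that the E-FRET
equation applied to noiseless channels returns $E(t)$ exactly — the
pipeline's algebraic round trip is an identity, which the tests verify at
$10^{-12}$. Multiplicative Gaussian noise (default 1 %) is applied last.
No published values exist for $a$, $d$, $G$, the channel amplitudes, or
the saturating stimuli; the defaults ($a = 0.08$, $d = 0.12$, $G = 1.8$,
1000 counts, 50-ms frames) are documented placeholders in the plausible
range for YFP/RFP-class three-cube setups.

### Analysis

* `fit_bleach_correction()` fits $I_0(A e^{-t/\tau_1} + (1-A)
  e^{-t/\tau_2})$ by bounded Levenberg–Marquardt and divides the raw
  trace by the normalized decay. Frames inside stimulus-response and
  saturating windows are excluded from the fit (the decay should be
  estimated from signal-stationary stretches), but the correction applies
  everywhere. Flat channels short-circuit to an identity correction;
  non-convergence raises an error with residual diagnostics rather than
  returning a silent misfit. Fits are reliable when the two time
  constants are well separated (the packaged check uses 50 s / 500 s,
  recovered within 1 %); nearly equal constants are intrinsically
  ill-posed and surface as large parameter uncertainty, though the fitted
  decay curve — all the correction uses — remains stable.
* `correct_fret_channels()` corrects IDD and IAA by their own decays.
  IDA mixes donor-derived sensitized emission with both bleed-through
  terms, so when constants are available its donor-derived component
  $(I_{DA} - aI_{AA} - dI_{DD})$ is corrected by the donor decay and the
  bleed-through terms are rebuilt from the corrected channels; this keeps
  the zero-noise pipeline exact even when donor and acceptor bleach
  differently.
* `compute_efret()` masks frames whose denominator magnitude falls below
  $10^{-6}$ of the median IDD as `NA` instead of clipping, so weak
  signal cannot fabricate efficiencies.
* `normalize_activity()` rescales each cell between the mean $E_{app}$ of
  its saturating kinase-OFF and kinase-ON windows (per-cell, never
  population-level), clipping to [0, 1].
* `estimate_adaptation_time()` takes the baseline mean and SD before the
  stimulus and reports the first time after the post-stimulus extremum at
  which a 1-s running mean of activity re-enters baseline ± 2 SD and
  stays for 5 s. The smoothing is needed because a raw 20 Hz series under
  independent noise essentially never stays inside a ±2 SD band for
  hundreds of consecutive frames; applied to an exponential decay of time
  constant $\tau$ at the default noise, the criterion crosses between
  about $2\tau$ and $5\tau$, which the tests assert.

The packaged validation runs 50 cells at default noise through
bleach-correction, E-FRET, and normalization, recovering the ground-truth
activity with mean RMSE well under 0.05.

## Vertical distribution in swarms: defocused ring tracking

Viewed from above, a fluorescent cell above the focal plane shows an
out-of-focus diffraction ring whose diameter grows with height; over a
~150 µm colony this yields a ~0.5 µm height resolution. The exact optics
of the published calibration are not reproduced here; monotonicity is the
only property asserted, and the package models the map as strictly linear
(`ring_calibration()`, default 6 px in-focus diameter, 0.5 px/µm slope),
always supplied as data rather than hard-coded.

`render_ring_image()` draws a radially symmetric Gaussian annulus
(default 96 px frame, 1.5 px profile width, amplitude 255 counts,
background SD 8 counts — a realistic defocused-epifluorescence regime)
with optional sub-pixel center offset. `estimate_ring_diameter()` refines
the center by intensity centroid, bins pixels into 0.25 px annuli with
linear interpolation, and reads the radius off the profile peak with
quadratic sub-bin interpolation; the quality score is peak prominence
over border-noise SD, and in-focus cells are flagged as spots.
`diameter_to_z()` inverts the calibration, clamping out-of-range values
with a flag so census totals are conserved. On noiseless renders the
estimator is accurate to better than half a pixel; on images at the
default noise the recovered-height RMSE is about 0.2 µm
(`scripts/acceptance.R` recomputes this over 2,500 images).

`summarize_colony()` reports per-condition height statistics and the
bottom-layer occupancy (default: fraction within 20 µm of the agar), and
compares each condition to the control with a paired Student's t-test on
replicate-plate mean heights — the replicate plate, not the cell, is the
pairing unit, the conservative choice when the pairing unit is not
stated. `preset_colony_z()` supplies the two study phenotypes: wild type
avoiding the surface on sublethal aminoglycoside (truncated normal
centered at two-thirds of the colony height, SD one-sixth of it) and the
receptor-deletion mutant spread uniformly.

## What the synthetic data does and does not emulate

The generators reproduce the *statistical* structure the estimators rely
on: exponential switching with stimulus-dependent rates, multiplicative
channel noise over bi-exponential bleaching with cross-talk, and a
monotone diameter–height map with Gaussian diameter noise. They do not
emulate bead wobble or motor speed fluctuations, camera vignetting or
segmentation errors, overlapping rings in crowded fields, or any
chemistry of the receptor's FAD cofactor. Passing tests therefore show
that the estimators are correct and well calibrated under the stated
noise models — not that real recordings are free of the artifacts above.

## Numerical choices and degenerate inputs

* All randomness flows through one explicitly passed seed per generator
  call (`withr::with_seed`), leaving the caller's RNG untouched; equal
  seeds give byte-identical outputs.
* Zero-radius bead traces, all-pause classifications, all-masked E-FRET
  frames, inverted saturating windows, unpaired replicates, and rings
  larger than the frame all raise informative errors or flags rather than
  returning numbers.
* With both switching rates zero an initial state must be supplied; the
  adaptation band carries a $10^{-9}$ numeric floor so that zero-noise
  re-entry is attainable under floating-point summation.
* CSV output uses 17 significant digits, so write/read round trips are
  lossless; schema violations are reported with the offending column or
  row.

## Problem sizes used in the packaged validation

Motor recovery: 200 motors × 10 min at 250 frames/s per condition.
FRET: 50 cells × 600 s at 20 Hz. Rings: 2,500 rendered 96-px images
(500 per replicate seed × 5 seeds) for the RMSE figure, 120 in the test
suite. These sizes put the Monte-Carlo standard errors comfortably below
the asserted tolerances.

## A worked example

```{r example, eval = FALSE}
model <- preset_switching_model("wt_peroxide")
sim <- simulate_motor_trace(model, duration_s = 120, fps = 250, seed = 1)
ds <- classify_direction(estimate_rotation(sim$trace))
summarize_motor(ds, window = c(0, 60))    # baseline
summarize_motor(ds, window = c(60, 120))  # after oxidant addition
```

## Known limitations

* The stimulus-to-rate kinetics, the FRET optical constants, and the
  saturating-stimulus identities are placeholders pending measured
  values; every one is a visible configuration default, not a buried
  constant.
* The linear diameter–height calibration is an idealization of a
  monotone but not necessarily linear optical relationship; supply a
  measured calibration for real data.
* The debounce makes direction dwells shorter than ~10 ms invisible;
  lower `min_dwell_s` for very fast switchers at high frame rates.
* `estimate_ring_diameter()` assumes one ring per image; crowded fields
  need upstream detection and cropping.
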