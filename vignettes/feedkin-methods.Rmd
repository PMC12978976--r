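---
title: "Methods: segmentation, hand metrics, and paired comparisons in feedkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segmentation, hand metrics, and paired comparisons in feedkin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(feedkin)
```

`feedkin` analyses upper-body kinematics of eating movements: joint-angle
time series and 3D hand positions sampled at 120 Hz, segmented into eating
cycles and feeding phases, summarised per phase, and compared between
paired utensil conditions (chopsticks for solid food vs a spoon for
semisolid food) separately per sex. This vignette documents the model
behind each stage, the tunable parameters, the numerical choices, and what
the synthetic validation does and does not establish.

## Event model for cycle and phase segmentation

The original study identified cycle and phase boundaries from synchronized
video. An automated pipeline needs an operational rule, and `feedkin` uses
proximity events of the hand origin (midpoint between the wrist styloid
processes) relative to two reference points, the mouth and the bowl:

* **mouth exit** (cycle start): the hand-mouth distance crosses `d_mouth`
  outward and stays outside for at least `min_dwell`;
* **bowl entry** (reach → table): hand-bowl distance falls below `d_bowl`,
  sustained;
* **bowl exit** (table → transport): hand-bowl distance exceeds
  `d_bowl + hysteresis`, sustained — the hysteresis band prevents jitter at
  the bowl rim from toggling events;
* **mouth entry** (transport → mouth): hand-mouth distance falls below
  `d_mouth`, sustained.

Positions are low-pass filtered before distances are computed (see below).
Phases are half-open windows `[start, end)` in 1-based sample indices, so
adjacent phases share a boundary index without overlapping and the four
phases partition the cycle exactly; this is asserted for every successful
segmentation. The trailing incomplete stretch after the last mouth exit is
discarded, so a trial with three sequential eats yields two complete
cycles. Cycles flagged as failures in the event annotations (excessive arm
elevation, looking away, extraneous head movement, separated food,
multiple scoops) are skipped; the first successful cycle is analysed, and
a participant with no successful cycle in a condition is excluded with a
classed error rather than silently dropped. Mid-reach pauses — hand speed
below 5% of the reach peak for at least 0.3 s — are flagged but never
excluded, matching the observed behaviour the generator reproduces
(84% of chopstick eats, 65% of spoon eats).

Defaults: `d_mouth` 0.10 m, `d_bowl` 0.08 m, `hysteresis` 0.02 m,
`min_dwell` 0.05 s. These radii are the package's operationalisation of
"reaching the food" and "inserting the food into the mouth"; they are
deliberately config-exposed (`event_thresholds()`) because no numeric
definition exists in the source material. Manual phase boundaries in the
annotations override event detection verbatim.

## Filtering

Kinematic positions are smoothed with a second-order Butterworth filter at
6 Hz, applied forward and backward for zero phase lag — the standard
choice for upper-limb kinematics, where voluntary movement content lies
below ~6 Hz. Because the plain two-pass filter rings at the series ends,
`lowpass_butter()` first extends the signal by odd (point-symmetric)
reflection at both ends and discards the padding afterwards; a
straight-line signal passes through unchanged, so constant-velocity motion
yields constant speed to numerical precision. Angles are *not* smoothed
before extrema are taken (extrema on filtered angles are available via the
`cutoff_hz` argument but off by default, since smoothing biases range
estimates downward).

## Hand spatiotemporal metrics

All transport metrics are computed on the filtered hand trajectory within
the transporting-phase window (any window can be supplied):

* **speed**: central differences of filtered position, one-sided at the
  window edges, reduced to the Euclidean norm;
* **actual distance**: sum of consecutive-sample displacements;
* **relative distance**: actual / straight-line start-to-end distance
  (≥ 1 by the triangle inequality; a window whose endpoints are closer
  than 1 mm is rejected as degenerate);
* **mean velocity**: time integral of speed (trapezoid) over the window
  duration; **maximum velocity**: the speed maximum, ties resolved to the
  first occurrence (a constant profile therefore has peak timing 0%);
* **timing of maximum velocity**: peak time as a percentage of the window
  duration (≈50% for a symmetric ballistic reach; the package verifies
  1.875·D/T peak speed and 50% ± 1 timing on pure minimum-jerk segments);
* **movement units**: see below.

"Velocity" throughout is scalar tangential speed; the source tables do not
distinguish velocity from speed, and mean velocity is path length over
duration rather than displacement over duration.

### Movement-unit counting

A movement unit is a local-minimum-to-next-maximum excursion of the speed
profile exceeding an amplitude limit of 20 mm/s, with retained maxima
separated by at least 150 ms. The implementation is a three-step rule:

1. local maxima and minima by sign change of the first difference, with
   plateaus collapsed to their midpoint sample;
2. minimum peak interval enforced on maxima only, scanning in time order:
   a maximum closer than the interval to the previously retained maximum
   merges with it and the larger survives;
3. one unit per retained maximum whose rise above the lowest speed since
   the previous retained maximum (or since the window start, for the first
   peak — so the initial rise counts when it exceeds the limit) is greater
   than the amplitude limit.

The source definition (adapted from a drinking-task metric) is ambiguous
about whether the interval applies to minima and how ties resolve;
applying it to maxima with larger-peak-wins is the package's documented
choice, and both thresholds are config-exposed
(`movement_unit_params()`). The count is validated against a brute-force
oracle (explicit-loop extremum enumeration with the same rule) on
randomized profiles, is monotonically non-increasing in both thresholds,
and recovers commanded submovement counts exactly on noise-free synthetic
transports.

## Paired statistics

The condition comparison follows the SPSS conventions of the original
analysis so that its reported statistics are reproducible arithmetic:

* **Medians and IQRs** by the weighted-average-at-(n+1)p quantile
  definition (R type 6, SPSS HAVERAGE); switchable via `quantile_type`.
* **Wilcoxon signed-rank z**: differences a − b, zeros dropped, midranks
  on |d|, tie-corrected variance, no continuity correction:
  `z = (W+ − n(n+1)/4) / sqrt(n(n+1)(2n+1)/24 − Σ(t³−t)/48)`.
  The sign convention is the display convention: z < 0 when the chopstick
  condition tends lower. Implemented directly (the convention is the
  point); `stats::wilcox.test(correct = FALSE)` serves as an independent
  cross-check in the test suite.
* **Effect size** `r = z / sqrt(2 · n_pairs)`. The source tables do not
  state the formula; this convention is the unique one consistent with
  every printed (z, n, r) triple — the package ships the transcription
  (`inst/extdata/table_effect_sizes.csv`, 284 rows) and the test suite
  verifies a maximum absolute deviation ≤ 0.001 across all of them.
  Categories: |r| ≥ 0.6 large, ≥ 0.5 medium, ≥ 0.3 small, else below
  small.
* **No multiple-testing correction** by default (per-test α = .05,
  matching the source analysis); `p_adjust = "holm"` is available.

### Discreteness of the exact null and the asymptotic p

For small n the signed-rank statistic is coarsely discrete. Comparing the
uncorrected asymptotic p with the plain exact enumeration p
(P(|W − μ| ≥ |w − μ|) over all 2ⁿ sign assignments), the worst-case
disagreement over all possible outcomes is 0.127 (n = 5), 0.099 (n = 6),
0.068 (n = 8), 0.050 (n = 10) — dominated by the near-null lattice region,
where the exact p saturates at 1 while the uncorrected z gives ~0.92-0.96.
This is an intrinsic property of the convention, not an implementation
artefact. The package therefore validates the approximation against the
**mid-p** enumeration (P(|W − μ| > |w − μ|) + ½·P(=)), the standard exact
counterpart of an uncorrected normal deviate: with 9-10 pairs the mid-p
disagreement is below 0.02 for *every* possible outcome (0.0197 at n = 9,
0.0173 at n = 10), which is the bound the acceptance suite asserts over
200 random paired samples, alongside exact agreement of W⁺ with the
brute-force rank sum. Users analysing fewer than ~10 pairs should prefer
an exact test; the package warns below 5 nonzero differences.

When every paired difference is zero the test is undefined;
`wilcoxon_signed_rank_z()` signals a classed error, and the table
assembler reports z = 0, p = 1, r = 0 for such rows (no evidence of a
difference) so that comparison tables remain complete.

## The synthetic feeding-motion generator

`synth_trial()` builds each trial from minimum-jerk primitives
(x(τ) = start + (end − start)(10τ³ − 15τ⁴ + 6τ⁵), zero velocity and
acceleration at the endpoints, peak speed 1.875·D/T at τ = 0.5):

* a mouth dwell, then for each of three eats: a brisk mouth-depart
  segment, a slow main reach (optionally split by a 0.3-1.0 s pause at a
  point safely outside both event radii), a table dwell with a small
  picking oscillation, a transport, and a mouth dwell;
* the transport is a slow approach from the bowl dwell point to just past
  the bowl-exit radius, then the commanded number of sequential min-jerk
  submovements along a span bulged laterally by a sin²(πs) detour solved
  numerically so the *measured window* path-length ratio equals the
  commanded relative distance, then a slow final approach to the mouth
  dwell point. The approach segments keep their speed peaks outside the
  transporting window and place the boundary crossings at low speed near
  zero-velocity junctions, so windowing costs little path; submovement
  durations taper slightly so the speed peak falls in the later half of
  the transport, as observed empirically;
* joint-angle channels are monotone cubic (Fritsch-Carlson) interpolations
  through per-phase keyframes at 30% and 70% of each phase span, drawn
  from per-sex, per-condition distributions; monotone interpolation cannot
  overshoot its knots, so commanded extrema are attained, not exceeded;
* Gaussian noise is added to angles (default SD 1°) and hand positions
  (default SD 1 mm).

Defaults are calibrated to the study conditions: phase-duration lognormals
with the reported per-sex/condition medians and IQR-derived spreads;
keyframe medians from the reported per-phase angle tables; pause
probabilities 0.84/0.65; detour ratios and submovement counts at the
reported medians of relative distance and movement units (the count gets
±1 per-trial jitter by default so cohort comparisons are not degenerate);
landmark separation chosen so the measured transporting window spans the
reported actual-distance scale. Within-participant trial-to-trial
keyframe variability is not reported by the source tables; the default
(SD 2°) is typical joint-angle reproducibility for repeated functional
tasks and was fixed once.

**Ground truth** is computed from the clean (noise-free) trajectory:
boundaries by applying the same sustained-crossing rules to the unfiltered
positions; transport metrics by applying the metric definitions — which
include the 6 Hz smoothing — to the noise-free trajectory over the truth
windows. The smoothing is part of the metric's definition: genuine 2-3 Hz
submovement peaks are attenuated ~3% by the filter, so an unfiltered
reference would disagree with any filtered analysis by more than the 1%
self-consistency tolerance the suite asserts. Commanded dwell durations
are deliberately *not* used as duration truth: measured phase durations
are crossing-to-crossing intervals and systematically include approach
tails (e.g. the measured table phase contains the slow pre-transport
approach), so duration recovery is asserted pipeline-vs-trajectory-truth,
within 2 samples at 120 Hz.

`synth_cohort()` pairs the two conditions within participant: angle
offsets (default between-participant SD 5°) and a duration deviate are
drawn once per participant and shared across conditions. For
effect-recovery experiments, `null_conditions = TRUE` pools the condition
defaults so that the only systematic condition difference is the
commanded `angle_shift`. `synth_paired_metric()` is the metric-level
abstraction (shared random effect + independent measurement noise +
location shift) used for calibration: with it the suite shows an
empirical test size of 0.05 ± 0.02 over 1000 null cohorts of 22 pairs and
≥ 95% detection of a −14° shift (between-SD 5°, noise SD 2°) over 200
replicates.

### What the generator does not emulate

The angle channels are phase-locked to the hand trajectory but not linked
to it by forward kinematics — no skeletal model constrains them, so
joint-angle/hand-path couplings present in real data are absent. The
mouth and bowl points are workspace calibration landmarks for the hand
origin, not anatomical positions (a real wrist stays a utensil-length
away from the anatomical mouth). Sensor-fusion artefacts (drift, soft
tissue, magnetic disturbance), utensil-tip motion, gaze and head events
are all out of scope. Passing the validation suite therefore demonstrates
that the pipeline recovers what its own event model defines on
phase-structured trajectories at realistic scale and noise — not that the
event thresholds reproduce video-confirmed boundaries on real recordings;
the thresholds remain the user's responsibility to validate per dataset.

## Numerical choices and degenerate inputs

* Windows are 1-based half-open `[start, end)`; every phase must contain
  at least 2 samples.
* Motion CSVs store angles in the skeletal-model sign convention (wrist
  palmar flexion, radial deviation, neck left rotation); the reader
  negates those three channels to the reported directions. The map is its
  own inverse, and round-trip identity is property-tested.
* NaN runs up to 0.1 s are linearly interpolated with a warning; longer
  runs are validation errors. Non-uniform sampling beyond 1 μs is
  rejected.
* Speed-profile plateaus collapse to their midpoint sample; peak-velocity
  ties take the first occurrence.
* The detour-height and bulge-arc-length equations are solved by
  `uniroot` on a trapezoid discretisation (4001 points, tolerance 1e-10).
* Problem sizes in the validation suite: 200 noise-free trials for
  boundary recovery, 100+ randomized profiles for the movement-unit
  oracle, 1000 null cohorts for size calibration, 200 replicates for
  power — chosen to bound Monte-Carlo error well below the asserted
  tolerances.

## Known limitations

Segmentation assumes one bowl visit per cycle; double scoops appear as a
single prolonged table phase unless annotated as failures. The asymptotic
z is unreliable below ~10 pairs (see the discreteness analysis above).
The generator's realism is calibrated to group-level medians and IQRs
only; higher moments and inter-metric correlations of real cohorts are
not matched. Angle summaries are computed within the single selected
cycle, mirroring the one-success-cycle-per-condition design, so no
within-participant cycle averaging is performed.
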