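---
title: "Methods: gesture-based motor signatures from tablet gameplay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gesture-based motor signatures from tablet gameplay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motorsig)
```

## The problem

Young children with autism spectrum disorder move differently: goal-directed
movements show disrupted prospective control, with over- and
under-compensation of force and velocity. When a child plays games on a
tablet lying flat on a table, those differences leave traces in two sensor
streams the device records for free — the touch screen (where, when and how
fast fingers move) and the inertial sensors (the accelerations and angular
rates the fingers' impacts and pressure put into the device). `motorsig`
implements a complete pipeline over such recordings: parse session logs,
segment touch events into atomic gestures, compute a fixed catalogue of
262 per-session features, classify children into two groups by repeated
cross-validation of tree ensembles, and rank the features that separate
the groups by two-sample Kolmogorov–Smirnov (KS) distance.

No clinical recordings ship with the package. Instead a first-class
synthetic-cohort generator emulates the study design (two groups of 37 and
45 children, two games, one 5-minute test session per child per game,
touch at 60 Hz and inertial sensing at 10 Hz) with group differences
injected in known directions, so every downstream stage is testable and
the whole analysis is reproducible end to end.

## Data model and gesture segmentation

A session log is one JSON document (optionally gzip-framed) holding a
touch-event stream — `began` / `moved` / `ended` records per pointer with
screen coordinates in points — and a nominally 10 Hz inertial stream of
tri-axial acceleration (g), rotation rate (rad/s) and attitude Euler
angles (rad). The device lies in landscape in front of the seated child;
`x` is the "height" axis running away from the child, `y` the lateral
axis. Timestamps are seconds from session start; epoch-millisecond clocks
are normalised on read.

A *gesture* is one atomic interaction: it opens at a `began` event that
arrives while no pointer is down and closes at the `ended` event that
returns the active-pointer count to zero. This single counting rule
yields taps, drags and multi-touch without special cases, partitions
every touch sample into exactly one gesture, and is what
`segment_gestures()` implements. Two conventions are deliberate choices:

* **Tap** means a single-pointer gesture whose first-pointer path length
  is under `tap_path_epsilon = 10` points (configurable) — the threshold
  is not defined quantitatively in the field, and 10 pt is well under a
  fingertip's width.
* A **cancelled pointer** (stream ends mid-gesture) closes its gesture at
  the last seen sample with a warning rather than an error: truncated
  logs are common and the partial gesture is still informative.

Only test-phase sessions are analysed by default; training-phase logs
parse but are a different behavioural regime (guided play).

## The feature catalogue

`feature_manifest()` fixes an ordered catalogue of 262 named features —
164 inertial and 98 screen. For each inertial signal (acceleration,
rotation rate, attitude) it takes 15 statistics per axis (mean,
population SD, RMS, min, max, range, median, IQR, skewness, excess
kurtosis, zero-crossing count and rate, mean absolute value, energy, mean
absolute successive difference), 5 magnitude statistics of the per-sample
Euclidean norm, and the 3 axis-pair Pearson correlations; plus 5
cross-signal features. Screen features aggregate 13 per-gesture kinematic
quantities (duration, path length, mean/max speed, mean/max acceleration,
convex-hull area, centroid height and lateral position, extents,
straightness, sample count) over the session's gestures by 6 aggregates,
plus 20 session-level count/timing features. Names follow the catalogue
conventions of this literature (`AccelZeroCrossing_x`, `Velocity`,
`AvgGestArea`, `GestureDurationMin`, `RotationCorrelation_1_2`, ...);
`AccelerationRMS_y` is accepted as an alias of `AccelRMS_y`.

Numerical conventions worth stating:

* All standard deviations use the population (N) denominator.
* Gesture *area* is the convex hull of all the gesture's touch points
  (shoelace formula on the hull); collinear point sets give exactly zero
  at any coordinate scale. A concave ("adaptive") polygon would give
  smaller areas for strongly curved strokes; the convex hull was chosen
  as the reproducible, parameter-free footprint measure.
* Zero crossings skip exact zeros: a crossing is a pair of consecutive
  nonzero samples with opposite sign.
* Attitude is treated as orientation (three Euler angles at 10 Hz), not a
  rate; "static" axis statistics are statistics of that orientation.
* Undefined values (fewer than 2 samples, zero gestures, constant axes
  in a correlation) are masked `NA`, never silently zero.
* Inertial features are computed across the whole stream irrespective of
  touch data; an optional window length computes them per consecutive
  non-overlapping window and averages the per-window values (the
  windowed values for each feature reduced to their mean). With the
  window equal to the session duration the two paths coincide, which is
  asserted in the tests. The default is a single pass.
* `FirstTouchLatency` is anchored to the session clock by definition;
  every other feature is invariant to a constant time shift of both
  streams, and the property tests assert exactly that split.

## Redundancy reduction

Feature sets like this are strongly collinear. `reduce_redundant()`
scans features in manifest order and drops any feature whose absolute
Pearson correlation with an already-retained feature exceeds 0.9,
reporting the retained representative for every dropped feature. The
first feature in manifest order wins ties — a deterministic, documented
tie-break. Inside cross-validation the reduction is fitted on the
training fold only and applied to the test fold (with a `"global"`
option for the in-sample variant); the defensible default avoids even
this mild form of test-set leakage.

## Classification harness

`run_cv()` implements 10 repetitions of stratified 10-fold
cross-validation (both `k` and the repetition count configurable). Per
repetition each child lands in exactly one test fold, so pooled records
number `repetitions x n`. Folds are stratified by group with per-fold
class counts within one of proportionality; the study-style per-model
configurations are extremely randomised trees (5000 trees), random
forest (5000 trees) and the Regularized Greedy Forest (500 trees), the
latter also in a variant that excludes the age and gender columns. RGF
has no R implementation here, so the RGF configurations substitute a
500-tree random forest and record the substitution in the run metadata
(`allow_fallback = FALSE` turns this into an error); the harness is
deliberately model-agnostic, since the scientific content is the
pipeline, not the learner. Missing feature values are imputed with
training-fold medians. All preprocessing statistics are computed on
training folds only, which an instrumentation hook lets the tests audit
fold by fold.

Discrimination is summarised two ways, both reported: per-repetition AUC
(mean and SD across the 10 repetitions, the convention of tabulated CV
results) and the single pooled AUC over all out-of-fold predictions (the
convention of pooled ROC plots). AUC is the rank-based (Mann–Whitney)
statistic with ties counting one half; `roc_curve()`'s trapezoid
integral equals it to numerical precision, which the tests assert at
1e-9. Cross-game scores average each child's two per-game probabilities
within a repetition. Sensitivity and specificity are counted over pooled
records at thresholds 0.50 and 0.55 (positive class: ASD).

## KS feature ranking

`rank_features()` computes, per game, the two-sample KS distance
`D = sup_x |ECDF_asd(x) - ECDF_control(x)|` for every feature, exact
under ties, and ranks features by descending D with manifest order
breaking ties. Direction of effect is the sign of the group median
difference. Asymptotic p-values are attached for information only; no
multiple-testing correction is applied because the ranking is a
descriptive screen of what drives the classifier, not an inferential
procedure — a property test checks that under label permutation the
maximum D over the catalogue stays below the analytic small-sample
envelope for the 99th percentile.

## The synthetic cohort generator

`sample_cohort()` draws per-child latent motor parameters from
group-level distributions (log-normal for strictly positive quantities);
`simulate_session()` plays a gameplay grammar with those parameters and
`inertial_response()` derives the matching inertial stream. The grammars
mirror the two games: *sharing* is cycles of one tap on the food item,
four target drags to the plates and a 3 s reward pause; *creativity* is
free strokes with occasional taps. Free strokes are wavy circular arcs:
arc length is a child trait, while the subtended angle grows with the
child's area parameter, so the gesture's convex hull fattens (area up)
at roughly constant path length — this keeps the area effect from
bleeding wholesale into the path-length features. Strokes are centred on
a start point drawn from the child's gesture-height distribution and
traversed with a minimum-jerk (bell-shaped) speed profile whose total
duration is path length over the child's speed parameter; tap durations
are a child-specific floor plus an exponential tail.

The inertial stream is Gaussian baseline noise plus, at every
touch-down, a signed exponentially decaying strike transient on the
force axes whose very first sample carries the full strike magnitude
(amplitude proportional to the child's impact force, split between the
vertical and lateral axes by the lateral-force share, with the split
varying touch to touch); contact signs and micro-timing are randomised
per touch so impulses are sign-symmetric over a session. Rotation-rate
impulses are damped sinusoids proportional to strike amplitude times the
lever arm from the device centre, mixed across gyroscope axes by the
group's 3x3 coupling matrix; drags add a sustained low-amplitude
pressure wobble; attitude is a leaky integral of rotation rate. This is
a phenomenological sensor model, not rigid-body dynamics: it reproduces
the *feature-level* structure the pipeline consumes (impulse magnitudes,
axis correlations, zero-crossing behaviour), which is what downstream
validation needs.

The default effect profile encodes the reported group differences as
directions with calibrated magnitudes in arbitrary units: impact force
1.0 vs 1.6 g, lateral force share 0.25 vs 0.45, gesture speed 300 vs
420 pts/s, area scale 1.0 vs 1.5, gesture height 0.35 vs 0.50 of the
screen's height axis with SD 0.08 vs 0.14, tap-duration floor 80 vs
45 ms, and a more cross-coupled gyroscope mixing matrix for the ASD-like
group. A global multiplier `m` interpolates the ASD-like group from the
control distribution (`m = 0`, the null) to the full difference
(`m = 1`); magnitudes were calibrated once so that the full pipeline
reaches the headline cross-validated AUC (>= 0.93) at `m = 1` with the
default cohort, and are exposed in `effect_profile()`.

Equally important is what does *not* differ between groups. Children
(and devices) vary in many ways unrelated to group: how strongly their
touches torque the device, sensor biases and noise floors, personal
pacing, stroke length and waviness, where the speed peak of a movement
falls, and their individual gyroscope coupling style. The generator
draws all of these from identical distributions in both groups. Without
them, every statistic of an affected axis would separate the groups
equally and perfectly — an unrealistic degeneracy; with them, the
injected effects surface most sharply in the features that measure them
directly, while sibling statistics of the same signal are progressively
diluted. Even so, some aggregates are statistically inseparable from
their named counterparts (the standard deviation of a lateral-force axis
carries the same information as its RMS; the median gesture speed tracks
the mean), so such siblings legitimately rank alongside the calibrated
features in the KS screen.

True effect magnitudes in children are unknown; the profile is a
calibration artefact, not an estimate of real ASD kinematics — which is
also why passing calibration tests demonstrate that the *pipeline*
recovers known structure, not that real data would separate this
cleanly.

Randomness is hierarchical: one master seed; per-child seeds derived by
a stable string hash so cohorts are reproducible and extensible; each
session seeded from its child and game.

## Problem sizes and determinism in the test-suite

The tests exercise the study-scale conditions directly: the calibration
suite simulates five independent 200 + 200-child cohorts at the default
profile and requires a 5-seed median KS distance of at least 0.3 with the
encoded direction for each manipulated feature; the discrimination checks
run the full 10 x 10-fold harness on 37 + 45-child cohorts with 500-tree
forests (the tabulated 5000-tree configurations remain the model-spec
defaults; forest size is a convergence knob, and 500 trees is past the
AUC plateau at this sample size). Monotonicity of AUC in `m` uses five
seeds of smaller (15 + 15, 120 s) cohorts at `m` in {0, 0.5, 1, 2}. All
stochastic checks run under fixed seeds, so the suite is deterministic.

## Known limitations

* The generator encodes seven group effects plus axis coupling; real
  gameplay has attention dynamics, game-logic events, fatigue and
  device-to-device variation it does not model.
* The inertial model is phenomenological (no gravity component, no
  rigid-body cross-axis physics beyond the coupling matrix).
* KS ranking on 262 correlated features is descriptive; the p-values are
  uncorrected by design.
* The screen/inertial split of the 262-entry catalogue follows the
  catalogue's documented composition (164 inertial + 98 screen); the
  per-gesture quantity set and session-level feature list are this
  package's reconstruction of the catalogue's documented names and
  definitions.
* Pointer ids are assumed unique within a gesture's lifetime; ids may be
  reused across gestures (as devices do).
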