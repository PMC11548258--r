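---
title: "Assessing mental fatigue from gaze movements: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing mental fatigue from gaze movements: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazefatigue)
```

# The problem

Prolonged monotonous work degrades a PC operator's mental performance well
before they notice it themselves.  Oculomotor behaviour changes measurably
with that state: fixations lengthen, fixational drift slows, gaze
trajectories become more tortuous, saccade metrics shift.  `gazefatigue`
turns raw gaze coordinates (degrees of visual angle over time) into a
catalogue of 27 oculomotor characteristics, screens those characteristics
for relevance to an independently measured fatigue ground truth, and trains
a binary classifier that can then assess fatigue on streaming gaze windows
in near real time.

Because longitudinal eye-tracking studies with psychometric ground truth
are expensive and rarely shareable, the package ships a fully seeded study
simulator.  Every stage of the pipeline is exercised and tested against
synthetic studies whose ground truth is known by construction.

# Event detection

## Fixations: dispersion threshold (I-DT)

A fixation is a maximal time window whose **dispersion** — the maximum
pairwise Euclidean distance between its samples, i.e. the diameter of the
occupied *fixation area* — stays within a configured diameter, and whose
duration reaches a minimum.  The scan is the classic greedy I-DT: grow the
window rightwards while the dispersion bound holds; accept it if long
enough and resume after it, otherwise advance the start by one sample.
Choices worth stating:

* **Dispersion metric.** Max pairwise distance (a true diameter), not the
  cheaper `(max-min x) + (max-min y)` variant: the fixation-area parameter
  is a diameter in degrees and the analysis sweeps it over a grid
  (0.1–2.5°, step 0.1° by default), so the metric should mean what the
  parameter says.  The inner loop is implemented in C++; the test suite
  checks it sample-for-sample against a brute-force full-pairwise rescan
  with binary search.
* **Minimum fixation duration** defaults to 0.1 s, the common I-DT
  setting; at lower values the detector emits fragments of windows that
  straddle saccade boundaries.
* **False fixations** (a per-minute catalogue entry) are defined here as
  dispersion-qualified windows too short to be fixations (duration at most
  `false_fixation_max_duration`, default 0.08 s), counted without
  double-counting overlapping rescans.  This quantity has no standard
  definition; ours is explicit and configurable.
* **Cleaning.** Invalid samples in gaps up to 0.3 s (a typical blink) are
  linearly interpolated; longer dropouts split the recording into segments
  that all later stages process independently, so no statistic ever spans
  fabricated data.  Interpolated samples are additionally excluded from
  all kinematic estimates — a linearly interpolated stretch has zero
  curvature and constant velocity by construction, which would contaminate
  extreme-value characteristics.

## Saccades and kinematics

Saccades are derived, not detected: one per consecutive fixation pair
within a segment, with length the angular distance between the flanking
centroids and duration the inter-fixation interval.  Per-sample kinematics
are finite differences: velocity from consecutive sample pairs,
acceleration as the modulus of the velocity-vector change, and curvature
as the **Menger curvature** of each interior triplet (the reciprocal of the
circumradius, 1/deg; collinear triplets give 0).  Menger curvature was
chosen over turning-angle forms because it has an exact analytic oracle —
points on a circle of radius *R* must yield 1/*R* — which the tests check
to 1%.

"Second interval" statistics are computed over non-overlapping 1-second
bins anchored at each segment start; only complete bins count.  The
curvature aggregates (average, minimum, maximum) are taken over per-second
*mean* curvature rather than raw triplets: the catalogue names its velocity
extreme "instantaneous" but its curvature entries not, and the raw-triplet
minimum is degenerate — some triplet in any noisy recording is nearly
collinear, so its minimum is an artefact of sample count rather than a
property of the trajectory.

# The characteristic catalogue

`characteristic_catalogue()` lists all 27 entries.  Conventions that make
the catalogue internally consistent and testable:

* Duration-bin tie rule: "shorter than T" means `< T`, "longer than T"
  means `>= T`, "between 150 and 900 ms" means `[0.15, 0.9)`.  The
  complementary percentage pairs therefore sum to exactly 100.
* "Proportion of time in fixations ..." uses **total fixation time** as the
  denominator, so the three duration bins partition it exactly (the
  whole-recording alternative would leave the partition identity untestable).
* "Average velocity within the fixation area" is net displacement over
  duration; the expert-added "average speed in the fixation area" is path
  length over duration.  That is the only reading under which the two
  names denote different quantities, and it is checked by a geometric
  construction (a zig-zag of equal net displacement doubles speed, not
  velocity).
* Per-recording values are event-weighted means over events (fixations,
  saccades, second bins), not time-weighted.

# Relevance screening

Four criteria, compiled into one table per study:

1. **Mental-performance split.** Sessions are labelled high/low by the
   Landolt-rings Au index at threshold 1.5 (the index is treated as an
   input; the simulator generates it in its observed −0.5..4 range).
   Each characteristic is compared across groups with a two-sided
   Wilcoxon rank-sum test — exact for combined n ≤ 25 without ties,
   normal approximation with tie and continuity correction otherwise;
   all-tied characteristics get p = 1.  The screening applies no
   multiple-testing correction by design (it is a screen, not an
   inference); a Benjamini–Hochberg adjustment can be applied by the
   caller if wanted.
2. **Inner-session dynamics.** Sessions begin and end with a
   reaction-time task; a fatigue-sensitive characteristic should drift in
   a consistent direction between those task epochs.  Lacking task
   timestamps, the first and last 10% of each session's recording stand
   in for the bracketing task blocks (configurable).  The statistic is
   max(share of sessions increasing, share decreasing); exact ties count
   in neither.
3. **CRT delta.** Spearman correlation (Pearson selectable) between
   session-level characteristic values and the post-minus-pre change of
   mean choice reaction time, maximized in absolute value over the
   fixation-area diameter grid; the signed maximum and its diameter are
   reported.
4. **VAS-F.** Same construction against the pre-session visual-analogue
   fatigue score.

`select_characteristics()` filters at p < alpha (0.05), ranks by p, then
dynamics score, then |CRT correlation|, and unions in *expert additions*.
The head size is explicit configuration and defaults to keeping the whole
filtered set: the truncation to a handful of characteristics in a real
analysis is expert judgment, not computation, and hard-coding it would
disguise that.  The reference configuration used in the examples adds
"average speed in the fixation area" on theoretical grounds — its
screening performance is poor but it tracks the same drift-slowing
mechanism as the fixation-velocity characteristic.

# Classification pipeline

Preprocessing is fit once on the training data and replayed at inference:
quasi-constant removal (dominant-value frequency ≥ 0.99), z-score
normalization, Kendall-correlation removal (|tau| ≥ 0.9, left-to-right
scan), then PCA keeping the smallest component count reaching 95%
explained variance.  The z-score uses the population SD convention
(denominator n) so that normalization is exactly idempotent and replaying
stored parameters on the training matrix reproduces it bit-for-bit; an
alternative reading of the normalization step as division by the mean was
rejected as ill-posed near zero-mean features.

The model grid covers six families: random forest (10–100 trees),
decision tree (gini/information splits — the log-loss criterion coincides
with information gain), k-NN (k = 1..10, uniform or inverse-distance
votes), a single-hidden-layer perceptron (sizes 1–20, logistic activation,
BFGS, cross-entropy loss), logistic regression (Fisher scoring,
cross-entropy loss), and an SVM over four kernels (hinge loss).  Where the
reference protocol enumerated solver or activation variants specific to
another ecosystem, the grid keeps the axis that exists in the R
implementations and fixes the rest, documented in `model_grid()`.

Evaluation mirrors the reference protocol: a stratified random split with
a **balanced held-out test set** (`test_per_class` per class; 100 per class
in the original 1112-sample protocol, scaled down for desk-size studies),
plus stratified 10-fold cross-validation of every configuration with
pooled out-of-fold predictions.  The best configuration is the
highest-accuracy one on the random split; CV metrics are reported
alongside.  The F1 positive class is the fatigued ("low" performance)
one.  Everything is seeded: the split, fold assignment, and each model fit
derive sub-seeds from `cfg$seed`, so a report is bit-reproducible.

`assess_stream()` replays a recording as a stream, recomputing the model's
feature definition over a sliding window (default 60 s, step 1 s) and
reporting `insufficient_data` before the first full window.

# The synthetic study simulator

The generator alternates fixation and saccade epochs on a uniform grid:

* fixation durations log-normal (median 0.25 s, sigma 0.4 — the standard
  oculomotor assumption, and it populates all duration bins, from
  sub-150 ms to beyond 900 ms);
* saccade amplitudes gamma (mean 4°, SD 2°); trajectories are
  minimum-jerk, so samples are smooth and differentiable, and obey a
  linear main sequence (peak velocity = 40/s × amplitude by default,
  which fixes the saccade duration at 1.875/slope ≈ 47 ms);
* saccades bow sideways by 6% of their amplitude (real saccades are
  measurably curved; perfectly straight ones would make trajectory
  curvature degenerate within saccades);
* within fixations the gaze drifts at 0.5 °/s with isotropic Gaussian
  jitter (SD 0.03°), typical video-oculography noise;
* blinks arrive as a Poisson process (12/min, 0.2 s) and are emitted as
  invalid samples so the cleaning path is always exercised;
* the eye tracker's rate defaults to 100 Hz (configurable; the reference
  study does not report its hardware rate).

A **study** is participants × days × sessions of this process.  A fatigue
schedule maps each session to a level in [0, 1] (default: mostly across
the sessions of a day, partly across days), and a level rises by 0.25
within each session, which is what the inner-session dynamics criterion
detects.  Fatigue acts on the generator through multiplicative effects
(`value × multiplier^fatigue`, monotone by construction): fixation
durations ×1.6, drift ×0.45, jitter ×0.6, amplitudes ×1.2 (scaling the
whole distribution), saccade bow ×1.6.  The directions follow the
within-session trends the screening criteria are built around — the share
of short fixations falls, fixation-area velocity falls, trajectory
curvature rises (curvature scales inversely with the spatial scale of the
jitter).  The magnitudes are strong by design — the simulator emulates a
regime in which fatigue dominates session-level variance of the selected
characteristics, the setting in which the screening-and-selection
technique is meant to operate — and they are fixed once as the package's
study conditions rather than tuned per experiment.  Ground truth follows the same level: Au falls
from ≈3.2 to ≈0.4 (threshold 1.5 splits the default schedule roughly
evenly), mean reaction time and VAS-F fatigue rise, each with configurable
Gaussian noise (zero-noise mode for deterministic tests).

## What the simulator does *not* emulate

Per-participant idiosyncrasies (no random effects), task structure within
a session, smooth pursuit, pupil dynamics and blink morphology,
tracker-specific noise spectra, and any correlation between ground-truth
noise and oculomotor state.  Passing tests therefore demonstrate that the
pipeline recovers *planted, monotone* effects under realistic event
statistics — not that the selected characteristics are relevant for any
particular real population.

# Numerical and degenerate-input choices

* Collinear or coincident triplets get curvature 0; windows shorter than
  the kinematic minimums yield empty series, and undefined characteristics
  (no saccades, no complete second bin) are `NA`, never 0.
* Characteristic provenance is enforced: events computed from one
  recording are refused by another's characteristic computation.
* Percentile summaries use linear interpolation (type 7); SD uses
  denominator n−1 (0 for a single value).
* Sessions shorter than ~2 s per dynamics block are skipped with a
  warning rather than producing unstable block values.
* All extreme-value characteristics (minimum saccade length in
  particular) remain noisy at desk scale; the minimum saccade length of a
  30 s recording is dominated by near-threshold detection geometry.  This
  is a property of the statistic, and the recovery tests are designed so
  that the selection technique succeeds without it.

# Problem sizes used by the test suite

The packaged checks run on one CPU in a few minutes, using study shapes
scaled down from the reference design (15 participants × 7 days × 3
one-hour sessions) to e.g. 15 × 2 × 3 with 30 s sessions for screening
recovery, 10 × 1 × 3 with 60 s sessions and disjoint 20 s windows for
classification, and 100 fuzzed recordings of up to 600 samples for the
detector-oracle equivalence.  Windows used for classification are
non-overlapping: overlapping windows share raw samples across
cross-validation folds and visibly inflate null-study accuracy, so the
default protocol keeps them disjoint.
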