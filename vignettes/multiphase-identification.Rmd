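---
title: "Multiphase identification of falls from a waist-worn inertial sensor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiphase identification of falls from a waist-worn inertial sensor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A fall is not a point event. Clinically it unfolds as an ordered sequence of
phases: the activity performed before balance is lost (*pre-fall*), the body's
movement toward the ground (*free-fall*), the shock of hitting it (*impact*),
a period of lying inactive (*resting*), and, when the faller can, getting back
up (*recovery*). Each phase carries its own clinical information — the
pre-fall activity hints at the cause, impact magnitude and direction relate to
injury risk, and a long resting phase with no recovery (the "long-lie") is an
emergency in its own right. Laboratory fall protocols bracket the sequence
with two quiet-standing bookends, *initial-static* and *ending-static*, giving
a seven-phase vocabulary coded 0–6 in that canonical order.

`fallphase` segments a recorded fall trial into these seven phases from a
single waist-worn inertial sensor: tri-axial acceleration (g) and tri-axial
angular velocity (deg/s) sampled at a fixed rate (128 Hz by default). The
output is a per-sample phase sequence and the derived *multiphase
information*: the starting point, ending point and duration of every phase.

## The identification pipeline

The pipeline has four stages.

**Sliding window.** The six-channel stream is cut into overlapping windows of
`W` samples advanced one sample at a time (`n − W + 1` windows). Window sizes
of 8, 16, 24, 32 and 40 samples (0.0625–0.3125 s at 128 Hz) are the studied
set; `W = 24` is the package default. One-sample stride keeps the label
resolution at the sample level; the window is the classification unit.

**Feature extraction.** Each window is summarised by 64 statistics: eight
estimators — mean, standard deviation, variance, maximum, minimum, range,
kurtosis and skewness — of eight signals — the six channels plus the
acceleration resultant $A_R = \sqrt{a_x^2+a_y^2+a_z^2}$ and angular-velocity
resultant $G_R = \sqrt{g_x^2+g_y^2+g_z^2}$. The layout is channel-major
(`ax_mean`, `ax_std`, …, `g_r_skewness`).

**Phase classification.** Five standard techniques are wrapped behind one
train/predict contract (`classifier_spec()`, `fit_multiphase()`, `predict()`):
a linear one-versus-one SVM, k-nearest-neighbour with Euclidean distance and
`k = 13`, Gaussian naive Bayes with the MAP rule, CART with Gini splits grown
unpruned, and multiclass AdaBoost (SAMME) over depth-1 trees with 10 rounds.
The window's training label is the majority of its per-sample ground-truth
labels, ties going to the earlier canonical phase.

**Fragment modification.** Stride-1 window classification inevitably produces
short runs of misclassified windows ("fragments"). A rule pass repairs them:
the first segment is forced to initial-static and the last three to
ending-static (the protocol starts and ends standing), and a single in-place
left-to-right sweep overwrites any 1-, 2- or 3-segment fragment whose
neighbours on both sides agree. The sweep deliberately matches its pseudocode
formulation line by line — repairs feed later comparisons within the same
pass, which is how two- and three-segment fragments are absorbed one segment
at a time — and the package carries a literal transcription
(`modify_fragments_oracle()`) used in tests to pin the optimised
implementation (`modify_fragments()`) to that exact semantics, including the
printed loop bounds (pseudo-indices 2 … N−3).

Finally the per-sample sequence is restored from the segment labels and
decomposed into maximal constant runs, giving the phase timeline.

## Evaluation

Performance is scored sample by sample, one phase versus the rest: TP, FP, TN
and FN counts per phase, from which four percentages are computed —
sensitivity TP/(TP+FN), precision TP/(TP+FP), Jaccard coefficient
TP/(TP+FP+FN), and accuracy (TP+TN)/(TP+FP+TN+FN). Jaccard is the headline
localisation measure: it directly penalises misplaced phase boundaries. The
harness is leave-one-subject-out cross-validation (`run_losocv()`): each fold
trains on all other subjects' windows and scores the held-out subject's
trials through the full pipeline (stride-1 prediction, fragment modification,
sample restoration). Cross-fold aggregation is the unweighted mean of fold
metrics; pooled-count metrics are also emitted. "Accuracy" is reported both
as overall sample-level correctness of the 7-class output (micro, the
headline) and as the mean of the per-phase one-vs-rest accuracies.

Degenerate counts follow explicit conventions: a phase absent from both truth
and prediction scores 100 (vacuous agreement); a phase absent from the truth
but predicted has undefined sensitivity (`NA`, excluded from averages);
present but never predicted, undefined precision.

## The synthetic protocol simulator

No public recording of the laboratory protocol exists, so the package ships a
seeded simulator (`generate_trial()`, `generate_protocol_dataset()`) that
plays the role of the experiment: 7 fall types — falling while standing,
standing up, sitting down, stooping, walking, jumping, and walking backward —
the first six in four directions (forward, backward, right- and left-lateral),
the last backward only, each (type, direction) pair repeated three times per
subject: 75 trials per subject, 525 for the standard 7 subjects.

Each trial traverses the seven phases in order. The *elapsed time* (pre-fall
start to recovery end) is drawn from a per-(type, direction) normal law whose
means and standard deviations (roughly 15–21 ± 2 s) are the package defaults;
free-fall and impact durations are drawn uniformly from 0.3–0.6 s and
0.2–0.5 s — physically these phases are short — and the remaining elapsed
time is split between pre-fall, resting and recovery in jittered proportions
25:25:20 (of the whole trial), with static bookends of about 15% each added
around the elapsed span. Per-phase durations are an assumption of the
simulator (only total elapsed time is protocol-calibrated) and every fraction
is configurable in `simulator_config()`.

The signal model, per phase (acceleration in g, gravity ≈ 1):

* **Statics**: gravity along the vertical axis plus white noise (0.02 g,
  1.5 deg/s). The ending-static bookend carries a small residual tilt
  (~0.08 g projection) and 1.5× the sway noise: people do not return to
  their exact initial posture after getting up, and without some such
  signature the two bookends would be statistically identical and no
  context-free classifier could tell them apart.
* **Pre-fall**: type-specific — gait oscillation (~0.22 g at ~1.8 Hz) for the
  walking types, a posture-transition bump for standing-up/sitting-down/
  stooping, periodic hop transients for jumping, anticipatory sway for plain
  standing.
* **Free-fall**: the acceleration resultant decays from 1 g toward a 0.3 g
  floor following a *quadratic* ease — support is lost progressively, so
  early free-fall still resembles the preceding activity — while the body
  starts toppling (angular velocity ramping to ~160 deg/s about the
  direction-appropriate axis). This is what makes free-fall the hardest
  phase, as it is in real data.
* **Impact**: a 3–6 g half-sine shock on the direction-loaded axis plus a
  decaying ~14 Hz ring and one or two smaller secondary contacts later in
  the phase (body parts landing sequentially, mattress rebound), with a
  matching 150–400 deg/s gyroscope transient.
* **Resting**: the reoriented gravity vector (lying prone/supine/lateral
  according to fall direction) with very low noise and a small breathing
  oscillation.
* **Recovery**: a smooth spherical interpolation of the gravity vector from
  lying back to upright, overlaid with ~1.2 Hz effort oscillation and
  moderate gyroscope activity.

Between-subject variation — what makes leave-one-*subject*-out meaningful —
enters through per-subject lognormal amplitude and tempo multipliers
(sd 0.15 and 0.08 on the log scale), a per-subject elapsed-time offset
(half of the configured standard deviation), and per-subject orientation
jitter. All randomness derives from one master seed through a counter-based
hash of (subject, type, direction, repetition), so any subset of the protocol
regenerates bit-identically and independently.

**What the simulator does not emulate** — and hence what passing tests do and
do not show: there is no rigid-body biomechanics, no soft-tissue or sensor
artefacts (saturation, drift), no near-falls or daily activities (the
protocol contains only falls), no failed recoveries, and phase boundaries in
the ground truth are exact rather than annotated from video by a human. Good
pipeline scores on this dataset demonstrate that the machinery recovers
phases whose statistical signatures are present; they are not a claim about
performance on real falls.

## Numerical and design choices

* **Moment estimators.** Variance is the population (1/n) estimator with
  `std = sqrt(var)`; skewness and kurtosis are the uncorrected moment
  estimators, kurtosis on the normal-baseline-3 convention — the defaults of
  the numerical environment the pipeline was configured after. On a constant
  window, std, var and range are 0 and skewness/kurtosis are *defined* as 0,
  so classifiers never see non-finite values.
* **Standardization default: off.** Per-feature z-scoring (training-fold
  statistics only) is implemented and switchable, but off by default. The
  global feature scales are set by the high-amplitude phases (impact spans
  several g, hundreds of deg/s), so z-scoring compresses the low-amplitude
  contrasts between the quiet-standing bookends to far below the sampling
  noise of the moment features, and distance-based classification of the
  statics degrades sharply (measured: about 8 accuracy points on a 2-subject
  cross-validation). Raw units also match the default behaviour of common
  kNN implementations, including the environment the method was tuned in.
  Axis-aligned trees are invariant to the choice, which the test suite uses
  as a cross-check of the standardization plumbing.
* **Segment-to-sample alignment: centre.** A segment's label summarises the
  window interior (its training label is the window majority), so assigning
  it back to the window's *starting* sample shifts every reconstructed
  boundary about `W/2` samples early — a systematic bias that caps the
  Jaccard of short phases like impact at roughly `(L − W/2)/(L + W/2)`
  however good the classifier. The default therefore aligns each segment
  label to the window centre; start alignment remains selectable for
  sensitivity analysis.
* **kNN.** Exact Euclidean search with deterministic tie handling:
  neighbours are the k smallest by (distance, training index); vote ties are
  broken by the smaller summed neighbour distance of the tied classes, then
  by the lower class code. The implementation groups training points by a
  deterministic Lloyd clustering and prunes clusters and points with the
  triangle inequality (seeding each query's pruning radius from the previous
  query — consecutive stride-1 windows are nearly identical), which keeps
  0.9 M stride-1 probes per fold tractable on one core while remaining
  exact; tests pin it against a brute-force all-pairs oracle.
* **Naive Bayes** uses a per-feature variance floor of 1e−9 so near-constant
  features keep a proper Gaussian likelihood; computation is in log space.
* **SVM** is libsvm's one-versus-one linear machine with C = 1 (the constant
  is not part of the studied configuration and is exposed as an option);
  vote ties are resolved by the aggregate pairwise decision-function margin,
  then the lower class code.
* **AdaBoost** is multiclass SAMME over depth-1 CART stumps, 10 rounds;
  rounds whose weak learner is no better than chance terminate the ensemble.
* **Training stride.** Adjacent stride-1 windows overlap by `W − 1` samples
  and are almost perfectly redundant as training examples, so `run_losocv()`
  trains on windows subsampled at `train_stride = W` (non-overlapping) by
  default while always predicting the held-out trials at stride 1. This is
  the package's tractability choice for the 525-trial default dataset
  (~1.5 M samples); the stride is a parameter.
* **Problem sizes.** The shipped evaluation runs use the full 7-subject
  protocol (525 trials, about 3.4 hours of signal at 128 Hz); simulator
  calibration checks use 300 independent trials of one (type, direction)
  cell.

## Known limitations

Free-fall identification is the weakest link by construction and by design —
the phase is short and its onset is statistically continuous with the
preceding activity; reported Jaccard for free-fall should be read with that
in mind. The fragment pass is a fixed-width rule (fragments of up to three
segments) and does not adapt to the window size. The pipeline assumes exactly
one fall per recording with static bookends, as in the laboratory protocol;
it is not a free-living fall detector. And all performance figures shipped
with the package are measured on synthetic data whose difficulty is
ultimately a modelling choice.
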