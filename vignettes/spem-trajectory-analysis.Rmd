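---
title: "Trajectory-based smooth pursuit analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trajectory-based smooth pursuit analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spemtrack)
```

## The problem

Smooth pursuit eye movement (SPEM) — the slow tracking movement that keeps a
moving object on the fovea — is reliably impaired in psychotic disorders, and
pursuit quality is a candidate low-cost biomarker for schizophrenia. The
package implements a trajectory-level analysis of pursuit: instead of
event-detecting saccades or estimating pursuit gain, it compares the raw gaze
trajectory with the stimulus trajectory through three geometric indices, runs
the group statistics appropriate for small clinical cohorts, and evaluates
whether the indices separate patients from controls with a leave-one-out SVM.

Everything operates on a single shared representation: a `trajectory` is an
ordered sequence of \((x_t, y_t)\) screen positions on a uniform 60 Hz clock.
Consumer eye trackers deliver irregularly timed samples (the reference device
has a nominal 30–60 Hz rate but an effective rate near 20 Hz), so recordings
are first resampled by strictly linear interpolation — no smoothing — onto the
60 Hz clock with `resample_to_uniform()`. The default screen geometry is a
14-inch 1366×768 display (355.6 mm diagonal, hence 0.227 mm per pixel) viewed
from 50 cm; physical ball radii in millimetres convert to pixels through this
single square-pixel scale.

## The pursuit task

`generate_target_trajectory()` reproduces the five-stage stimulus: the target
ball appears at the screen centre and stays still for 1 s; moves along a
random direction at 250 px/s for 5 s, reflecting specularly off the screen
edges; stops for 2 s; resumes in the same direction for 5 s; and stops for a
final 1 s. At 60 Hz the 14 s task gives exactly \(N = 840\) samples. The
initial direction is drawn uniformly on \([0, 2\pi)\) from a seeded generator;
everything else is exact kinematics, so a seed fully determines the stimulus.

Two conventions are worth stating because the task description leaves them
open. Reflection is resolved by mirroring the overshoot inside the step (path
length is preserved, never clamped), and it is computed at the ball's centre —
the displayed ball radius does not affect bounce timing. Bounce samples are
logged by the generator and can also be recovered from any sampled trajectory
with `find_bounce_points()`, which detects direction changes between
consecutive displacement vectors, merges the double flag produced when a
reflection happens mid-step, and ignores zero-displacement stop/start
boundaries. A *straight segment* is a maximal run between consecutive events
(stage transitions and bounces); segments are the unit of analysis for the
regression direction index.

## The three indices

**Spatiotemporal colocality.** On the integer pixel lattice, a closed ball
\(B_r(x, y)\) is the set of lattice points within Euclidean distance \(r\).
With a target ball of radius \(r_1\) and a gaze ball of radius \(r_2\),

\[
Co = \frac{\sum_t |B_{r_1}(r_o(t)) \cap B_{r_2}(r_g(t))|}
          {\sum_t |B_{r_2}(r_g(t))|},
\]

so \(Co = 1\) when every gaze ball sits inside its paired target ball and 0
when the balls never meet. The radius grids are \(r_1 \in \{5, 10, 15\}\) mm
and \(r_2 \in \{2, 4, 8\}\) mm. Positions are snapped to the lattice with
half-away-from-zero rounding before ball construction; radii convert mm→px as
real values. Balls are deliberately *not* clipped at screen edges: the
denominator's per-frame cardinality is centre-independent, which the
normalisation relies on, and clipping would break that. When \(r_2 > r_1\)
the index cannot reach 1 (the gaze ball can never be contained), which is why
large-\(r_2\) columns plateau below the rest.

**Direction difference.** Each step of a trajectory has an angle
\(\theta(t) = \mathrm{atan2}(y_{t+1} - y_t,\ x_{t+1} - x_t)\). The per-sample
index is one minus the length of the circular mean resultant of the angle
differences,

\[
\Delta\theta_{sample} = 1 - \Bigl|\tfrac{1}{M}\sum_t e^{i(\theta_o(t) - \theta_g(t))}\Bigr|,
\]

0 for perfectly coherent directions and near 1 for uniform scatter. The
modulus is taken before subtraction so the index is real; it is a coherence
measure, not a metric (a constant angular offset gives 0). Only the \(M\)
steps where **both** trajectories move are used: a stationary target (stop
stages) or a frozen gaze sample has no defined step angle, and exclusion is
the only well-defined choice. The regression index \(\Delta\theta_{regr}\)
fits a line to the gaze points over each straight target segment and takes
the acute angle between the two orientations, averaged over segments. Lines
are fitted by total least squares (the principal axis of the point cloud)
because an ordinary regression of \(y\) on \(x\) is undefined for vertical
target segments; orientations are compared modulo \(\pi\) and folded into
\([0, \pi/2]\) since a fitted line has no direction. Segments with fewer than
3 samples, or with all gaze points coincident, are skipped.

**Polygon area.** A trajectory that follows a straight line encloses no area.
Cutting the trajectory into non-overlapping windows of \(n\) consecutive
samples (a trailing partial window is dropped) and treating each window's
points as polygon vertices in temporal order, the Shoelace formula

\[
A = \tfrac{1}{2}\sum_i (x_i y_{i+1} - y_i x_{i+1})
\]

gives a signed area whose self-intersection contributions cancel by
orientation; the index is the mean absolute area per window. Window sizes
\(n \in \{15, 30, 45, 60, 90\}\) correspond to 250–1500 ms at 60 Hz. For
cohort reporting, each subject's mean area is divided by the cohort-wide
maximum for that window (both groups pooled), mapping the largest subject
to 1.

## Reference cohort and statistics

The package ships the per-subject index table of the reference pursuit
cohort — nine patients with schizophrenia under treatment and nine controls —
transcribed at its published 2-decimal precision (`reference_cohort()`).
`reproduce_reference_means()` re-averages every column and compares against
the published group-mean row after half-away-from-zero rounding to 2
decimals. Four published means are internally inconsistent with their own
printed subject values (per-sample direction SZ prints 0.66 but the nine
values average 0.64; colocality 10/4 SZ prints 0.95 vs recomputed 0.96;
colocality 15/8 SZ prints 0.97 vs 0.98; area 1000 ms CNT prints 0.06 vs
0.05). These are flagged as documented discrepancies of the source table, not
failures — the per-subject values are taken as authoritative.

Because the samples are small (n = 9) and visibly non-normal (one patient is
an extreme outlier in every colocality column), the group comparison is the
two-sided Wilcoxon–Mann–Whitney test with midrank tie handling, preceded by a
normality screen. The screen is a Lilliefors-type KS test: the KS distance is
computed against a normal with the sample's own mean and SD, and the p-value
comes from a seeded Monte-Carlo simulation of the composite null (default
10,000 draws), because the classical KS null is wrong once parameters are
estimated. Effect sizes are Hedges' g — the pooled-SD standardized mean
difference with the small-sample correction \(J = 1 - 3/(4n - 9)\). Two-sided
tests at \(\alpha = 0.05\), no multiple-testing correction by default (a Holm
option exists), matching the reference analysis. On the shipped table,
colocality (5 mm / 2 mm) separates the groups at p = 0.0029 with g = 0.74,
the regression direction index at p = 0.0008, and every column has
|g| ≥ 0.45. One caveat the package surfaces rather than hides: the
per-sample direction index recomputes to p = 0.12 from the printed subject
values even though the source table stars it, so only the regression index's
significance should be treated as reproducible.

## Classifier harness

The feature vector per subject is one column from each index family; the
default — colocality (5 mm / 2 mm), the regression direction index, and the
normalised 250 ms polygon area — is the most discriminative column of each
family, and is configurable. Indices already live on comparable 0–1 scales,
so no feature scaling is applied. The classifier is a soft-margin SVM with
Gaussian kernel \(k(u, v) = \exp(-\lVert u-v\rVert^2 / 2\sigma^2)\)
(`e1071::svm` with `gamma` = \(1/2\sigma^2\)), evaluated by leave-one-out
cross-validation; hyperparameters come from an exhaustive 50×50 grid over
\(C, \sigma \in \{0.1, 0.2, \dots, 5.0\}\), ties broken towards the smallest
\(C\) then the smallest \(\sigma\). Significance uses a permutation test:
labels are reshuffled B = 1000 times, the LOOCV accuracy recomputed, and
\(p = (1 + \#\{\hat\Theta_b \ge \hat\Theta_{true}\})/(1 + B)\), so the
smallest attainable p is \(1/(B+1)\). Permutations reuse the
original-label hyperparameters; re-running the grid search inside every
permutation is available behind a flag but is 2500× slower, and neither
choice is exactly conservative (fixed hyperparameters ignore selection
variability, per-permutation search gives the null its own optimism).
Stability uses bootstrap resampling of subjects (B = 1000) with percentile
95% intervals; resamples where either class drops below 2 members are redrawn
since LOOCV needs both classes in every training fold, which conditions the
bootstrap on evaluable resamples.

On the reference features this harness reaches 94.4% LOOCV accuracy (17/18;
sensitivity 100%, specificity 88.9%) at C = 0.30, with permutation p ≈ 0.001.
The bootstrap means are lower (≈85% accuracy) because n = 18 resamples often
duplicate the hardest subjects; they are reported for comparison, not as
targets.

## The synthetic gaze simulator

The reference recordings are not redistributable, so the package includes a
generative stand-in (`simulate_gaze()`) that makes every downstream stage
testable end to end. The model has three ingredients, applied to a lagged
copy of the target:

* **tracking noise** — AR(1) isotropic Gaussian jitter (marginal SD
  `jitter_sd_px` per axis, correlation `jitter_ar`) around the target delayed
  by `lag_ms`;
* **attentional lapses** — onsets as a Poisson process (`lapse_rate_per_s`),
  exponential durations (`lapse_duration_s`); during a lapse the gaze
  decouples and performs a *directed* random walk: a random heading is drawn
  per lapse and the gaze drifts `drift_sd_px` px/step along it with isotropic
  scatter of the same scale superimposed;
* **recovery** — after a lapse the gaze closes a fraction `catchup_gain` of
  its positional error per step until back on target.

The lapse drift is directed rather than a plain isotropic walk for two
reasons. Behaviourally, an attentional lapse sends the gaze somewhere — to a
distractor or another screen region — rather than diffusing around the
target. Numerically, an isotropic blob barely rotates the principal axis of a
several-hundred-pixel segment, so no physically plausible isotropic noise
reproduces the large regression-direction values seen in impaired pursuit;
directed excursions do.

The shipped profiles are calibration constants of the simulator, chosen once
so that 9 + 9 simulated cohorts land near the reference cohort's headline
group means, and not revisited: `control_profile()` (jitter 4 px, lag 30 ms,
lapses 0.02/s of mean 0.5 s, drift 2 px, catch-up 0.5) and
`impaired_profile()` (jitter 5 px, lag 30 ms, lapses 0.35/s of mean 0.6 s,
drift 18 px, catch-up 0.5). A note on the lag: pursuit of a predictable
target is largely predictive, with near-zero effective phase lag. A literal
reaction-time lag of 100–200 ms at 250 px/s would displace the gaze 25–50 px —
outside the 5 mm (22 px) target ball at all times — and drive colocality far
below anything observed even in impaired pursuit; 30 ms models the small
residual servo error instead. With 12-replicate calibration runs the
simulated group means are approximately 0.99/0.82 for colocality (5/2),
0.56/0.71 for the per-sample direction index and 0.01/0.22 for the
regression index (control/impaired), each within ±0.15 of the reference
cohort's 0.98/0.87, 0.56/0.66 and 0.09/0.31. This is a regression-tested
soft calibration, not a claim that the simulator reproduces the clinical
population.

What the simulator does **not** model: saccade main-sequence kinematics,
blinks and tracker dropouts, anisotropic or heavy-tailed tracker noise
spectra, head movement, and any medication effect. Passing tests on
synthetic cohorts therefore demonstrate that the pipeline recovers the group
structure its generative model encodes — directionally consistent with the
reference cohort — not that it would classify new clinical recordings at the
reported accuracy.

## Numerical choices and degenerate inputs

* Positions are stored real-valued; only colocality snaps them to the lattice
  (half-away-from-zero, matching the rounding used when comparing against the
  published 2-decimal table).
* Resampling requires at least 2 samples and full coverage of the requested
  window; the error names the uncovered interval. A window of `duration_s`
  at rate `f` yields `round(f * duration_s)` samples starting at 0; by
  default the window is the recorded span plus one step, which makes
  resampling an already-uniform recording at its own rate the identity.
* `reflect_step()` rejects steps longer than both screen dimensions as
  nonphysical; repeated reflection handles corner exits.
* Zero-displacement steps are masked out of all angle computations; the
  per-sample direction index errors if no jointly moving steps remain.
* The Monte-Carlo normality screen errors on zero-variance samples; Hedges' g
  errors on zero pooled SD; the area normaliser errors on all-zero cohorts.
* All stochastic procedures (target direction, gaze simulation, Monte-Carlo
  null, permutations, bootstrap) take explicit seeds, evaluate under a
  temporary RNG state, and restore the caller's `.Random.seed`.

## Problem sizes used in the shipped checks

The test suite exercises the oracle comparisons at 100 random colocality
cases and 1,000 random simple polygons, the uniform-scatter direction limit
at M = 10,000 steps, cohort-recovery ordering over 100 seeded 9 + 9
replicates, permutation-null calibration over 100 synthetic null datasets at
B = 99, and the full 50×50 grid with B = 1000 permutation and bootstrap
replicates on the reference features. The analysis scripts under `analysis/`
run the same stages at the same sizes and write their tables under
`results/`.

## Known limitations

* The reference feature choice is reconstructed: the original analysis does
  not state which colocality pair or which area window enters the classifier.
  The default is the most discriminative column per family; the achieved
  94.4% accuracy happens to match the published point estimate, but the
  bootstrap means do not, and both are sensitive to that choice.
* With 2-decimal fixture data, rank ties are guaranteed; the Mann-Whitney
  test then uses the tie-corrected normal approximation rather than the
  exact distribution.
* The simulator's lapse mechanism is the minimal one that reproduces the
  impaired index pattern; it is not a physiological model of schizophrenic
  pursuit.
* Colocality is quadratic in ball radius per distinct target–gaze offset;
  the implementation memoises on the integer offset, which keeps the default
  grids fast but means pathological trajectories with 840 distinct offsets
  gain nothing from the cache.
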