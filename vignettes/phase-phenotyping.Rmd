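---
title: "Quantifying locust phase state from arena trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying locust phase state from arena trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(locustphase)
```

## The assay and its geometry

Locust nymphs express two behavioral phases. Gregarious animals, reared
crowded, are active and approach conspecifics; solitary animals, reared in
isolation, move little, avoid conspecifics and follow walls. The arena
assay quantifies this: a focal nymph explores a rectangular arena for six
minutes while a stimulus group of gregarious conspecifics sits behind a
partition at one end. `arena_geometry()` models the *open test area* only —
with the default 40 × 30 cm arena and two 7.5 cm deep end chambers, a
25 × 30 cm rectangle. The stimulus zone is the 25% of the test area nearest
the stimulus partition, the opposite zone the 25% at the far end, and a
wall band (default 2 cm, about one nymph body length; the assay literature
reports no standard value) captures thigmotaxis. Zone strips could
alternatively be read as percentages of the full 40 cm box; because the
chambers are inaccessible to the animal we take the accessible-area
reading, and both `test_length` and `stimulus_zone_fraction` are exposed so
the other convention is one configuration change. Zones are closed sets, so
boundary samples count as inside; the mean distance to the stimulus group
is measured to the partition-wall midpoint, a fixed, reproducible proxy for
the (moving) stimulus animals.

## The eleven behavioral parameters

`extract_features()` reduces a uniformly sampled trajectory to the eleven
standard parameters (see `FEATURE_NAMES`). Conventions that the tracker
literature leaves open, fixed here:

* **Occupancy** is attributed per sample — each sample inside a zone
  contributes one sampling interval `dt`. The error relative to exact
  segment intersection is bounded by `dt` per zone crossing, which the
  upsampling property test verifies. Consistently, a trial's duration is
  `n_samples * dt`, so a full 6-minute recording at 12.5 Hz (4500 samples)
  has exactly 360 s of occupancy available.
* **Entries**: an entry is an outside→inside transition between consecutive
  samples, and an animal released inside a zone counts as having entered it
  with latency 0. Whether the original assays counted initial placement as
  an entry is not documented; this package asserts the start-inside
  convention.
* **Censoring**: a zone never entered gets latency equal to the trial
  duration (not a missing value), so every animal has a complete covariate
  vector for the model.
* **Movement bouts** use a hysteresis detector: a bout starts when the
  per-interval speed reaches `start_speed` (default 1 cm/s) and ends when
  it drops to `stop_speed` (default 0.5 cm/s); bouts shorter than
  `min_bout` (default 0.5 s) are discarded. Hysteresis prevents tracking
  jitter from inflating the bout count. Original tracker settings are
  unreported, so all three are configurable (`movement_params()`), and the
  feature-oracle tests hold across a sweep of start thresholds from 0.5 to
  2 cm/s.
* **Total distance moved** sums consecutive displacements with no minimum
  distance filter by default (`min_step` provides one).

Trajectories are exchanged in a plain CSV dialect (`subject_id, phase,
time_s, x_cm, y_cm`) with strict validation: non-uniform sampling beyond
1 µs, duplicate timestamps, and out-of-arena points are rejected, naming
the subject. Tracking dropouts are not imputed; a file with gaps is
rejected (a documented limitation). Times are stored in seconds rather
than frames to stay tracker-agnostic; the default rate of 12.5 Hz is a
common video-tracking export rate, and the feature definitions are
rate-robust within roughly 5–30 Hz (tested).

## The P-sol model

Phase state is scored by binary logistic regression on the untransformed
parameters, with outcome coding fixed project-wide as 1 = solitary,
0 = gregarious:

$$P_{sol} = \frac{e^\eta}{1+e^\eta}, \qquad
  \eta = \beta_0 + \beta_1 X_1 + \dots + \beta_k X_k.$$

`fit_logistic()` maximizes the likelihood by Newton scoring (IRLS),
declaring convergence when the log-likelihood changes by less than 1e-8
(at most 50 iterations); standard errors come from the inverse observed
information, and each coefficient gets a Wald statistic $(\beta/SE)^2$ on
1 df. Units are fixed (cm, s, counts) because the coefficients are
unit-dependent.

Degenerate inputs: complete or quasi-complete separation makes the MLE
diverge; it is flagged when any standardized coefficient
($|\beta|\,\mathrm{sd}(x)$) passes 50 — a pragmatic, configurable
threshold — and reported as an error naming the culprit variables. A
singular information matrix raises a collinearity error. Note that on
*strongly but not pathologically* separated data the likelihood can level
off (all margins large) before the cap is reached; the fit then converges
with large coefficients and huge standard errors, which is the familiar
behavior of mainstream statistics packages and is what makes the end-to-end
simulation study below work.

`forward_stepwise()` mirrors the standard forward-selection build: starting
from the intercept-only model it adds, at each step, the candidate with the
smallest likelihood-ratio p-value if below `p_enter` (default 0.05), and
stops otherwise; ties break toward the larger likelihood gain, then
candidate order; there is no removal step. The original model-building
settings (entry statistic and thresholds) are unreported; the
likelihood-ratio criterion is the most defensible default and is
config-exposed. Candidates whose trial fit raises a separation or
collinearity error are ineligible at that step, since their
likelihood-ratio and Wald inference is undefined. Exact reproduction of the
published coefficient table is impossible without the original 200-animal
recordings and is not attempted.

`psol_reference_model()` ships the published fixed-coefficient discriminant
(TDM, FOM, AI, all negative: activity and attraction lower P-sol). Its
Exp(β) column follows from exponentiating the coefficients; its Wald
statistics are recomputed from the rounded published β/SE and therefore
differ slightly from the originally reported ones, which used unrounded
estimates — the printed test statistics are not recoverable and are not
asserted anywhere in the package.

## Group comparisons

Behavioral and P-sol data are non-normal, so phase contrasts use the
Mann-Whitney U test: U is reported as min(U1, U2); with
$n_1 + n_2 \le 20$ and no ties the two-sided p is exact (full null
distribution of U), otherwise a normal approximation with tie correction
and continuity correction is used — a crossover balancing fidelity and
runtime. One-way ANOVA and the pooled two-sample t (Welch by flag) cover
the approximately normal quantities these studies compare. No
multiple-testing correction is applied across contrasts, matching standard
practice in this assay literature. P-sol distributions are summarized by
the median (midpoint convention) and proportions over five intervals
[0, 0.2), …, [0.6, 0.8), [0.8, 1] — the top interval closed so a score of
exactly 0.8 or 1 lands in it.

## The synthetic cohort generator

No public trajectory recordings exist for this assay, so validation relies
on a simulator that reproduces the *qualitative* phase contrast: a
two-state (pause/move) Markov chain; while moving, step lengths are
positive-truncated normal with mean `speed_mean · dt`, and the heading is a
correlated random walk — the previous heading plus a Gaussian deviate of
standard deviation $1/\sqrt{\kappa}$ — mixed as a unit-vector convex
combination with weight `|stimulus_bias|` toward (or away from) the
stimulus partition and `wall_affinity` along the nearest wall. Walls
reflect specularly, so boundary dwell comes only from `wall_affinity`, not
from the integrator. Per-second transition probabilities are converted per
step as $1-(1-p)^{dt}$.

Defaults (gregarious: start 0.5 /s, stop 0.1 /s, 3 cm/s, bias +0.6;
solitary: start 0.05 /s, stop 0.5 /s, 1.5 cm/s, bias −0.4, wall affinity
0.5) are stipulations — the literature prints no movement statistics — and
were chosen once so that the described contrast (active/attracted vs
inactive/repulsed/wall-following) emerges robustly. Remaining free
parameters were likewise fixed once: `speed_sd = speed_mean/3` (moderate
step-length variability), `turn_concentration = 4` (≈ 0.5 rad heading
deviation per step, a strongly persistent walk). Cohorts draw per-subject
seeds from the master seed up front, so results are reproducible and
independent of generation order.

What passing tests show — and what they do not: the simulator produces
clean, stationary phase contrasts without tracking noise, dropouts,
habituation, or individual variability beyond its stochastic kernels. A
pipeline validated on it is verified as *software* (geometry, features,
fitter, statistics); how sharply real phases separate remains a property of
real data. Under the default contrast the cohorts are so well separated
that a single parameter usually suffices for near-perfect discrimination —
the stepwise model then scores phases at the extremes of the P-sol scale,
which is the designed validation signal, not an empirical claim about
animals.

## Problem sizes and numerics

The validation suite uses: the 100 + 100 cohort design at 6 min / 12.5 Hz
for the end-to-end study (10 seed replicates); 100 replicates of n = 200
for Wald-interval coverage against a known logistic truth; 20 small
(n ≤ 12) datasets against a direct likelihood-maximization oracle (1e-4
agreement); exhaustive Mann-Whitney enumeration for all group sizes up to
6; and 50 random 20-sample trajectories against a brute-force per-sample
feature recomputation. Shorter trials (60–120 s) are used for simulator
distribution properties, where trial length is immaterial. Numerical
conventions: the logistic log-likelihood is computed with a stable
log1p/exponential guard; IRLS weights are floored at 1e-12; trajectory
round-trips write coordinates at full double precision (`%.17g`).

## Known limitations

* Tracking dropouts are rejected, not imputed.
* Zone occupancy is per-sample, not segment-intersected (error ≤ dt per
  crossing).
* The simulator does not model stimulus-animal movement, posture, or
  pharmacological dynamics; treatments are represented only as alternative
  phase parameter sets.
* The reference discriminant is only meaningful for features measured in
  the original units over a 360 s trial.
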