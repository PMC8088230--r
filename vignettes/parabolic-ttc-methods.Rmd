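---
title: "Time-to-contact estimation for parabolic flights: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-to-contact estimation for parabolic flights: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parattc)
library(dplyr)
```

## The problem

An observer watches a ball launched on a parabolic flight that starts and
ends at eye level, sees it only briefly (300 ms at launch, plus one
self-triggered 400-ms window in midflight), and must press a button at the
exact moment the ball would return to eye level. Doing this well requires
an estimate of the remaining time to contact (TTC) from monocular optic
information plus prior knowledge. `parattc` implements the full
computational apparatus for studying this task: the flight geometry, the
optic variables, a gravity-and-size heuristic TTC predictor and its
zero-error structure, an inverse trajectory designer, a generative model
of observer behaviour, and the mixed-model analysis pipeline for the
resulting trial tables.

## Flight geometry

A trajectory is parameterised by the launch depth `z_init`, the landing
point (`x_end`, `z_end`), the flight duration `T`, gravity `g` and the
ball radius `r`, in a right-handed frame with the eye at the origin, y up
and +z toward the launch point. Launch and landing at eye level force the
vertical launch speed to `g*T/2`; the horizontal velocity components are
constant (drag and spin are neglected). The lateral offset is stored as a
magnitude with a `side` label: all geometry is computed on `|x|`, so
left/right mirrors are interchangeable everywhere downstream.

```{r}
spec <- trajectory(z_init = 25.16, x_end = 10.06, z_end = -5.03,
                   flight_time = 3, gs_rel = 0.5)
launch_velocity(spec)
```

## Optic variables and the GS predictor

From the eye, the ball subtends the angular size `theta = 2*atan(r/d)`,
sits at elevation `gamma = atan(y/rho)` above eye level (`rho` the
horizontal distance) and at azimuth `beta = atan2(|x|, z)` from the
initial line of sight (`beta > 90` degrees means the ball has passed
behind the observer's frontal plane). The elevation rate `gamma_dot` is
computed analytically as `(vy*rho - y*rho_dot)/d^2`; a finite-difference
oracle checks it in the tests but never stands in for it.

The gravity-and-size (GS) heuristic combines the known ball size `s = 2r`
and gravity with three of these optic variables into a predicted
remaining TTC:

$$\widehat{TTC}_{GS} \;=\; \frac{2}{g}\,\frac{s}{\theta}\,
\frac{\dot\gamma}{\cos\gamma}.$$

`s/theta` recovers distance from angular size, and `g` converts the
elevation rate into time. Two structural identities pin down the
conventions (and are asserted in the test suite): the prediction equals
the full flight duration at launch for *every* trajectory, and it is
exact throughout flight when the ball lands on the eye (a head-on
approach). Using the exact `theta = 2*atan(r/d)` rather than the
small-angle form leaves a relative error below `(r/d)^2/3`, i.e. under a
millisecond everywhere the package evaluates the model.

For lateral trajectories the predictor is biased: substituting the
parabola into the formula gives, with flight fraction `tau = t/T` and
`phi = tau - tau^2`,

$$\widehat{TTC}_{GS}(\tau) = T\left(\phi'(\tau) -
\phi(\tau)\,\frac{\rho'(\tau)}{\rho(\tau)}\right),$$

so the prediction error is
`-T * tau * (1 + (1 - tau) * rho'/rho)`. It vanishes at launch, grows
positive (overestimation), crosses zero once at the *privileged time*
where

$$\frac{\rho'(\tau^{*})}{\rho(\tau^{*})} = -\frac{1}{1-\tau^{*}},$$

and is negative (severe underestimation) thereafter. Because the
condition involves only the ground track, the privileged *fraction* of
flight time is independent of `T` — the same endpoint triple yields its
zero crossing at the same fraction for a 3-s and a 3.5-s flight.
`privileged_time()` does not use this closed form: it scans the error of
the full optic pipeline on a 1-ms grid and refines the first
positive-to-negative crossing after 5% of flight time by bisection to
1e-6 s; the closed-form condition serves as an independent oracle in the
tests.

```{r}
privileged_time(spec)    # designed to be accurate at 50% of a 3-s flight
```

## Inverse trajectory design

`design_trajectory()` solves the inverse problem: fix two of
(`z_init`, `x_end`, `z_end`), prescribe a target fraction, and solve the
zero-error condition for the third parameter by a 512-point bracketing
scan plus bisection to 1e-10 m. The result is always verified through the
full optic projection (realised fraction within 1e-4 of the target);
head-on geometries are rejected as infeasible because the condition
degenerates (the model is exact throughout, so there is no crossing to
place). When several roots fall in the search interval the smallest free
parameter is returned with a warning, since the package cannot know which
branch an experimenter intends.

The built-in `experiment_trajectories()` set pairs five endpoint triples
(launch depths 23.49–27.47 m) with design fractions 0.3–0.7 and the two
flight durations; its privileged times are re-verified on every
`run_experiment()` call.

## The synthetic observer

No behavioural dataset ships with the package; `generate_dataset()`
creates trial tables with the statistical structure the analyses assume,
so every analysis is testable end to end. The generator emulates:

* **Session layout.** 12 participants, 6 blocks of 120 trials; each of
  the 5 trajectory shapes appears 24 times per block — 20 test trials of
  3 s and 4 control trials of 3.5 s (a 5:1 ratio that discourages rhythm
  but induces a central-tendency bias) — with left/right mirrors
  balanced and order shuffled within block.
* **Viewing policy.** Each participant triggers the midflight window at
  `t_visible ~ N(tvis_base + tvis_gsrel_slope * gs_rel, tvis_sd)`,
  clamped to [0.5, T − 0.7] s (the ball is occluded before 0.3 s plus a
  look-down latency, and always 0.3 s before landing, with a 0.4-s
  window). Seven participants are "early viewers" (baseline drawn from
  0.8–1.3 s) and five "late viewers" (1.7–2.2 s), the two regimes that a
  1.5-s mean-viewing-time split recovers. The default trajectory slope
  (0.118 s per unit design fraction) makes viewing time track the
  trajectory but not the flight duration.
* **Gaze coupling.** Gaze azimuth and vertical gaze rate at reappearance
  are linear in the ball's angular position
  (`gain * angle + intercept + noise`, defaults gain 1, noise 2 deg and
  1.5 deg/s), the generative counterpart of the gaze-prediction
  regressions.
* **Response model.** The prediction is consumed at
  `t_pred = t_visible + 0.2` s (the midpoint of the 400-ms window). Per
  participant strategy: `"gs"` responds at `t_pred + TTC_GS(t_pred)`,
  `"true_ttc"` at the true duration, `"constant_map"` at a fixed time.
  The response is pulled toward the frequent 3-s duration by a convex
  weight `w`, shifted by a constant per-participant bias, and perturbed
  by Gaussian noise with SD `response_sd0 + decay_rate * (T - t_pred)` —
  the *prediction decay* that makes early viewers more variable and
  explains their lower hit rates under the ±50-ms hit criterion. No
  quantitative decay constant is established in the literature for this
  task; the default (0.05 s of SD per second of prediction span, on a
  0.05-s floor) puts hit probabilities in the plausible 0.1–0.45 range.

All randomness flows from one seed; participants are iterated in a fixed
order with column-wise draws, so a dataset is byte-reproducible and
row-level reproducibility survives filtering.

What the generator does **not** emulate: continuous head/eye kinematics,
binocular depth compression of virtual displays, retinal-eccentricity
effects, learning across blocks, or any coupling between gaze accuracy
and the timing response. Passing tests therefore certify the pipeline's
statistical behaviour (coding, recovery, calibration), not the full
richness of human data.

## Analysis pipeline

* **Outlier filter.** Response times outside 1.5 IQR fences within each
  (participant, trajectory, duration) group are dropped; groups smaller
  than 4 are left untouched with a warning. By construction the filter
  can never remove more than half a group.
* **Mixed models.** All models are participant-random-intercept LMMs
  fitted by full maximum likelihood (not REML), so likelihood-ratio
  tests on fixed effects are valid and BICs comparable. Flight duration
  is coded as a 0/1 indicator — the coefficient *is* the mean
  response-time difference in seconds — and the design fraction as a
  numeric fraction (0.3–0.7); the literature does not fix these units,
  so the coding is recorded here and `tidy()` output should be read
  accordingly. Wald 95% intervals are reported; singular fits are
  flagged, in which case fixed effects coincide with pooled OLS.
* **Likelihood-ratio tests.** `2 * (llik_test - llik_null)` against a
  chi-square with df equal to the difference in fixed-effect count;
  nesting is validated, and the statistic is floored at zero against
  convergence jitter.
* **Deming regression.** Closed-form errors-in-variables slope with
  variance ratio `delta = 1` (orthogonal) by default — the right default
  when both axes carry comparable measurement noise and no calibration
  data justify another ratio.
* **GS correspondence.** Per participant and trajectory, the remaining
  response time (`response_time - t_pred`) is Deming-regressed on the
  GS prediction at `t_pred`; the pooled slope gets a participant-level
  nonparametric bootstrap percentile CI (1000 resamples), and an
  across-trajectory LMM regresses the remaining response time on the
  design fraction. One identifiability caveat is worth stating: when
  viewing times vary within a cell, even a fixed-criterion responder
  induces a nonzero slope through `t_pred` (both axes depend on it), so
  the clean null requires a fixed per-participant viewing policy. This
  mirrors the task's real ambiguity — a learnt time mapping can mimic
  model use.
* **Proximity split.** Trials are split per participant and trajectory
  at the median distance between `t_pred` and the privileged time (ties
  to "closer") and the mean signed error compared by Welch's t-test.
* **Multiple testing.** None applied; the analyses are a fixed, small
  family and are reported in full.

## Numerical choices and problem sizes

Grids use 1-ms steps; error profiles stop 1 ms before landing to avoid
the vanishing-distance regime that only head-on flights enter; root
finding is bisection (`uniroot`) at 1e-6 s in time and 1e-10 m in the
design parameter. Degenerate inputs fail loudly with typed conditions:
the eye inside the ball, a ball passing through the eye (undefined
elevation), `cos(gamma) = 0`, zero-variance or uncorrelated Deming
inputs, non-nested LRT models.

The test suite exercises the generator at full session size (8640
trials) where the claim concerns the layout, and at 1–2 blocks for
stochastic recovery properties; interval-coverage properties use 100
seeded replicates of one-block sessions. These sizes give Monte-Carlo
error comfortably below the tolerances being asserted while keeping a
full run in well under a minute.

## Worked example

```{r, fig.width = 6, fig.height = 4}
cfg <- simulation_config(seed = 11)
trials <- generate_dataset(cfg)
kept <- filter_outliers(trials)
kept$pct_removed

rt <- response_time_analysis(kept$trials)
tidy(rt$model)
rt$lrt$chi_square
```

The duration coefficient above is the fitted mean response-time
difference between 3.5-s and 3-s flights for this synthetic cohort; with
the default GS-strategy observers it sits well above zero, and the LRT
against the intercept-only null is decisive. `run_experiment()` wraps
the whole chain and writes a self-describing CSV bundle.

## Known limitations

The observer model is intentionally modular rather than mechanistic: it
reproduces the *regression structure* of the behavioural analyses, not a
process model of interception. Deming pooling assumes exchangeable
participants; the bootstrap CI is percentile-based and mildly
anticonservative with 12 participants. The GS predictor is evaluated on
noiseless optics — perceptual noise on `theta` or `gamma_dot` propagates
nonlinearly and is left to the response-noise terms.
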