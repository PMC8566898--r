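---
title: "Modelling stress-blunted prediction-error signalling: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling stress-blunted prediction-error signalling: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the scientific model behind `stressrl`, the
parameters that matter, what the synthetic-data generator does and does not
emulate, and the design decisions taken where the underlying analysis left
the choice open.

## The task and its generative structure

The task is an instrumental learning paradigm that disentangles reward
from punishment learning. A session has two runs, each containing one
stress and one control block in alternation; the starting condition
alternates across runs (counterbalanced; even participant ids start with
stress by default). Each block introduces three fresh pairs of stimuli —
one gain pair (win 0.5 € or nothing), one loss pair (lose 0.5 € or
nothing), one neutral pair (no monetary outcome) — and presents each pair
24 times in random order, i.e. 72 trials per block and 288 per session.
Within each pair one stimulus ("correct") delivers the better outcome with
probability 0.75 and the other with 0.25, reciprocally; the side on which
the correct stimulus appears is balanced 12/12 within each pair.

Trial timing is not part of the analysed design and was not reported, so
the package defaults are ordinary event-related spacing: a 4-s
stimulus-to-outcome delay and an inter-trial interval drawn uniformly from
[2, 6] s, both configurable in `task_config()`. Timing affects only the
conditioning of the fMRI design matrix, not the learning model.

Missed responses (no key press) produce neither outcome nor value update
and are modelled as a nuisance regressor; the generator's default miss
probability (0.002) reproduces the ~0.2 % rate typical of this paradigm.

## The learning model

Each stimulus of each pair carries a value $Q$, initialised at 0 when the
pair is introduced — the neutral prior midway between the possible
outcomes, chosen because no other initialisation is implied by the task.
On every financial trial the chosen stimulus's value is updated by

$$Q_{chosen}(t+1) = Q_{chosen}(t) + \alpha\,\delta(t), \qquad
  \delta(t) = r(t) - Q_{chosen}(t),$$

with $r(t) \in \{-0.5, 0, 0.5\}$ € and a *signed* learning rate:
$\alpha^{+}$ when $\delta > 0$, $\alpha^{-}$ when $\delta < 0$. A zero
prediction error updates nothing (and, where a binary sign label is
forced, is classed as positive — $\delta \ge 0$ — purely so the labelling
is deterministic). Under these rules $Q$ stays in $[-0.5, 0.5]$ and
$\delta$ in $[-1, 1]$ for any admissible parameters; the test suite checks
this as a property.

Choices follow the standard two-option logistic softmax,
$P(a) = e^{\beta Q_a} / (e^{\beta Q_a} + e^{\beta Q_b})$, the form used
throughout the dual-learning-rate literature. It is implemented via
`plogis` on $\beta\,\Delta Q$ (with `log.p = TRUE` inside the likelihood),
so extreme drives saturate without overflow. Neutral trials carry no
reinforcement, no update, and no likelihood term; their regressors exist
only as columns of no interest in the fMRI model.

## Parameter estimation

`fit_condition()` maximises the choice likelihood per participant and
condition (stress blocks pooled, control blocks pooled) over
$\alpha^{+}, \alpha^{-} \in [0, 1]$ and $\beta \in [0, 20]$ by L-BFGS-B
from 20 seeded uniform random starts. The $\beta$ bound covers
near-deterministic choice at the task's maximal value separation; the
multi-start guards against the known multimodality of dual-learning-rate
likelihoods. Plain maximum likelihood is used — no priors — matching the
most conservative reading of the estimation procedure; a MAP hook would be
the natural extension if shrinkage is wanted.

Two properties of this estimator matter for interpretation and are worth
stating plainly. First, with ~96 financial trials per condition the
per-subject estimates are noisy and pile up at the bounds (a substantial
minority of $\hat\alpha^{+}$ land at 1), so single-subject parameter
differences are weakly identified; group-level statements should rest on
group means over many subjects, and that is how the recovery checks are
framed. Second, the likelihood is *centred* on the generating parameters —
on 2000-trial simulations the truth beats every symmetric ±0.2
perturbation pair on average — but an individual perturbed point
(especially in $\beta$) can win by sampling noise; the test suite
therefore checks the statistically well-defined paired version. A
brute-force grid evaluator (`grid_oracle()`) cross-checks the optimizer:
the multi-start minimum must never exceed the grid minimum.

## Behavioural statistics

`code_correct()` scores each financial trial as correct (chose the
0.75-win stimulus on gain pairs; the 0.75-avoid stimulus on loss pairs).
The manipulation check is a 2 × 2 within-subject ANOVA (condition × block)
on the self-report ratings of stress responders — participants whose mean
rating is strictly higher under stress; with two-level factors no
sphericity correction is needed, and effect sizes are partial
eta-squared. Exactly-null effects (zero sum of squares) report F = 0
rather than 0/0.

Trial-wise accuracy is analysed with a mixed-effects logistic regression
(`lme4::glmer`): condition + valence + block + trial +
condition × valence, with a random intercept per participant. Block and
trial enter as raw numeric covariates (no standardisation; only sign and
significance of the interaction and simple effects are interpreted).
Treatment coding uses control and *loss* as reference levels, so the
`conditionstress:valencegain` coefficient is the stress effect on gain
accuracy relative to loss and comes out *negative* when stress selectively
impairs reward learning — the sign convention in which this interaction is
conventionally reported. Planned simple effects (stress vs control within
each valence) are Wald contrasts on the fixed-effect covariance, the
contrast-matrix approach.

One genuine subtlety the simulations expose: lowering $\alpha^{+}$ alone
impairs loss avoidance too (zero outcomes after negative expectations are
positive prediction errors), so the gain-specificity of the behavioural
effect is a matter of degree driven by the transient phase of learning.
Under the default generator the gain − loss asymmetry is real but modest
(~4 percentage points of accuracy), which is why behavioural significance
at n = 23 is not treated as a pass/fail property of the pipeline.

## The ROI GLM

All fMRI computation operates on ROI-averaged time series at TR = 2 s —
the package's "cluster" is the ROI; voxelwise mapping, small-volume
correction and atlas construction are out of scope.

The first-level design models each trial at two time points: stimulus and
outcome onset, as zero-duration sticks binned to the scan grid (floor
alignment; no microtime upsampling at TR = 2 s) and convolved with the
canonical double-gamma HRF (`dgamma(t, 6, 1) − dgamma(t, 16, 1)/6`, 32-s
support, scaled to unit peak so slopes are per unit modulator at the
response peak). There are six stimulus and six outcome condition × valence
regressors per run, plus parametric modulators on financial trials:
$Q_{chosen}$ at stimulus onset and $\delta$ at outcome onset, separately
for gain and loss in each condition. Modulators are mean-centered within
run and deliberately *not* orthogonalised against their parent sticks
beyond centering — centering alone keeps modulator betas interpretable and
avoids regressor-order dependence. Missing trials get a nuisance stick. A
discrete-cosine basis spanning periods above 128 s plus an intercept
complete the matrix; absent event types are omitted and logged, and a
constant modulator (zero after centering) is dropped with a flag.

`fit_ar1_glm()` fits by OLS, estimates the residual lag-1 autocorrelation,
prewhitens data and design (Cochrane–Orcutt, first observation scaled by
$\sqrt{1-\rho^2}$) and refits; whitened residuals are checked to be
serially flat. Rank deficiency aborts with the offending columns named.
Per-run $\delta$-modulator slopes are combined across runs by
inverse-variance weighting (equal variances reduce to the simple mean).

Second-level inference is the summary-statistics battery over subjects:
one-sample t per condition × valence cell, a paired t for the
control > stress main effect averaged over valences (the blunting test),
and a paired t for the condition × valence interaction. Subjects with
incomplete cells are dropped with a message; fewer than three complete
subjects is an error.

The subsidiary models contain no modulators. The quartile-bin model splits
each cell's prediction errors into four bins of as-equal-as-possible size
by stable sort on (value, trial index) — ties therefore never empty a bin
— and estimates one outcome regressor per bin; interior bin boundaries are
compared across conditions by paired t-tests (zero-variance boundaries are
flagged degenerate, not tested). The sign-split model separates positive
($\delta \ge 0$) from negative prediction errors, and its group analysis
is a condition × sign × valence repeated-measures ANOVA with paired
Cohen's $d$ (mean/sd of differences; undefined at zero variance and
flagged) per cell.

## The synthetic cohort

`effect_spec()` fixes the study conditions the generator emulates:

* 37 participants, of whom a fraction 23/37 are stress responders —
  enforced exactly, by construction of the ratings;
* learning parameters drawn per condition around
  $\alpha^{+}$ = 0.40 (control) vs 0.20 (stress), $\alpha^{-}$ = 0.30,
  $\beta$ = 3 (jitter: sd 0.10 on rates, 1.0 on $\beta$, clamped to
  bounds) — the direction, stress lowering the positive-PE learning rate,
  is the effect under study;
* self-reports on the 1–9 scale: control mean 3, responder stress mean 5,
  sd 1, rounded and clamped; responder status is repaired
  deterministically where rounding would violate it;
* BOLD ground truth: control $\delta$-slope 1.0 (arbitrary units, both
  valences), stress slope multiplied by a blunting factor of 0.3,
  between-subject slope sd 0.3, stimulus/outcome stick amplitudes 0.5/1.0,
  $Q$-modulator slope 0.3, baseline 100, AR(1) noise with $\rho$ = 0.3 and
  innovation sd 1.0. With these values a single subject's slope is
  estimated with SE ≈ 0.25, giving comfortably detectable but not trivial
  second-level effects at n = 23 — "moderate effects at study scale" was
  the calibration target, chosen once;
* optional extensions used by specific analyses: a coupling in [0, 1]
  linking a responder's self-report increase to stronger blunting (for the
  responsivity correlation; default 0), and sign-specific blunting factors
  that scale only the positive or negative part of the stress PE response
  piecewise (for the sign-split analyses; default off).

BOLD is composed as $Y = Xb + \text{AR(1) noise}$ from the participant's
*own* primary design built on their true latent trace, so the generator
and the analysis share conventions exactly and recovery is a genuine
round-trip. The full pipeline (`run_pipeline()`) instead re-estimates the
parameters by maximum likelihood and builds analysis designs from the
*fitted* traces, as the analysed study does — a deliberate mismatch that
mimics reality.

What the generator does **not** emulate: voxel-level images, head motion
and its regressors, physiological noise structure beyond AR(1),
scanner drift beyond what the DCT basis removes (drift is generated as
exactly zero), non-stationary learning strategies, and any dependence of
timing on behaviour. Passing tests therefore demonstrate internal
consistency of the pipeline under its own assumptions — they do not
validate the model against real neural data.

## Problem sizes used by the test suite

The property studies run at sizes chosen to make their statistics
decisive: slope recovery on a 10-subject fixture (every cell within 3
SEs); blunting power and type-I calibration over 100 seeded cohorts each
at the full study size (power ≥ 80 % required; type-I between 1 % and
12 % around the nominal 5 %); bin monotonicity over 20 cohorts of 8
subjects at reduced noise (≥ 19/20 monotone); sign-split detection over 5
cohorts of 16 subjects (≥ 4/5 detected, ≥ 4/5 with larger positive-cell
effect sizes); parameter recovery over 30 subjects (rank correlation
> 0.3) and group ordering over 100 subjects (direction of means).

## Known limitations

* Per-subject dual-$\alpha$ estimates from ~96 trials are noisy and
  bound-inflated; hierarchical or MAP estimation would shrink them but is
  intentionally out of scope.
* The behavioural gain-specificity produced by lowering $\alpha^{+}$ is
  modest at study scale (see above), so the behavioural interaction is
  reported, not asserted.
* The AR(1)+OLS two-step estimator of $\rho$ is slightly biased downward
  in short, heavily parameterised runs; at the default run length the bias
  is immaterial to the slope tests.
* Events are binned to whole scans; at TR = 2 s with jittered ITIs this
  loses sub-scan timing information, a standard and documented
  simplification shared by the generator and the analysis.
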