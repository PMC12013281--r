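---
title: "Modelling serial response time task performance with a hierarchical drift-diffusion model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling serial response time task performance with a hierarchical drift-diffusion model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The task and the scientific question

In the serial response time task (SRTT) a stimulus appears in one of six
horizontal screen locations and the participant presses the spatially
corresponding key. Unbeknownst to the participant, stimulus locations follow
a repeating six-item sequence — either *probabilistically* (each transition
follows the sequence with probability .6, otherwise another location is
drawn) or in a *mixed-deterministic* regime (blocks that follow the sequence
without exception alternate with fully random blocks). Orthogonally, the
sequence may be *revealed* to the participant in advance or remain
*concealed*. Sequence learning shows up as faster and more accurate
responses on sequence-consistent ("regular") trials.

Mean response times conflate several cognitive stages. The two-boundary
drift-diffusion model (DDM) separates them: on each trial, noisy evidence
accumulates from a starting point $\beta$ (anticipatory bias) at average
rate $\delta$ (response selection / information uptake) between two
absorbing boundaries set $\alpha$ apart (response caution); everything
outside the decision — stimulus detection, encoding, motor execution — is
the nondecision time $\theta$. We code the upper boundary as the
sequence-predicted (regular) response, so a starting point above .5 or a
positive drift on regular trials indicates sequence knowledge feeding
response selection. An extended *response-competition* parameter $\xi$
splits nondecision time by the regularity of the *executed* response: a
motor-regular keypress takes $\theta - \xi/2$, a motor-nonregular one
$\theta + \xi/2$, so $\xi > 0$ means practiced (sequence-consistent) motor
responses are executed faster. This parameter isolates motor-level learning
from response selection.

The package implements the full analysis chain for such experiments:
design-faithful trial-plan generation, a synthetic-cohort generator driven
by the DDM, the screening/filtering pipeline, the behavioural statistics,
and hierarchical Bayesian estimation of the cell-wise DDM parameters with
Bayes-factor tests.

## The generative model

`simulate_participant()` is a forward model. A participant receives a
uniformly random six-item permutation as their sequence and a trial plan
from `build_probabilistic_plan()` or `build_mixed_deterministic_plan()`.
Each trial belongs to one design cell: trial type (regular, nonregular,
deterministic) crossed with block pair (14 blocks collapse into 7 pairs).
Cell-wise parameter *trajectories* (`trajectory(start, end, shape)`) state
how each DDM parameter moves over block pairs — constant, linear, or
saturating-exponential with a time constant of one third of the session.
Participants deviate from the group trajectory by one random offset per
parameter on the sampling (link) scale: log for $\alpha$ and $\theta$,
logit for $\beta$, identity for $\delta$ and $\xi$.

Decisions are sampled exactly: the boundary from the closed-form absorption
probability, the decision time by inverse-CDF sampling from the conditional
first-passage distribution on a dense integration grid. The binary outcome
maps to one of six keys so that the behavioural error analyses remain
meaningful: an upper-boundary decision executes the sequence-predicted key.
A lower-boundary decision on a regular trial cannot be correct (there the
correct key *is* the predicted key), so it draws uniformly among the four
non-repeating wrong keys; on a nonregular trial it executes the correct
key, except for a `slip_prob` chance of a random other wrong key.
This preserves the distinction between *rule-adhering* errors (pressing the
sequence-predicted key when the stimulus was nonregular) and other errors
while keeping the decision model binary.

Response deadlines follow the protocol: 900/800/700/600 ms for 24 trials
each in block 1, then 500 ms throughout. Deadline violations and errors
trigger feedback, and the following trial is flagged `post_feedback`.

`preset_scenarios()` ships four groups whose trajectories reproduce the
qualitative signatures of the task: probabilistic groups express learning
through starting point, drift separation and a growing positive $\xi$;
mixed-deterministic groups through strong anticipation (large $\beta$), a
steep nondecision drop and higher caution in deterministic blocks, with a
response-competition effect only when the sequence was concealed. The
preset numbers are illustrative generator defaults — chosen once to produce
plausible RT magnitudes (~300–450 ms), error rates (~10–35 % on nonregular
trials under deadline pressure) and a near-zero screening exclusion rate —
not empirical estimates.

**What the generator does not emulate:** premature responses (excluded
procedurally in the protocol), fatigue or block-break effects, sudden
insight-driven strategy shifts (trajectories are smooth), and any
dependence of the starting point on the upcoming trial type beyond the
fitted cell structure. Passing tests on synthetic cohorts therefore
validate the estimation machinery, not claims about real data.

## Design generation details

Two points the protocol leaves open were fixed as follows:

* Nonregular draws exclude both the previous location (no immediate
  repetitions) and the sequence successor, leaving four candidates. Had the
  successor remained admissible, chance hits would push the realized
  regular proportion above .6; with the exclusion the pooled proportion is
  .6 exactly in expectation (the `nonregular_excludes_successor` flag
  restores the alternative reading).
* Deterministic blocks start at a uniformly drawn cycle phase, restricted
  to phases whose first stimulus differs from the previous block's last
  stimulus so that the no-repetition invariant holds across block
  boundaries.

The first trial of each block is labelled `undefined` (its predecessor
belongs to the previous block); the first four trials of every block are
excluded downstream regardless.

## Data preparation

`screen_participants()` excludes a participant iff in at least one of block
pairs 2–7 the error rate strictly exceeds 50 % or the deadline-violation
rate strictly exceeds 30 % — pair 1 (the deadline ramp) never triggers
exclusion, and "exceeds" is strict, so a participant at exactly the
threshold stays. Denominators are all trials of the block pair; the
too-slow numerator is the deadline-exceeded flag.

`filter_trials()` removes, as a union of independently counted rules:
post-feedback trials, the first four trials of each block, and responses
faster than 20 ms or slower than 2 s. Error responses themselves are
retained — they carry the error-RT and rule-adhering analyses and enter the
DDM likelihood. Deadline-exceeded trials are retained here but dropped from
the DDM likelihood by default (`drop_deadline_exceeded = TRUE`), because
their generation competes with the deadline and the model has no censoring
term; the flag exposes the alternative.

## Behavioural statistics

`aggregate_cells()` averages within participant first, then unweighted
across participants; between-subject 95 % CIs come from the t distribution
on participant means, and within-subject CIs use Cousineau normalization
with the Morey cell-count correction (used for the error-RT figures, where
between-participant level differences would swamp the within effect).

`mixed_anova()` is a classical mixed-design ANOVA on a balanced table of
participant-by-cell means: error-stratum sums of squares,
Greenhouse-Geisser $\varepsilon$ from the pooled within-group covariance of
the cell scores applied to every effect involving a within factor, and
generalized eta-squared with the all-manipulated-factors convention
(SS~effect~ / (SS~effect~ + all error SS)). It is oracle-tested against a
hand-worked decomposition and cross-checked against the multivariate
repeated-measures route (`car::Anova`).

The error analyses follow the task's logic: among error responses on
nonregular trials, excluding response repetitions, the chance probability
of the sequence-predicted key is 1/4 (six keys minus the correct one and
the repetition); `rule_adhering_analysis()` tests the per-participant
proportions against that baseline one-sidedly, mirroring the one-sided
confidence bounds such tests report. Forced-choice interview performance is
tested against 1/5 (six locations minus the probe repetition). Free recall
is scored as correct cyclic successor transitions, because a six-cycle has
six transitions and a full correct report closes the cycle; position-based
matching would miscount reports that start mid-sequence.

## The hierarchical model

For participant $i$, trial $t$ in cell $c$, the likelihood is the Wiener
first-passage density at the observed boundary, with the response-
competition shift of nondecision time. Group-level means are indexed the
way the design warrants: $\beta$, $\delta$, $\theta$ per trial type ×
block pair; $\alpha$ per block kind × block pair (caution is set per
block, not per trial — a trial's type is unknown when caution is set);
$\xi$ per block pair only (motor facilitation does not depend on the
stimulus). `share_beta = TRUE` additionally collapses $\beta$ across trial
types, reflecting that the starting point is set before the stimulus
appears; the default keeps the per-type cells that the figures of such
analyses report. Boundary coding is `"regularity"` by default (upper =
sequence-predicted response); `"accuracy"` coding (upper = correct) is a
switch, since per-trial-type starting-point effects are most naturally
expressed there.

Participant offsets are one random intercept per parameter family, shared
across cells (a per-cell-offset variant would need far more data than a
single session provides). Priors are weakly informative and configurable:
group means normal(0, 1.5) on the link scale, except drift normal(0, 2);
group SDs half-normal(1). The `mean_structure = "linear"` option replaces
free cell means by intercept + centred-block-pair slope per stratum — the
regression approach to learning curves — behind the same interface.

### Sampler

No probabilistic-programming backend with a Wiener likelihood is available
to the package, so the sampler is authored here: adaptive
Metropolis-within-Gibbs with per-quantity random-walk steps tuned to a .44
acceptance rate during warmup, plus three structural moves that the
posterior geometry requires. A *translation* move shifts all intercept-like
group coefficients of a family by $d$ and every participant offset by $-d$
— the likelihood is invariant, so the move is accepted on the prior ratio
and decorrelates the weakly identified group-level/offset split. Two
*adaptive-Metropolis* blocks (one over all group coefficients, one per
participant over its five offsets) propose from a scaled empirical
covariance learned during warmup, handling the strong $\beta$–$\delta$ and
$\alpha$–$\theta$ trade-offs that scalar updates cannot traverse
efficiently. Chains are independently seeded from one integer, making every
fit bit-reproducible.

Convergence is a contract, not an assumption: split-R-hat and effective
sample sizes are computed for all group-level quantities, and a fit with
R-hat > 1.01 or ESS < 400 is flagged (`converged = FALSE`, with a
per-quantity table) rather than silently returned. Short test-scale fits
routinely trip this flag; the recovery and calibration checks assert the
scientific quantities, not the flag.

### Bayes factors

Effects on parameters are tested with Savage-Dickey density ratios on
linear contrasts of group-level cell means (e.g. mean over block pairs of
$\mu^{(\beta)}_{\text{regular}} - \mu^{(\beta)}_{\text{nonregular}}$):
BF~10~ is the prior over posterior density at zero, the prior SD of the
contrast being the one implied by the model's coefficient priors unless
overridden. The posterior density at zero uses a normal approximation to
the contrast draws, with a kernel estimate retained as a cross-check (the
normal approximation is the stable choice when the posterior sits far from
zero, where a kernel tail estimate is vacuous). Savage-Dickey on one fit
was chosen over bridge sampling between refitted models because a single
fit serves many tests and avoids per-test refits; this is a method choice
of this package.

## Numerical choices

* Diffusion coefficient fixed at 1 (avoids the 0.1 legacy convention's
  magnitudes). All times in seconds internally; tables store milliseconds,
  converted at one point.
* The first-passage density uses the standard small-time/large-time series
  with automatic selection of the cheaper series at a 10⁻¹⁰ truncation
  error; the two series agree to 10⁻⁶ across the switch region (tested).
* Inter-trial drift variability uses the closed-form normal-mixture
  density; starting-point and nondecision variability integrate by 7-point
  Gauss-Legendre quadrature. All variabilities default to zero (the basic
  model); the extension exists because the full model is standard in the
  field, but none of the shipped analyses enable it.
* Sampling inverts a trapezoid-rule CDF on an 8192-point grid reaching to
  where the survival function is ~10⁻¹⁰ (decay rate
  $\delta^2/2 + \pi^2/(2\alpha^2)$); interpolation error is far below
  Monte-Carlo noise at the sample sizes used (KS < 0.02 at 10⁵ samples is
  asserted).
* Impossible data (RT at or below the effective nondecision time) yield a
  flagged `-Inf` log-likelihood, never a crash; the sampler treats such
  proposals as rejected and can escape an impossible initial state.
* Initial values are data-driven only where needed ($\theta$ starts below
  the minimum observed RT); everything else starts at the link-scale origin
  with small per-chain jitter.

## Validation and problem sizes

The shipped checks run at sizes chosen to make their statistical claims at
desk scale: design-rate checks pool 50 generated sessions (binomial CI well
inside the ±0.01 band); the likelihood grid search uses 10⁴ trials over a
625-point grid; the main parameter-recovery run uses 12 participants with
$\beta$ and $\delta$ varying over 2 trial types × 2 block pairs (~300
trials per cell) and asserts a truth–posterior-mean correlation ≥ .9 on
the link scale across all cells; interval coverage of a true zero $\xi$ is
checked over 10 replicates of an 8-participant scenario; Bayes-factor
calibration uses 20 null replicates (median BF~01~ > 1) and one
large-effect run (BF~10~ > 10). Recovery scenarios lift the response
deadline (2 s) so that deadline censoring does not interact with the
recovery claim.

## Known limitations

* The sampler is a random-walk scheme; fits at publication scale need more
  draws than the test-scale schedules and remain slower than gradient-based
  samplers would be.
* The DDM assumes serially organized stages; if encoding, selection and
  execution overlap in real SRTT performance, parameter interpretations
  shift. The package estimates the model, it does not adjudicate it.
* Deadline-exceeded trials are dropped from the likelihood rather than
  censored; with heavy truncation (slow parameter regimes) this biases
  estimates, which is why the recovery scenarios lift the deadline.
* The generator's interview model is a simple per-transition knowledge
  probability; it supports the classification logic but is not a model of
  explicit memory.

## A short session

```r
library(srttddm)
presets <- preset_scenarios(n_participants = 12)
cohort <- simulate_cohort(presets$probabilistic_concealed, rng_seed = 1)
prepared <- prepare_dataset(cohort$trials)

rule_adhering_analysis(prepared)

model <- build_ddm_model(prepared)
fit <- fit_ddm_model(model, n_chains = 4, n_warmup = 500, n_draws = 500,
                     seed = 1)
cell_mean_summary(fit)
effect_bayes_factor(fit, regularity_contrast(fit, "delta"))
```
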