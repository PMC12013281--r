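# srttddm

Simulation and drift-diffusion analysis of serial response time task
(SRTT) experiments.

## What problem this solves, and for whom

In the SRTT, stimuli appear in one of six screen locations and
participants press spatially corresponding keys; unbeknownst to them,
locations follow a repeating six-item sequence — probabilistically (60 %
of transitions) or in alternating deterministic and random blocks — and
the sequence may be revealed in advance or concealed. Sequence learning
shows up as faster, more accurate responding on sequence-consistent
("regular") trials. Researchers who want to know *which cognitive stage*
expresses that learning (anticipatory bias, response selection, stimulus
processing, motor execution) need more than mean RTs: they need a process
model.

`srttddm` implements the full analysis chain around an extended
two-boundary drift-diffusion model (DDM). On each trial, evidence
accumulates from starting point β at mean rate δ between boundaries α
apart; nondecision time θ covers encoding and motor execution, and a
response-competition offset ξ splits θ by the regularity of the executed
response (effective nondecision time θ − ξ/2 for a sequence-consistent
keypress, θ + ξ/2 otherwise). With the upper boundary coded as the
sequence-predicted response, anticipation shows up in β, response-
selection learning in δ, and motor facilitation in ξ > 0. Group-level
means of every parameter are estimated per design cell (trial type ×
block pair, with α per block kind and ξ per block pair) in a hierarchical
Bayesian model with participant-level random offsets, and effects are
tested with Savage-Dickey Bayes factors.

The package covers:

* **Design generation** — trial plans for probabilistic and
  mixed-deterministic materials (14 blocks × 144 trials, deadline ramp,
  regularity labels), instruction-phase plans, plain-text round trips.
* **Synthetic cohorts** — a DDM-driven forward model with per-cell
  parameter trajectories over block pairs, between-participant variation,
  key-level error semantics and post-experimental interview responses;
  four qualitative group presets ship with the package.
* **Data preparation** — participant screening (error rate > 50 % or
  too-slow rate > 30 % in any of block pairs 2–7), trial filters
  (post-feedback, first four per block, < 20 ms, > 2 s), block pairs.
* **Behavioural statistics** — cell means with between- or within-subject
  CIs, mixed ANOVAs with Greenhouse-Geisser correction and generalized
  eta-squared, rule-adhering error tests against the enumerated 1/4
  chance baseline, error-RT analyses, interview scoring and the
  implicit/intermediate/explicit classification.
* **Hierarchical inference** — Wiener first-passage likelihood (authored
  small-time/large-time series), adaptive Metropolis-within-Gibbs sampler
  with convergence contracts, Bayes factors, awareness-subset refits, and
  parameter-recovery studies.

## Worked example

```r
library(srttddm)
presets <- preset_scenarios(n_participants = 8)
cohort <- simulate_cohort(presets$probabilistic_concealed, rng_seed = 1)
prepared <- prepare_dataset(cohort$trials)
attr(prepared, "filter_counts")
#> post_feedback    first_four  rt_below_min  rt_above_max       removed      retained
#>          4211           448             0             0          4549         11579
```

Eight simulated participants produce 8 × 2,016 = 16,128 trials; the
filters drop post-feedback trials and block warm-ups, leaving 11,579.
Regular trials gain a large RT advantage by the last block pair:

```r
cm <- aggregate_cells(prepared, "rt_correct", c("trial_type", "block_pair"))
subset(cm$group_means, block_pair %in% c(1, 7) & trial_type != "undefined")
#>  trial_type block_pair n  mean ci_lower ci_upper
#>  nonregular          1 8 386.5    361.4    411.6
#>     regular          1 8 401.0    363.4    438.6
#>  nonregular          7 8 432.3    410.0    454.6
#>     regular          7 8 305.2    281.1    329.2
```

Errors on nonregular trials preferentially hit the sequence-predicted key
(chance would be 1/4):

```r
rule_adhering_analysis(prepared)
#> rule-adhering errors: M = 0.317 vs chance 0.25 (n = 8 participants)
#>   one-sided t(7) = 3.42, p = 0.005563
```

The hierarchical DDM separates the processes behind that advantage
(short demo schedule; publication-scale fits need more chains/draws —
under-converged fits say so):

```r
model <- build_ddm_model(prepared, share_beta = TRUE)
fit <- fit_ddm_model(model, n_chains = 2, n_warmup = 400, n_draws = 400,
                     seed = 1)
#> Warning: convergence contract not met (max R-hat = 1.261, min ESS = 5); ...

effect_bayes_factor(fit, regularity_contrast(fit, "delta"))
#> BF10 > 1,000, Savage-Dickey (normal approximation)
#>   contrast posterior: 6.400 (SD 0.065); prior SD 1.069

effect_bayes_factor(fit, mean_level_contrast(fit, "xi"))
#> BF10 > 1,000, Savage-Dickey (normal approximation)
#>   contrast posterior: 0.037 (SD 0.008); prior SD 0.567
```

Evidence accumulation is strongly faster toward regular responses (the
δ contrast of ≈ 6.4 evidence units/s is the regular-minus-nonregular
drift difference under regularity coding), and motor-regular responses
are executed ≈ 37 ms faster (ξ) — the two signatures the generator put
into this preset. The starting point drifts toward the regular boundary
over practice:

```r
s <- cell_mean_summary(fit)
subset(s, family == "beta" & block_pair %in% c(1, 7))
#>  family stratum block_pair mean_natural
#>    beta     all          1        0.461
#>    beta     all          7        0.537
```

A scripted end-to-end run (simulate → prepare → analyze-behavior →
fit-ddm → compare → recover → report) is available through
`run_pipeline()` with a single YAML configuration, or from a shell via
`inst/scripts/srtt-pipeline.R`.

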