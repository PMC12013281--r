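# Shared oracles and fixture builders. Oracles are deliberately independent
# of the implementation paths they check (brute force / tiny-step path
# simulation / hand counting).

# Euler-Maruyama path simulation of the diffusion process: an independent
# sampler for cross-checking densities and closed forms at small n.
euler_diffusion <- function(n, alpha, beta, delta, dt = 1e-4) {
  t_out <- numeric(n)
  upper <- logical(n)
  for (i in seq_len(n)) {
    x <- alpha * beta
    t <- 0
    repeat {
      x <- x + delta * dt + sqrt(dt) * stats::rnorm(1)
      t <- t + dt
      if (x >= alpha) { upper[i] <- TRUE; break }
      if (x <= 0) { upper[i] <- FALSE; break }
    }
    t_out[i] <- t
  }
  data.frame(decision_time = t_out, upper = upper)
}

# Small probabilistic-material scenario with flat or cell-varying truth,
# used by the hierarchical-inference tests.
tiny_scenario <- function(n_participants = 6,
                          beta_reg = 0.5, beta_non = 0.5,
                          delta_reg = 1.8, delta_non = -1.4,
                          xi = 0, sd_xi = 0.01) {
  cohort_scenario(
    material = "probabilistic", instructions = "concealed",
    n_participants = n_participants,
    alpha = trajectory(0.9),
    beta = list(regular = trajectory(beta_reg),
                nonregular = trajectory(beta_non)),
    delta = list(regular = trajectory(delta_reg),
                 nonregular = trajectory(delta_non)),
    theta = trajectory(0.25),
    xi = trajectory(xi),
    sd = c(alpha = 0.1, beta = 0.1, delta = 0.2, theta = 0.08, xi = sd_xi))
}

# Reduced session design without deadline pressure, for inference tests.
tiny_design <- function(n_blocks = 2, trials_per_block = 150) {
  design_config(material = "probabilistic", n_blocks = n_blocks,
                trials_per_block = trials_per_block,
                deadline_schedule = NULL, deadline_main = 2000)
}

# Simulate, screen and filter a tiny cohort in one step.
tiny_prepared <- function(scenario, seed, config = tiny_design()) {
  cohort <- simulate_cohort(scenario, rng_seed = seed,
                            config_fn = function(s) config)
  prepare_dataset(cohort$trials)
}

# Hand-constructable trial records for the filtering / behavioural tests.
make_trials <- function(participant = "P001", block = 1L,
                        n = 12L, stimulus = rep(1:6, length.out = n),
                        predicted = stimulus, pressed = stimulus,
                        rt_ms = rep(400, n), deadline_ms = rep(500, n),
                        block_pair = ceiling(block / 2),
                        trial_type = rep("regular", n)) {
  correct <- pressed == stimulus
  deadline_exceeded <- rt_ms > deadline_ms
  feedback <- !correct | deadline_exceeded
  data.frame(
    participant = participant, material = "probabilistic",
    instructions = "concealed", block = block, block_pair = block_pair,
    trial_in_block = seq_len(n), stimulus = stimulus,
    trial_type = trial_type, block_kind = "probabilistic",
    predicted = predicted, pressed = pressed, rt_ms = rt_ms,
    correct = correct, deadline_ms = deadline_ms,
    deadline_exceeded = deadline_exceeded,
    post_feedback = c(FALSE, feedback[-n]),
    motor_regular = pressed == predicted)
}
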