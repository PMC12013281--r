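#' Parameter trajectory over block pairs
#'
#' Describes how one diffusion parameter of one design cell evolves over the
#' block pairs of a session: from `start` to `end` along a `constant`,
#' `linear` or `exponential` (saturating) path. Values are on the natural
#' parameter scale.
#'
#' @param start,end Values at the first and last block pair.
#' @param shape Interpolation shape. `"exponential"` approaches `end` with a
#'   time constant of one third of the session, so learning is front-loaded.
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(start, end = start,
                       shape = c("linear", "constant", "exponential")) {
  shape <- match.arg(shape)
  if (shape == "constant") end <- start
  structure(list(start = start, end = end, shape = shape),
            class = "trajectory")
}

#' @rdname trajectory
#' @param traj A `trajectory`.
#' @param pair Block-pair index (vectorized), in `1:n_pairs`.
#' @param n_pairs Number of block pairs in the session.
#' @export
trajectory_value <- function(traj, pair, n_pairs) {
  stopifnot(inherits(traj, "trajectory"))
  if (n_pairs == 1L) return(rep(traj$start, length(pair)))
  frac <- (pair - 1) / (n_pairs - 1)
  g <- switch(traj$shape,
    constant = rep(0, length(pair)),
    linear = frac,
    exponential = {
      tau <- 1 / 3
      (1 - exp(-frac / tau)) / (1 - exp(-1 / tau))
    })
  traj$start + (traj$end - traj$start) * g
}

#' Cohort scenario: the generative truth for one experimental group
#'
#' Bundles a group's design cell trajectories, between-participant
#' variation, the residual error ("slip") model and interview knowledge into
#' one generative scenario. Trajectories are keyed by design cell:
#' * `beta`, `delta`, `theta`: a single `trajectory` or a named list with
#'   entries for `regular`, `nonregular` and (mixed material)
#'   `deterministic` trials. `delta` is boundary-coded: the upper boundary is
#'   the sequence-predicted response, so drifts on nonregular trials (where
#'   the correct response is the lower boundary) are negative.
#' * `alpha`: a single `trajectory` or a named list keyed by block kind
#'   (`probabilistic`, `random`, `deterministic`).
#' * `xi`: a single `trajectory` (the response-competition offset is not
#'   cell-specific).
#'
#' Between-participant SDs are on the sampling (link) scale of the
#' hierarchical model: log for `alpha` and `theta`, logit for `beta`,
#' identity for `delta` and `xi`.
#'
#' @param material,instructions Group labels (see [design_config()]).
#' @param n_participants Number of participants to simulate.
#' @param alpha,beta,delta,theta,xi Trajectories (see above).
#' @param sd Named numeric vector of between-participant SDs (link scale)
#'   with names `alpha`, `beta`, `delta`, `theta`, `xi`.
#' @param slip_prob Probability that a lower-boundary decision on a
#'   nonregular trial is executed as a random wrong key instead of the
#'   correct key (keeps the binary decision model while producing
#'   non-rule-adhering errors).
#' @param interview_knowledge Probability that one sequence transition is
#'   reported correctly in the post-experimental interview.
#' @param name Optional scenario label.
#' @return An object of class `cohort_scenario`.
#' @export
cohort_scenario <- function(material, instructions, n_participants,
                            alpha, beta, delta, theta, xi,
                            sd = c(alpha = 0.1, beta = 0.15, delta = 0.25,
                                   theta = 0.08, xi = 0.015),
                            slip_prob = 0.25, interview_knowledge = 0.1,
                            name = NULL) {
  stopifnot(n_participants >= 1,
            slip_prob >= 0, slip_prob <= 1,
            interview_knowledge >= 0, interview_knowledge <= 1,
            all(c("alpha", "beta", "delta", "theta", "xi") %in% names(sd)))
  as_traj_set <- function(x) if (inherits(x, "trajectory")) list(all = x) else x
  structure(list(
    material = material, instructions = instructions,
    n_participants = as.integer(n_participants),
    alpha = as_traj_set(alpha), beta = as_traj_set(beta),
    delta = as_traj_set(delta), theta = as_traj_set(theta),
    xi = as_traj_set(xi), sd = sd, slip_prob = slip_prob,
    interview_knowledge = interview_knowledge,
    name = name %||% paste(material, instructions, sep = "_")
  ), class = "cohort_scenario")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cohort_scenario <- function(x, ...) {
  cat("cohort scenario:", x$name, "\n")
  cat(sprintf("  %s material, %s instructions, %d participants\n",
              x$material, x$instructions, x$n_participants))
  invisible(x)
}

traj_lookup <- function(traj_set, key) {
  traj_set[[key]] %||% traj_set[["all"]] %||%
    stop("no trajectory for cell '", key, "'")
}

link_fun <- function(param) {
  switch(param,
         alpha = log, theta = log,
         beta = stats::qlogis,
         delta = identity, xi = identity)
}

inv_link_fun <- function(param) {
  switch(param,
         alpha = exp, theta = exp,
         beta = stats::plogis,
         delta = identity, xi = identity)
}

# Cell keys used by the generator, per trial.
generator_cell_key <- function(param, eff_type, block_kind) {
  if (param == "alpha") block_kind
  else if (param == "xi") rep("all", length(eff_type))
  else eff_type
}

#' Simulate one participant's SRTT session
#'
#' Runs the forward model: generate a sequence and a trial plan from the
#' design, interpolate the scenario's cell parameters at each trial's block
#' pair, draw a participant-level offset per parameter family (on the link
#' scale), sample a (boundary, decision time) pair from the diffusion model
#' for every trial, and map the binary outcome to a concrete key press:
#' upper-boundary decisions execute the sequence-predicted key, lower-
#' boundary decisions the correct key (on nonregular trials, with
#' probability `slip_prob` a random other wrong key). Deadline violations
#' and post-feedback flags are derived from the sampled response times.
#'
#' @param config A [design_config()].
#' @param scenario A [cohort_scenario()] (material must match the config).
#' @param rng_seed Optional integer seed.
#' @param participant_id Identifier stored in the records.
#' @return A list with `trials` (trial-record data.frame), `sequence`, and
#'   `offsets` (the participant's link-scale offsets).
#' @export
simulate_participant <- function(config, scenario, rng_seed = NULL,
                                 participant_id = "P001") {
  if (!is.null(rng_seed))
    return(with_seed(rng_seed,
                     simulate_participant(config, scenario,
                                          participant_id = participant_id)))
  if (config$material != scenario$material)
    stop("config and scenario disagree on material")
  seq_spec <- generate_sequence(config$n_locations)
  succ <- sequence_successor(seq_spec)
  plan <- if (config$material == "probabilistic")
    build_probabilistic_plan(config, seq_spec)
  else build_mixed_deterministic_plan(config, seq_spec)

  n <- nrow(plan)
  nloc <- config$n_locations
  block_pair <- ceiling(plan$block / 2)
  n_pairs <- config$n_blocks %/% 2L

  prev_stim <- c(NA_integer_, plan$stimulus[-n])
  predicted <- succ[prev_stim]
  # session's very first trial: no predecessor; treat as regular with the
  # stimulus itself predicted (it is labelled undefined and filtered anyway)
  predicted[1L] <- plan$stimulus[1L]
  eff_type <- ifelse(plan$block_kind == "deterministic", "deterministic",
                     ifelse(plan$stimulus == predicted, "regular",
                            "nonregular"))

  params <- c("alpha", "beta", "delta", "theta", "xi")
  offsets <- vapply(params, function(p)
    stats::rnorm(1, 0, scenario$sd[[p]]), numeric(1))

  # per-trial natural-scale parameter values
  val <- lapply(params, function(p) {
    keys <- generator_cell_key(p, eff_type, plan$block_kind)
    out <- numeric(n)
    for (k in unique(keys)) {
      idx <- keys == k
      tr <- traj_lookup(scenario[[p]], k)
      cell <- trajectory_value(tr, block_pair[idx], n_pairs)
      out[idx] <- inv_link_fun(p)(link_fun(p)(cell) + offsets[[p]])
    }
    out
  })
  names(val) <- params

  # sample decisions in batches of identical (alpha, beta, delta)
  key <- paste(signif(val$alpha, 12), signif(val$beta, 12),
               signif(val$delta, 12))
  upper <- logical(n)
  dtime <- numeric(n)
  for (k in unique(key)) {
    idx <- which(key == k)
    i1 <- idx[1L]
    s <- .sample_wiener_cpp(length(idx), val$alpha[i1], val$delta[i1],
                            val$beta[i1])
    upper[idx] <- s$upper
    dtime[idx] <- s$decision_time
  }

  t0 <- ifelse(upper, val$theta - val$xi / 2, val$theta + val$xi / 2)
  rt_ms <- (dtime + t0) * 1000

  # map the binary decision to a concrete key
  pressed <- integer(n)
  all_keys <- seq_len(nloc)
  for (t in seq_len(n)) {
    correct_key <- plan$stimulus[t]
    prev <- prev_stim[t]
    if (upper[t]) {
      pressed[t] <- predicted[t]
    } else if (eff_type[t] %in% c("regular", "deterministic")) {
      cand <- setdiff(all_keys, c(correct_key, prev))
      pressed[t] <- cand[sample.int(length(cand), 1L)]
    } else { # nonregular, lower boundary: correct unless a slip occurs
      if (stats::runif(1) < scenario$slip_prob) {
        cand <- setdiff(all_keys, c(correct_key, predicted[t], prev))
        pressed[t] <- cand[sample.int(length(cand), 1L)]
      } else {
        pressed[t] <- correct_key
      }
    }
  }

  correct <- pressed == plan$stimulus
  deadline_exceeded <- rt_ms > plan$deadline_ms
  feedback <- !correct | deadline_exceeded
  post_feedback <- c(FALSE, feedback[-n])

  trials <- data.frame(
    participant = participant_id,
    material = config$material,
    instructions = config$instructions,
    block = plan$block,
    block_pair = as.integer(block_pair),
    trial_in_block = plan$trial_in_block,
    stimulus = plan$stimulus,
    trial_type = plan$trial_type,
    block_kind = plan$block_kind,
    predicted = predicted,
    pressed = pressed,
    rt_ms = rt_ms,
    correct = correct,
    deadline_ms = plan$deadline_ms,
    deadline_exceeded = deadline_exceeded,
    post_feedback = post_feedback,
    motor_regular = pressed == predicted
  )
  list(trials = trials, sequence = seq_spec, offsets = offsets)
}

#' Simulate the post-experimental interview
#'
#' Each of the six sequence transitions is known (reported correctly) with
#' probability `interview_knowledge`; unknown forced-choice probes are
#' guessed uniformly over the five admissible successors (so incorrect
#' answers are uniform over the four non-correct candidates). Belief of
#' having worked on sequenced material increases with knowledge.
#'
#' @param scenario A [cohort_scenario()].
#' @param seq_spec The participant's sequence (kept for interface symmetry;
#'   scoring is count-based).
#' @return A one-row data.frame with `belief_sequenced` (logical),
#'   `free_recall_correct` and `forced_choice_correct` (counts 0-6).
#' @export
simulate_interview <- function(scenario, seq_spec) {
  k <- scenario$interview_knowledge
  n_trans <- length(as.integer(seq_spec))
  belief <- stats::runif(1) < (0.15 + 0.85 * k)
  free_recall <- if (belief) stats::rbinom(1, n_trans, k) else 0L
  forced <- stats::rbinom(1, n_trans, k + (1 - k) / 5)
  data.frame(belief_sequenced = belief,
             free_recall_correct = as.integer(free_recall),
             forced_choice_correct = as.integer(forced))
}

#' Simulate a full cohort
#'
#' Concatenates per-participant simulations (with fresh sequences, plans,
#' parameter offsets and interviews) over one or more scenarios. Fully
#' deterministic for a fixed seed.
#'
#' @param scenarios A [cohort_scenario()] or list of them.
#' @param rng_seed Integer seed.
#' @param config_fn Function mapping a scenario to a [design_config()];
#'   defaults to the standard design with the scenario's material and
#'   instructions.
#' @return An object of class `srtt_cohort`: a list with `trials` (all trial
#'   records) and `participants` (one row per participant with group labels
#'   and interview scores).
#' @export
simulate_cohort <- function(scenarios, rng_seed = 1L, config_fn = NULL) {
  if (inherits(scenarios, "cohort_scenario")) scenarios <- list(scenarios)
  if (is.null(config_fn))
    config_fn <- function(sc) design_config(material = sc$material,
                                            instructions = sc$instructions)
  with_seed(rng_seed, {
    trial_list <- list()
    part_list <- list()
    pid <- 0L
    for (sc in scenarios) {
      config <- config_fn(sc)
      for (i in seq_len(sc$n_participants)) {
        pid <- pid + 1L
        id <- sprintf("P%03d", pid)
        sim <- simulate_participant(config, sc, participant_id = id)
        iv <- simulate_interview(sc, sim$sequence)
        trial_list[[pid]] <- sim$trials
        part_list[[pid]] <- cbind(
          data.frame(participant = id, material = sc$material,
                     instructions = sc$instructions, scenario = sc$name),
          iv)
      }
    }
    structure(list(trials = do.call(rbind, trial_list),
                   participants = do.call(rbind, part_list)),
              class = "srtt_cohort")
  })
}

#' @export
print.srtt_cohort <- function(x, ...) {
  cat(sprintf("SRTT cohort: %d participants, %d trials\n",
              nrow(x$participants), nrow(x$trials)))
  print(table(x$participants$material, x$participants$instructions))
  invisible(x)
}
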