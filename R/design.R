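#' Experimental design configuration for an SRTT session
#'
#' Encodes every constant of the serial response time task protocol: six
#' horizontal stimulus locations mapped to six keys, 14 blocks of 144 trials,
#' a response-stimulus interval of 250 ms, and a response deadline that ramps
#' from 900 ms down to the 500 ms main deadline over the first block.
#'
#' @param n_locations Number of stimulus locations (and response keys).
#' @param n_blocks Number of SRTT blocks; must be even (blocks are collapsed
#'   into block pairs downstream).
#' @param trials_per_block Trials per block; must be divisible by
#'   `n_locations`.
#' @param p_regular For probabilistic material: probability that a transition
#'   follows the six-item sequence.
#' @param rsi Response-stimulus interval in ms (recorded, not simulated).
#' @param deadline_schedule Deadline ramp for block 1 as a two-column
#'   data.frame with columns `deadline_ms` and `n_trials`, or `NULL` for a
#'   flat `deadline_main` throughout. The trial counts must sum to
#'   `trials_per_block`.
#' @param deadline_main Response deadline (ms) for all blocks after the ramp.
#' @param material `"probabilistic"` (every transition regular with
#'   probability `p_regular`) or `"mixed_deterministic"` (alternating fully
#'   deterministic and fully random blocks).
#' @param instructions `"concealed"` (sequence never mentioned) or
#'   `"revealed"` (sequence shown and practiced before the task).
#' @param practice_cycles Number of full sequence repetitions in the
#'   instruction phase (revealed conditions only).
#' @param nonregular_excludes_successor If `TRUE` (default), nonregular draws
#'   exclude both the previous location and the sequence successor, so that
#'   the realized regular proportion equals `p_regular` exactly in
#'   expectation. If `FALSE`, only immediate repetitions are excluded and
#'   chance hits inflate the realized rate above `p_regular`.
#'
#' @return An object of class `design_config`.
#' @examples
#' cfg <- design_config()
#' cfg$n_blocks * cfg$trials_per_block  # 2016 trials per session
#' @export
design_config <- function(n_locations = 6L,
                          n_blocks = 14L,
                          trials_per_block = 144L,
                          p_regular = 0.6,
                          rsi = 250,
                          deadline_schedule = default_deadline_schedule(),
                          deadline_main = 500,
                          material = c("probabilistic", "mixed_deterministic"),
                          instructions = c("concealed", "revealed"),
                          practice_cycles = 3L,
                          nonregular_excludes_successor = TRUE) {
  material <- match.arg(material)
  instructions <- match.arg(instructions)
  n_locations <- as.integer(n_locations)
  n_blocks <- as.integer(n_blocks)
  trials_per_block <- as.integer(trials_per_block)
  if (n_locations < 3L) stop("need at least 3 locations")
  if (n_blocks %% 2L != 0L) stop("n_blocks must be even (block pairs)")
  if (trials_per_block %% n_locations != 0L)
    stop("trials_per_block must be divisible by n_locations")
  if (!(p_regular > 0 && p_regular < 1)) stop("p_regular must lie in (0,1)")
  if (!is.null(deadline_schedule)) {
    stopifnot(is.data.frame(deadline_schedule),
              all(c("deadline_ms", "n_trials") %in% names(deadline_schedule)))
    if (sum(deadline_schedule$n_trials) != trials_per_block)
      stop("deadline_schedule trial counts must sum to trials_per_block")
  }
  structure(list(
    n_locations = n_locations, n_blocks = n_blocks,
    trials_per_block = trials_per_block, p_regular = p_regular,
    rsi = rsi, deadline_schedule = deadline_schedule,
    deadline_main = deadline_main, material = material,
    instructions = instructions, practice_cycles = as.integer(practice_cycles),
    nonregular_excludes_successor = isTRUE(nonregular_excludes_successor)
  ), class = "design_config")
}

#' @rdname design_config
#' @export
default_deadline_schedule <- function() {
  data.frame(deadline_ms = c(900, 800, 700, 600, 500),
             n_trials = c(24L, 24L, 24L, 24L, 48L))
}

#' @export
print.design_config <- function(x, ...) {
  cat("SRTT design:", x$material, "material,", x$instructions, "instructions\n")
  cat(sprintf("  %d blocks x %d trials (%d total), %d locations\n",
              x$n_blocks, x$trials_per_block,
              x$n_blocks * x$trials_per_block, x$n_locations))
  cat(sprintf("  p_regular = %.2f, RSI = %g ms, main deadline = %g ms\n",
              x$p_regular, x$rsi, x$deadline_main))
  invisible(x)
}

#' Generate a six-item stimulus sequence
#'
#' Draws a uniformly random permutation of the stimulus locations to serve as
#' the repeating first-order sequence of a participant. Read cyclically, the
#' permutation defines a successor map: the sequence successor of location
#' `order[i]` is `order[i + 1]` (wrapping around).
#'
#' @param n_locations Number of locations.
#' @param rng_seed Optional integer seed; when given, the draw is
#'   reproducible and the caller's RNG state is untouched.
#' @return An integer vector of class `sequence_spec` (a permutation of
#'   `1:n_locations`).
#' @examples
#' s <- generate_sequence(rng_seed = 1)
#' sequence_successor(s)
#' @export
generate_sequence <- function(n_locations = 6L, rng_seed = NULL) {
  if (!is.null(rng_seed)) {
    return(with_seed(rng_seed, generate_sequence(n_locations)))
  }
  ord <- sample.int(n_locations)
  structure(as.integer(ord), class = "sequence_spec")
}

#' Successor map of a sequence
#'
#' @param seq_spec A `sequence_spec` (or plain permutation vector).
#' @return Integer vector `succ` with `succ[loc]` the sequence successor of
#'   location `loc`.
#' @export
sequence_successor <- function(seq_spec) {
  ord <- as.integer(seq_spec)
  n <- length(ord)
  if (!setequal(ord, seq_len(n))) stop("not a permutation")
  succ <- integer(n)
  succ[ord] <- ord[c(2:n, 1L)]
  succ
}

# Evaluate expr under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

deadline_for_trials <- function(config, block) {
  n <- config$trials_per_block
  if (block == 1L && !is.null(config$deadline_schedule)) {
    rep(config$deadline_schedule$deadline_ms, config$deadline_schedule$n_trials)
  } else {
    rep(config$deadline_main, n)
  }
}

new_plan_row_store <- function(config) {
  n <- config$n_blocks * config$trials_per_block
  list(block = integer(n), trial_in_block = integer(n),
       stimulus = integer(n), block_kind = character(n),
       deadline_ms = numeric(n))
}

#' Build a probabilistic-material trial plan
#'
#' Generates the full stimulus plan of one session with probabilistic
#' material: after the (uniformly drawn) first stimulus, each transition
#' follows the sequence successor with probability `p_regular`; otherwise
#' another location is drawn uniformly, excluding the immediate repetition
#' and (by default) the successor itself. Block boundaries are generation-
#' continuous: the first trial of a block uses the last stimulus of the
#' previous block as its predecessor.
#'
#' @param config A `design_config` with `material = "probabilistic"`.
#' @param seq_spec The participant's `sequence_spec`.
#' @param rng_seed Optional integer seed.
#' @return A data.frame of trial plan entries with columns `block`,
#'   `trial_in_block`, `stimulus`, `trial_type`, `block_kind`, `deadline_ms`.
#' @export
build_probabilistic_plan <- function(config, seq_spec, rng_seed = NULL) {
  if (config$material != "probabilistic")
    stop("config$material must be 'probabilistic'")
  if (!is.null(rng_seed))
    return(with_seed(rng_seed, build_probabilistic_plan(config, seq_spec)))
  succ <- sequence_successor(seq_spec)
  nloc <- config$n_locations
  n_total <- config$n_blocks * config$trials_per_block
  stim <- integer(n_total)
  stim[1L] <- sample.int(nloc, 1L)
  for (t in 2:n_total) {
    prev <- stim[t - 1L]
    if (runif(1) < config$p_regular) {
      stim[t] <- succ[prev]
    } else {
      if (config$nonregular_excludes_successor) {
        cand <- setdiff(seq_len(nloc), c(prev, succ[prev]))
      } else {
        cand <- setdiff(seq_len(nloc), prev)
      }
      stim[t] <- cand[sample.int(length(cand), 1L)]
    }
  }
  plan <- data.frame(
    block = rep(seq_len(config$n_blocks), each = config$trials_per_block),
    trial_in_block = rep(seq_len(config$trials_per_block), config$n_blocks),
    stimulus = stim,
    block_kind = "probabilistic",
    deadline_ms = unlist(lapply(seq_len(config$n_blocks),
                                function(b) deadline_for_trials(config, b)))
  )
  label_regularity(plan, seq_spec)
}

#' Build a mixed-deterministic trial plan
#'
#' Generates the stimulus plan of one session with mixed-deterministic
#' material: one parity of blocks (odd or even, drawn at random) follows the
#' six-item sequence without exception, the other parity draws locations
#' uniformly (excluding immediate repetitions). Each deterministic block
#' starts at a uniformly drawn cycle phase whose first stimulus differs from
#' the previous block's last stimulus.
#'
#' @inheritParams build_probabilistic_plan
#' @param config A `design_config` with `material = "mixed_deterministic"`.
#' @return A trial-plan data.frame (see [build_probabilistic_plan()]).
#' @export
build_mixed_deterministic_plan <- function(config, seq_spec, rng_seed = NULL) {
  if (config$material != "mixed_deterministic")
    stop("config$material must be 'mixed_deterministic'")
  if (!is.null(rng_seed))
    return(with_seed(rng_seed,
                     build_mixed_deterministic_plan(config, seq_spec)))
  ord <- as.integer(seq_spec)
  succ <- sequence_successor(seq_spec)
  nloc <- config$n_locations
  det_parity <- sample(c(1L, 0L), 1L) # 1: odd blocks deterministic
  npb <- config$trials_per_block
  stim_all <- integer(0)
  kind_all <- character(0)
  prev <- NA_integer_
  for (b in seq_len(config$n_blocks)) {
    deterministic <- (b %% 2L) == det_parity
    stim <- integer(npb)
    if (deterministic) {
      phases <- seq_len(nloc)
      if (!is.na(prev)) phases <- phases[ord[phases] != prev]
      phase <- phases[sample.int(length(phases), 1L)]
      stim <- ord[((phase - 1L + seq_len(npb) - 1L) %% nloc) + 1L]
    } else {
      for (t in seq_len(npb)) {
        p <- if (t == 1L) prev else stim[t - 1L]
        cand <- if (is.na(p)) seq_len(nloc) else setdiff(seq_len(nloc), p)
        stim[t] <- cand[sample.int(length(cand), 1L)]
      }
    }
    stim_all <- c(stim_all, stim)
    kind_all <- c(kind_all, rep(if (deterministic) "deterministic" else "random", npb))
    prev <- stim[npb]
  }
  plan <- data.frame(
    block = rep(seq_len(config$n_blocks), each = npb),
    trial_in_block = rep(seq_len(npb), config$n_blocks),
    stimulus = stim_all,
    block_kind = kind_all,
    deadline_ms = unlist(lapply(seq_len(config$n_blocks),
                                function(b) deadline_for_trials(config, b)))
  )
  label_regularity(plan, seq_spec)
}

#' Label trial regularity
#'
#' Assigns a `trial_type` to every plan entry: a transition is `regular` iff
#' its stimulus equals the sequence successor of the previous stimulus, else
#' `nonregular`; trials in deterministic blocks are labelled `deterministic`;
#' the first trial of each block is labelled `undefined` (its predecessor
#' belongs to another block and it is excluded downstream anyway).
#'
#' @param plan A trial-plan data.frame with `block`, `stimulus` and
#'   `block_kind` columns.
#' @param seq_spec The participant's `sequence_spec`.
#' @return The plan with a `trial_type` column (re)computed.
#' @export
label_regularity <- function(plan, seq_spec) {
  if (nrow(plan) == 0L) stop("empty plan")
  succ <- sequence_successor(seq_spec)
  if (any(plan$stimulus < 1L | plan$stimulus > length(succ)))
    stop("unknown location index in plan")
  prev <- c(NA_integer_, plan$stimulus[-nrow(plan)])
  first_of_block <- c(TRUE, diff(plan$block) != 0L)
  type <- ifelse(plan$stimulus == succ[prev], "regular", "nonregular")
  type[first_of_block] <- "undefined"
  type[plan$block_kind == "deterministic"] <- "deterministic"
  plan$trial_type <- type
  plan
}

#' Build the instruction-phase practice plan
#'
#' For sequence-revealed conditions: participants see their six-item sequence
#' and practice it for `practice_cycles` full repetitions (18 trials at the
#' default of three cycles).
#'
#' @inheritParams build_probabilistic_plan
#' @return A trial-plan data.frame with `block = 0` and all transitions
#'   `deterministic`-coded as `regular` practice entries.
#' @export
build_instruction_phase <- function(config, seq_spec) {
  if (config$instructions != "revealed")
    stop("instruction phase exists only in the revealed condition")
  ord <- as.integer(seq_spec)
  stim <- rep(ord, config$practice_cycles)
  data.frame(
    block = 0L,
    trial_in_block = seq_along(stim),
    stimulus = stim,
    block_kind = "practice",
    deadline_ms = NA_real_,
    trial_type = c("undefined", rep("regular", length(stim) - 1L))
  )
}
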