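#' Cell means of a dependent variable
#'
#' Aggregates trial records into participant-level cell means and then
#' unweighted group-level means with 95% confidence intervals. Between-
#' subject CIs use the t distribution on the participant means; within-
#' subject CIs use Cousineau-normalized values with the Morey cell-count
#' correction.
#'
#' @param trials Filtered trial-record data.frame.
#' @param dv `"rt_correct"` (mean RT of correct responses, ms),
#'   `"error_rate"`, or `"rt_error"` (mean RT of error responses, ms).
#' @param factors Character vector of grouping columns (e.g.
#'   `c("instructions", "trial_type", "block_pair")`).
#' @param ci `"between"` or `"within"` (Cousineau-Morey); within-subject CIs
#'   treat all `factors` as repeated over participants.
#' @return A list of class `cell_means`: `participant_means` and
#'   `group_means` (with `n`, `mean`, `ci_lower`, `ci_upper`; empty cells
#'   are reported with `n = 0` and `NA` means, not zero).
#' @export
aggregate_cells <- function(trials, dv = c("rt_correct", "error_rate",
                                           "rt_error"),
                            factors, ci = c("between", "within")) {
  dv <- match.arg(dv)
  ci <- match.arg(ci)
  d <- switch(dv,
    rt_correct = transform(trials[trials$correct, ], .y = NA),
    rt_error = transform(trials[!trials$correct, ], .y = NA),
    error_rate = trials)
  d$.y <- switch(dv, error_rate = as.numeric(!d$correct), d$rt_ms)

  fac_list <- c(list(participant = d$participant),
                lapply(factors, function(f) d[[f]]))
  names(fac_list) <- c("participant", factors)
  pm <- stats::aggregate(d$.y, by = fac_list, FUN = mean)
  names(pm)[ncol(pm)] <- "value"

  if (ci == "within") {
    # Cousineau: remove participant means, add back the grand mean
    part_mean <- stats::ave(pm$value, pm$participant, FUN = mean)
    norm_val <- pm$value - part_mean + mean(pm$value)
    n_cells <- nrow(unique(pm[factors]))
    morey <- sqrt(n_cells / max(1, n_cells - 1))
    pm$.ci_val <- mean(pm$value) + (norm_val - mean(pm$value)) * morey
  } else {
    pm$.ci_val <- pm$value
  }

  gsplit <- split(pm, pm[factors], drop = FALSE)
  gm <- do.call(rbind, lapply(names(gsplit), function(k) {
    g <- gsplit[[k]]
    n <- nrow(g)
    lab <- if (n) g[1, factors, drop = FALSE] else {
      parts <- strsplit(k, ".", fixed = TRUE)[[1]]
      stats::setNames(as.data.frame(as.list(parts)), factors)
    }
    m <- if (n) mean(g$value) else NA_real_
    half <- if (n > 1)
      stats::qt(0.975, n - 1) * stats::sd(g$.ci_val) / sqrt(n) else NA_real_
    cbind(lab, data.frame(n = n, mean = m,
                          ci_lower = m - half, ci_upper = m + half))
  }))
  rownames(gm) <- NULL
  pm$.ci_val <- NULL
  structure(list(participant_means = pm, group_means = gm, dv = dv, ci = ci),
            class = "cell_means")
}

#' @export
print.cell_means <- function(x, ...) {
  cat("cell means of", x$dv, "(", x$ci, "CIs )\n")
  print.data.frame(x$group_means, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Chance baseline by candidate enumeration
#'
#' The chance probability of hitting a designated key equals one over the
#' number of admissible candidate locations after the stated exclusions:
#' excluding correct responses and response repetitions from an error
#' analysis leaves 4 of 6 keys (baseline 1/4); excluding only the probe
#' repetition in the forced-choice test leaves 5 (baseline 1/5).
#'
#' @param n_locations Total number of locations/keys.
#' @param exclusions Character vector naming the excluded candidates; each
#'   distinct exclusion removes one location.
#' @return The chance probability.
#' @examples
#' chance_baseline(6, c("correct", "repetition"))  # 0.25
#' chance_baseline(6, "repetition")                # 0.2
#' @export
chance_baseline <- function(n_locations = 6L, exclusions = character()) {
  k <- n_locations - length(unique(exclusions))
  if (k < 1) stop("exclusions leave no admissible candidate")
  1 / k
}

#' Rule-adhering error analysis
#'
#' Among error responses on nonregular trials (response repetitions
#' excluded), computes per participant the proportion of errors whose key is
#' the sequence-predicted key, and tests the proportions against the chance
#' baseline of 1/4 with a one-sided t test. Assumes post-feedback trials
#' were already removed by [filter_trials()].
#'
#' @param trials Filtered trial-record data.frame.
#' @param baseline Chance proportion (default
#'   `chance_baseline(6, c("correct", "repetition"))`).
#' @return A list of class `rule_adhering_result`: `by_participant`
#'   (proportions and counts), `excluded` (participants without qualifying
#'   errors), `mean`, and `test` (the `htest`).
#' @export
rule_adhering_analysis <- function(trials,
                                   baseline = chance_baseline(
                                     6L, c("correct", "repetition"))) {
  d <- trials[!trials$correct & trials$trial_type == "nonregular", ,
              drop = FALSE]
  # response repetition: pressed equals the pressed key of the immediately
  # preceding trial (looked up in the full input, which may be filtered)
  key_all <- paste(trials$participant, trials$block, trials$trial_in_block)
  key_prev <- paste(d$participant, d$block, d$trial_in_block - 1L)
  prev_pressed <- trials$pressed[match(key_prev, key_all)]
  repetition <- !is.na(prev_pressed) & d$pressed == prev_pressed
  d <- d[!repetition, , drop = FALSE]
  if (nrow(d) == 0L) stop("no qualifying error responses")

  prop <- tapply(d$motor_regular, d$participant, mean)
  cnt <- tapply(d$motor_regular, d$participant, length)
  by_participant <- data.frame(participant = names(prop),
                               n_errors = as.integer(cnt),
                               prop_rule_adhering = as.numeric(prop),
                               row.names = NULL)
  all_parts <- unique(trials$participant)
  excluded <- setdiff(all_parts, by_participant$participant)
  test <- if (nrow(by_participant) > 1)
    stats::t.test(by_participant$prop_rule_adhering, mu = baseline,
                  alternative = "greater") else NULL
  structure(list(by_participant = by_participant, excluded = excluded,
                 mean = mean(by_participant$prop_rule_adhering),
                 baseline = baseline, test = test),
            class = "rule_adhering_result")
}

#' @export
print.rule_adhering_result <- function(x, ...) {
  cat(sprintf(
    "rule-adhering errors: M = %.3f vs chance %.2f (n = %d participants",
    x$mean, x$baseline, nrow(x$by_participant)))
  if (length(x$excluded))
    cat(sprintf(", %d without qualifying errors", length(x$excluded)))
  cat(")\n")
  if (!is.null(x$test))
    cat(sprintf("  one-sided t(%d) = %.2f, p = %.4g\n",
                as.integer(x$test$parameter), x$test$statistic,
                x$test$p.value))
  invisible(x)
}

#' Error response times by motor regularity
#'
#' Mean error RT per participant per (motor regularity x block pair) cell,
#' ready for [mixed_anova()] with `response_regularity` as a within factor.
#'
#' @param trials Filtered trial-record data.frame (post-feedback trials
#'   removed).
#' @return A list of class `error_rt_result` with `cell_means` (participant
#'   x cell means, column `value` in ms) and `group_means`.
#' @export
error_rt_analysis <- function(trials) {
  d <- trials[!trials$correct, , drop = FALSE]
  if (nrow(d) == 0L) stop("no error responses in dataset")
  d$response_regularity <- ifelse(d$motor_regular, "motor_regular",
                                  "motor_nonregular")
  agg <- aggregate_cells(d, dv = "rt_error",
                         factors = c("response_regularity", "block_pair"),
                         ci = "within")
  structure(list(cell_means = agg$participant_means,
                 group_means = agg$group_means),
            class = "error_rt_result")
}

#' Score a free-recall report
#'
#' Counts the adjacent pairs of a reported location list that are successor
#' pairs of the sequence; a complete six-item report is scored cyclically
#' (its closing transition counts), so a fully correct report scores 6.
#'
#' @param reported Integer vector of reported locations (possibly empty).
#' @param seq_spec The participant's [generate_sequence()] result.
#' @return Correct-transition count, 0-6.
#' @examples
#' s <- structure(c(2L, 1L, 6L, 5L, 3L, 4L), class = "sequence_spec")
#' score_free_recall(c(2, 1, 6), s)  # 2
#' @export
score_free_recall <- function(reported, seq_spec) {
  succ <- sequence_successor(seq_spec)
  n_loc <- length(succ)
  reported <- as.integer(reported)
  if (length(reported) == 0L) return(0L)
  if (any(is.na(reported) | reported < 1L | reported > n_loc))
    stop("invalid location symbols in report")
  if (length(reported) == n_loc)
    reported <- c(reported, reported[1L]) # cyclic closure
  hits <- sum(succ[reported[-length(reported)]] == reported[-1L])
  as.integer(min(hits, n_loc))
}

#' Classify awareness from interview scores
#'
#' Three-way classification: `implicit` — believed the material was random
#' and reproduced fewer than two transitions in both the free-recall and the
#' forced-choice test; `explicit` — believed it was sequenced and reproduced
#' all six transitions in both tests; `intermediate` — everything in
#' between.
#'
#' @param belief_sequenced Logical (vectorized).
#' @param free_recall_correct,forced_choice_correct Counts 0-6.
#' @return Character vector in `c("implicit", "intermediate", "explicit")`.
#' @export
classify_awareness <- function(belief_sequenced, free_recall_correct,
                               forced_choice_correct) {
  stopifnot(all(free_recall_correct <= 6), all(forced_choice_correct <= 6))
  ifelse(!belief_sequenced & free_recall_correct < 2 &
           forced_choice_correct < 2, "implicit",
         ifelse(belief_sequenced & free_recall_correct == 6 &
                  forced_choice_correct == 6, "explicit", "intermediate"))
}
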