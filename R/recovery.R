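#' Subset refits by awareness class
#'
#' Classifies participants by interview performance (see
#' [classify_awareness()]), splits each experimental group (material x
#' instructions) by class, and re-estimates the hierarchical DDM for every
#' subset with at least `min_n` participants; smaller subsets are reported
#' as skipped.
#'
#' @param trials Filtered trial-record data.frame.
#' @param participants Participant table with interview columns
#'   (`belief_sequenced`, `free_recall_correct`, `forced_choice_correct`).
#' @param min_n Minimum participants per refitted subset.
#' @param build_args,fit_args Lists of extra arguments for
#'   [build_ddm_model()] and [fit_ddm_model()].
#' @return A list of class `subset_refits`: `fits` (named by
#'   `material.instructions.class`), `skipped` (data.frame with sizes), and
#'   `classes` (the per-participant classification).
#' @export
subset_refit <- function(trials, participants, min_n = 4L,
                         build_args = list(), fit_args = list()) {
  cls <- classify_awareness(participants$belief_sequenced,
                            participants$free_recall_correct,
                            participants$forced_choice_correct)
  classes <- data.frame(participant = participants$participant,
                        material = participants$material,
                        instructions = participants$instructions,
                        awareness = cls)
  key <- paste(classes$material, classes$instructions, classes$awareness,
               sep = ".")
  fits <- list()
  skipped <- list()
  for (k in unique(key)) {
    ids <- classes$participant[key == k]
    ids <- intersect(ids, unique(trials$participant))
    if (length(ids) < min_n) {
      skipped[[k]] <- data.frame(subset = k, n = length(ids))
      next
    }
    sub <- trials[trials$participant %in% ids, , drop = FALSE]
    model <- do.call(build_ddm_model, c(list(sub), build_args))
    fits[[k]] <- do.call(fit_ddm_model, c(list(model), fit_args))
  }
  structure(list(fits = fits,
                 skipped = if (length(skipped))
                   do.call(rbind, skipped) else
                     data.frame(subset = character(), n = integer()),
                 classes = classes),
            class = "subset_refits")
}

#' @export
print.subset_refits <- function(x, ...) {
  cat("subset refits:", length(x$fits), "fitted,",
      nrow(x$skipped), "skipped (n < minimum)\n")
  if (nrow(x$skipped)) print.data.frame(x$skipped, row.names = FALSE)
  invisible(x)
}

# Link-scale truth of every model cell under a generative scenario.
truth_cell_means <- function(scenario, model, n_pairs) {
  out <- list()
  for (fam in names(model$cells)) {
    tab <- model$cells[[fam]]
    truth <- vapply(seq_len(nrow(tab)), function(i) {
      key <- tab$stratum[i]
      # the generator keys alpha by block kind and xi by "all"; beta, delta
      # and theta by trial type — same strata the model uses
      tr <- traj_lookup(scenario[[fam]], key)
      link_fun(fam)(trajectory_value(tr, tab$block_pair[i], n_pairs))
    }, numeric(1))
    out[[fam]] <- data.frame(family = fam, stratum = tab$stratum,
                             block_pair = tab$block_pair,
                             truth_link = truth, row.names = NULL)
  }
  do.call(rbind, out)
}

#' Parameter recovery study
#'
#' Simulates cohorts from a known scenario, runs them through the full
#' pipeline (screening, filtering, model building, MCMC), and compares the
#' recovered group-level cell means with the generating truth: link-scale
#' truth-versus-posterior-mean correlation across all cells, per-family
#' correlations, 95% credible-interval coverage per cell, and coverage of
#' the session-average response-competition offset (the natural check when
#' its truth is zero).
#'
#' @param scenario A [cohort_scenario()].
#' @param config A [design_config()] for the simulated sessions (defaults
#'   to the standard design).
#' @param n_reps Number of independent replicates.
#' @param seed Integer seed (replicate r uses `seed + r - 1`).
#' @param build_args,fit_args Extra arguments for [build_ddm_model()] /
#'   [fit_ddm_model()].
#' @return An object of class `recovery_report`: `cells` (per replicate and
#'   cell: truth, posterior mean, interval, coverage), `correlation`
#'   (per replicate, across all cells), `xi_covered` (per replicate), and
#'   `coverage_rate` over all cells and replicates.
#' @export
parameter_recovery <- function(scenario, config = NULL, n_reps = 1L,
                               seed = 1L, build_args = list(),
                               fit_args = list()) {
  if (is.null(config))
    config <- design_config(material = scenario$material,
                            instructions = scenario$instructions)
  n_pairs <- config$n_blocks %/% 2L
  cells <- list()
  correlation <- numeric(n_reps)
  xi_covered <- logical(n_reps)
  for (r in seq_len(n_reps)) {
    cohort <- simulate_cohort(scenario, rng_seed = seed + r - 1L,
                              config_fn = function(sc) config)
    prepared <- prepare_dataset(cohort$trials)
    model <- do.call(build_ddm_model, c(list(prepared), build_args))
    fit <- do.call(fit_ddm_model,
                   c(list(model, seed = seed + 1000L * r), fit_args))
    est <- cell_mean_summary(fit)
    truth <- truth_cell_means(scenario, model, n_pairs)
    stopifnot(nrow(est) == nrow(truth))
    rep_tab <- cbind(rep = r, truth,
                     est[, c("mean_link", "ci_lower", "ci_upper")])
    rep_tab$covered <- rep_tab$truth_link >= rep_tab$ci_lower &
      rep_tab$truth_link <= rep_tab$ci_upper
    cells[[r]] <- rep_tab
    correlation[r] <- stats::cor(rep_tab$truth_link, rep_tab$mean_link)
    xi_c <- mean_level_contrast(fit, "xi")
    xi_draws <- as.numeric(cell_mean_draws(fit, "xi") %*%
                             xi_c[colnames(cell_mean_draws(fit, "xi"))])
    xi_truth <- mean(rep_tab$truth_link[rep_tab$family == "xi"])
    ci <- stats::quantile(xi_draws, c(0.025, 0.975))
    xi_covered[r] <- xi_truth >= ci[1] && xi_truth <= ci[2]
  }
  cells <- do.call(rbind, cells)
  structure(list(cells = cells, correlation = correlation,
                 xi_covered = xi_covered,
                 coverage_rate = mean(cells$covered)),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf(
    "parameter recovery: %d replicate(s); truth-estimate r = %s\n",
    length(x$correlation),
    paste(round(x$correlation, 3), collapse = ", ")))
  cat(sprintf("  95%% interval coverage %.2f; xi-average covered in %d/%d\n",
              x$coverage_rate, sum(x$xi_covered), length(x$xi_covered)))
  invisible(x)
}
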