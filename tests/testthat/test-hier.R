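test_that("model builder lays out cells per parameter family", {
  ps <- preset_scenarios(n_participants = 2)
  coh <- simulate_cohort(ps$probabilistic_concealed, rng_seed = 301)
  prep <- prepare_dataset(coh$trials)
  m <- build_ddm_model(prep)
  # probabilistic material: 2 trial types x 7 block pairs for beta, delta,
  # theta; 7 for alpha (one block kind); 7 for xi
  expect_equal(nrow(m$cells$beta), 14L)
  expect_equal(nrow(m$cells$delta), 14L)
  expect_equal(nrow(m$cells$theta), 14L)
  expect_equal(nrow(m$cells$alpha), 7L)
  expect_equal(nrow(m$cells$xi), 7L)
  # shared starting point collapses its trial types
  ms <- build_ddm_model(prep, share_beta = TRUE)
  expect_equal(nrow(ms$cells$beta), 7L)
  # linear-in-block-pair structure: 2 coefficients per stratum
  ml <- build_ddm_model(prep, mean_structure = "linear")
  expect_equal(ncol(ml$design$delta), 4L) # 2 strata x (intercept, slope)
  expect_equal(ncol(ml$design$xi), 2L)
  # every trial maps to exactly one cell per family
  expect_true(all(m$cell_idx >= 0))
  expect_true(all(m$cell_idx[, 2] < nrow(m$cells$beta)))
})

test_that("mixed material gets the coarser caution index and 3 trial types", {
  ps <- preset_scenarios(n_participants = 2)
  coh <- simulate_cohort(ps$mixed_deterministic_concealed, rng_seed = 302)
  prep <- prepare_dataset(coh$trials)
  m <- build_ddm_model(prep)
  expect_setequal(unique(m$cells$alpha$stratum),
                  c("deterministic", "random"))
  expect_setequal(unique(m$cells$delta$stratum),
                  c("deterministic", "regular", "nonregular"))
  expect_equal(nrow(m$cells$alpha), 14L) # 2 block kinds x 7 pairs
})

test_that("degenerate inputs are rejected", {
  sc <- tiny_scenario(n_participants = 1)
  coh <- simulate_cohort(sc, rng_seed = 303,
                         config_fn = function(s) tiny_design())
  prep <- prepare_dataset(coh$trials)
  expect_error(build_ddm_model(prep), "at least 2 participants")
})

test_that("fits are deterministic for a fixed seed", {
  sc <- tiny_scenario(n_participants = 3)
  prep <- tiny_prepared(sc, seed = 304, config = tiny_design(2, 60))
  m <- build_ddm_model(prep)
  f1 <- suppressWarnings(fit_ddm_model(m, n_chains = 2, n_warmup = 40,
                                       n_draws = 40, seed = 5))
  f2 <- suppressWarnings(fit_ddm_model(m, n_chains = 2, n_warmup = 40,
                                       n_draws = 40, seed = 5))
  expect_identical(f1$chains, f2$chains)
  f3 <- suppressWarnings(fit_ddm_model(m, n_chains = 2, n_warmup = 40,
                                       n_draws = 40, seed = 6))
  expect_false(identical(f1$chains, f3$chains))
  # short fits report their non-convergence instead of failing
  expect_false(f1$converged)
  expect_true(all(c("quantity", "rhat", "ess") %in%
                    names(diagnostics(f1))))
})

test_that("Savage-Dickey machinery is symmetric and has the Lindley limit", {
  sc <- tiny_scenario(n_participants = 4, beta_reg = 0.58, beta_non = 0.45)
  prep <- tiny_prepared(sc, seed = 305, config = tiny_design(2, 102))
  m <- build_ddm_model(prep)
  f <- suppressWarnings(fit_ddm_model(m, n_chains = 2, n_warmup = 150,
                                      n_draws = 150, seed = 7))
  ctr <- regularity_contrast(f, "beta")
  bf_pos <- effect_bayes_factor(f, ctr)
  bf_neg <- effect_bayes_factor(f, -ctr)
  expect_gt(bf_pos$bf10, 0)
  expect_equal(bf_pos$bf10 * bf_pos$bf01, 1)
  # the reversed contrast carries the same evidence (symmetric prior,
  # symmetric normal approximation)
  expect_equal(bf_pos$bf10, bf_neg$bf10, tolerance = 1e-9)
  # Lindley behaviour: an absurdly wide prior drives BF10 to zero
  bf_wide <- effect_bayes_factor(f, ctr, prior_sd = 1e6)
  expect_lt(bf_wide$bf10, 1e-3)
  expect_lt(bf_wide$bf10, bf_pos$bf10)
  # kernel cross-check of the posterior density at zero is in the same
  # ballpark as the normal approximation for a null-centred contrast
  # (the generating theta truth is identical across trial types)
  bf_null <- effect_bayes_factor(
    f, regularity_contrast(f, "theta", "regular", "nonregular"))
  expect_lt(abs(log(bf_null$post_density_kde + 1e-12) -
                  log(bf_null$post_density_normal)), 1)
  expect_error(effect_bayes_factor(f, c("mu_beta[nothere,9]" = 1)),
               "unknown cells")
})

test_that("subset refits honor the minimum group size", {
  sc <- tiny_scenario(n_participants = 6)
  coh <- simulate_cohort(sc, rng_seed = 306,
                         config_fn = function(s) tiny_design(2, 60))
  prep <- prepare_dataset(coh$trials)
  parts <- coh$participants
  # force a 3/3 split: 3 explicit, 3 implicit -> both below min_n = 4
  parts$belief_sequenced <- rep(c(TRUE, FALSE), each = 3)
  parts$free_recall_correct <- rep(c(6L, 0L), each = 3)
  parts$forced_choice_correct <- rep(c(6L, 0L), each = 3)
  out <- subset_refit(prep, parts, min_n = 4,
                      fit_args = list(n_chains = 1, n_warmup = 20,
                                      n_draws = 20))
  expect_length(out$fits, 0)
  expect_equal(sort(out$skipped$n), c(3L, 3L))
  # 4 implicit participants cross the threshold and get fitted
  parts$belief_sequenced <- c(TRUE, TRUE, rep(FALSE, 4))
  parts$free_recall_correct <- c(6L, 6L, rep(0L, 4))
  parts$forced_choice_correct <- c(6L, 6L, rep(0L, 4))
  out2 <- suppressWarnings(subset_refit(
    prep, parts, min_n = 4,
    fit_args = list(n_chains = 1, n_warmup = 20, n_draws = 20)))
  expect_named(out2$fits, "probabilistic.concealed.implicit")
  expect_s3_class(out2$fits[[1]], "ddm_fit")
})

test_that("posterior SDs shrink as trial counts grow", {
  sds <- sapply(c(42, 162), function(tpb) {
    sc <- tiny_scenario(n_participants = 4)
    prep <- tiny_prepared(sc, seed = 307, config = tiny_design(2, tpb))
    m <- build_ddm_model(prep)
    f <- suppressWarnings(fit_ddm_model(m, n_chains = 2, n_warmup = 150,
                                        n_draws = 150, seed = 8))
    mean(cell_mean_summary(f)$sd_link)
  })
  expect_lt(sds[2], sds[1])
})
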