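test_that("cell aggregation averages participants before groups", {
  tr <- rbind(make_trials(participant = "A", n = 8L, rt_ms = rep(400, 8)),
              make_trials(participant = "B", n = 8L, rt_ms = rep(500, 8)))
  cm <- aggregate_cells(tr, "rt_correct", factors = "block_pair")
  expect_equal(cm$group_means$mean, 450)
  expect_equal(cm$group_means$n, 2L)
  # all-correct data: error rate zero everywhere
  er <- aggregate_cells(tr, "error_rate", factors = "block_pair")
  expect_equal(er$group_means$mean, 0)
  # imbalance in trial counts must not tilt the unweighted group mean
  tr2 <- rbind(make_trials(participant = "A", n = 20L, rt_ms = rep(400, 20)),
               make_trials(participant = "B", n = 4L, stimulus = 1:4,
                           rt_ms = rep(500, 4)))
  cm2 <- aggregate_cells(tr2, "rt_correct", factors = "block_pair")
  expect_equal(cm2$group_means$mean, 450)
})

test_that("chance baselines come from candidate enumeration", {
  expect_equal(chance_baseline(6, c("correct", "repetition")), 0.25)
  expect_equal(chance_baseline(6, "repetition"), 0.2)
  expect_equal(chance_baseline(6), 1 / 6)
  expect_error(chance_baseline(2, c("a", "b")), "no admissible")
})

test_that("rule-adhering proportion identifies response-selection bias", {
  # responder that always presses the sequence-predicted key on errors
  tr <- make_trials(n = 40L, stimulus = rep(c(1L, 3L, 5L, 2L), 10),
                    predicted = rep(c(6L, 4L, 2L, 5L), 10))
  tr$trial_type <- "nonregular"
  err_idx <- seq(6, 40, by = 4)
  tr$pressed[err_idx] <- tr$predicted[err_idx]
  tr$correct <- tr$pressed == tr$stimulus
  tr$motor_regular <- tr$pressed == tr$predicted
  tr$post_feedback <- FALSE
  res <- rule_adhering_analysis(tr)
  expect_equal(res$mean, 1.0)
  # uniform-slip errors over the 4 admissible keys: proportion ~ 1/4 and the
  # one-sided test against chance stays non-significant in most replicates
  set.seed(201)
  n_rep <- 60
  sig <- 0
  props <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    trs <- lapply(sprintf("P%02d", 1:12), function(id) {
      d <- make_trials(participant = id, n = 60L,
                       stimulus = rep(c(1L, 3L, 5L, 2L, 6L, 4L), 10),
                       predicted = rep(c(4L, 6L, 2L, 5L, 3L, 1L), 10))
      d$trial_type <- "nonregular"
      err <- seq(5, 60, by = 3)
      for (i in err) {
        cand <- setdiff(1:6, c(d$stimulus[i], d$pressed[i - 1L]))
        d$pressed[i] <- sample(cand, 1)
      }
      d$correct <- d$pressed == d$stimulus
      d$motor_regular <- d$pressed == d$predicted
      d$post_feedback <- FALSE
      d
    })
    res <- rule_adhering_analysis(do.call(rbind, trs))
    props[r] <- res$mean
    sig <- sig + (res$test$p.value < 0.05)
  }
  expect_lt(abs(mean(props) - 0.25), 0.02)
  expect_gte(mean(sig == 0), 0) # bookkeeping; the rate check is below
  expect_lt(sig / n_rep, 0.10)
})

test_that("rule-adhering proportion is invariant to relabeling wrong keys", {
  set.seed(202)
  d <- make_trials(n = 60L, stimulus = rep(c(1L, 3L, 5L, 2L, 6L, 4L), 10),
                   predicted = rep(c(4L, 6L, 2L, 5L, 3L, 1L), 10))
  d$trial_type <- "nonregular"
  err <- seq(5, 60, by = 3)
  for (i in err)
    d$pressed[i] <- sample(setdiff(1:6, c(d$stimulus[i], d$pressed[i - 1L])), 1)
  d$correct <- d$pressed == d$stimulus
  d$motor_regular <- d$pressed == d$predicted
  d$post_feedback <- FALSE
  base <- rule_adhering_analysis(d)$mean
  # cyclically relabel, per trial, the admissible non-predicted wrong keys
  # (correctness, repetition and motor-regularity flags all preserved)
  d2 <- d
  for (i in err) {
    cand <- setdiff(1:6, c(d2$stimulus[i], d2$predicted[i],
                           d2$pressed[i - 1L]))
    j <- match(d2$pressed[i], cand)
    if (!is.na(j)) d2$pressed[i] <- cand[(j %% length(cand)) + 1L]
  }
  d2$correct <- d2$pressed == d2$stimulus
  d2$motor_regular <- d2$pressed == d2$predicted
  expect_equal(rule_adhering_analysis(d2)$mean, base)
})

test_that("participants without qualifying errors are reported, not dropped silently", {
  good <- make_trials(participant = "A", n = 20L)
  good$trial_type <- "nonregular"
  errs <- make_trials(participant = "B", n = 20L,
                      stimulus = rep(c(1L, 3L), 10),
                      predicted = rep(c(4L, 6L), 10))
  errs$trial_type <- "nonregular"
  errs$pressed[c(6, 10, 14)] <- errs$predicted[c(6, 10, 14)]
  errs$correct <- errs$pressed == errs$stimulus
  errs$motor_regular <- errs$pressed == errs$predicted
  errs$post_feedback <- FALSE
  res <- rule_adhering_analysis(rbind(good, errs))
  expect_identical(res$excluded, "A")
  expect_equal(nrow(res$by_participant), 1L)
})

test_that("error RT analysis returns per-cell means of error trials", {
  tr <- make_trials(n = 12L, stimulus = rep(c(1L, 3L, 5L, 2L, 6L, 4L), 2),
                    predicted = rep(c(4L, 6L, 2L, 5L, 3L, 1L), 2))
  tr$pressed[5] <- tr$predicted[5]   # motor-regular error, rt 350
  tr$pressed[9] <- 6L                # motor-nonregular error (stim 5, pred 2)
  tr$rt_ms[5] <- 350
  tr$rt_ms[9] <- 490
  tr$correct <- tr$pressed == tr$stimulus
  tr$motor_regular <- tr$pressed == tr$predicted
  tr$post_feedback <- FALSE
  res <- error_rt_analysis(tr)
  gm <- res$group_means
  expect_equal(gm$mean[gm$response_regularity == "motor_regular"], 350)
  expect_equal(gm$mean[gm$response_regularity == "motor_nonregular"], 490)
})

test_that("motor-regular errors are faster when the offset is positive", {
  sc <- tiny_scenario(n_participants = 10, beta_reg = 0.55, beta_non = 0.45,
                      xi = 0.06)
  coh <- simulate_cohort(sc, rng_seed = 203,
                         config_fn = function(s) tiny_design(4, 150))
  prep <- prepare_dataset(coh$trials)
  res <- error_rt_analysis(prep)
  agg <- tapply(res$cell_means$value, res$cell_means$response_regularity,
                mean)
  expect_lt(agg[["motor_regular"]], agg[["motor_nonregular"]])
})

test_that("free-recall scoring counts cyclic successor transitions", {
  s <- structure(c(2L, 1L, 6L, 5L, 3L, 4L), class = "sequence_spec")
  expect_equal(score_free_recall(c(2, 1, 6, 5, 3, 4), s), 6L)
  expect_equal(score_free_recall(c(2, 1, 6), s), 2L)
  expect_equal(score_free_recall(integer(), s), 0L)
  expect_equal(score_free_recall(c(3, 2, 1), s), 1L) # only 2->1 correct
  expect_error(score_free_recall(c(2, 9), s), "invalid location")
})

test_that("awareness classification follows the interview rules", {
  expect_equal(classify_awareness(FALSE, 1, 0), "implicit")
  expect_equal(classify_awareness(TRUE, 6, 6), "explicit")
  expect_equal(classify_awareness(TRUE, 4, 6), "intermediate")
  expect_equal(classify_awareness(FALSE, 0, 2), "intermediate")
  expect_equal(classify_awareness(c(FALSE, TRUE), c(0, 6), c(0, 6)),
               c("implicit", "explicit"))
})

test_that("within-subject CIs are narrower when participant offsets dominate", {
  set.seed(204)
  tr <- do.call(rbind, lapply(1:10, function(i) {
    d <- make_trials(participant = sprintf("P%02d", i), n = 12L)
    d$rt_ms <- 400 + 80 * i + rep(c(0, 8), 6) + rnorm(12, 0, 4)
    d$trial_type <- rep(c("regular", "nonregular"), 6)
    d
  }))
  cm_b <- aggregate_cells(tr, "rt_correct", "trial_type", ci = "between")
  cm_w <- aggregate_cells(tr, "rt_correct", "trial_type", ci = "within")
  width <- function(x) mean(x$group_means$ci_upper - x$group_means$ci_lower)
  expect_lt(width(cm_w), width(cm_b) / 4)
  expect_equal(cm_w$group_means$mean, cm_b$group_means$mean)
})
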