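test_that("effective nondecision splits the offset symmetrically", {
  expect_equal(effective_nondecision(0.30, 0, TRUE), 0.30)
  expect_equal(effective_nondecision(0.30, 0.04, TRUE), 0.28)
  expect_equal(effective_nondecision(0.30, 0.04, FALSE), 0.32)
  # positive offsets make motor-regular responses faster
  expect_lt(effective_nondecision(0.3, 0.05, TRUE),
            effective_nondecision(0.3, 0.05, FALSE))
  expect_error(effective_nondecision(0.01, 0.04, TRUE), "theta")
  expect_error(diffusion_params(1, 0.5, 1, theta = 0.01, xi = 0.1), "xi")
})

test_that("parameter constructor enforces domain invariants", {
  expect_error(diffusion_params(-1, 0.5, 0), "alpha")
  expect_error(diffusion_params(1, 1.2, 0), "beta")
  expect_error(diffusion_params(1, 0.5, 0, sv = -1), "variabilities")
})

test_that("density normalizes and matches the closed-form split of mass", {
  grid <- expand.grid(alpha = c(0.7, 1, 1.4), beta = c(0.3, 0.5, 0.65),
                      delta = c(-1.5, 0, 2))
  for (i in seq_len(nrow(grid))) {
    p <- diffusion_params(grid$alpha[i], grid$beta[i], grid$delta[i])
    g <- srttddm:::.wiener_cdf_grid_cpp(p$alpha, p$delta, p$beta)
    expect_lt(abs(g$p_lower + g$p_upper - 1), 1e-4)
    expect_lt(abs(g$p_upper - choice_probability(p)), 1e-4)
  }
  # zero drift, central start: half the mass at the upper boundary
  p0 <- diffusion_params(1, 0.5, 0)
  g0 <- srttddm:::.wiener_cdf_grid_cpp(1, 0, 0.5)
  expect_lt(abs(g0$p_upper - 0.5), 1e-6)
  expect_equal(choice_probability(p0), 0.5)
})

test_that("choice probability has the closed form and its limits", {
  p <- diffusion_params(1, 0.5, 1)
  expect_equal(choice_probability(p),
               (1 - exp(-2 * 1 * 1 * 0.5)) / (1 - exp(-2 * 1 * 1)))
  expect_equal(choice_probability(diffusion_params(1, 0.3, 0)), 0.3)
  expect_gt(choice_probability(diffusion_params(1, 0.5, 30)), 1 - 1e-10)
  # monotone in drift and in starting point
  pb <- sapply(c(0.2, 0.4, 0.6, 0.8), function(b)
    choice_probability(diffusion_params(1, b, 0.5)))
  pd <- sapply(c(-1, 0, 1, 2), function(v)
    choice_probability(diffusion_params(1, 0.4, v)))
  expect_true(all(diff(pb) > 0))
  expect_true(all(diff(pd) > 0))
  # Monte-Carlo agreement at alpha=1, beta=0.3, delta=0.8
  p2 <- diffusion_params(1, 0.3, 0.8)
  set.seed(31)
  s <- sample_trials(1e5, p2)
  phat <- mean(s$boundary == "upper")
  expect_lt(abs(phat - choice_probability(p2)),
            3 * sqrt(0.25 / 1e5) + 1e-3)
})

test_that("small-time and large-time series agree in the overlap region", {
  for (w in c(0.3, 0.5, 0.7)) {
    tau <- seq(0.05, 3, length.out = 300)
    small <- srttddm:::.wfpt_f_series(tau, w, 1L, n_terms = 64)
    large <- srttddm:::.wfpt_f_series(tau, w, 2L, n_terms = 64)
    expect_lt(max(abs(small - large)), 1e-6)
    auto <- srttddm:::.wfpt_f_series(tau, w, 0L)
    expect_lt(max(abs(auto - large)), 1e-6)
  }
})

test_that("density is zero at or below the effective nondecision time", {
  p <- diffusion_params(1, 0.5, 1, theta = 0.3, xi = 0.04)
  t0_reg <- 0.28
  expect_equal(fpt_density(c(0.1, t0_reg), p, "upper", TRUE), c(0, 0))
  expect_gt(fpt_density(t0_reg + 0.05, p, "upper", TRUE), 0)
  # shifting by xi moves the support for the motor-nonregular class
  expect_equal(fpt_density(0.31, p, "upper", FALSE), 0)
  expect_gt(fpt_density(0.33, p, "upper", FALSE), 0)
})

test_that("sampler matches the density (KS) and zero-drift mean exit time", {
  p <- diffusion_params(1, 0.4, 1.2)
  set.seed(52)
  s <- sample_trials(1e5, p)
  g <- srttddm:::.wiener_cdf_grid_cpp(p$alpha, p$delta, p$beta)
  for (b in c("upper", "lower")) {
    x <- s$decision_time[s$boundary == b]
    Fb <- if (b == "upper") g$F_upper / g$p_upper else g$F_lower / g$p_lower
    Fn <- approxfun(g$t, Fb, yleft = 0, yright = 1)
    ks <- suppressWarnings(ks.test(x, Fn))
    expect_lt(unname(ks$statistic), 0.02)
  }
  # zero-drift mean decision time alpha^2 beta (1 - beta)
  p0 <- diffusion_params(1, 0.5, 0)
  set.seed(53)
  s0 <- sample_trials(2e5, p0)
  expect_lt(abs(mean(s0$decision_time) - 0.25), 0.005)
  # response times include the effective nondecision time
  p1 <- diffusion_params(1, 0.5, 1, theta = 0.3, xi = 0.04)
  set.seed(54)
  s1 <- sample_trials(1000, p1, motor_regular = TRUE)
  expect_equal(s1$rt - s1$decision_time, rep(0.28, 1000))
})

test_that("path-simulation oracle agrees with the series density machinery", {
  # Euler-Maruyama at a tiny step is an independent route to the same law
  set.seed(61)
  e <- euler_diffusion(2000, alpha = 1, beta = 0.4, delta = 1.2)
  p <- diffusion_params(1, 0.4, 1.2)
  expect_lt(abs(mean(e$upper) - choice_probability(p)), 0.035)
  set.seed(62)
  s <- sample_trials(2e4, p)
  # small positive discretization bias is expected in the Euler times
  expect_lt(abs(mean(e$decision_time) - mean(s$decision_time)), 0.02)
})

test_that("drift-variability density stays normalized and mixes wider", {
  p <- diffusion_params(1, 0.5, 1.5, sv = 0.8)
  tt <- seq(1e-4, 8, length.out = 8000)
  up <- sum(fpt_density(tt, p, "upper")) * diff(tt[1:2])
  lo <- sum(fpt_density(tt, p, "lower")) * diff(tt[1:2])
  expect_lt(abs(up + lo - 1), 1e-3)
  # with uniform nondecision variability the quadrature density integrates to 1
  p2 <- diffusion_params(1, 0.5, 1.5, theta = 0.2, st0 = 0.1)
  tt2 <- seq(1e-4, 8, length.out = 8000)
  tot <- sum(fpt_density(tt2, p2, "upper") +
               fpt_density(tt2, p2, "lower")) * diff(tt2[1:2])
  expect_lt(abs(tot - 1), 1e-3)
})

test_that("trial-set log-likelihood is additive and flags impossible data", {
  p <- diffusion_params(1, 0.45, 1.3, theta = 0.25, xi = 0.04)
  one <- data.frame(rt = 0.5, boundary = "upper", motor_regular = TRUE)
  ll1 <- loglik_trialset(one, p)
  expect_equal(ll1, log(fpt_density(0.5, p, "upper", TRUE)))
  two <- rbind(one, one)
  expect_equal(loglik_trialset(two, p), 2 * ll1)
  bad <- data.frame(rt = 0.2, boundary = "upper", motor_regular = TRUE)
  llb <- loglik_trialset(bad, p)
  expect_identical(unclass(llb)[1], -Inf)
  expect_true(isTRUE(attr(llb, "impossible")))
})

test_that("likelihood surface peaks near the generating parameters", {
  p <- diffusion_params(1, 0.45, 1.6, theta = 0.25)
  set.seed(71)
  s <- sample_trials(4000, p)
  trials <- data.frame(rt = s$rt, boundary = s$boundary,
                       motor_regular = TRUE)
  betas <- seq(0.3, 0.6, 0.05)
  lls <- sapply(betas, function(b)
    loglik_trialset(trials, diffusion_params(1, b, 1.6, theta = 0.25)))
  expect_equal(betas[which.max(lls)], 0.45)
  deltas <- seq(0.8, 2.4, 0.2)
  lld <- sapply(deltas, function(v)
    loglik_trialset(trials, diffusion_params(1, 0.45, v, theta = 0.25)))
  expect_lt(abs(deltas[which.max(lld)] - 1.6), 0.21)
})
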