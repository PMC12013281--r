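#' Build a hierarchical diffusion model from trial records
#'
#' Maps every fitted trial to one design cell per parameter family and
#' assembles the data structures for [fit_ddm_model()]. The group-level
#' structure follows the design: starting point, drift rate and nondecision
#' time get one group mean per (trial type x block pair) cell; boundary
#' separation one mean per (block kind x block pair) — the coarser index
#' reflecting that caution is set per block, not per trial; the response-
#' competition offset one mean per block pair only. Group means live on the
#' sampling (link) scale: log for boundary separation and nondecision time,
#' logit for starting point, identity for drift and response competition.
#' Participants contribute one random offset per parameter family (shared
#' across cells) with a half-normal prior on the group SD.
#'
#' @param trials Filtered trial-record data.frame (see [prepare_dataset()]).
#' @param coding Boundary semantics. `"regularity"` (default): the upper
#'   boundary is the sequence-predicted response, so the observed boundary
#'   is `motor_regular`. `"accuracy"`: the upper boundary is the correct
#'   response of the trial.
#' @param mean_structure `"cell"` — free group means per cell (matches the
#'   per-block-pair figures); `"linear"` — intercept + centred-block-pair
#'   slope per stratum (the regression approach to learning curves).
#' @param share_beta If `TRUE`, the starting point is indexed by block pair
#'   only (one mean across trial types; the starting point is set before
#'   the stimulus reveals the trial type).
#' @param drop_deadline_exceeded Drop deadline-exceeded trials from the
#'   likelihood (their generation competes with the deadline). Default
#'   `TRUE`.
#' @param priors List with `coef_sd` (named per-family prior SDs of the
#'   group-level means on the link scale) and `sd_scale` (half-normal scale
#'   of the group SDs).
#' @return An object of class `ddm_model`.
#' @export
build_ddm_model <- function(trials,
                            coding = c("regularity", "accuracy"),
                            mean_structure = c("cell", "linear"),
                            share_beta = FALSE,
                            drop_deadline_exceeded = TRUE,
                            priors = default_ddm_priors()) {
  coding <- match.arg(coding)
  mean_structure <- match.arg(mean_structure)
  d <- as.data.frame(trials)
  if (any(d$trial_type == "undefined")) {
    warning("dropping trials with undefined regularity")
    d <- d[d$trial_type != "undefined", , drop = FALSE]
  }
  if (drop_deadline_exceeded) d <- d[!d$deadline_exceeded, , drop = FALSE]
  if (nrow(d) == 0L) stop("no trials left to fit")
  parts <- sort(unique(d$participant))
  if (length(parts) < 2L)
    stop("hierarchical model needs at least 2 participants")

  strata <- list(
    alpha = as.character(d$block_kind),
    beta = if (share_beta) rep("all", nrow(d)) else as.character(d$trial_type),
    delta = as.character(d$trial_type),
    theta = as.character(d$trial_type),
    xi = rep("all", nrow(d)))
  fams <- names(strata)

  cells <- list()
  cell_idx <- matrix(0L, nrow(d), 5L)
  for (j in seq_along(fams)) {
    fam <- fams[j]
    lab <- paste(strata[[fam]], d$block_pair, sep = ",")
    tab <- unique(data.frame(stratum = strata[[fam]],
                             block_pair = d$block_pair,
                             stringsAsFactors = FALSE))
    tab <- tab[order(tab$stratum, tab$block_pair), , drop = FALSE]
    rownames(tab) <- NULL
    tab$label <- paste(tab$stratum, tab$block_pair, sep = ",")
    cell_idx[, j] <- match(lab, tab$label) - 1L
    cells[[fam]] <- tab
  }

  design <- list()
  shiftable <- list()
  coef_names <- character()
  prior_coef_sd <- numeric()
  for (fam in fams) {
    tab <- cells[[fam]]
    if (mean_structure == "cell") {
      D <- diag(nrow(tab))
      rownames(D) <- tab$label
      colnames(D) <- paste0("mu_", fam, "[", tab$label, "]")
      psd <- rep(priors$coef_sd[[fam]], nrow(tab))
      shiftable[[fam]] <- rep(1L, nrow(tab))
    } else {
      st <- unique(tab$stratum)
      z <- tab$block_pair - mean(unique(tab$block_pair))
      D <- matrix(0, nrow(tab), 2L * length(st))
      cn <- character(2L * length(st))
      for (s in seq_along(st)) {
        r <- tab$stratum == st[s]
        D[r, 2L * s - 1L] <- 1
        D[r, 2L * s] <- z[r]
        cn[2L * s - 1L] <- paste0(fam, "0[", st[s], "]")
        cn[2L * s] <- paste0(fam, "1[", st[s], "]")
      }
      rownames(D) <- tab$label
      colnames(D) <- cn
      psd <- rep(priors$coef_sd[[fam]], ncol(D))
      shiftable[[fam]] <- rep(c(1L, 0L), length(st))
    }
    design[[fam]] <- D
    coef_names <- c(coef_names, colnames(D))
    prior_coef_sd <- c(prior_coef_sd, psd)
  }

  upper <- if (coding == "regularity") d$motor_regular else d$correct
  structure(list(
    rt_s = d$rt_ms / 1000,
    upper = as.integer(upper),
    motor_regular = as.integer(d$motor_regular),
    participant = match(d$participant, parts) - 1L,
    participants = parts,
    cell_idx = cell_idx,
    cells = cells,
    design = design,
    shiftable = shiftable,
    coef_names = coef_names,
    prior_coef_sd = prior_coef_sd,
    priors = priors,
    coding = coding,
    mean_structure = mean_structure,
    share_beta = share_beta,
    n_trials = nrow(d)
  ), class = "ddm_model")
}

#' @rdname build_ddm_model
#' @export
default_ddm_priors <- function() {
  list(coef_sd = c(alpha = 1.5, beta = 1.5, delta = 2, theta = 1.5,
                   xi = 1.5),
       sd_scale = 1)
}

#' @export
print.ddm_model <- function(x, ...) {
  cat("hierarchical DDM:", x$n_trials, "trials,",
      length(x$participants), "participants,", x$coding, "coding,",
      x$mean_structure, "group-mean structure\n")
  for (fam in names(x$cells))
    cat(sprintf("  %-6s %d cells, %d group-level coefficients\n", fam,
                nrow(x$cells[[fam]]), ncol(x$design[[fam]])))
  invisible(x)
}

#' Fit a hierarchical diffusion model by MCMC
#'
#' Adaptive Metropolis-within-Gibbs over group-level coefficients,
#' participant offsets and group SDs, with step sizes tuned to a 0.44
#' acceptance rate during warmup and frozen afterwards. Runs `n_chains`
#' independent chains (deterministically seeded from `seed`) and computes
#' split-R-hat and effective sample sizes for all group-level quantities.
#' If any group-level R-hat exceeds 1.01 or any effective sample size falls
#' below 400 the fit is flagged as non-converged (`converged = FALSE`, with
#' a per-quantity diagnostics table and a warning) rather than failing
#' silently.
#'
#' @param model A [build_ddm_model()] object.
#' @param n_chains,n_warmup,n_draws MCMC schedule per chain.
#' @param seed Integer seed; fixed seeds give identical draws.
#' @param rhat_max,ess_min Convergence contract for group-level quantities.
#' @return An object of class `ddm_fit`.
#' @export
fit_ddm_model <- function(model, n_chains = 4L, n_warmup = 500L,
                          n_draws = 500L, seed = 1L, rhat_max = 1.01,
                          ess_min = 400) {
  stopifnot(inherits(model, "ddm_model"))
  fams <- names(model$design)
  npart <- length(model$participants)

  init_for_chain <- function(chain) {
    coef <- numeric(length(model$coef_names))
    names(coef) <- model$coef_names
    min_rt <- min(model$rt_s)
    pos <- 1L
    for (fam in fams) {
      D <- model$design[[fam]]
      nc <- ncol(D)
      base <- switch(fam, alpha = 0, beta = 0, delta = 0,
                     theta = log(min(0.8 * min_rt, 0.25)), xi = 0)
      v <- numeric(nc)
      if (model$mean_structure == "cell") {
        v[] <- base
      } else {
        v[seq(1L, nc, by = 2L)] <- base
      }
      jit <- stats::rnorm(nc, 0, 0.05)
      if (fam == "theta") jit <- -abs(jit)
      coef[pos:(pos + nc - 1L)] <- v + jit
      pos <- pos + nc
    }
    coef
  }

  chains <- vector("list", n_chains)
  for (ch in seq_len(n_chains)) {
    chains[[ch]] <- with_seed(seed + ch - 1L, {
      init <- init_for_chain(ch)
      res <- .hier_fit_chain_cpp(
        model$rt_s, model$upper, model$motor_regular, model$participant,
        model$cell_idx, unname(model$design), unname(model$shiftable),
        npart,
        model$prior_coef_sd, model$priors$sd_scale,
        unname(init), rep(0.3, 5), as.integer(n_warmup),
        as.integer(n_draws))
      m <- res$draws
      colnames(m) <- c(model$coef_names, paste0("sd_", fams),
                       as.vector(outer(model$participants, fams,
                                       function(p, f) paste0("u_", f, "[", p, "]"))))
      m
    })
  }

  group_cols <- c(model$coef_names, paste0("sd_", fams))
  diag_tab <- mcmc_diagnostics(chains, group_cols)
  converged <- all(diag_tab$rhat <= rhat_max, na.rm = TRUE) &&
    all(diag_tab$ess >= ess_min, na.rm = TRUE)
  if (!converged)
    warning("convergence contract not met (max R-hat = ",
            round(max(diag_tab$rhat, na.rm = TRUE), 3), ", min ESS = ",
            round(min(diag_tab$ess, na.rm = TRUE)),
            "); inspect diagnostics(fit)")

  structure(list(model = model, chains = chains, n_warmup = n_warmup,
                 n_draws = n_draws, seed = seed,
                 diagnostics = diag_tab, converged = converged),
            class = "ddm_fit")
}

#' Posterior draws of the group-level cell means
#'
#' Reconstructs link-scale cell-mean draws `mu = D coef` for one parameter
#' family from the stored coefficient draws, pooling chains.
#'
#' @param fit A [fit_ddm_model()] object.
#' @param fam One of `"alpha"`, `"beta"`, `"delta"`, `"theta"`, `"xi"`.
#' @return Matrix of draws (rows) by cells (columns, named
#'   `mu_<fam>[stratum,pair]`).
#' @export
cell_mean_draws <- function(fit, fam) {
  D <- fit$model$design[[fam]]
  cols <- colnames(D)
  draws <- do.call(rbind, lapply(fit$chains, function(m) m[, cols, drop = FALSE]))
  out <- draws %*% t(D)
  colnames(out) <- paste0("mu_", fam, "[", rownames(D), "]")
  out
}

#' Posterior summary of all group-level cell means
#'
#' @param fit A `ddm_fit`.
#' @return Data.frame with one row per cell: family, stratum, block pair,
#'   link-scale posterior mean/SD and 95% credible interval, and the
#'   natural-scale posterior mean (inverse link applied per draw).
#' @export
cell_mean_summary <- function(fit) {
  out <- list()
  for (fam in names(fit$model$design)) {
    draws <- cell_mean_draws(fit, fam)
    tab <- fit$model$cells[[fam]]
    inv <- inv_link_fun(fam)
    out[[fam]] <- data.frame(
      family = fam, stratum = tab$stratum, block_pair = tab$block_pair,
      mean_link = colMeans(draws),
      sd_link = apply(draws, 2, stats::sd),
      ci_lower = apply(draws, 2, stats::quantile, 0.025),
      ci_upper = apply(draws, 2, stats::quantile, 0.975),
      mean_natural = colMeans(inv(draws)),
      row.names = NULL)
  }
  do.call(rbind, out)
}

#' @export
print.ddm_fit <- function(x, ...) {
  cat(sprintf("hierarchical DDM fit: %d chains x %d draws (%d warmup)\n",
              length(x$chains), x$n_draws, x$n_warmup))
  cat(sprintf("  converged: %s (max R-hat %.3f, min ESS %d)\n",
              x$converged, max(x$diagnostics$rhat, na.rm = TRUE),
              round(min(x$diagnostics$ess, na.rm = TRUE))))
  invisible(x)
}

#' @rdname fit_ddm_model
#' @param fit A `ddm_fit`.
#' @export
diagnostics <- function(fit) fit$diagnostics

# Split-R-hat and effective sample size for the named columns.
mcmc_diagnostics <- function(chains, cols) {
  split_chains <- function(m) {
    n <- nrow(m)
    h <- n %/% 2L
    list(m[seq_len(h), , drop = FALSE],
         m[(n - h + 1L):n, , drop = FALSE])
  }
  halves <- unlist(lapply(chains, split_chains), recursive = FALSE)
  res <- lapply(cols, function(cl) {
    seqs <- lapply(halves, function(m) m[, cl])
    n <- length(seqs[[1]])
    means <- vapply(seqs, mean, numeric(1))
    vars <- vapply(seqs, stats::var, numeric(1))
    W <- mean(vars)
    B <- n * stats::var(means)
    var_hat <- (n - 1) / n * W + B / n
    rhat <- if (W > 0) sqrt(var_hat / W) else NA_real_
    # ESS from chain-averaged autocovariances (initial positive sequence)
    max_lag <- min(n - 1L, 200L)
    acov <- rowMeans(vapply(seqs, function(x) {
      as.numeric(stats::acf(x, lag.max = max_lag, plot = FALSE,
                            type = "covariance")$acf)
    }, numeric(max_lag + 1L)))
    rho <- 1 - (W - acov) / var_hat
    s <- 0
    t <- 1L
    while (t + 1L <= max_lag) {
      pair <- rho[t + 1L] + rho[t + 2L]
      if (!is.finite(pair) || pair < 0) break
      s <- s + pair
      t <- t + 2L
    }
    ess <- length(seqs) * n / (1 + 2 * s)
    c(rhat = rhat, ess = min(ess, length(seqs) * n))
  })
  out <- as.data.frame(do.call(rbind, res))
  out$quantity <- cols
  out[, c("quantity", "rhat", "ess")]
}
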