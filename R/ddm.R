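#' Diffusion-model parameter vector
#'
#' Parameters of the extended two-boundary drift-diffusion model used
#' throughout the package (diffusion coefficient fixed at 1):
#' * `alpha` — boundary separation (response caution), > 0;
#' * `beta` — relative starting point in (0,1), measured from the lower
#'   boundary (0.5 = unbiased);
#' * `delta` — drift rate (evidence/s); positive drifts favour the upper
#'   boundary;
#' * `theta` — mean nondecision time in seconds (stimulus detection and
#'   encoding plus motor execution);
#' * `xi` — response-competition offset in seconds: the difference in
#'   nondecision time between motor-nonregular and motor-regular responses,
#'   applied as a symmetric split (`theta - xi/2` for motor-regular
#'   executions, `theta + xi/2` otherwise). Positive `xi` means motor-regular
#'   responses are executed faster.
#' * `sv`, `szr`, `st0` — optional inter-trial variabilities (normal in
#'   drift; uniform half-ranges in starting point and nondecision time).
#'
#' @param alpha,beta,delta,theta,xi,sv,szr,st0 Numeric scalars, see above.
#' @return An object of class `diffusion_params`.
#' @examples
#' p <- diffusion_params(alpha = 1, beta = 0.5, delta = 2, theta = 0.3,
#'                       xi = 0.04)
#' choice_probability(p)
#' @export
diffusion_params <- function(alpha, beta, delta, theta = 0, xi = 0,
                             sv = 0, szr = 0, st0 = 0) {
  stopifnot(is.finite(alpha), is.finite(beta), is.finite(delta),
            is.finite(theta), is.finite(xi))
  if (alpha <= 0) stop("alpha must be > 0")
  if (beta <= 0 || beta >= 1) stop("beta must lie in (0,1)")
  if (theta < 0) stop("theta must be >= 0")
  if (theta < abs(xi) / 2)
    stop("theta must be >= |xi|/2 (effective nondecision time must stay >= 0)")
  if (sv < 0 || szr < 0 || st0 < 0) stop("variabilities must be >= 0")
  if (szr > 0 && (beta - szr / 2 <= 0 || beta + szr / 2 >= 1))
    stop("starting-point variability range must stay inside (0,1)")
  structure(list(alpha = alpha, beta = beta, delta = delta, theta = theta,
                 xi = xi, sv = sv, szr = szr, st0 = st0, scale = 1),
            class = "diffusion_params")
}

#' @export
print.diffusion_params <- function(x, ...) {
  cat(sprintf(
    "diffusion params: alpha=%.3f beta=%.3f delta=%.3f theta=%.3f xi=%.3f\n",
    x$alpha, x$beta, x$delta, x$theta, x$xi))
  if (x$sv > 0 || x$szr > 0 || x$st0 > 0)
    cat(sprintf("  variabilities: sv=%.3f szr=%.3f st0=%.3f\n",
                x$sv, x$szr, x$st0))
  invisible(x)
}

#' Effective nondecision time under response competition
#'
#' Motor-regular responses (executed key equals the sequence-predicted key)
#' are executed `xi/2` faster than the mean nondecision time, motor-
#' nonregular responses `xi/2` slower, so that `xi` is the motor-regularity
#' difference in nondecision time.
#'
#' @param theta Mean nondecision time (s).
#' @param xi Response-competition offset (s, signed).
#' @param motor_regular Logical (vectorized): was the executed response the
#'   sequence-predicted one?
#' @return Effective nondecision time(s) in seconds.
#' @export
effective_nondecision <- function(theta, xi, motor_regular) {
  if (any(theta < abs(xi) / 2))
    stop("theta must be >= |xi|/2")
  ifelse(motor_regular, theta - xi / 2, theta + xi / 2)
}

#' First-passage-time density of the diffusion model
#'
#' Density of the observed response time at one boundary, i.e. the Wiener
#' first-passage density of the decision time shifted by the effective
#' nondecision time. Evaluated through the standard small-time/large-time
#' series with automatic switching. Zero for `t` at or below the effective
#' nondecision time. With `sv > 0` the closed-form normal-drift-mixture
#' density is used; `szr`/`st0 > 0` are integrated by Gauss-Legendre
#' quadrature.
#'
#' @param t Response times (s), vectorized.
#' @param params A [diffusion_params()] object.
#' @param boundary `"upper"` or `"lower"`.
#' @param motor_regular Logical scalar: regularity class of the executed
#'   response (determines the nondecision shift).
#' @return Density values (1/s).
#' @export
fpt_density <- function(t, params, boundary = c("upper", "lower"),
                        motor_regular = TRUE) {
  boundary <- match.arg(boundary)
  stopifnot(inherits(params, "diffusion_params"))
  t0 <- effective_nondecision(params$theta, params$xi, motor_regular)
  td <- t - t0
  up <- boundary == "upper"
  if (params$szr == 0 && params$st0 == 0) {
    return(.wiener_pdf_cpp(td, params$alpha, params$delta, params$beta,
                           up, params$sv))
  }
  # quadrature over uniform starting-point and nondecision variability
  gl <- gauss_legendre(7)
  dens <- numeric(length(td))
  wsum <- 0
  zr_nodes <- if (params$szr > 0)
    params$beta + params$szr / 2 * gl$x else params$beta
  zr_w <- if (params$szr > 0) gl$w / 2 else 1
  t0_nodes <- if (params$st0 > 0) params$st0 / 2 * gl$x else 0
  t0_w <- if (params$st0 > 0) gl$w / 2 else 1
  for (i in seq_along(zr_nodes)) {
    for (j in seq_along(t0_nodes)) {
      wgt <- zr_w[i] * t0_w[j]
      dens <- dens + wgt *
        .wiener_pdf_cpp(td - t0_nodes[j], params$alpha, params$delta,
                        zr_nodes[i], up, params$sv)
      wsum <- wsum + wgt
    }
  }
  dens / wsum
}

gauss_legendre <- function(n) {
  # nodes/weights on [-1, 1] via the Golub-Welsch eigenvalue method
  if (n == 1) return(list(x = 0, w = 2))
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  list(x = e$values, w = 2 * e$vectors[1, ]^2)
}

#' Probability of absorption at the upper boundary
#'
#' Closed form for drifted Brownian motion with unit diffusion coefficient:
#' `(1 - exp(-2 delta alpha beta)) / (1 - exp(-2 delta alpha))`, with the
#' martingale limit `beta` at `delta = 0`.
#'
#' @param params A [diffusion_params()] object (variabilities ignored except
#'   `sv = 0` is required).
#' @return Probability of an upper-boundary response.
#' @export
choice_probability <- function(params) {
  stopifnot(inherits(params, "diffusion_params"))
  .p_upper_cpp(params$alpha, params$delta, params$beta)
}

#' Sample trials from the diffusion model
#'
#' Draws (boundary, response time) pairs. The boundary is drawn from the
#' closed-form absorption probability; the decision time from the exact
#' conditional first-passage distribution by inverse-CDF sampling on a dense
#' integration grid. Response times include the effective nondecision time.
#'
#' @param n Number of trials.
#' @param params A [diffusion_params()] object (base model; variabilities
#'   must be zero for sampling).
#' @param motor_regular Logical scalar or vector of length `n`.
#' @return A data.frame with columns `decision_time` (s), `boundary`
#'   (`"upper"`/`"lower"`) and `rt` (s).
#' @export
sample_trials <- function(n, params, motor_regular = TRUE) {
  stopifnot(inherits(params, "diffusion_params"))
  if (params$sv > 0 || params$szr > 0 || params$st0 > 0)
    stop("sampling implemented for the base model (variabilities = 0)")
  out <- .sample_wiener_cpp(as.integer(n), params$alpha, params$delta,
                            params$beta)
  mr <- rep_len(motor_regular, n)
  t0 <- effective_nondecision(params$theta, params$xi, mr)
  data.frame(decision_time = out$decision_time,
             boundary = ifelse(out$upper, "upper", "lower"),
             rt = out$decision_time + t0,
             motor_regular = mr)
}

#' Log-likelihood of a trial set
#'
#' Sum of log first-passage densities over trials under one parameter
#' vector, with the response-competition nondecision split. Data that are
#' impossible under the parameters (a response time at or below the
#' effective nondecision time, or a zero-density point) yield `-Inf` with
#' attribute `impossible = TRUE` rather than an error.
#'
#' @param trials A data.frame with columns `rt` (s), `boundary`
#'   (`"upper"`/`"lower"` or logical `upper`), `motor_regular` (logical).
#' @param params A [diffusion_params()] object.
#' @return Scalar log-likelihood, possibly `-Inf` (attribute `impossible`).
#' @export
loglik_trialset <- function(trials, params) {
  stopifnot(inherits(params, "diffusion_params"))
  upper <- if (is.logical(trials$boundary)) trials$boundary
           else trials$boundary == "upper"
  ll <- .loglik_trialset_cpp(trials$rt, upper,
                             as.logical(trials$motor_regular),
                             params$alpha, params$beta, params$delta,
                             params$theta, params$xi, params$sv)
  if (!is.finite(ll)) attr(ll, "impossible") <- TRUE
  ll
}
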