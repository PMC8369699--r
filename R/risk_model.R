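#' Raw log-odds of disease given a PRS value
#'
#' Bayesian inversion of the normal case and non-case score densities
#' \eqn{p_1, p_0} with prior equal to the prevalence:
#' \deqn{y(x) = \log\frac{K\,p_1(x)}{(1-K)\,p_0(x)}}
#' Evaluated entirely in log space, so it stays finite far into the tails
#' where the raw densities underflow.
#'
#' @param x Numeric vector of PRS values (raw scale).
#' @param cases,noncases [group_moments()] of the two groups.
#' @param K Disease prevalence, strictly in (0, 1).
#' @return Numeric vector of log-odds.
#' @export
raw_log_odds <- function(x, cases, noncases, K) {
  cases <- .check_moments(cases, "cases")
  noncases <- .check_moments(noncases, "noncases")
  .check_prevalence(K)
  stopifnot(is.numeric(x))
  stats::qlogis(K) +
    stats::dnorm(x, cases$mean, sqrt(cases$variance), log = TRUE) -
    stats::dnorm(x, noncases$mean, sqrt(noncases$variance), log = TRUE)
}

#' Raw probability of disease given a PRS value
#'
#' \deqn{\hat P(x) = \frac{K\,p_1(x)}{K\,p_1(x) + (1-K)\,p_0(x)}}
#' the posterior probability of being a case given the score, under normal
#' group densities. When the two densities coincide the score carries no
#' information and \eqn{\hat P(x) = K} everywhere.
#'
#' @inheritParams raw_log_odds
#' @return Numeric vector of probabilities in (0, 1).
#' @export
raw_probability <- function(x, cases, noncases, K) {
  stats::plogis(raw_log_odds(x, cases, noncases, K))
}

#' Closed-form logistic coefficients from summary parameters
#'
#' Computes the intercept and slope of the logistic probability-of-disease
#' model directly from the prevalence and the group moments, with no
#' individual-level data. The coefficients are the weighted least-squares
#' projection of the raw log-odds [raw_log_odds()] onto an affine function
#' of the score, weighted by the population mixture density:
#' \deqn{\beta = \frac{m_1 - m_0}{\sigma_p^2}\left(
#'   K(1-K)\left(\frac{r_0 + r_1}{2} - 1\right)
#'   + K\frac{\sigma_1^2}{\sigma_0^2}
#'   + (1-K)\frac{\sigma_0^2}{\sigma_1^2}\right)}
#' \deqn{\alpha = \log\frac{K\sigma_0}{(1-K)\sigma_1}
#'   + \frac12\big((r_0-1)K + (1-r_1)(1-K)\big) - m_p\,\beta}
#' with \eqn{r_0 = (\sigma_1^2 + (m_1-m_0)^2)/\sigma_0^2},
#' \eqn{r_1 = (\sigma_0^2 + (m_1-m_0)^2)/\sigma_1^2} and
#' \eqn{m_p, \sigma_p^2} the mixture moments.
#'
#' When the two variances are equal the log-odds is exactly affine and the
#' formulas reduce to the discriminant-analysis coefficients
#' \eqn{\beta = (m_1-m_0)/\sigma^2},
#' \eqn{\alpha = \log(K/(1-K)) - (m_1^2 - m_0^2)/(2\sigma^2)}. With unequal
#' variances the true log-odds is quadratic in the score and the affine
#' coefficients are its best population-weighted linear approximation.
#'
#' @inheritParams raw_log_odds
#' @return An object of class `logistic_curve`: fields `alpha`, `beta`, `K`,
#'   the source moments `cases` and `noncases`, and the derived quantities
#'   `r0`, `r1`, `m_p`, `var_p`.
#' @seealso [logistic_probability()], [probability_curve()],
#'   [weighted_logit_fit()] for the finite-grid regression equivalent.
#' @export
closed_form_coefficients <- function(cases, noncases, K) {
  cases <- .check_moments(cases, "cases")
  noncases <- .check_moments(noncases, "noncases")
  .check_prevalence(K)
  m1 <- cases$mean; v1 <- cases$variance
  m0 <- noncases$mean; v0 <- noncases$variance
  d <- m1 - m0
  r0 <- (v1 + d^2) / v0
  r1 <- (v0 + d^2) / v1
  mp <- K * m1 + (1 - K) * m0
  vp <- K * v1 + (1 - K) * v0 + K * (1 - K) * d^2
  beta <- d / vp * (K * (1 - K) * ((r0 + r1) / 2 - 1) + K * v1 / v0 + (1 - K) * v0 / v1)
  alpha <- log(K * sqrt(v0) / ((1 - K) * sqrt(v1))) +
    0.5 * ((r0 - 1) * K + (1 - r1) * (1 - K)) - mp * beta
  structure(list(alpha = alpha, beta = beta, K = K,
                 cases = cases, noncases = noncases,
                 r0 = r0, r1 = r1, m_p = mp, var_p = vp),
            class = "logistic_curve")
}

#' @export
print.logistic_curve <- function(x, ...) {
  cat(sprintf("Logistic disease-probability curve (K = %.4g)\n", x$K))
  cat(sprintf("  alpha = %.6g, beta = %.6g\n", x$alpha, x$beta))
  cat(sprintf("  cases:    mean %.6g, var %.6g\n", x$cases$mean, x$cases$variance))
  cat(sprintf("  noncases: mean %.6g, var %.6g\n", x$noncases$mean, x$noncases$variance))
  cat(sprintf("  population: mean %.6g, var %.6g\n", x$m_p, x$var_p))
  invisible(x)
}

.check_curve <- function(curve) {
  if (!inherits(curve, "logistic_curve"))
    stop("curve must be a 'logistic_curve' (see closed_form_coefficients())")
  curve
}

#' Probability of disease under the logistic model
#'
#' \eqn{P(x) = 1/(1 + e^{-(\alpha + \beta x)})}, evaluated with
#' [stats::plogis()] so it is numerically stable for extreme linear
#' predictors.
#'
#' @param curve A `logistic_curve`.
#' @param x Numeric vector of PRS values on the same (raw) scale as the
#'   moments that produced the curve.
#' @return Numeric vector of probabilities.
#' @export
logistic_probability <- function(curve, x) {
  curve <- .check_curve(curve)
  stopifnot(is.numeric(x))
  stats::plogis(curve$alpha + curve$beta * x)
}

#' Tabulate a probability curve on the standardized PRS axis
#'
#' Evaluates a logistic curve on a grid of standardized scores
#' \eqn{x_{st}}, mapping each grid point back to the raw scale via
#' \eqn{x = m_p + x_{st}\,\sigma_p}. Also tabulates the raw
#' Bayesian-inversion probability for comparison.
#'
#' @param curve A `logistic_curve`.
#' @param population Optional [group_moments()] for the standardization; by
#'   default the mixture moments stored in the curve are used.
#' @param lo,hi Grid end points on the standardized scale (`lo < hi`).
#' @param n Number of grid points (`>= 2`).
#' @param raw If `TRUE` (default), include the raw probability column.
#' @return A `data.frame` of class `curve_table` with columns `x_st`,
#'   `probability` and optionally `raw_probability`; the curve's `alpha`,
#'   `beta` and `K` are attached as attributes.
#' @export
probability_curve <- function(curve, population = NULL, lo = -4, hi = 4,
                              n = 161L, raw = TRUE) {
  curve <- .check_curve(curve)
  if (is.null(population))
    population <- group_moments(curve$m_p, curve$var_p, "population")
  population <- .check_moments(population, "population")
  stopifnot(is.numeric(lo), is.numeric(hi), length(lo) == 1L, length(hi) == 1L)
  if (!(lo < hi)) stop("invalid grid: lo must be < hi")
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop("invalid grid: need at least 2 points")
  x_st <- seq(lo, hi, length.out = n)
  x <- population$mean + x_st * sqrt(population$variance)
  out <- data.frame(x_st = x_st, probability = logistic_probability(curve, x))
  if (raw)
    out$raw_probability <- raw_probability(x, curve$cases, curve$noncases, curve$K)
  attr(out, "alpha") <- curve$alpha
  attr(out, "beta") <- curve$beta
  attr(out, "K") <- curve$K
  attr(out, "population") <- population
  class(out) <- c("curve_table", "data.frame")
  out
}

#' Check that Bayesian inversion conserves the prevalence
#'
#' The raw probability must average to the prevalence over the population
#' score distribution: \eqn{\int \hat P(x)\, p_p(x)\, dx = K}. This is an
#' exact identity of the mixture construction; the function evaluates the
#' integral by adaptive quadrature over an interval extending 10 component
#' SDs beyond both component means (mixture mass outside is negligible at
#' double precision) and returns it, for use in consistency checks.
#'
#' @inheritParams raw_log_odds
#' @param rel.tol Quadrature relative tolerance.
#' @return The value of the integral (should equal `K`).
#' @export
prevalence_integral <- function(cases, noncases, K, rel.tol = 1e-9) {
  cases <- .check_moments(cases, "cases")
  noncases <- .check_moments(noncases, "noncases")
  .check_prevalence(K)
  s1 <- sqrt(cases$variance); s0 <- sqrt(noncases$variance)
  f <- function(x) {
    pp <- K * stats::dnorm(x, cases$mean, s1) +
      (1 - K) * stats::dnorm(x, noncases$mean, s0)
    raw_probability(x, cases, noncases, K) * pp
  }
  lo <- min(cases$mean - 10 * s1, noncases$mean - 10 * s0)
  hi <- max(cases$mean + 10 * s1, noncases$mean + 10 * s0)
  stats::integrate(f, lo, hi, rel.tol = rel.tol, abs.tol = 0)$value
}
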