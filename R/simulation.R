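#' Case allele frequency implied by a control frequency and odds ratio
#'
#' Allelic odds scaling: if the effect allele has frequency `f_control` in
#' controls and per-allele odds ratio `OR`, its frequency in cases is
#' \deqn{f_{case} = \frac{OR\, f_{control}}{1 + f_{control}(OR - 1)}.}
#'
#' @param f_control Control allele frequency in (0, 1) (vectorized).
#' @param OR Per-allele odds ratio, > 0 (vectorized).
#' @return Case allele frequency, same length.
#' @export
case_maf_from_or <- function(f_control, OR) {
  stopifnot(is.numeric(f_control), all(f_control > 0 & f_control < 1),
            is.numeric(OR), all(is.finite(OR) & OR > 0))
  OR * f_control / (1 + f_control * (OR - 1))
}

#' Configuration for case/control genotype simulation
#'
#' Describes a set of independent SNPs by their control allele frequencies
#' and per-allele log odds ratios, plus the sample sizes and the root seed.
#'
#' @param n_cases,n_controls Group sizes, each at least 2.
#' @param maf_controls Numeric vector of control effect-allele frequencies
#'   in (0, 1), one per SNP.
#' @param beta Numeric vector of per-allele log odds ratios, one per SNP.
#' @param seed Integer root seed (< 2^31) governing all randomness.
#' @param scenario Optional label (e.g. `"prs"`, `"ors"`).
#' @return An object of class `simulation_config`.
#' @seealso [scenario_config()] for ready-made weak/strong SNP scenarios.
#' @export
simulation_config <- function(n_cases, n_controls, maf_controls, beta,
                              seed = 1L, scenario = NULL) {
  n_cases <- as.integer(n_cases); n_controls <- as.integer(n_controls)
  stopifnot(n_cases >= 2L, n_controls >= 2L,
            is.numeric(maf_controls), length(maf_controls) >= 1L,
            all(maf_controls > 0 & maf_controls < 1),
            is.numeric(beta), length(beta) == length(maf_controls),
            all(is.finite(beta)))
  seed <- as.integer(seed)
  stopifnot(!is.na(seed))
  structure(list(n_cases = n_cases, n_controls = n_controls,
                 maf_controls = as.numeric(maf_controls),
                 beta = as.numeric(beta), seed = seed,
                 scenario = scenario,
                 n_snps = length(maf_controls)),
            class = "simulation_config")
}

#' Ready-made simulation scenarios
#'
#' Two scenario shapes used to probe the closed-form calibration:
#' \describe{
#'   \item{`"ors"`}{an oligogenic score of 39 strong SNPs, odds ratios drawn
#'     uniformly from 1.1-1.4 — few SNPs, so the score distribution departs
#'     visibly from normality;}
#'   \item{`"prs"`}{a polygenic score of 10,039 SNPs: the 39 strong SNPs
#'     plus 10,000 weak SNPs with odds ratios drawn uniformly from
#'     1.00-1.05 and random effect direction — many small contributions,
#'     so the score is close to normal.}
#' }
#' Control allele frequencies are drawn uniformly from 0.05-0.5 in both. The
#' weak-SNP odds ratios are kept close to 1 so that the total case/control
#' separation of the aggregate score stays in the range observed for highly
#' predictive real polygenic scores (standardized mean difference around
#' 1.5-2 population SDs); thousands of independent SNPs each carrying a
#' substantially larger marginal effect would imply a jointly impossible,
#' perfectly discriminating score for which logistic ML estimates do not
#' exist.
#'
#' @param scenario `"prs"` (many weak SNPs) or `"ors"` (few strong SNPs).
#' @param n_cases,n_controls Group sizes (default 10,000 each).
#' @param seed Integer root seed; SNP frequencies and effects are drawn from
#'   it, and genotype simulation continues from the same stream.
#' @return A [simulation_config()].
#' @export
scenario_config <- function(scenario = c("prs", "ors"),
                            n_cases = 10000L, n_controls = 10000L, seed = 1L) {
  scenario <- match.arg(scenario)
  seed <- as.integer(seed)
  set.seed(seed)
  n_strong <- 39L
  or_strong <- stats::runif(n_strong, 1.1, 1.4)
  maf_strong <- stats::runif(n_strong, 0.05, 0.5)
  if (scenario == "ors") {
    maf <- maf_strong
    beta <- log(or_strong)
  } else {
    n_weak <- 10000L
    or_weak <- stats::runif(n_weak, 1.00, 1.05)
    sign_weak <- sample(c(-1, 1), n_weak, replace = TRUE)
    maf <- c(maf_strong, stats::runif(n_weak, 0.05, 0.5))
    beta <- c(log(or_strong), sign_weak * log(or_weak))
  }
  simulation_config(n_cases, n_controls, maf, beta,
                    seed = seed, scenario = scenario)
}

.group_dosages <- function(n, f) {
  # one SNP, HWE: dosage ~ Binomial(2, f)
  stats::rbinom(n, 2L, f)
}

#' Simulate case/control genotypes in Hardy-Weinberg equilibrium
#'
#' Draws independent SNP dosages for cases and controls, each group in HWE
#' at its own allele frequency: controls at `maf_controls`, cases at the
#' frequency implied by [case_maf_from_or()]. Reproducible: the same
#' configuration (including seed) always yields the same matrix.
#'
#' Intended for moderate SNP counts; for scoring very large panels without
#' materializing the matrix, see [simulate_prs()].
#'
#' @param config A [simulation_config()].
#' @return A list with `genotypes` (matrix, individuals x SNPs, cases
#'   first), `status` (1 = case, 0 = control) and `config`.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  f1 <- case_maf_from_or(config$maf_controls, exp(config$beta))
  n1 <- config$n_cases; n0 <- config$n_controls
  G <- matrix(0L, nrow = n1 + n0, ncol = config$n_snps,
              dimnames = list(NULL, paste0("snp_", seq_len(config$n_snps))))
  for (i in seq_len(config$n_snps)) {
    G[seq_len(n1), i] <- .group_dosages(n1, f1[i])
    G[n1 + seq_len(n0), i] <- .group_dosages(n0, config$maf_controls[i])
  }
  list(genotypes = G, status = rep(c(1L, 0L), c(n1, n0)), config = config)
}

#' Simulate PRS values from HWE genotypes without storing the matrix
#'
#' Streaming equivalent of [simulate_genotypes()] followed by
#' [compute_prs()]: SNPs are generated in chunks and immediately folded into
#' the running weighted sum, so panels of tens of thousands of SNPs fit in
#' modest memory. Uses the same per-SNP draw order as
#' [simulate_genotypes()], hence identical scores for the same config.
#'
#' @param config A [simulation_config()].
#' @param chunk_size SNPs generated per chunk.
#' @return A labelled [score_set()] (cases first).
#' @export
simulate_prs <- function(config, chunk_size = 500L) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  f1 <- case_maf_from_or(config$maf_controls, exp(config$beta))
  n1 <- config$n_cases; n0 <- config$n_controls
  acc <- numeric(n1 + n0)
  i <- 1L
  while (i <= config$n_snps) {
    j <- min(i + as.integer(chunk_size) - 1L, config$n_snps)
    for (s in i:j) {
      g <- c(.group_dosages(n1, f1[s]), .group_dosages(n0, config$maf_controls[s]))
      acc <- acc + g * config$beta[s]
    }
    i <- j + 1L
  }
  score_set(acc / config$n_snps, status = rep(c(1L, 0L), c(n1, n0)),
            n_snps = config$n_snps)
}

#' Sample PRS values directly from the two-normal summary model
#'
#' Draws case scores from \eqn{N(m_1, \sigma_1^2)} and control scores from
#' \eqn{N(m_0, \sigma_0^2)} — the summary-level analogue of genotype
#' simulation, bypassing individual SNPs.
#'
#' @param cases,noncases [group_moments()] of the two groups.
#' @param n_cases,n_controls Group sizes.
#' @param seed Integer seed.
#' @return A labelled [score_set()] (cases first).
#' @export
simulate_scores <- function(cases, noncases, n_cases, n_controls, seed = 1L) {
  cases <- .check_moments(cases, "cases")
  noncases <- .check_moments(noncases, "noncases")
  n_cases <- as.integer(n_cases); n_controls <- as.integer(n_controls)
  stopifnot(n_cases >= 2L, n_controls >= 2L)
  set.seed(as.integer(seed))
  v <- c(stats::rnorm(n_cases, cases$mean, sqrt(cases$variance)),
         stats::rnorm(n_controls, noncases$mean, sqrt(noncases$variance)))
  score_set(v, status = rep(c(1L, 0L), c(n_cases, n_controls)))
}

#' Maximum-likelihood logistic regression of status on score
#'
#' Fits `status ~ score` by ML logistic regression. Case/control samples are
#' usually collected at a case fraction very different from the population
#' prevalence (e.g. balanced 50:50); when `K` is supplied, the fitted
#' intercept is re-anchored to the population scale by adding
#' \eqn{\log(K/(1-K)) - \log(n_{cases}/n_{controls})}, the standard
#' case-control intercept correction, so the returned curve gives
#' population-scale probabilities. The slope is unaffected by outcome-based
#' sampling.
#'
#' @param scores A labelled [score_set()] with both statuses present.
#' @param K Optional prevalence for intercept re-anchoring.
#' @return An object of class `logistic_fit`: `alpha`, `beta`, their
#'   standard errors (`se_alpha` on the sample scale, before re-anchoring),
#'   `K`, group sizes.
#' @export
fit_logistic <- function(scores, K = NULL) {
  if (!inherits(scores, "score_set")) stop("scores must be a 'score_set'")
  if (is.null(scores$status) || length(unique(scores$status)) < 2L)
    stop("scores must carry both case and control labels")
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(scores$status ~ scores$values, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|algorithm did not converge",
                conditionMessage(w))) {
        sep <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (sep || !fit$converged)
    stop("perfect (or quasi-perfect) separation: logistic ML estimate does not exist")
  cf <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  n1 <- sum(scores$status == 1L); n0 <- sum(scores$status == 0L)
  alpha <- unname(cf[1]); beta <- unname(cf[2])
  if (!is.null(K)) {
    .check_prevalence(K)
    alpha <- alpha + log(K / (1 - K)) - log(n1 / n0)
  }
  structure(list(alpha = alpha, beta = beta,
                 se_alpha = unname(se[1]), se_beta = unname(se[2]),
                 K = K, n_cases = n1, n_controls = n0),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("Logistic ML fit: alpha = %.6g (se %.3g), beta = %.6g (se %.3g)\n",
              x$alpha, x$se_alpha, x$beta, x$se_beta))
  if (!is.null(x$K))
    cat(sprintf("  intercept re-anchored to prevalence K = %.4g (%d cases / %d controls)\n",
                x$K, x$n_cases, x$n_controls))
  invisible(x)
}

#' Weighted linear regression of the raw log-odds (logit-link projection)
#'
#' The finite-grid counterpart of [closed_form_coefficients()]: regresses
#' the raw log-odds [raw_log_odds()] on the score over a dense grid, with
#' the population mixture density as weight. For equal group variances the
#' log-odds is exactly affine and the regression is exact; with unequal
#' variances both this fit and the closed form compute the same weighted
#' linear projection of a quadratic log-odds, differing only by grid
#' discretisation.
#'
#' @inheritParams raw_log_odds
#' @param grid_n Number of grid points (odd so the mean is included).
#' @param width Half-width of the grid in population SDs.
#' @return A list with `alpha`, `beta`.
#' @export
weighted_logit_fit <- function(cases, noncases, K, grid_n = 2001L, width = 8) {
  cases <- .check_moments(cases, "cases")
  noncases <- .check_moments(noncases, "noncases")
  .check_prevalence(K)
  grid_n <- as.integer(grid_n)
  if (is.na(grid_n) || grid_n < 3L) stop("degenerate grid: need at least 3 points")
  pop <- mixture_moments(cases, noncases, K)
  sp <- sqrt(pop$variance)
  x <- seq(pop$mean - width * sp, pop$mean + width * sp, length.out = grid_n)
  y <- raw_log_odds(x, cases, noncases, K)
  w <- K * stats::dnorm(x, cases$mean, sqrt(cases$variance)) +
    (1 - K) * stats::dnorm(x, noncases$mean, sqrt(noncases$variance))
  fit <- stats::lm(y ~ x, weights = w)
  list(alpha = unname(stats::coef(fit)[1]), beta = unname(stats::coef(fit)[2]))
}

#' Relative weights of a high-effect variant and a variant-free PRS
#'
#' Bivariate ML logistic regression of status on the PRS (computed without
#' the variant's region) and the variant score (e.g. risk-allele count, or
#' an effect-weighted genotype). The fitted coefficients are the relative
#' weights with which the two predictors combine into a composite score.
#'
#' @param prs_no_variant Numeric vector: PRS excluding the variant.
#' @param variant_score Numeric vector: per-individual variant score.
#' @param status Integer vector, 1 = case, 0 = control.
#' @return Named numeric vector `c(prs = ..., variant = ...)` of logistic
#'   coefficients, with the intercept as attribute `"alpha"`.
#' @export
composite_score_weights <- function(prs_no_variant, variant_score, status) {
  stopifnot(is.numeric(prs_no_variant), is.numeric(variant_score),
            length(variant_score) == length(prs_no_variant),
            length(status) == length(prs_no_variant))
  status <- as.integer(status)
  stopifnot(all(status %in% c(0L, 1L)), length(unique(status)) == 2L)
  if (stats::var(variant_score) == 0 || stats::var(prs_no_variant) == 0)
    stop("constant predictor: weight is unidentifiable (collinearity)")
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(status ~ prs_no_variant + variant_score, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|algorithm did not converge",
                conditionMessage(w))) {
        sep <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (sep || !fit$converged || any(is.na(stats::coef(fit))))
    stop("separation or collinearity: bivariate logistic weights do not exist")
  cf <- stats::coef(fit)
  out <- c(prs = unname(cf[2]), variant = unname(cf[3]))
  attr(out, "alpha") <- unname(cf[1])
  out
}

#' Validate the closed-form calibration against regression procedures
#'
#' Runs the three-procedure validation ladder for a simulation scenario:
#' \enumerate{
#'   \item genotype simulation in HWE ([simulate_prs()]), scoring, and ML
#'     logistic regression of status on score;
#'   \item normal score sampling at the moments estimated in (1), and ML
#'     logistic regression;
#'   \item weighted linear regression of the raw log-odds with the mixture
#'     density as weight ([weighted_logit_fit()]).
#' }
#' Each procedure's probability curve is tabulated on a standardized grid
#' and compared pointwise with the closed-form curve built from the same
#' (estimated) moments; the report records the maximum absolute probability
#' discrepancy per procedure. All fits are re-anchored to the prevalence
#' `K`, so curves are on the population scale.
#'
#' @param config A [simulation_config()] (see [scenario_config()]).
#' @param K Population prevalence used for calibration and re-anchoring.
#' @param grid Standardized grid on which curves are compared.
#' @return An object of class `validation_report`: `table` (data frame of
#'   curves), `max_discrepancy` (named vector), the estimated moments, the
#'   fitted coefficients, `config` and `K`.
#' @export
validate <- function(config, K, grid = seq(-4, 4, by = 0.05)) {
  stopifnot(inherits(config, "simulation_config"))
  .check_prevalence(K)

  # (a) genotypes -> PRS -> logistic ML
  scores_a <- simulate_prs(config)
  m1 <- sample_moments(scores_a, "cases")
  m0 <- sample_moments(scores_a, "noncases")
  fit_a <- fit_logistic(scores_a, K = K)

  theory <- closed_form_coefficients(m1, m0, K)
  pop <- mixture_moments(m1, m0, K)

  # (b) normal score sampling at the estimated moments -> logistic ML
  scores_b <- simulate_scores(m1, m0, config$n_cases, config$n_controls,
                              seed = config$seed + 1L)
  fit_b <- fit_logistic(scores_b, K = K)

  # (c) density-weighted logit-link linear regression
  fit_c <- weighted_logit_fit(m1, m0, K)

  x <- pop$mean + grid * sqrt(pop$variance)
  curves <- data.frame(
    x_st = grid,
    p_closed_form    = stats::plogis(theory$alpha + theory$beta * x),
    p_genotype_sim   = stats::plogis(fit_a$alpha + fit_a$beta * x),
    p_score_sim      = stats::plogis(fit_b$alpha + fit_b$beta * x),
    p_weighted_logit = stats::plogis(fit_c$alpha + fit_c$beta * x)
  )
  disc <- c(
    genotype_sim   = max(abs(curves$p_genotype_sim - curves$p_closed_form)),
    score_sim      = max(abs(curves$p_score_sim - curves$p_closed_form)),
    weighted_logit = max(abs(curves$p_weighted_logit - curves$p_closed_form))
  )
  structure(list(table = curves, max_discrepancy = disc,
                 cases = m1, noncases = m0, population = pop,
                 closed_form = theory,
                 fits = list(genotype_sim = fit_a, score_sim = fit_b,
                             weighted_logit = fit_c),
                 config = config, K = K),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("Validation report (%s scenario: %d SNPs, %d cases + %d controls, seed %d, K = %.3g)\n",
              if (is.null(x$config$scenario)) "custom" else x$config$scenario,
              x$config$n_snps, x$config$n_cases, x$config$n_controls,
              x$config$seed, x$K))
  cat(sprintf("  closed form: alpha = %.6g, beta = %.6g\n",
              x$closed_form$alpha, x$closed_form$beta))
  cat("  max |probability - closed form| on the standardized grid:\n")
  for (nm in names(x$max_discrepancy))
    cat(sprintf("    %-15s %.5f\n", nm, x$max_discrepancy[[nm]]))
  invisible(x)
}
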