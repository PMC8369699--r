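#' Group moments of a polygenic risk score distribution
#'
#' Container for the mean and variance of the PRS in one labelled group:
#' cases, non-cases, or the whole population. These five numbers (together
#' with the disease prevalence) are the only reference data the probability
#' framework needs, so summary statistics can be shared without exchanging
#' individual-level genotypes.
#'
#' @param mean PRS mean of the group (dimensionless, on whatever scale the
#'   score was computed).
#' @param variance PRS variance of the group; must be strictly positive.
#' @param label One of `"cases"`, `"noncases"`, `"population"`.
#' @return An object of class `group_moments` with fields `mean`, `variance`,
#'   `label`.
#' @examples
#' group_moments(0.5, 1.2, "cases")
#' @export
group_moments <- function(mean, variance, label = c("population", "cases", "noncases")) {
  label <- match.arg(label)
  stopifnot(is.numeric(mean), length(mean) == 1L, is.finite(mean),
            is.numeric(variance), length(variance) == 1L, is.finite(variance))
  if (variance <= 0)
    stop("group_moments: variance must be strictly positive (got ",
         format(variance), ")")
  structure(list(mean = as.numeric(mean), variance = as.numeric(variance),
                 label = label),
            class = "group_moments")
}

#' @export
print.group_moments <- function(x, ...) {
  cat(sprintf("PRS moments [%s]: mean = %.6g, variance = %.6g (sd = %.6g)\n",
              x$label, x$mean, x$variance, sqrt(x$variance)))
  invisible(x)
}

.check_moments <- function(x, arg) {
  if (!inherits(x, "group_moments"))
    stop(arg, " must be a 'group_moments' object (see group_moments())")
  x
}

.check_prevalence <- function(K, open = TRUE) {
  stopifnot(is.numeric(K), length(K) == 1L, is.finite(K))
  if (open) {
    if (K <= 0 || K >= 1) stop("prevalence K must lie strictly in (0, 1), got ", format(K))
  } else {
    if (K < 0 || K > 1) stop("prevalence K must lie in [0, 1], got ", format(K))
  }
  K
}

#' Population moments of the case/non-case mixture
#'
#' The population PRS distribution is the two-component mixture of the case
#' and non-case distributions with mixing proportion equal to the prevalence
#' `K`. Its mean and variance are
#' \deqn{m_p = K m_1 + (1-K) m_0}
#' \deqn{\sigma_p^2 = K \sigma_1^2 + (1-K)\sigma_0^2 + K(1-K)(m_1-m_0)^2}
#'
#' @param cases `group_moments` of the case group.
#' @param noncases `group_moments` of the non-case group.
#' @param K Disease prevalence in `[0, 1]`.
#' @return `group_moments` with label `"population"`.
#' @seealso [infer_noncase_moments()] for the inverse operation.
#' @export
mixture_moments <- function(cases, noncases, K) {
  cases <- .check_moments(cases, "cases")
  noncases <- .check_moments(noncases, "noncases")
  .check_prevalence(K, open = FALSE)
  m1 <- cases$mean; v1 <- cases$variance
  m0 <- noncases$mean; v0 <- noncases$variance
  mp <- K * m1 + (1 - K) * m0
  vp <- K * v1 + (1 - K) * v0 + K * (1 - K) * (m1 - m0)^2
  group_moments(mp, vp, "population")
}

#' Infer non-case moments from population (unscreened control) moments
#'
#' When controls are unscreened population samples, the observed "control"
#' distribution is really the population mixture and contains a fraction `K`
#' of undetected cases. Given the case moments and the prevalence, the
#' non-case moments are recovered by inverting the mixture formulas:
#' \deqn{m_0 = \frac{m_p - K m_1}{1-K}}
#' \deqn{\sigma_0^2 = \frac{\sigma_p^2 - K\sigma_1^2}{1-K}
#'       - \frac{K (m_p - m_1)^2}{(1-K)^2}}
#'
#' @param population `group_moments` of the unscreened population sample.
#' @param cases `group_moments` of the case group.
#' @param K Disease prevalence, strictly in `(0, 1)`.
#' @return `group_moments` with label `"noncases"`.
#' @details Inputs whose implied non-case variance is non-positive are
#'   rejected (they cannot arise from any genuine case/non-case mixture with
#'   the stated prevalence), rather than silently clamped.
#' @export
infer_noncase_moments <- function(population, cases, K) {
  population <- .check_moments(population, "population")
  cases <- .check_moments(cases, "cases")
  .check_prevalence(K)
  mp <- population$mean; vp <- population$variance
  m1 <- cases$mean; v1 <- cases$variance
  m0 <- (mp - K * m1) / (1 - K)
  v0 <- (vp - K * v1) / (1 - K) - K * (mp - m1)^2 / (1 - K)^2
  if (!is.finite(v0) || v0 <= 0)
    stop("inconsistent summary inputs: implied non-case variance is ",
         format(v0), " <= 0")
  group_moments(m0, v0, "noncases")
}

#' Standardize a PRS value against the population distribution
#'
#' Expresses a raw PRS as standard deviations from the population mean,
#' `x_st = (x - m_p) / sigma_p`. Scores computed from different SNP sets are
#' not comparable on their raw scale; the standardized axis is the common
#' scale on which probability curves are reported.
#'
#' @param x Numeric vector of raw PRS values.
#' @param population `group_moments` of the population distribution.
#' @return Numeric vector of standardized PRS values.
#' @export
standardize <- function(x, population) {
  population <- .check_moments(population, "population")
  stopifnot(is.numeric(x))
  (x - population$mean) / sqrt(population$variance)
}
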