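#' Intrinsic disease probability of a rare risk variant
#'
#' For a risk allele rare enough not to shift the population prevalence
#' `K`, the probability that carrying it causes disease irrespective of
#' polygenic background is
#' \deqn{p_{rare} = \frac{K (OR - 1)}{K (OR - 1) + 1}}
#' where `OR` is the variant's odds ratio. This is the low-PRS asymptote of
#' the combined probability curve: even with minimal polygenic risk, a
#' carrier's disease probability does not fall below \eqn{p_{rare}}.
#'
#' @param odds_ratio Odds ratio of the variant; must exceed 1 (the model
#'   covers risk variants only).
#' @param K Disease prevalence in the (sub)population, strictly in (0, 1).
#' @return Intrinsic probability in (0, 1).
#' @examples
#' intrinsic_probability(7.2, 0.10)   # SORL1-like variant, 65+ age group
#' intrinsic_probability(2.46, 0.10)  # TREM2-like variant, 65+ age group
#' @export
intrinsic_probability <- function(odds_ratio, K) {
  .check_prevalence(K)
  stopifnot(is.numeric(odds_ratio), all(is.finite(odds_ratio)))
  if (any(odds_ratio <= 1))
    stop("protective or null rare variants are out of model scope (odds_ratio must be > 1)")
  K * (odds_ratio - 1) / (K * (odds_ratio - 1) + 1)
}

#' Rare-variant descriptor
#'
#' A rare risk allele with its odds ratio and the intrinsic probability it
#' implies at prevalence `K`. The "very rare" assumption (the variant does
#' not move the population prevalence) is not checked numerically; a warning
#' is raised when a supplied allele frequency exceeds 0.005, where the
#' assumption starts to strain.
#'
#' @param name Variant or gene name.
#' @param odds_ratio Odds ratio, > 1.
#' @param K Prevalence used to derive `p_rare`.
#' @param allele_frequency Optional allele frequency, for the rarity check.
#' @return An object of class `rare_variant` with field `p_rare`.
#' @export
rare_variant <- function(name, odds_ratio, K, allele_frequency = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  p <- intrinsic_probability(odds_ratio, K)
  if (!is.null(allele_frequency)) {
    stopifnot(is.numeric(allele_frequency), length(allele_frequency) == 1L,
              allele_frequency > 0, allele_frequency < 1)
    if (allele_frequency > 0.005)
      warning("allele frequency ", format(allele_frequency), " for '", name,
              "' is high for the rare-variant model; ",
              "the assumption that it leaves the prevalence unchanged may fail")
  }
  structure(list(name = name, odds_ratio = odds_ratio, K = K,
                 p_rare = p, allele_frequency = allele_frequency),
            class = "rare_variant")
}

#' @export
print.rare_variant <- function(x, ...) {
  cat(sprintf("Rare variant '%s': OR = %.4g, K = %.4g -> p_rare = %.4f\n",
              x$name, x$odds_ratio, x$K, x$p_rare))
  invisible(x)
}

#' Combine the intrinsic probabilities of several independent rare variants
#'
#' Under mutually independent effects the combined intrinsic probability is
#' the union probability \eqn{1 - \prod_j (1 - p_{rare,j})}. Because of the
#' very-small-frequency assumption, carrying more than one independent rare
#' variant is itself unlikely; the formula is provided for completeness.
#'
#' @param variants A non-empty list of [rare_variant()] objects (a single
#'   `rare_variant` is accepted).
#' @return Combined intrinsic probability in (0, 1).
#' @export
combine_intrinsic <- function(variants) {
  if (inherits(variants, "rare_variant")) variants <- list(variants)
  if (!is.list(variants) || length(variants) == 0L)
    stop("variants must be a non-empty list of rare_variant objects")
  p <- vapply(variants, function(v) {
    if (!inherits(v, "rare_variant")) stop("all elements must be rare_variant objects")
    v$p_rare
  }, numeric(1))
  1 - prod(1 - p)
}

#' Combine PRS-based and rare-variant probabilities
#'
#' Assuming the rare variant acts independently of the polygenic
#' background, a carrier's probability of disease is
#' \deqn{P = P_{PRS} + p_{rare} (1 - P_{PRS})}
#' which ranges from \eqn{p_{rare}} (no polygenic risk) to 1. When
#' \eqn{P_{PRS}} comes from a logistic curve with linear predictor
#' \eqn{\eta = \alpha + \beta x}, this equals
#' \eqn{(1 + p_{rare} e^{-\eta}) / (1 + e^{-\eta})}.
#'
#' @param p_prs Probability from the PRS curve, in `[0, 1]` (vectorized).
#' @param p_rare Intrinsic probability of the carried rare variant(s), in
#'   `[0, 1]`.
#' @return Combined probability, same length as `p_prs`.
#' @export
combined_probability <- function(p_prs, p_rare) {
  stopifnot(is.numeric(p_prs), is.numeric(p_rare), length(p_rare) == 1L)
  if (any(!is.finite(p_prs)) || any(p_prs < 0 | p_prs > 1))
    stop("p_prs must lie in [0, 1]")
  if (!is.finite(p_rare) || p_rare < 0 || p_rare > 1)
    stop("p_rare must lie in [0, 1]")
  p_prs + p_rare * (1 - p_prs)
}
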