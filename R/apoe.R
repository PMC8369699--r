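#' Auxiliary frequency-shift parameter for genotype-stratified prevalences
#'
#' For a biallelic high-effect common variant with risk-allele frequency `f`
#' and allelic odds ratio `OR` in a population with disease prevalence `K`,
#' assuming Hardy-Weinberg equilibrium both in the population and among
#' non-cases, the genotype-specific prevalences are driven by an auxiliary
#' parameter \eqn{\nu} solving a quadratic:
#' \deqn{\nu = \frac{b - \sqrt{b^2 - 16 (1-OR)(1-f) K}}{4 (1-OR)}, \qquad
#'       b = 2\,(1 + (1-OR)(K - f)).}
#' \eqn{\nu} relates the non-case allele frequency to the population one:
#' \eqn{f_0 = (f + \nu - K)/(1-K)}. The singularity at `OR = 1` is
#' removable; for `|OR - 1|` below `tol` the analytic limit
#' \eqn{\nu = K (1-f)} is returned.
#'
#' @param K Disease prevalence, strictly in (0, 1).
#' @param f Risk-allele frequency, strictly in (0, 1).
#' @param OR Allelic odds ratio, > 0.
#' @param tol Switch-over width around `OR = 1` for the limit branch.
#' @return The scalar \eqn{\nu}.
#' @export
solve_nu <- function(K, f, OR, tol = 1e-8) {
  .check_prevalence(K)
  stopifnot(is.numeric(f), length(f) == 1L, f > 0, f < 1,
            is.numeric(OR), length(OR) == 1L, is.finite(OR), OR > 0)
  if (abs(OR - 1) < tol) return(K * (1 - f))
  b <- 2 * (1 + (1 - OR) * (K - f))
  disc <- b^2 - 16 * (1 - OR) * (1 - f) * K
  if (disc < 0)
    stop("no real solution; inconsistent (K, f, OR) combination")
  (b - sqrt(disc)) / (4 * (1 - OR))
}

#' Genotype-stratified prevalences for a high-effect common variant
#'
#' Splits the overall prevalence `K` into prevalences for the three
#' genotypes of a biallelic variant (non-risk homozygote, heterozygote,
#' risk homozygote) under Hardy-Weinberg equilibrium in the population and
#' in non-cases:
#' \deqn{K_0 = 1 - \frac{(1-f-\nu)^2}{(1-K)(1-f)^2}, \quad
#'       K_1 = 1 - \frac{(1-f-\nu)(\nu+f-K)}{(1-K) f (1-f)}, \quad
#'       K_2 = 1 - \frac{(\nu+f-K)^2}{(1-K) f^2}}
#' with \eqn{\nu} from [solve_nu()]. By construction the HWE mixture
#' identity \eqn{(1-f)^2 K_0 + 2 f (1-f) K_1 + f^2 K_2 = K} holds exactly.
#' The HWE-in-non-cases approximation is sound for low-prevalence diseases
#' (a few percent); for high prevalences the formulas can leave `[0, 1]`,
#' which is reported as an error rather than repaired.
#'
#' @inheritParams solve_nu
#' @return An object of class `genotype_prevalence` with fields `K0`, `K1`,
#'   `K2`, `nu` and the inputs.
#' @export
genotype_prevalences <- function(K, f, OR, tol = 1e-8) {
  nu <- solve_nu(K, f, OR, tol = tol)
  K0 <- 1 - (1 - f - nu)^2 / ((1 - K) * (1 - f)^2)
  K1 <- 1 - (1 - f - nu) * (nu + f - K) / ((1 - K) * f * (1 - f))
  K2 <- 1 - (nu + f - K)^2 / ((1 - K) * f^2)
  Kg <- c(K0, K1, K2)
  eps <- 1e-9
  if (any(Kg < -eps) || any(Kg > 1 + eps))
    stop("model assumptions violated (prevalence too high for HWE approximation): ",
         "genotype prevalences ", paste(format(Kg, digits = 6), collapse = ", "))
  Kg <- pmin(pmax(Kg, 0), 1)
  structure(list(K0 = Kg[1], K1 = Kg[2], K2 = Kg[3], nu = nu,
                 K = K, f = f, odds_ratio = OR),
            class = "genotype_prevalence")
}

#' @export
print.genotype_prevalence <- function(x, ...) {
  cat(sprintf("Genotype-stratified prevalence (K = %.4g, f = %.4g, OR = %.4g)\n",
              x$K, x$f, x$odds_ratio))
  cat(sprintf("  K0 (non-risk homozygote): %.6f\n", x$K0))
  cat(sprintf("  K1 (heterozygote):        %.6f\n", x$K1))
  cat(sprintf("  K2 (risk homozygote):     %.6f\n", x$K2))
  invisible(x)
}

#' Per-genotype probability curves for a high-effect common variant
#'
#' Builds three logistic disease-probability curves, one per genotype of a
#' high-effect common variant (e.g. APOE epsilon-4 in Alzheimer's disease),
#' by replacing the overall prevalence with the genotype-specific
#' prevalences of [genotype_prevalences()] while keeping the same case and
#' non-case PRS moments. The moments must describe a PRS computed
#' *excluding* the variant's region; its distribution is then approximately
#' independent of the variant genotype, which is what justifies sharing the
#' moments across strata.
#'
#' Age-stratified analyses are handled by calling this function once per age
#' group with that group's `(K, f)`; there is no internal age model.
#'
#' @param cases,noncases [group_moments()] of the PRS excluding the
#'   variant's region.
#' @inheritParams solve_nu
#' @return A named list of three `logistic_curve` objects
#'   (`noncarrier`, `heterozygote`, `homozygote`) with the
#'   `genotype_prevalence` attached as attribute `"prevalences"`.
#' @export
stratified_curves <- function(cases, noncases, K, f, OR) {
  cases <- .check_moments(cases, "cases")
  noncases <- .check_moments(noncases, "noncases")
  gp <- genotype_prevalences(K, f, OR)
  curves <- list(
    noncarrier   = closed_form_coefficients(cases, noncases, gp$K0),
    heterozygote = closed_form_coefficients(cases, noncases, gp$K1),
    homozygote   = closed_form_coefficients(cases, noncases, gp$K2)
  )
  attr(curves, "prevalences") <- gp
  curves
}
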