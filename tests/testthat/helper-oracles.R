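# Independent brute-force oracle for genotype-stratified prevalences:
# numerically solve the HWE system for the non-case allele frequency f0
# such that the allelic case/non-case odds ratio equals OR, then read the
# genotype prevalences off the HWE mixture. No use of the closed-form nu.
oracle_genotype_prevalences <- function(K, f, OR) {
  lo <- max(0, (f - K) / (1 - K))
  hi <- min(1, f / (1 - K))
  eps <- 1e-12
  or_gap <- function(f0) {
    f1 <- (f - (1 - K) * f0) / K
    log(f1 / (1 - f1)) - log(f0 / (1 - f0)) - log(OR)
  }
  f0 <- stats::uniroot(or_gap, c(lo + eps, hi - eps), tol = 1e-14)$root
  # P(noncase, g) = (1-K) * HWE(f0); P(g) = HWE(f) in the population
  list(
    K0 = 1 - (1 - K) * (1 - f0)^2 / (1 - f)^2,
    K1 = 1 - (1 - K) * f0 * (1 - f0) / (f * (1 - f)),
    K2 = 1 - (1 - K) * f0^2 / f^2,
    f0 = f0
  )
}

# Allelic OR reconstructed from genotype prevalences and population frequency
# (inverts the HWE construction; used to check OR recovery).
oracle_recover_or <- function(K0, K1, K2, K, f) {
  f0 <- sqrt((1 - K2) * f^2 / (1 - K))
  f1 <- (f - (1 - K) * f0) / K
  (f1 / (1 - f1)) / (f0 / (1 - f0))
}

# Random valid moment draws shared by property tests.
draw_moments <- function(n, seed) {
  set.seed(seed)
  data.frame(
    m0 = stats::runif(n, -1, 1),
    d = stats::runif(n, 0.05, 1.5),   # m1 = m0 + d
    v0 = stats::runif(n, 0.2, 3),
    v1 = stats::runif(n, 0.2, 3),
    K = stats::runif(n, 0.01, 0.5)
  )
}

# Draw box restricted to the model's domain of validity: risk alleles with
# prevalence and frequency in the range of high-effect common variants of
# complex disease. Strongly protective alleles, or risk alleles at jointly
# high (K, f, OR), push a genotype prevalence outside [0, 1] (the HWE
# approximation genuinely breaks there and the package reports it).
draw_hwe_params <- function(n, seed) {
  set.seed(seed)
  data.frame(
    K = stats::runif(n, 0.01, 0.3),
    f = stats::runif(n, 0.05, 0.4),
    OR = exp(stats::runif(n, 0, log(3.5)))
  )
}
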