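test_that("case allele frequency scales the allelic odds", {
  expect_equal(case_maf_from_or(0.3, 1), 0.3)
  expect_equal(case_maf_from_or(0.5, 3), 0.75)  # odds 1 -> 3
  # rare-allele limit: multiplicative in OR
  expect_equal(case_maf_from_or(1e-6, 5) / 1e-6, 5, tolerance = 1e-4)
})

test_that("genotype simulation is reproducible and in HWE", {
  cfg <- simulation_config(300, 300, maf_controls = c(0.5, 0.2),
                           beta = c(log(1.3), 0), seed = 91)
  a <- simulate_genotypes(cfg)
  b <- simulate_genotypes(cfg)
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$status, rep(c(1L, 0L), c(300, 300)))

  # mean dosage at f = 0.5 in controls: 1.0 within 5 SE
  cfg2 <- simulation_config(2, 20000, maf_controls = 0.5, beta = 0, seed = 13)
  g <- simulate_genotypes(cfg2)
  ctrl <- g$genotypes[g$status == 0L, 1]
  se <- sqrt(2 * 0.5 * 0.5 / length(ctrl))
  expect_lt(abs(mean(ctrl) - 1.0), 5 * se)

  # HWE genotype proportions not rejected at alpha = 0.001 for a large draw
  cfg3 <- simulation_config(2, 50000, maf_controls = 0.3, beta = 0, seed = 17)
  g3 <- simulate_genotypes(cfg3)
  counts <- tabulate(g3$genotypes[g3$status == 0L, 1] + 1L, nbins = 3)
  p_hwe <- c((1 - 0.3)^2, 2 * 0.3 * 0.7, 0.3^2)
  expect_gt(chisq.test(counts, p = p_hwe)$p.value, 0.001)
})

test_that("streaming PRS simulation equals scoring the materialized matrix", {
  cfg <- simulation_config(150, 200, maf_controls = runif(25, 0.1, 0.5),
                           beta = rnorm(25, 0, 0.1), seed = 37)
  direct <- simulate_prs(cfg, chunk_size = 7L)
  g <- simulate_genotypes(cfg)
  w <- effect_weights(colnames(g$genotypes),
                      rep("A", cfg$n_snps), cfg$beta)
  scored <- compute_prs(g$genotypes, w)
  expect_equal(direct$values, scored$values, tolerance = 1e-12)
  expect_identical(direct$status, g$status)
})

test_that("normal score sampling hits its target moments and is seeded", {
  m1 <- group_moments(0.4, 1.2, "cases")
  m0 <- group_moments(0, 0.8, "noncases")
  s <- simulate_scores(m1, m0, 100000, 100000, seed = 3)
  s2 <- simulate_scores(m1, m0, 100000, 100000, seed = 3)
  expect_identical(s$values, s2$values)
  got1 <- sample_moments(s, "cases")
  got0 <- sample_moments(s, "noncases")
  expect_lt(abs(got1$mean - 0.4), 5 * sqrt(1.2 / 1e5))
  expect_lt(abs(got0$mean - 0), 5 * sqrt(0.8 / 1e5))
  expect_lt(abs(got1$variance - 1.2) / 1.2, 0.05)
})

test_that("logistic ML fit recovers null and non-null models", {
  m <- group_moments(0, 1, "cases")
  m0 <- group_moments(0, 1, "noncases")
  null <- fit_logistic(simulate_scores(m, m0, 20000, 20000, seed = 5))
  expect_lt(abs(null$beta), 5 * null$se_beta)

  # equal-variance two-normal model: ML consistent for the closed form
  m1 <- group_moments(0.3, 1, "cases")
  K <- 0.1
  cf <- closed_form_coefficients(m1, m0, K)
  fit <- fit_logistic(simulate_scores(m1, m0, 50000, 50000, seed = 8), K = K)
  expect_lt(abs(fit$beta - cf$beta), 3 * fit$se_beta)
  expect_lt(abs(fit$alpha - cf$alpha), 3 * fit$se_alpha)

  # re-anchoring with K equal to the sample case fraction changes nothing
  s <- simulate_scores(m1, m0, 5000, 5000, seed = 9)
  expect_equal(fit_logistic(s, K = 0.5)$alpha, fit_logistic(s)$alpha,
               tolerance = 1e-12)

  # separated samples have no ML estimate
  sep <- score_set(c(rnorm(50, 10), rnorm(50, -10)),
                   status = rep(c(1L, 0L), each = 50))
  expect_error(fit_logistic(sep), "separation")
  expect_error(fit_logistic(score_set(rnorm(10), status = rep(1L, 10))),
               "both case and control")
})

test_that("weighted logit regression reproduces the closed form", {
  m0 <- group_moments(0, 1, "noncases")
  m1 <- group_moments(0.5, 1, "cases")
  cf <- closed_form_coefficients(m1, m0, 0.1)
  wf <- weighted_logit_fit(m1, m0, 0.1)
  expect_equal(wf$alpha, cf$alpha, tolerance = 1e-6)
  expect_equal(wf$beta, cf$beta, tolerance = 1e-6)

  # unequal variances: same projection, grid discretisation only
  m1u <- group_moments(0.5, 1.6, "cases")
  cfu <- closed_form_coefficients(m1u, m0, 0.1)
  wfu <- weighted_logit_fit(m1u, m0, 0.1)
  expect_equal(wfu$alpha, cfu$alpha, tolerance = 1e-3)
  expect_equal(wfu$beta, cfu$beta, tolerance = 1e-3)

  # uninformative score: flat log-odds, zero slope
  flat <- weighted_logit_fit(group_moments(0.2, 1, "cases"),
                             group_moments(0.2, 1, "noncases"), 0.3)
  expect_equal(flat$beta, 0, tolerance = 1e-10)
  expect_equal(flat$alpha, log(0.3 / 0.7), tolerance = 1e-10)

  expect_error(weighted_logit_fit(m1, m0, 0.1, grid_n = 2), "degenerate grid")
})

test_that("bivariate weights recover a true variant effect and reject collinearity", {
  set.seed(55)
  n <- 20000
  prs <- rnorm(n)
  variant <- rbinom(n, 2, 0.15)
  eta <- -2 + 0.5 * prs + 0.9 * variant
  status <- rbinom(n, 1, plogis(eta))
  w <- composite_score_weights(prs, variant, status)
  expect_lt(abs(w[["prs"]] - 0.5), 0.1)
  expect_lt(abs(w[["variant"]] - 0.9), 0.15)

  # permuted labels carry no signal
  w0 <- composite_score_weights(prs, variant, sample(status))
  expect_lt(abs(w0[["prs"]]), 0.1)
  expect_lt(abs(w0[["variant"]]), 0.1)

  expect_error(composite_score_weights(prs, rep(1, n), status), "collinearity")
})

test_that("the validation report is deterministic and internally consistent", {
  cfg <- simulation_config(2000, 2000, maf_controls = runif(100, 0.05, 0.5),
                           beta = rnorm(100, 0, 0.05), seed = 71)
  rep1 <- validate(cfg, K = 0.1)
  rep2 <- validate(cfg, K = 0.1)
  expect_identical(rep1$table, rep2$table)
  expect_true(all(rep1$max_discrepancy >= 0))
  expect_named(rep1$max_discrepancy,
               c("genotype_sim", "score_sim", "weighted_logit"))
  # procedure (c) is the same projection as the closed form
  expect_lt(rep1$max_discrepancy[["weighted_logit"]], 1e-6)
  expect_true(all(rep1$table$p_closed_form >= 0 & rep1$table$p_closed_form <= 1))
})

test_that("few strong SNPs deviate more from normality than many weak SNPs", {
  rep_ors <- validate(scenario_config("ors", n_cases = 10000,
                                      n_controls = 10000, seed = 7), K = 0.1)
  cfg_prs <- scenario_config("prs", n_cases = 10000, n_controls = 10000, seed = 7)
  expect_identical(cfg_prs$n_snps, 10039L)
  rep_prs <- validate(cfg_prs, K = 0.1)
  expect_gt(rep_ors$max_discrepancy[["genotype_sim"]],
            rep_prs$max_discrepancy[["genotype_sim"]])
})
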