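test_that("raw probability is the Bayesian posterior of the two-normal model", {
  m1 <- group_moments(1, 1, "cases")
  m0 <- group_moments(0, 1, "noncases")

  # identical densities: the score is uninformative, posterior equals prior
  same1 <- group_moments(0.4, 1.1, "cases")
  same0 <- group_moments(0.4, 1.1, "noncases")
  x <- seq(-3, 3, by = 0.5)
  expect_equal(raw_probability(x, same1, same0, 0.23), rep(0.23, length(x)))

  # symmetric groups at K = 0.5: the midpoint is a coin flip
  sym1 <- group_moments(0.8, 1, "cases")
  sym0 <- group_moments(-0.8, 1, "noncases")
  expect_equal(raw_probability(0, sym1, sym0, 0.5), 0.5)

  # equal variances: densities cross at the midpoint, posterior = K there
  expect_equal(raw_probability(0.5, m1, m0, 0.1), 0.1)
})

test_that("raw log-odds is affine for equal variances and matches the logit", {
  m1 <- group_moments(0.7, 1.3, "cases")
  m0 <- group_moments(-0.1, 1.3, "noncases")
  K <- 0.08
  x <- seq(-5, 5, by = 0.25)
  y <- raw_log_odds(x, m1, m0, K)

  # exact affine form: slope (m1-m0)/sigma^2, intercept from the density ratio
  slope <- (m1$mean - m0$mean) / m1$variance
  intercept <- log(K / (1 - K)) - (m1$mean^2 - m0$mean^2) / (2 * m1$variance)
  expect_equal(y, intercept + slope * x, tolerance = 1e-12)

  # definitional identity with the raw probability
  expect_equal(y, qlogis(raw_probability(x, m1, m0, K)), tolerance = 1e-12)

  # uninformative score: log prior odds everywhere
  same <- raw_log_odds(x, group_moments(0, 1, "cases"),
                       group_moments(0, 1, "noncases"), 0.2)
  expect_equal(same, rep(log(0.2 / 0.8), length(x)))
})

test_that("closed-form coefficients reduce to discriminant analysis for equal variances", {
  # null separation: flat curve at the prevalence
  null <- closed_form_coefficients(group_moments(0.3, 1.7, "cases"),
                                   group_moments(0.3, 1.7, "noncases"), 0.12)
  expect_equal(null$beta, 0)
  expect_equal(null$alpha, log(0.12 / 0.88))
  expect_equal(logistic_probability(null, c(-10, 0, 10)), rep(0.12, 3))

  # worked numbers: m0=0, m1=0.5, sigma^2=1, K=0.1
  cf <- closed_form_coefficients(group_moments(0.5, 1, "cases"),
                                 group_moments(0, 1, "noncases"), 0.1)
  expect_equal(cf$beta, 0.5, tolerance = 1e-12)
  expect_equal(cf$alpha, log(1 / 9) - 0.125, tolerance = 1e-12)

  # property over random equal-variance draws
  draws <- draw_moments(300, seed = 7)
  for (i in seq_len(nrow(draws))) {
    v <- draws$v0[i]
    m0 <- draws$m0[i]; m1 <- m0 + draws$d[i]; K <- draws$K[i]
    cf <- closed_form_coefficients(group_moments(m1, v, "cases"),
                                   group_moments(m0, v, "noncases"), K)
    expect_equal(cf$beta, (m1 - m0) / v, tolerance = 1e-10)
    expect_equal(cf$alpha, log(K / (1 - K)) - (m1^2 - m0^2) / (2 * v),
                 tolerance = 1e-10)
  }
})

test_that("logistic probability is stable, bounded and monotone", {
  curve <- closed_form_coefficients(group_moments(0.5, 1, "cases"),
                                    group_moments(0, 1, "noncases"), 0.1)
  flat <- curve; flat$alpha <- 0; flat$beta <- 0
  expect_equal(logistic_probability(flat, c(-100, 0, 100)), rep(0.5, 3))

  # logit zero at x = -alpha/beta
  expect_equal(logistic_probability(curve, -curve$alpha / curve$beta), 0.5)

  # alpha = -2.32222, beta = 0.5 at x = 0: 1/(1 + e^{2.32222})
  lit <- curve; lit$alpha <- -2.32222; lit$beta <- 0.5
  expect_equal(logistic_probability(lit, 0), 0.089294, tolerance = 1e-4)

  # extreme linear predictors saturate without NaN
  big <- curve; big$alpha <- 0; big$beta <- 1
  expect_equal(logistic_probability(big, c(-700, 700)), c(0, 1))

  x <- seq(-6, 6, by = 0.1)
  p <- logistic_probability(curve, x)
  expect_true(all(diff(p) > 0))
  expect_true(all(p > 0 & p < 1))
})

test_that("probability_curve tabulates the logistic curve on the standardized axis", {
  m1 <- group_moments(0.6, 1.2, "cases")
  m0 <- group_moments(0, 0.9, "noncases")
  K <- 0.1
  curve <- closed_form_coefficients(m1, m0, K)
  ct <- probability_curve(curve, n = 81)
  expect_s3_class(ct, "curve_table")
  expect_true(all(diff(ct$x_st) > 0))
  expect_true(all(diff(ct$probability) > 0))  # beta > 0
  expect_true(all(ct$probability >= 0 & ct$probability <= 1))

  # pointwise agreement with logistic_probability on the raw scale
  pop <- mixture_moments(m1, m0, K)
  x <- pop$mean + ct$x_st * sqrt(pop$variance)
  expect_equal(ct$probability, logistic_probability(curve, x))
  expect_equal(ct$raw_probability, raw_probability(x, m1, m0, K))

  # null curve: constant at the prevalence
  null <- closed_form_coefficients(group_moments(0, 1, "cases"),
                                   group_moments(0, 1, "noncases"), 0.2)
  ctn <- probability_curve(null, lo = -4, hi = 4, n = 11)
  expect_equal(ctn$probability, rep(0.2, 11))

  expect_error(probability_curve(curve, lo = 2, hi = -2), "lo must be < hi")
  expect_error(probability_curve(curve, n = 1), "at least 2")
})

test_that("Bayesian inversion conserves the prevalence", {
  draws <- draw_moments(20, seed = 33)
  for (i in seq_len(nrow(draws))) {
    m0 <- group_moments(draws$m0[i], draws$v0[i], "noncases")
    m1 <- group_moments(draws$m0[i] + draws$d[i], draws$v1[i], "cases")
    expect_equal(prevalence_integral(m1, m0, draws$K[i]), draws$K[i],
                 tolerance = 1e-7)
  }
})
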