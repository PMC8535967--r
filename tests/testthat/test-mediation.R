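test_that("sobel_test reproduces the worked first-order statistic", {
  s <- sobel_test(-0.079, 0.006, 0.21, 0.01)
  expect_equal(round(s$z, 2), -11.16)
  expect_lt(s$p, 1e-8)

  # null path: zero coefficient gives z = 0, p = 1
  s0 <- sobel_test(0, 0.01, 0.5, 0.01)
  expect_equal(s0$z, 0)
  expect_equal(s0$p, 1)
  expect_equal(sobel_test(0, 0.02, 0, 0.02)$p, 1)
  expect_error(sobel_test(1, 0, 1, 0.1), "standard errors")

  # the Aroian variance is strictly larger, so |z| strictly smaller
  sa <- sobel_test(-0.079, 0.006, 0.21, 0.01, variant = "aroian")
  expect_lt(abs(sa$z), abs(s$z))
  expect_equal(round(sa$z, 2), -11.15)
})

test_that("sobel_test is antisymmetric in the sign of either path", {
  set.seed(40)
  for (i in 1:10) {
    a <- rnorm(1); b <- rnorm(1)
    se_a <- runif(1, 0.01, 0.3); se_b <- runif(1, 0.01, 0.3)
    s <- sobel_test(a, se_a, b, se_b)
    sn <- sobel_test(-a, se_a, b, se_b)
    expect_equal(sn$z, -s$z)
    expect_equal(sn$p, s$p)
  }
})

test_that("first-order Sobel SE matches a Monte-Carlo delta-method oracle", {
  set.seed(61)
  cases <- list(c(a = -0.8, se_a = 0.08, b = 0.5, se_b = 0.05),
                c(a = 1.2, se_a = 0.1, b = -0.9, se_b = 0.09),
                c(a = 0.6, se_a = 0.05, b = 0.7, se_b = 0.06))
  for (cs in cases) {
    draws_a <- rnorm(1e6, cs["a"], cs["se_a"])
    draws_b <- rnorm(1e6, cs["b"], cs["se_b"])
    sd_mc <- sd(draws_a * draws_b)
    z_mc <- cs[["a"]] * cs[["b"]] / sd_mc
    z <- sobel_test(cs[["a"]], cs[["se_a"]], cs[["b"]], cs[["se_b"]])$z
    expect_lt(abs(z - z_mc) / abs(z_mc), 0.02)
  }
})

test_that("classify_effect implements the four-criterion scheme", {
  # suppression: criteria 1/2/4, |direct| > |total|, opposing signs
  expect_equal(classify_effect(c(TRUE, TRUE, FALSE, TRUE),
                               direct = 0.015, direct_p = 1e-7,
                               indirect = -0.017, total = -0.001),
               "suppression")
  # full mediation: all criteria, direct non-significant
  expect_equal(classify_effect(c(TRUE, TRUE, TRUE, TRUE),
                               direct = 0.001, direct_p = 0.6,
                               indirect = 0.02, total = 0.021),
               "full_mediation")
  # partial mediation: all criteria, direct significant, same signs
  expect_equal(classify_effect(c(TRUE, TRUE, TRUE, TRUE),
                               direct = 0.01, direct_p = 0.001,
                               indirect = 0.02, total = 0.03),
               "partial_mediation")
  # no mediator path
  expect_equal(classify_effect(c(TRUE, FALSE, FALSE, FALSE),
                               direct = 0.02, direct_p = 0.001,
                               indirect = 0.001, total = 0.021),
               "none")
})

test_that("mediation_analyze reproduces the suppression structure", {
  co <- simulate_cohort(simulation_config(seed = 16))
  m <- mediation_analyze(co$genotypes, co$phenotypes, "rs4783244")
  expect_false(m$untestable)
  expect_equal(m$classification, "suppression")
  expect_true(m$criteria_met[1] && m$criteria_met[2] && m$criteria_met[4])
  expect_false(m$criteria_met[3]) # total effect non-significant
  expect_equal(m$indirect, m$alpha$estimate * m$beta$estimate)
  expect_lt(m$indirect, 0)
  expect_gt(m$gamma_prime$estimate, 0)
  expect_gt(abs(m$gamma_prime$estimate), abs(m$total$estimate))
  # estimates near generative truth (wide stochastic bands)
  expect_lt(abs(m$alpha$estimate - (-0.079)), 4 * m$alpha$se)
  expect_lt(abs(m$beta$estimate - 0.21), 4 * m$beta$se)
})

test_that("total effect equals indirect + direct on complete data", {
  for (seed in c(2, 3)) {
    co <- simulate_cohort(quick_config(n_samples = 300, seed = seed,
                                       missing_rate_genotype = 0))
    m <- mediation_analyze(co$genotypes, co$phenotypes, "rs4783244")
    expect_lt(abs(m$total$estimate - m$total_sum), 1e-10)
  }
})

test_that("degenerate path coefficients yield the expected classifications", {
  # no mediator -> outcome path: criterion 2 fails
  co0 <- simulate_cohort(simulation_config(n_samples = 1500, n_null_snps = 0,
                                           beta = 0, seed = 23))
  m0 <- mediation_analyze(co0$genotypes, co0$phenotypes, "rs4783244")
  expect_false(m0$criteria_met[2])
  expect_equal(m0$classification, "none")

  # no direct path, strong indirect path: full mediation
  co1 <- simulate_cohort(simulation_config(n_samples = 2199, n_null_snps = 0,
                                           gamma_prime = 0, seed = 24))
  m1 <- mediation_analyze(co1$genotypes, co1$phenotypes, "rs4783244")
  expect_equal(m1$classification, "full_mediation")
})

test_that("classification is invariant to swapping minor/major allele coding", {
  co <- simulate_cohort(simulation_config(seed = 33, n_null_snps = 0,
                                          missing_rate_genotype = 0))
  m <- mediation_analyze(co$genotypes, co$phenotypes, "rs4783244")
  flipped <- co$genotypes
  flipped$dosages[, "rs4783244"] <- 2L - flipped$dosages[, "rs4783244"]
  mf <- mediation_analyze(flipped, co$phenotypes, "rs4783244")
  expect_equal(mf$alpha$estimate, -m$alpha$estimate, tolerance = 1e-10)
  expect_equal(mf$gamma_prime$estimate, -m$gamma_prime$estimate,
               tolerance = 1e-10)
  expect_equal(mf$beta$estimate, m$beta$estimate, tolerance = 1e-10)
  expect_equal(mf$sobel_z, -m$sobel_z, tolerance = 1e-10)
  expect_equal(mf$classification, m$classification)
})

test_that("mediation_scan reduces to mediation_analyze and handles empty lists", {
  co <- simulate_cohort(quick_config(seed = 44))
  tab <- mediation_scan(co$genotypes, co$phenotypes, "rs4783244")
  m <- mediation_analyze(co$genotypes, co$phenotypes, "rs4783244")
  expect_equal(nrow(tab), 1)
  expect_equal(tab$alpha, m$alpha$estimate)
  expect_equal(tab$sobel_z, m$sobel_z)
  expect_equal(tab$classification, m$classification)

  empty <- mediation_scan(co$genotypes, co$phenotypes, character(0))
  expect_equal(nrow(empty), 0)
  expect_true(all(c("sobel_z", "classification") %in% names(empty)))

  # sorted by |sobel z|
  tab2 <- mediation_scan(co$genotypes, co$phenotypes,
                         co$genotypes$snp_meta$id)
  expect_false(is.unsorted(rev(abs(tab2$sobel_z)), na.rm = TRUE))
})
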