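test_that("EM equals the closed-form counting solution when phase is unambiguous", {
  # no double heterozygotes: every haplotype is directly countable
  g1 <- c(0, 0, 2, 2, 1, 0, 2, 1, 0, 2)
  g2 <- c(0, 1, 2, 2, 0, 0, 1, 0, 1, 2)
  expect_true(sum(g1 == 1 & g2 == 1) == 0)
  est <- em_haplotype_freqs(g1, g2)
  # direct haplotype counting oracle
  count <- c(`00` = 0, `01` = 0, `10` = 0, `11` = 0)
  for (i in seq_along(g1)) {
    h1 <- if (g1[i] == 2) c(1, 1) else if (g1[i] == 1) c(0, 1) else c(0, 0)
    h2 <- if (g2[i] == 2) c(1, 1) else if (g2[i] == 1) c(0, 1) else c(0, 0)
    for (k in 1:2) {
      count[paste0(h1[k], h2[k])] <- count[paste0(h1[k], h2[k])] + 1
    }
  }
  expect_equal(est$frequencies, count / sum(count), tolerance = 1e-9)
  expect_true(est$converged)
})

test_that("haplotype r2 converges to the squared dosage correlation", {
  # the haplotype-based r2 and the composite (dosage) correlation estimate
  # the same population quantity under random mating; at large n they agree
  fp <- simulate_focal_pair(simulation_config(n_samples = 1e5,
                                              ld_dprime = 0.5, seed = 17))
  g1 <- fp$dosages[, 1]; g2 <- fp$dosages[, 2]
  est <- em_haplotype_freqs(g1, g2)
  expect_lt(abs(est$r2 - cor(g1, g2)^2), 0.01)
  # and exactly 1 under complete LD with equal frequencies
  fp1 <- simulate_focal_pair(simulation_config(
    n_samples = 500, maf_focal = c(0.3, 0.3), ld_dprime = 1, seed = 18))
  est1 <- em_haplotype_freqs(fp1$dosages[, 1], fp1$dosages[, 2])
  expect_equal(est1$r2, cor(fp1$dosages[, 1], fp1$dosages[, 2])^2,
               tolerance = 1e-9)
})

test_that("EM maximises the 1-D profile likelihood over the free haplotype frequency", {
  set.seed(90)
  for (i in 1:8) {
    maf <- runif(2, 0.15, 0.45)
    dp <- runif(1, 0, 0.95)
    cfg <- simulation_config(n_samples = 20, maf_focal = sort(maf),
                             ld_dprime = dp, seed = 900 + i)
    fp <- simulate_focal_pair(cfg)
    g1 <- fp$dosages[, 1]; g2 <- fp$dosages[, 2]
    if (var(g1) == 0 || var(g2) == 0) next
    est <- em_haplotype_freqs(g1, g2)
    # grid search over f11 holding the allele-frequency margins fixed
    p1 <- sum(g1) / (2 * length(g1)); p2 <- sum(g2) / (2 * length(g2))
    lo <- max(0, p1 + p2 - 1); hi <- min(p1, p2)
    grid <- seq(lo, hi, by = 1e-5)
    ll <- vapply(grid, function(f11) hap_loglik_f11(g1, g2, f11), numeric(1))
    best <- grid[which.max(ll)]
    expect_lt(abs(est$frequencies[["11"]] - best), 1e-4)
    expect_gte(est$loglik, max(ll) - 1e-6)
  }
})

test_that("EM log-likelihood is non-decreasing and margins are preserved exactly", {
  set.seed(91)
  fp <- simulate_focal_pair(simulation_config(n_samples = 400,
                                              ld_dprime = 0.6, seed = 101))
  g1 <- fp$dosages[, 1]; g2 <- fp$dosages[, 2]
  est <- em_haplotype_freqs(g1, g2)
  expect_true(all(diff(est$loglik_trace) > -1e-8))
  expect_true(est$converged)
  # marginal consistency: fitted frequencies reproduce observed allele freqs
  expect_equal(est$frequencies[["10"]] + est$frequencies[["11"]],
               sum(g1) / (2 * length(g1)), tolerance = 1e-12)
  expect_equal(est$frequencies[["01"]] + est$frequencies[["11"]],
               sum(g2) / (2 * length(g2)), tolerance = 1e-12)
  expect_equal(sum(est$frequencies), 1, tolerance = 1e-12)
})

test_that("generator round trip: D' = 0.9 is recovered within 0.02 at n = 1e5", {
  fp <- simulate_focal_pair(simulation_config(n_samples = 1e5,
                                              ld_dprime = 0.9, seed = 7))
  est <- em_haplotype_freqs(fp$dosages[, 1], fp$dosages[, 2])
  expect_lt(abs(est$dprime - 0.9), 0.02)
})

test_that("monomorphic sites yield a flagged degenerate estimate", {
  g1 <- rep(0, 30)
  g2 <- c(rep(0, 15), rep(1, 10), rep(2, 5))
  est <- em_haplotype_freqs(g1, g2)
  expect_true(est$degenerate)
  expect_equal(est$r2, 0)
  expect_equal(est$dprime, 0)
})

test_that("haplotype association collapses to single-SNP association under complete LD", {
  cfg <- simulation_config(n_samples = 800, maf_focal = c(0.3, 0.3),
                           ld_dprime = 1, n_null_snps = 0,
                           missing_rate_genotype = 0, seed = 50)
  co <- simulate_cohort(cfg)
  hap <- haplotype_association(co$genotypes, cfg$focal_ids, co$phenotypes)
  snp <- snp_association(co$genotypes, co$phenotypes, "rs4783244",
                         "base")
  # under complete LD the TT dosage equals the SNP dosage
  tt <- hap$coefficients[hap$coefficients$haplotype == "11", ]
  expect_equal(tt$estimate, snp$beta, tolerance = 1e-8)
  expect_equal(tt$p, snp$p, tolerance = 1e-8)
  expect_equal(hap$reference, "00")
})

test_that("rare haplotypes are flagged unstable", {
  # deterministic fixture: 40 samples in near-complete LD plus two carriers
  # of the rare recombinant haplotype 01 (expected count 2 < 5)
  g1 <- c(rep(0, 20), rep(1, 10), rep(2, 8), 0, 0)
  g2 <- c(rep(0, 20), rep(1, 10), rep(2, 8), 1, 1)
  dos <- cbind(sA = as.integer(g1), sB = as.integer(g2))
  gm <- gm_from(dos)
  set.seed(99)
  ph <- data.frame(sample_id = gm$sample_ids, sex = rep(0:1, 20),
                   age = rnorm(40, 50, 10), bmi = rnorm(40, 24, 3),
                   smoking = rbinom(40, 1, 0.2),
                   hdl_c = exp(rnorm(40, 4, 0.2)))
  hap <- haplotype_association(gm, c("sA", "sB"), ph)
  tab <- hap$coefficients
  expect_true(tab$unstable[tab$haplotype == "01"])
  expect_lt(tab$expected_count[tab$haplotype == "01"], 5)
  expect_false(tab$unstable[tab$haplotype == "11"])
})

test_that("haplotype p-values are calibrated under the null", {
  pvals <- vapply(1:80, function(i) {
    cfg <- simulation_config(n_samples = 250, alpha = 0, beta = 0,
                             gamma_prime = 0, n_null_snps = 0,
                             ld_dprime = 0.5, missing_rate_genotype = 0,
                             seed = 3000 + i)
    co <- simulate_cohort(cfg)
    hap <- haplotype_association(co$genotypes, cfg$focal_ids, co$phenotypes)
    hap$coefficients$p[hap$coefficients$haplotype == "11"]
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(pvals, "punif")$p.value), 0.01)
})
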