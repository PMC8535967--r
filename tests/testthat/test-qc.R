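test_that("minor allele frequency counts minor alleles over non-missing calls", {
  expect_equal(as.numeric(minor_allele_frequency(c(0, 0, 1, 2))), 0.375)
  expect_equal(as.numeric(minor_allele_frequency(c(0, 0, 0, 0))), 0)
  expect_equal(as.numeric(minor_allele_frequency(c(0, NA, 1, 2))), 0.5)

  # folding when labels are swapped
  f <- minor_allele_frequency(c(2, 2, 2, 1))
  expect_equal(as.numeric(f), 1 / 8)
  expect_true(attr(f, "swapped"))

  expect_error(minor_allele_frequency(c(NA, NA)), "all genotypes missing")

  # brute-force allele-count oracle on random vectors
  set.seed(101)
  for (i in 1:20) {
    g <- sample(c(0:2, NA), 50, replace = TRUE, prob = c(0.5, 0.3, 0.1, 0.1))
    if (all(is.na(g))) next
    cnt <- sum(g, na.rm = TRUE)
    tot <- 2 * sum(!is.na(g))
    expect_equal(as.numeric(minor_allele_frequency(g)),
                 min(cnt / tot, 1 - cnt / tot))
  }
})

test_that("HWE exact test matches full enumeration and handles degenerate input", {
  expect_equal(hwe_exact_test(17, 0, 0), 1)       # monomorphic
  expect_equal(hwe_exact_test(0, 0, 9), 1)        # monomorphic, minor side
  expect_equal(hwe_exact_test(49, 0, 1), hwe_enum(49, 0, 1))
  expect_error(hwe_exact_test(-1, 2, 3), "non-negative")
  expect_error(hwe_exact_test(0, 0, 0), "at least one")

  set.seed(7)
  for (i in 1:50) {
    tab <- as.integer(rmultinom(1, sample(5:200, 1), prob = runif(3)))
    p <- hwe_exact_test(tab[1], tab[2], tab[3])
    expect_gt(p, 0)
    expect_lte(p, 1)
    expect_equal(p, hwe_enum(tab[1], tab[2], tab[3]), tolerance = 1e-12)
  }
})

test_that("HWE exact test agrees with the chi-square test for large balanced counts", {
  # expected cell counts all > 50: asymptotics should hold within 10%
  cases <- list(c(400, 500, 120), c(900, 950, 260), c(500, 480, 130))
  for (cs in cases) {
    n <- sum(cs)
    q <- (2 * cs[3] + cs[2]) / (2 * n)
    e <- n * c((1 - q)^2, 2 * q * (1 - q), q^2)
    expect_true(all(e > 50))
    chi_p <- pchisq(sum((cs - e)^2 / e), df = 1, lower.tail = FALSE)
    exact_p <- hwe_exact_test(cs[1], cs[2], cs[3])
    expect_lt(abs(exact_p - chi_p) / chi_p, 0.10)
  }
})

test_that("apply_qc filters samples first, then SNPs, with reason codes", {
  # 10-sample hand-crafted fixture:
  #   sample 10 has call rate 1/4 (fails the 0.7 floor; sample 3 at 3/4 passes)
  #   after its removal: snp_clean passes everything;
  #   snp_miss has 1/9 missing (> 3%); snp_hwe is (5,0,4) with exact
  #   p = 0.00288 (< 0.01 floor); snp_rare is monomorphic (MAF 0)
  dos <- cbind(
    snp_clean = c(0, 0, 1, 1, 0, 2, 1, 0, 1, 0),
    snp_miss  = c(0, 1, NA, 0, 1, 0, 1, 0, 0, NA),
    snp_hwe   = c(0, 0, 0, 0, 0, 2, 2, 2, 2, NA),
    snp_rare  = c(0, 0, 0, 0, 0, 0, 0, 0, 0, NA)
  )
  gm <- gm_from(dos)
  th <- qc_thresholds(min_maf = 0.05, max_snp_missing = 0.03,
                      min_sample_call_rate = 0.7, hwe_p_floor = 0.01)
  res <- apply_qc(gm, th)
  rep <- res$report

  expect_equal(rep$n_samples_retained, 9)
  expect_false(rep$samples$pass[10])
  expect_equal(rep$samples$reason[10], "call_rate")

  expect_equal(rep$n_snps_retained, 1)
  expect_equal(rep$snps$reason[rep$snps$id == "snp_miss"], "missing")
  expect_equal(rep$snps$reason[rep$snps$id == "snp_hwe"], "hwe")
  expect_equal(rep$snps$reason[rep$snps$id == "snp_rare"], "maf")
  expect_equal(rep$snps$hwe_p[rep$snps$id == "snp_hwe"], hwe_enum(5, 0, 4))
  expect_equal(colnames(res$genotypes$dosages), "snp_clean")

  # retained SNPs satisfy the thresholds
  kept <- rep$snps[rep$snps$pass, ]
  expect_true(all(kept$maf >= th$min_maf))
  expect_true(all(kept$hwe_p >= th$hwe_p_floor))
})

test_that("apply_qc is idempotent and is the identity on an all-pass matrix", {
  co <- simulate_cohort(quick_config(n_samples = 300, n_null_snps = 10,
                                     seed = 5, missing_rate_genotype = 0.001,
                                     maf_range_null = c(0.2, 0.5)))
  res1 <- apply_qc(co$genotypes)
  res2 <- apply_qc(res1$genotypes)
  expect_identical(res1$genotypes$dosages, res2$genotypes$dosages)
  expect_equal(res2$report$n_snps_retained, res1$report$n_snps_retained)
  expect_equal(res2$report$n_samples_retained, res1$report$n_samples_retained)

  # clean matrix: output identical to input, report all-pass
  dos <- cbind(a = c(0, 1, 2, 1, 0, 1, 0, 2), b = c(1, 0, 1, 1, 2, 0, 0, 1))
  gm <- gm_from(dos)
  res <- apply_qc(gm)
  expect_identical(res$genotypes$dosages, gm$dosages)
  expect_true(all(res$report$snps$pass))
  expect_true(all(res$report$samples$pass))
})

test_that("QC that removes everything raises an error carrying the report", {
  dos <- cbind(a = c(0, 0, 0, 0), b = c(0, 0, 0, 0)) # monomorphic only
  err <- tryCatch(apply_qc(gm_from(dos)), error = identity)
  expect_s3_class(err, "qc_empty_error")
  expect_false(is.null(err$report))
})
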