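# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: normal equations instead of QR, log-factorial
# enumeration instead of the recurrence, grid search instead of EM.

# OLS via the normal equations
ne_ols <- function(y, X) {
  XtX <- crossprod(X)
  beta <- solve(XtX, crossprod(X, y))
  res <- y - X %*% beta
  df <- nrow(X) - ncol(X)
  sigma2 <- sum(res^2) / df
  se <- sqrt(diag(solve(XtX)) * sigma2)
  tval <- as.numeric(beta) / as.numeric(se)
  list(estimate = as.numeric(beta), se = unname(as.numeric(se)),
       p = unname(2 * pt(-abs(tval), df)))
}

# HWE exact p by full enumeration of heterozygote counts (log-factorials)
hwe_enum <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  nm <- 2 * naa + nAa
  rare <- min(nm, 2 * n - nm)
  if (rare == 0) return(1)
  hets <- seq(rare %% 2, rare, by = 2)
  lp <- vapply(hets, function(h) {
    homr <- (rare - h) / 2
    homc <- n - h - homr
    h * log(2) + lfactorial(n) - lfactorial(homr) - lfactorial(h) -
      lfactorial(homc)
  }, numeric(1))
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  obs <- pr[match(min(nAa, rare), hets)]
  min(sum(pr[pr <= obs * (1 + 1e-12)]), 1)
}

# two-locus log-likelihood at haplotype frequencies constrained to the
# observed allele-frequency margins, parameterised by f11
hap_loglik_f11 <- function(g1, g2, f11) {
  keep <- !is.na(g1) & !is.na(g2)
  g1 <- g1[keep]; g2 <- g2[keep]
  n <- length(g1)
  p1 <- sum(g1) / (2 * n); p2 <- sum(g2) / (2 * n)
  f <- c(1 - p1 - p2 + f11, p2 - f11, p1 - f11, f11)
  if (any(f < -1e-12)) return(-Inf)
  f <- pmax(f, 1e-300)
  P <- matrix(0, 3, 3)
  P[1, 1] <- f[1]^2;           P[1, 2] <- 2 * f[1] * f[2]; P[1, 3] <- f[2]^2
  P[2, 1] <- 2 * f[1] * f[3];  P[2, 2] <- 2 * f[1] * f[4] + 2 * f[2] * f[3]
  P[2, 3] <- 2 * f[2] * f[4]
  P[3, 1] <- f[3]^2;           P[3, 2] <- 2 * f[3] * f[4]; P[3, 3] <- f[4]^2
  ll <- 0
  for (i in 0:2) for (j in 0:2) {
    cnt <- sum(g1 == i & g2 == j)
    if (cnt > 0) ll <- ll + cnt * log(P[i + 1, j + 1])
  }
  ll
}

# small fast cohort for unit tests
quick_config <- function(n_samples = 400, n_null_snps = 3, seed = 42, ...) {
  simulation_config(n_samples = n_samples, n_null_snps = n_null_snps,
                    seed = seed, ...)
}

# genotype matrix from a bare dosage matrix with default metadata
gm_from <- function(dos, ids = NULL) {
  if (is.null(colnames(dos))) {
    colnames(dos) <- sprintf("snp%02d", seq_len(ncol(dos)))
  }
  genotype_matrix(dos, sample_ids = ids)
}
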