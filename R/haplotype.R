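# Two-locus haplotype frequency estimation and LD statistics.
#
# Phase is ambiguous only in double heterozygotes; the EM algorithm iterates
# between splitting those samples across the two consistent haplotype pairs
# (E-step) and re-counting haplotype frequencies (M-step). All other genotype
# combinations contribute known haplotype counts.

# genotype-pair probability table from haplotype freqs f = c(f00,f01,f10,f11)
# (index 1 = allele 0/0 etc.; "1" = minor allele). Returns 3x3 matrix P[g1+1, g2+1].
.hap_geno_probs <- function(f) {
  f00 <- f[1]; f01 <- f[2]; f10 <- f[3]; f11 <- f[4]
  P <- matrix(0, 3, 3)
  P[1, 1] <- f00^2
  P[1, 2] <- 2 * f00 * f01
  P[1, 3] <- f01^2
  P[2, 1] <- 2 * f00 * f10
  P[2, 2] <- 2 * f00 * f11 + 2 * f01 * f10
  P[2, 3] <- 2 * f01 * f11
  P[3, 1] <- f10^2
  P[3, 2] <- 2 * f10 * f11
  P[3, 3] <- f11^2
  P
}

.hap_loglik <- function(counts, f) {
  P <- .hap_geno_probs(f)
  sel <- counts > 0
  sum(counts[sel] * log(P[sel]))
}

#' EM estimation of two-locus haplotype frequencies
#'
#' Maximum-likelihood haplotype frequencies for two biallelic SNPs from
#' unphased dosages, resolving the double-heterozygote phase ambiguity by
#' expectation-maximisation. Iteration starts from linkage-equilibrium
#' frequencies (a deterministic start), stops when the largest frequency
#' change is below `tol` or after `max_iter` iterations, and the
#' log-likelihood is checked to be non-decreasing at every step.
#'
#' LD statistics are derived from the fitted frequencies:
#' `D = f11 - p1 p2`, `D'` is `|D|` over its admissible maximum, and
#' `r^2 = D^2 / (p1 (1-p1) p2 (1-p2))`.
#'
#' @param g1,g2 dosage vectors (0/1/2/NA) over the same samples.
#' @param tol convergence tolerance on haplotype frequencies.
#' @param max_iter iteration cap.
#' @return object of class `haplotype_estimate`: `frequencies` (named
#'   `"00","01","10","11"`, 0 = major and 1 = minor allele, site 1 first),
#'   `D`, `dprime`, `r2`, `loglik`, `loglik_trace`, `iterations`,
#'   `converged`, `degenerate`, `n` (complete sample pairs).
#' @export
em_haplotype_freqs <- function(g1, g2, tol = 1e-10, max_iter = 1000L) {
  if (length(g1) != length(g2)) stop("dosage vectors must cover the same samples")
  keep <- !is.na(g1) & !is.na(g2)
  g1 <- g1[keep]; g2 <- g2[keep]
  n <- length(g1)
  if (n < 1) stop("no complete genotype pairs")
  counts <- matrix(0, 3, 3)
  for (i in 0:2) for (j in 0:2) counts[i + 1, j + 1] <- sum(g1 == i & g2 == j)

  p1 <- sum(g1) / (2 * n)
  p2 <- sum(g2) / (2 * n)
  base <- list(D = 0, dprime = 0, r2 = 0)
  if (p1 %in% c(0, 1) || p2 %in% c(0, 1)) {
    f <- c(`00` = (1 - p1) * (1 - p2), `01` = (1 - p1) * p2,
           `10` = p1 * (1 - p2), `11` = p1 * p2)
    return(structure(list(
      frequencies = f, D = 0, dprime = 0, r2 = 0,
      loglik = .hap_loglik(counts, f), loglik_trace = numeric(0),
      iterations = 0L, converged = TRUE, degenerate = TRUE, n = n
    ), class = "haplotype_estimate"))
  }

  # unambiguous haplotype counts (everything but double heterozygotes)
  c00 <- 2 * counts[1, 1] + counts[1, 2] + counts[2, 1]
  c01 <- 2 * counts[1, 3] + counts[1, 2] + counts[2, 3]
  c10 <- 2 * counts[3, 1] + counts[2, 1] + counts[3, 2]
  c11 <- 2 * counts[3, 3] + counts[3, 2] + counts[2, 3]
  n_dh <- counts[2, 2]

  f <- c((1 - p1) * (1 - p2), (1 - p1) * p2, p1 * (1 - p2), p1 * p2)
  ll <- .hap_loglik(counts, f)
  trace <- ll
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    w <- if (n_dh > 0) {
      num <- f[1] * f[4]
      den <- f[1] * f[4] + f[2] * f[3]
      if (den == 0) 0.5 else num / den
    } else 0
    new_f <- c(c00 + w * n_dh, c01 + (1 - w) * n_dh,
               c10 + (1 - w) * n_dh, c11 + w * n_dh) / (2 * n)
    new_ll <- .hap_loglik(counts, new_f)
    if (new_ll < ll - 1e-8) {
      stop("internal error: EM log-likelihood decreased")
    }
    delta <- max(abs(new_f - f))
    f <- new_f
    ll <- new_ll
    trace <- c(trace, ll)
    if (delta < tol) { converged <- TRUE; break }
  }

  names(f) <- c("00", "01", "10", "11")
  p1_hat <- f[["10"]] + f[["11"]]
  p2_hat <- f[["01"]] + f[["11"]]
  D <- f[["11"]] - p1_hat * p2_hat
  dmax <- if (D >= 0) {
    min(p1_hat * (1 - p2_hat), (1 - p1_hat) * p2_hat)
  } else {
    min(p1_hat * p2_hat, (1 - p1_hat) * (1 - p2_hat))
  }
  dprime <- if (dmax > 0) abs(D) / dmax else 0
  denom <- p1_hat * (1 - p1_hat) * p2_hat * (1 - p2_hat)
  r2 <- if (denom > 0) D^2 / denom else 0

  structure(list(
    frequencies = f, D = D, dprime = dprime, r2 = r2,
    loglik = ll, loglik_trace = trace, iterations = it,
    converged = converged, degenerate = FALSE, n = n
  ), class = "haplotype_estimate")
}

#' @export
print.haplotype_estimate <- function(x, ...) {
  cat(sprintf("haplotype_estimate (n = %d, %s in %d iteration(s))\n", x$n,
              if (x$converged) "converged" else "NOT converged", x$iterations))
  print(round(x$frequencies, 6))
  cat(sprintf("D = %.5f, D' = %.4f, r2 = %.4f, loglik = %.4f\n",
              x$D, x$dprime, x$r2, x$loglik))
  invisible(x)
}

# expected per-sample haplotype dosages given EM frequencies (n x 4 matrix)
.expected_hap_dosages <- function(g1, g2, f) {
  n <- length(g1)
  H <- matrix(0, n, 4, dimnames = list(NULL, c("00", "01", "10", "11")))
  num <- f[["00"]] * f[["11"]]
  den <- num + f[["01"]] * f[["10"]]
  w <- if (den > 0) num / den else 0.5
  for (i in seq_len(n)) {
    a <- g1[i]; b <- g2[i]
    if (is.na(a) || is.na(b)) { H[i, ] <- NA_real_; next }
    if (a == 1 && b == 1) {
      H[i, ] <- c(w, 1 - w, 1 - w, w)
    } else {
      # haplotype alleles determined: site1 contributes a copies of "1"
      h1_minor <- if (a == 2) c(1, 1) else if (a == 1) c(0, 1) else c(0, 0)
      h2_minor <- if (b == 2) c(1, 1) else if (b == 1) c(0, 1) else c(0, 0)
      # pair the unique assignment (only one site can be heterozygous here)
      for (k in 1:2) {
        lab <- paste0(h1_minor[k], h2_minor[k])
        H[i, lab] <- H[i, lab] + 1
      }
    }
  }
  H
}

#' Haplotype association with a quantitative outcome
#'
#' Regresses the transformed outcome on expected per-sample haplotype dosages
#' (posterior counts from the EM fit) plus covariates, one coefficient per
#' non-reference haplotype. The reference is the most frequent haplotype.
#' Haplotypes with expected total count below 5 are flagged unstable;
#' haplotypes with (near-)zero expected count are dropped as non-estimable.
#'
#' @param genotypes a [genotype_matrix].
#' @param snps length-2 character vector of SNP ids forming the pair.
#' @param phenotypes phenotype data.frame with `sample_id`.
#' @param outcome outcome column (default `hdl_c`).
#' @param covariates covariate columns.
#' @param log_outcome log-transform the outcome (default TRUE).
#' @return list with `estimate` (the `haplotype_estimate`), `reference`
#'   (haplotype label) and `coefficients`: data.frame of haplotype,
#'   expected_count, estimate, se, p, unstable.
#' @export
haplotype_association <- function(genotypes, snps, phenotypes,
                                  outcome = "hdl_c",
                                  covariates = c("age", "sex", "bmi", "smoking"),
                                  log_outcome = TRUE) {
  stopifnot(length(snps) == 2)
  g1 <- .get_dosage(genotypes, snps[1])
  g2 <- .get_dosage(genotypes, snps[2])
  est <- em_haplotype_freqs(g1, g2)
  if (!est$converged) stop("EM did not converge; cannot run haplotype association")

  idx <- match(genotypes$sample_ids, phenotypes$sample_id)
  ph <- phenotypes[idx, , drop = FALSE]
  H <- .expected_hap_dosages(g1, g2, est$frequencies)
  df <- data.frame(ph[, c(outcome, covariates), drop = FALSE], H,
                   check.names = FALSE)
  keep <- complete.cases(df)
  df <- df[keep, , drop = FALSE]
  Hk <- as.matrix(df[, colnames(H), drop = FALSE])

  exp_counts <- colSums(Hk)
  reference <- names(which.max(est$frequencies))
  candidates <- setdiff(colnames(H), reference)
  estimable <- candidates[exp_counts[candidates] > 1e-8]
  y <- transform_phenotype(df[[outcome]], if (log_outcome) "log" else "identity")
  X <- cbind(intercept = 1, as.matrix(df[, covariates, drop = FALSE]),
             Hk[, estimable, drop = FALSE])
  fit <- ols_fit(as.numeric(y), X)
  rows <- do.call(rbind, lapply(estimable, function(h) {
    r <- .coef_row(fit, h)
    data.frame(haplotype = h, expected_count = exp_counts[[h]],
               estimate = r$estimate, se = r$se, p = r$p,
               unstable = exp_counts[[h]] < 5, stringsAsFactors = FALSE)
  }))
  rownames(rows) <- NULL
  list(estimate = est, reference = reference, coefficients = rows,
       n = nrow(df))
}

#' Write a two-locus LD/haplotype report to TSV
#' @param hap result of [haplotype_association()] or a `haplotype_estimate`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_haplotype_tsv <- function(hap, path) {
  est <- if (inherits(hap, "haplotype_estimate")) hap else hap$estimate
  freq <- data.frame(record = "frequency", key = names(est$frequencies),
                     value = as.numeric(est$frequencies),
                     stringsAsFactors = FALSE)
  ld <- data.frame(record = "ld", key = c("D", "dprime", "r2", "loglik", "n"),
                   value = c(est$D, est$dprime, est$r2, est$loglik, est$n),
                   stringsAsFactors = FALSE)
  write.table(rbind(freq, ld), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!inherits(hap, "haplotype_estimate") && !is.null(hap$coefficients)) {
    write.table(hap$coefficients, paste0(path, ".assoc.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
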