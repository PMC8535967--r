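#' QC thresholds
#'
#' Default filter set for a quantitative-trait GWAS: minimum minor allele
#' frequency 0.05, maximum per-SNP missingness 3%, minimum per-sample call
#' rate 97%, Hardy-Weinberg exact-test p-value floor 1e-6.
#'
#' @param min_maf minimum minor allele frequency for a SNP to be retained.
#' @param max_snp_missing maximum fraction of missing calls per SNP.
#' @param min_sample_call_rate minimum fraction of non-missing calls per sample.
#' @param hwe_p_floor SNPs with exact-test p below this are excluded.
#' @return An object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_maf = 0.05, max_snp_missing = 0.03,
                          min_sample_call_rate = 0.97, hwe_p_floor = 1e-6) {
  th <- list(min_maf = min_maf, max_snp_missing = max_snp_missing,
             min_sample_call_rate = min_sample_call_rate,
             hwe_p_floor = hwe_p_floor)
  if (any(unlist(th) <= 0) || any(unlist(th) >= 1)) {
    stop("all QC thresholds must lie strictly in (0, 1)")
  }
  structure(th, class = "qc_thresholds")
}

#' Minor allele frequency of a dosage vector
#'
#' Counts minor alleles over non-missing calls. If the computed frequency
#' exceeds 0.5 the minor/major labels were evidently swapped; the returned
#' value is folded to the minor side and the swap recorded in the `swapped`
#' attribute.
#'
#' @param dosages vector of 0/1/2/NA minor-allele counts.
#' @return frequency in `[0, 0.5]` with attribute `swapped` (logical).
#' @examples
#' minor_allele_frequency(c(0, 0, 1, 2)) # 3 minor alleles / 8 = 0.375
#' @export
minor_allele_frequency <- function(dosages) {
  ok <- !is.na(dosages)
  if (!any(ok)) stop("cannot compute MAF: all genotypes missing")
  f <- sum(dosages[ok]) / (2 * sum(ok))
  swapped <- f > 0.5
  if (swapped) f <- 1 - f
  structure(f, swapped = swapped)
}

# vectorised MAF over matrix columns (no swap bookkeeping)
.maf_cols <- function(dos) {
  nm <- colSums(!is.na(dos))
  f <- colSums(dos, na.rm = TRUE) / (2 * pmax(nm, 1L))
  f[nm == 0] <- NA_real_
  pmin(f, 1 - f)
}

#' Hardy-Weinberg exact test
#'
#' Conditional exact test for deviation from Hardy-Weinberg genotype
#' proportions: given the observed allele counts, the probability of each
#' possible heterozygote count is computed by recurrence and the two-sided
#' p-value is the sum of probabilities of all configurations no more likely
#' than the observed one (plain tail summation, no mid-p correction).
#'
#' @param n_hom_major count of major-allele homozygotes.
#' @param n_het count of heterozygotes.
#' @param n_hom_minor count of minor-allele homozygotes.
#' @return exact p-value in `(0, 1]`; monomorphic input returns 1 by
#'   convention (no test possible).
#' @examples
#' hwe_exact_test(25, 50, 25)
#' hwe_exact_test(49, 0, 1) # strong heterozygote deficit
#' @export
hwe_exact_test <- function(n_hom_major, n_het, n_hom_minor) {
  counts <- c(n_hom_major, n_het, n_hom_minor)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("genotype counts must be non-negative integers")
  }
  n <- sum(counts)
  if (n < 1) stop("at least one genotyped sample is required")
  n_minor <- 2 * n_hom_minor + n_het
  rare <- min(n_minor, 2L * n - n_minor)
  if (rare == 0L) return(1)

  hets <- seq.int(rare %% 2L, rare, by = 2L)
  probs <- numeric(length(hets))
  # start at an interior heterozygote count and fill by recurrence
  mid <- floor(rare * (2 * n - rare) / (2 * n))
  if (mid %% 2L != rare %% 2L) mid <- mid + 1L
  mid_i <- match(mid, hets)
  probs[mid_i] <- 1
  if (mid_i > 1) {
    for (i in seq(mid_i, 2L)) {
      h <- hets[i]
      homr <- (rare - h) / 2          # rare-allele homozygotes at h
      homc <- n - h - homr            # common-allele homozygotes at h
      probs[i - 1L] <- probs[i] * h * (h - 1) /
        (4 * (homr + 1) * (homc + 1))
    }
  }
  if (mid_i < length(hets)) {
    for (i in seq(mid_i, length(hets) - 1L)) {
      h <- hets[i]
      homr <- (rare - h) / 2
      homc <- n - h - homr
      probs[i + 1L] <- probs[i] * 4 * homr * homc / ((h + 1) * (h + 2))
    }
  }
  probs <- probs / sum(probs)
  obs <- probs[match(min(n_het, rare), hets)]
  p <- sum(probs[probs <= obs * (1 + 1e-12)])
  min(p, 1)
}

#' Apply sample- and SNP-level quality control
#'
#' Samples are filtered first on call rate; SNP statistics (missingness, MAF,
#' Hardy-Weinberg exact p) are then computed on the retained samples, in that
#' fixed order. Every exclusion carries its triggering reason codes.
#'
#' @param genotypes a [genotype_matrix].
#' @param thresholds a [qc_thresholds()].
#' @return list with `genotypes` (the filtered [genotype_matrix]) and
#'   `report` (class `qc_report`): per-sample and per-SNP tables with pass
#'   flags and reason codes, plus retained counts.
#' @export
apply_qc <- function(genotypes, thresholds = qc_thresholds()) {
  stopifnot(inherits(genotypes, "genotype_matrix"),
            inherits(thresholds, "qc_thresholds"))
  dos <- genotypes$dosages
  call_rate <- rowMeans(!is.na(dos))
  sample_pass <- call_rate >= thresholds$min_sample_call_rate
  sample_table <- data.frame(
    sample_id = genotypes$sample_ids, call_rate = call_rate,
    pass = sample_pass,
    reason = ifelse(sample_pass, "", "call_rate"),
    stringsAsFactors = FALSE
  )
  if (!any(sample_pass)) {
    stop(errorCondition("QC removed every sample",
                        class = c("qc_empty_error", "error", "condition"),
                        report = list(samples = sample_table)))
  }
  dos <- dos[sample_pass, , drop = FALSE]

  miss <- colMeans(is.na(dos))
  maf <- .maf_cols(dos)
  hwe_p <- vapply(seq_len(ncol(dos)), function(j) {
    g <- dos[, j]
    g <- g[!is.na(g)]
    if (!length(g)) return(NA_real_)
    hwe_exact_test(sum(g == 0L), sum(g == 1L), sum(g == 2L))
  }, numeric(1))

  fail_missing <- miss > thresholds$max_snp_missing
  fail_maf <- is.na(maf) | maf < thresholds$min_maf
  fail_hwe <- !is.na(hwe_p) & hwe_p < thresholds$hwe_p_floor
  snp_pass <- !(fail_missing | fail_maf | fail_hwe)
  reasons <- vapply(seq_len(ncol(dos)), function(j) {
    paste(c(if (fail_maf[j]) "maf", if (fail_missing[j]) "missing",
            if (fail_hwe[j]) "hwe"), collapse = ";")
  }, character(1))
  snp_table <- data.frame(
    id = genotypes$snp_meta$id, maf = as.numeric(maf),
    missing = miss, hwe_p = hwe_p, pass = snp_pass, reason = reasons,
    stringsAsFactors = FALSE
  )

  report <- structure(list(
    samples = sample_table, snps = snp_table,
    n_samples_retained = sum(sample_pass),
    n_snps_retained = sum(snp_pass),
    thresholds = thresholds
  ), class = "qc_report")

  if (!any(snp_pass)) {
    stop(errorCondition("QC removed every SNP",
                        class = c("qc_empty_error", "error", "condition"),
                        report = report))
  }
  filtered <- genotype_matrix(
    dos[, snp_pass, drop = FALSE],
    sample_ids = genotypes$sample_ids[sample_pass],
    snp_meta = genotypes$snp_meta[snp_pass, , drop = FALSE]
  )
  list(genotypes = filtered, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("qc_report: %d/%d samples and %d/%d SNPs retained\n",
              x$n_samples_retained, nrow(x$samples),
              x$n_snps_retained, nrow(x$snps)))
  excl <- x$snps[!x$snps$pass, , drop = FALSE]
  if (nrow(excl)) {
    tab <- sort(table(excl$reason), decreasing = TRUE)
    cat("SNP exclusions:",
        paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a QC report to disk
#'
#' Per-SNP and per-sample tables as TSV plus a JSON summary of the retained
#' counts and thresholds.
#'
#' @param report a `qc_report` from [apply_qc()].
#' @param dir output directory.
#' @return written paths, invisibly.
#' @export
write_qc_report <- function(report, dir) {
  stopifnot(inherits(report, "qc_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "qc_snps.tsv")
  p2 <- file.path(dir, "qc_samples.tsv")
  p3 <- file.path(dir, "qc_summary.json")
  write.table(report$snps, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(report$samples, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(
    n_samples_retained = report$n_samples_retained,
    n_snps_retained = report$n_snps_retained,
    thresholds = unclass(report$thresholds)
  ), p3, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(p1, p2, p3))
}
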