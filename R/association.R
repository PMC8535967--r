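#' Ordinary least squares fit with classical standard errors
#'
#' Thin fitting engine used by every regression in the package: QR-based
#' least squares (via [stats::lm.fit]) with homoscedastic standard errors and
#' two-sided p-values from the t distribution on the residual degrees of
#' freedom.
#'
#' @param response numeric vector.
#' @param design numeric matrix of predictors including an intercept column;
#'   must have column names and full column rank.
#' @return object of class `regression_fit`: list with `coefficients`
#'   (data.frame term/estimate/se/t/p), `sigma`, `df_residual`, `n`.
#' @examples
#' x <- 1:10
#' f <- ols_fit(2 * x + 1, cbind(intercept = 1, x = x))
#' f$coefficients
#' @export
ols_fit <- function(response, design) {
  y <- as.numeric(response)
  X <- as.matrix(design)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (anyNA(y) || anyNA(X)) {
    stop("ols_fit expects complete data; apply list-wise deletion first")
  }
  n <- length(y)
  p <- ncol(X)
  if (nrow(X) != n) stop("response and design dimensions disagree")
  if (n <= p) {
    stop(sprintf("insufficient rows: %d observations for %d predictors", n, p))
  }
  fit <- stats::lm.fit(X, y)
  if (fit$rank < p) {
    dropped <- colnames(X)[is.na(fit$coefficients)]
    stop("rank-deficient design; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  res <- fit$residuals
  df <- fit$df.residual
  sigma2 <- sum(res^2) / df
  R <- fit$qr$qr[seq_len(p), seq_len(p), drop = FALSE]
  R[lower.tri(R)] <- 0
  cov_unscaled <- chol2inv(R)
  piv <- fit$qr$pivot
  cov <- matrix(NA_real_, p, p)
  cov[piv, piv] <- cov_unscaled
  se <- sqrt(diag(cov) * sigma2)
  est <- fit$coefficients
  tval <- est / se
  pval <- 2 * pt(-abs(tval), df)
  structure(list(
    coefficients = data.frame(term = colnames(X), estimate = unname(est),
                              se = unname(se), t = unname(tval),
                              p = unname(pval), stringsAsFactors = FALSE),
    sigma = sqrt(sigma2), df_residual = df, n = n
  ), class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("regression_fit: n = %d, residual df = %d, sigma = %.4g\n",
              x$n, x$df_residual, x$sigma))
  print(x$coefficients, row.names = FALSE)
  invisible(x)
}

.coef_row <- function(fit, term) {
  fit$coefficients[fit$coefficients$term == term, , drop = FALSE]
}

#' Transform a phenotype vector
#'
#' Natural-log or identity transform, recording which was applied. Positive
#' phenotypes such as HDL-C and triglycerides are log-transformed before
#' regression to better satisfy normality assumptions.
#'
#' @param values numeric vector; strictly positive when `transform = "log"`.
#' @param transform `"log"` or `"identity"`.
#' @return transformed vector with attribute `transform`.
#' @export
transform_phenotype <- function(values, transform = c("log", "identity")) {
  transform <- match.arg(transform)
  v <- as.numeric(values)
  if (transform == "log") {
    bad <- which(!is.na(v) & v <= 0)
    if (length(bad)) {
      stop("log transform requires strictly positive values; offending ",
           "sample index(es): ", paste(head(bad, 10), collapse = ", "),
           if (length(bad) > 10) ", ..." else "")
    }
    v <- log(v)
  }
  structure(v, transform = transform)
}

# assemble aligned, list-wise-deleted model data for one SNP.
# Alignment is by sample id, never by row order.
.model_data <- function(genotypes, phenotypes, snp, outcome, mediator,
                        covariates, use_mediator, log_outcome, log_mediator) {
  g <- .get_dosage(genotypes, snp)
  idx <- match(genotypes$sample_ids, phenotypes$sample_id)
  ph <- phenotypes[idx, , drop = FALSE]
  vars <- c(outcome, covariates, if (use_mediator) mediator)
  missing_cols <- setdiff(vars, names(ph))
  if (length(missing_cols)) {
    stop("phenotype table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df <- data.frame(g = as.numeric(g), ph[, vars, drop = FALSE])
  keep <- complete.cases(df)
  df <- df[keep, , drop = FALSE]
  y <- transform_phenotype(df[[outcome]],
                           if (log_outcome) "log" else "identity")
  X <- cbind(intercept = 1, dosage = df$g,
             as.matrix(df[, covariates, drop = FALSE]))
  if (use_mediator) {
    med <- transform_phenotype(df[[mediator]],
                               if (log_mediator) "log" else "identity")
    X <- cbind(X, mediator = as.numeric(med))
  }
  list(y = as.numeric(y), X = X, n = nrow(df), dosage = df$g)
}

#' Per-SNP association under one adjustment set
#'
#' Fits the additive model `transformed outcome ~ dosage + covariates`
#' (adjustment `"base"`) or additionally adjusted for the transformed mediator
#' (`"base+mediator"`). Samples are aligned by id and list-wise deleted over
#' all model variables. SNPs monomorphic after deletion are flagged
#' untestable rather than raising an error.
#'
#' @param genotypes a [genotype_matrix] (QC-passed).
#' @param phenotypes phenotype data.frame with `sample_id`.
#' @param snp SNP identifier.
#' @param adjustment `"base"` (age, sex, BMI, smoking) or `"base+mediator"`.
#' @param outcome,mediator phenotype column names (defaults `hdl_c`,
#'   `adiponectin`).
#' @param covariates covariate column names.
#' @param log_outcome,log_mediator log-transform before regression
#'   (default TRUE).
#' @return one-row data.frame (an association record): snp, chrom, pos,
#'   minor_allele, adjustment, beta, se, t, p, n, untestable.
#' @export
snp_association <- function(genotypes, phenotypes, snp,
                            adjustment = c("base", "base+mediator"),
                            outcome = "hdl_c", mediator = "adiponectin",
                            covariates = c("age", "sex", "bmi", "smoking"),
                            log_outcome = TRUE, log_mediator = TRUE) {
  adjustment <- match.arg(adjustment)
  use_med <- adjustment == "base+mediator"
  meta <- genotypes$snp_meta[genotypes$snp_meta$id == snp, , drop = FALSE]
  if (!nrow(meta)) stop("SNP not found in genotype matrix: ", snp)
  md <- .model_data(genotypes, phenotypes, snp, outcome, mediator,
                    covariates, use_med, log_outcome, log_mediator)
  rec <- data.frame(
    snp = snp, chrom = meta$chrom, pos = meta$pos,
    minor_allele = meta$minor, adjustment = adjustment,
    beta = NA_real_, se = NA_real_, t = NA_real_, p = NA_real_,
    n = md$n, untestable = FALSE, stringsAsFactors = FALSE
  )
  if (md$n <= ncol(md$X) || var(md$dosage) == 0) {
    rec$untestable <- TRUE
    return(rec)
  }
  fit <- ols_fit(md$y, md$X)
  cr <- .coef_row(fit, "dosage")
  rec$beta <- cr$estimate; rec$se <- cr$se; rec$t <- cr$t; rec$p <- cr$p
  rec
}

#' Genome-wide association scan
#'
#' Runs [snp_association()] for every SNP under each requested adjustment
#' set, sorts by p within set, flags genome-wide significance, and attaches a
#' `neglog10_p` column ready for Manhattan plotting.
#'
#' @inheritParams snp_association
#' @param adjustments character vector of adjustment-set labels.
#' @param threshold genome-wide significance threshold (default 5e-8).
#' @param ... further arguments passed to [snp_association()].
#' @return data.frame of association records with columns `significant` and
#'   `neglog10_p`, ordered by adjustment then ascending p (untestable SNPs
#'   last).
#' @export
genome_scan <- function(genotypes, phenotypes,
                        adjustments = c("base", "base+mediator"),
                        threshold = 5e-8, ...) {
  stopifnot(ncol(genotypes$dosages) >= 1)
  recs <- lapply(adjustments, function(adj) {
    out <- lapply(genotypes$snp_meta$id, function(s) {
      snp_association(genotypes, phenotypes, s, adjustment = adj, ...)
    })
    out <- do.call(rbind, out)
    out[order(out$p, na.last = TRUE), , drop = FALSE]
  })
  scan <- do.call(rbind, recs)
  scan$significant <- !is.na(scan$p) & scan$p < threshold
  scan$neglog10_p <- -log10(scan$p)
  attr(scan, "threshold") <- threshold
  rownames(scan) <- NULL
  scan
}

#' Manhattan plot of a genome scan
#'
#' @param scan data.frame from [genome_scan()].
#' @param adjustment which adjustment set to plot.
#' @param threshold significance line (defaults to the scan's threshold).
#' @param ... passed to [graphics::plot].
#' @return the plotted data, invisibly.
#' @export
manhattan_plot <- function(scan, adjustment = scan$adjustment[1],
                           threshold = attr(scan, "threshold"), ...) {
  d <- scan[scan$adjustment == adjustment & !is.na(scan$p), , drop = FALSE]
  ord <- order(suppressWarnings(as.numeric(d$chrom)), d$pos)
  d <- d[ord, , drop = FALSE]
  chrom_f <- factor(d$chrom, levels = unique(d$chrom))
  col <- c("grey30", "steelblue")[(as.integer(chrom_f) %% 2L) + 1L]
  graphics::plot(seq_len(nrow(d)), d$neglog10_p, col = col, pch = 20,
                 xlab = "SNP (ordered by chromosome, position)",
                 ylab = expression(-log[10](p)),
                 main = paste("Adjustment:", adjustment), ...)
  if (!is.null(threshold)) {
    graphics::abline(h = -log10(threshold), col = "red", lty = 2)
  }
  invisible(d)
}

#' Write an association scan table to TSV
#' @param scan data.frame from [genome_scan()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_association_tsv <- function(scan, path) {
  write.table(scan, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
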