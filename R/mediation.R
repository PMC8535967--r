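#' Sobel test for an indirect (mediation) effect
#'
#' Normal-approximation test of the product of two regression coefficients:
#' the exposure-to-mediator path `a` and the mediator-to-outcome path `b`.
#' The default first-order delta-method variance is
#' \deqn{Var(ab) = a^2 se_b^2 + b^2 se_a^2,}
#' the `"aroian"` variant adds the `se_a^2 se_b^2` cross term.
#'
#' @param a,se_a exposure-to-mediator coefficient and its standard error.
#' @param b,se_b mediator-to-outcome coefficient (exposure-adjusted) and its
#'   standard error.
#' @param variant `"first_order"` (default) or `"aroian"`.
#' @return list with `z` and two-sided `p`. When `a = b = 0` the statistic is
#'   defined as `z = 0`, `p = 1`.
#' @examples
#' sobel_test(-0.079, 0.006, 0.21, 0.01) # z approximately -11.16
#' @export
sobel_test <- function(a, se_a, b, se_b,
                       variant = c("first_order", "aroian")) {
  variant <- match.arg(variant)
  if (se_a <= 0 || se_b <= 0) stop("standard errors must be > 0")
  v <- a^2 * se_b^2 + b^2 * se_a^2
  if (variant == "aroian") v <- v + se_a^2 * se_b^2
  if (v == 0) return(list(z = 0, p = 1)) # a = b = 0 under first-order variance
  z <- a * b / sqrt(v)
  list(z = z, p = 2 * pnorm(-abs(z)))
}

#' Classify a mediation decomposition
#'
#' Applies the four-criterion scheme: with `criteria` the significance flags
#' of (1) exposure-to-mediator path, (2) mediator-to-outcome path, (3) total
#' effect, (4) Sobel test of the indirect effect,
#' * `suppression` iff criteria 1, 2, 4 hold, `|direct| > |total|`, and the
#'   indirect and direct effects have opposite signs;
#' * `full_mediation` iff criteria 1-4 hold and the direct effect is
#'   non-significant;
#' * `partial_mediation` iff criteria 1-4 hold, the direct effect is
#'   significant and same-signed as the indirect effect;
#' * otherwise `none`.
#'
#' @param criteria logical vector of length 4 (criteria 1-4).
#' @param direct direct-effect estimate (gamma prime).
#' @param direct_p its p-value.
#' @param indirect indirect-effect estimate (alpha * beta).
#' @param total total-effect estimate.
#' @param significance significance level for the direct-effect call.
#' @return one of `"suppression"`, `"full_mediation"`, `"partial_mediation"`,
#'   `"none"`.
#' @export
classify_effect <- function(criteria, direct, direct_p, indirect, total,
                            significance = 0.05) {
  stopifnot(length(criteria) == 4)
  direct_sig <- !is.na(direct_p) && direct_p < significance
  if (criteria[1] && criteria[2] && criteria[4] &&
      abs(direct) > abs(total) && sign(indirect) != sign(direct)) {
    return("suppression")
  }
  if (all(criteria)) {
    if (!direct_sig) return("full_mediation")
    if (sign(indirect) == sign(direct)) return("partial_mediation")
  }
  "none"
}

#' Four-criterion mediation analysis for one SNP
#'
#' Runs three regressions on the identical list-wise-deleted sample:
#' (i) `mediator ~ G + covariates` giving the path `alpha`;
#' (ii) `outcome ~ mediator + G + covariates` giving the mediator path `beta`
#' and the direct effect `gamma_prime`;
#' (iii) `outcome ~ G + covariates` giving the total effect.
#' The indirect effect is `alpha * beta`, tested with [sobel_test()]. The
#' four criteria are evaluated at `significance` and the effect classified
#' with [classify_effect()].
#'
#' @inheritParams snp_association
#' @param significance significance level for the criteria (default 0.05).
#' @param sobel_variant passed to [sobel_test()].
#' @return object of class `mediation_result`: `alpha`, `beta`, `gamma_prime`
#'   and `total` (each estimate/se/p), `indirect`, `total_sum`
#'   (= indirect + gamma_prime), `sobel_z`, `sobel_p`, `criteria_met`,
#'   `classification`, `n`, `untestable`.
#' @export
mediation_analyze <- function(genotypes, phenotypes, snp,
                              outcome = "hdl_c", mediator = "adiponectin",
                              covariates = c("age", "sex", "bmi", "smoking"),
                              significance = 0.05,
                              log_outcome = TRUE, log_mediator = TRUE,
                              sobel_variant = "first_order") {
  meta <- genotypes$snp_meta[genotypes$snp_meta$id == snp, , drop = FALSE]
  if (!nrow(meta)) stop("SNP not found in genotype matrix: ", snp)
  md <- .model_data(genotypes, phenotypes, snp, outcome, mediator,
                    covariates, use_mediator = TRUE,
                    log_outcome = log_outcome, log_mediator = log_mediator)
  blank <- list(estimate = NA_real_, se = NA_real_, p = NA_real_)
  res <- structure(list(
    snp = snp, alpha = blank, beta = blank, gamma_prime = blank,
    total = blank, indirect = NA_real_, total_sum = NA_real_,
    sobel_z = NA_real_, sobel_p = NA_real_,
    criteria_met = rep(NA, 4), classification = NA_character_,
    significance = significance, n = md$n, untestable = TRUE
  ), class = "mediation_result")
  if (md$n <= ncol(md$X) || var(md$dosage) == 0) return(res)

  mvec <- md$X[, "mediator"]
  X_base <- md$X[, setdiff(colnames(md$X), "mediator"), drop = FALSE]
  fit_i <- ols_fit(mvec, X_base)                   # mediator ~ G + covars
  fit_ii <- ols_fit(md$y, md$X)                    # outcome ~ M + G + covars
  fit_iii <- ols_fit(md$y, X_base)                 # outcome ~ G + covars

  pick <- function(fit, term) {
    r <- .coef_row(fit, term)
    list(estimate = r$estimate, se = r$se, p = r$p)
  }
  res$alpha <- pick(fit_i, "dosage")
  res$beta <- pick(fit_ii, "mediator")
  res$gamma_prime <- pick(fit_ii, "dosage")
  res$total <- pick(fit_iii, "dosage")
  res$indirect <- res$alpha$estimate * res$beta$estimate
  res$total_sum <- res$indirect + res$gamma_prime$estimate
  sob <- sobel_test(res$alpha$estimate, res$alpha$se,
                    res$beta$estimate, res$beta$se, variant = sobel_variant)
  res$sobel_z <- sob$z
  res$sobel_p <- sob$p
  res$criteria_met <- c(
    res$alpha$p < significance,
    res$beta$p < significance,
    res$total$p < significance,
    res$sobel_p < significance
  )
  res$classification <- classify_effect(
    res$criteria_met, res$gamma_prime$estimate, res$gamma_prime$p,
    res$indirect, res$total$estimate, significance)
  res$untestable <- FALSE
  res
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("mediation_result for %s (n = %d)\n", x$snp, x$n))
  if (x$untestable) {
    cat("  untestable (monomorphic or insufficient data)\n")
    return(invisible(x))
  }
  fmt <- function(nm, e) sprintf("  %-12s %9.4f (se %.4f, p %.3g)\n",
                                 nm, e$estimate, e$se, e$p)
  cat(fmt("alpha", x$alpha), fmt("beta", x$beta),
      fmt("gamma_prime", x$gamma_prime), fmt("total", x$total), sep = "")
  cat(sprintf("  indirect (alpha*beta) %.4f; indirect + gamma' %.4f\n",
              x$indirect, x$total_sum))
  cat(sprintf("  Sobel z = %.3f, p = %.3g\n", x$sobel_z, x$sobel_p))
  cat(sprintf("  criteria met: %s; classification: %s\n",
              paste(ifelse(x$criteria_met, "yes", "no"), collapse = "/"),
              x$classification))
  invisible(x)
}

# flatten a mediation_result into a one-row data.frame
.mediation_row <- function(r) {
  data.frame(
    snp = r$snp,
    alpha = r$alpha$estimate, alpha_se = r$alpha$se, alpha_p = r$alpha$p,
    beta = r$beta$estimate, beta_se = r$beta$se, beta_p = r$beta$p,
    gamma_prime = r$gamma_prime$estimate, gamma_prime_se = r$gamma_prime$se,
    gamma_prime_p = r$gamma_prime$p,
    total = r$total$estimate, total_se = r$total$se, total_p = r$total$p,
    indirect = r$indirect, total_sum = r$total_sum,
    sobel_z = r$sobel_z, sobel_p = r$sobel_p,
    criterion1 = r$criteria_met[1], criterion2 = r$criteria_met[2],
    criterion3 = r$criteria_met[3], criterion4 = r$criteria_met[4],
    classification = r$classification, n = r$n, untestable = r$untestable,
    stringsAsFactors = FALSE
  )
}

#' Mediation analysis over a candidate SNP list
#'
#' Applies [mediation_analyze()] to each candidate (e.g. the hits of a
#' mediator-adjusted scan) and returns one table sorted by decreasing
#' `|sobel_z|`.
#'
#' @inheritParams mediation_analyze
#' @param snps character vector of SNP ids; an empty vector yields an empty
#'   table.
#' @return data.frame with one row per SNP (all `mediation_result` fields
#'   flattened).
#' @export
mediation_scan <- function(genotypes, phenotypes, snps, ...) {
  if (!length(snps)) {
    blank <- list(estimate = NA_real_, se = NA_real_, p = NA_real_)
    proto <- list(snp = NA_character_, alpha = blank, beta = blank,
                  gamma_prime = blank, total = blank, indirect = NA_real_,
                  total_sum = NA_real_, sobel_z = NA_real_, sobel_p = NA_real_,
                  criteria_met = rep(NA, 4), classification = NA_character_,
                  n = NA_integer_, untestable = NA)
    return(.mediation_row(proto)[0, , drop = FALSE])
  }
  rows <- lapply(snps, function(s) {
    .mediation_row(mediation_analyze(genotypes, phenotypes, s, ...))
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(-abs(tab$sobel_z), na.last = TRUE), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Write a mediation table to TSV (with JSON detail)
#' @param table data.frame from [mediation_scan()].
#' @param path output TSV path; a `.json` twin is written alongside.
#' @return `path`, invisibly.
#' @export
write_mediation_tsv <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(table, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, dataframe = "rows")
  invisible(path)
}
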