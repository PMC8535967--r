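#' Pipeline run configuration
#'
#' Exactly one input source must be given: either a `simulation` config (the
#' cohort is generated) or real input paths (`vcf` or `dosage_tsv`, plus
#' `phenotypes_tsv`).
#'
#' @param simulation a [simulation_config()], or `NULL` when reading files.
#' @param vcf,dosage_tsv,phenotypes_tsv input paths for a real-data run.
#' @param thresholds a [qc_thresholds()].
#' @param adjustments adjustment-set labels for the scan.
#' @param outcome,mediator,covariates phenotype column names.
#' @param significance significance level for mediation criteria.
#' @param genome_threshold genome-wide significance threshold.
#' @param candidate_p mediation candidates are SNPs with mediator-adjusted
#'   scan p below this value (the focal pair is always included for
#'   simulated runs).
#' @param haplo_snps length-2 SNP ids for the haplotype stage; defaults to
#'   the simulated focal pair, else the two top mediator-adjusted hits.
#' @param log_outcome,log_mediator transform flags.
#' @param seed integer seed (overrides the simulation config's seed).
#' @param out_dir output directory.
#' @return object of class `run_config`.
#' @export
run_config <- function(simulation = NULL, vcf = NULL, dosage_tsv = NULL,
                       phenotypes_tsv = NULL,
                       thresholds = qc_thresholds(),
                       adjustments = c("base", "base+mediator"),
                       outcome = "hdl_c", mediator = "adiponectin",
                       covariates = c("age", "sex", "bmi", "smoking"),
                       significance = 0.05, genome_threshold = 5e-8,
                       candidate_p = 1e-4, haplo_snps = NULL,
                       log_outcome = TRUE, log_mediator = TRUE,
                       seed = NULL, out_dir = tempfile("suppscan_run_")) {
  simulated <- !is.null(simulation)
  real <- !is.null(vcf) || !is.null(dosage_tsv)
  if (simulated == real) {
    stop("exactly one of (simulation config, genotype input path) is required")
  }
  if (real && is.null(phenotypes_tsv)) {
    stop("real-data runs require phenotypes_tsv")
  }
  if (simulated && !is.null(seed)) {
    simulation <- do.call(simulation_config,
                          utils::modifyList(unclass(simulation),
                                            list(seed = as.integer(seed))))
  }
  structure(list(
    simulation = simulation, vcf = vcf, dosage_tsv = dosage_tsv,
    phenotypes_tsv = phenotypes_tsv, thresholds = thresholds,
    adjustments = adjustments, outcome = outcome, mediator = mediator,
    covariates = covariates, significance = significance,
    genome_threshold = genome_threshold, candidate_p = candidate_p,
    haplo_snps = haplo_snps, log_outcome = isTRUE(log_outcome),
    log_mediator = isTRUE(log_mediator), out_dir = out_dir
  ), class = "run_config")
}

#' Load a run configuration from a YAML/JSON document
#'
#' Top-level keys mirror the arguments of [run_config()]; `simulation` may be
#' a nested mapping of [simulation_config()] arguments, and `thresholds` of
#' [qc_thresholds()] arguments.
#'
#' @param path YAML (or JSON) file.
#' @param ... overrides applied after reading (CLI flags beat config fields).
#' @return a `run_config`.
#' @export
read_run_config <- function(path, ...) {
  doc <- yaml::read_yaml(path)
  if (!is.null(doc$simulation)) {
    doc$simulation <- do.call(simulation_config, doc$simulation)
  }
  if (!is.null(doc$thresholds)) {
    doc$thresholds <- do.call(qc_thresholds, doc$thresholds)
  }
  overrides <- list(...)
  doc[names(overrides)] <- overrides
  do.call(run_config, doc)
}

.stage_log <- function(con, stage, msg, t0) {
  line <- sprintf("[%s] %s (%.2fs)", stage, msg,
                  as.numeric(proc.time()[3] - t0))
  message(line)
  if (!is.null(con)) writeLines(line, con)
  invisible(NULL)
}

#' Run the full suppression-scan pipeline
#'
#' Executes simulate (or load) -> QC -> genome scan -> mediation ->
#' haplotype/LD, writing every stage output under `config$out_dir` and a
#' `manifest.json` recording each file with its md5 hash. A rerun with the
#' same config and seed reproduces an identical manifest. Structured progress
#' goes to stderr and `run.log` (excluded from the manifest).
#'
#' @param config a [run_config()].
#' @return the manifest (named list), invisibly; element `files` maps
#'   relative paths to md5 hashes, `paths` gives absolute locations.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  logf <- file(file.path(out, "run.log"), open = "wt")
  on.exit(close(logf), add = TRUE)
  t0 <- proc.time()[3]
  files <- character(0)
  stage <- "init"
  result <- tryCatch({
    if (!is.null(config$simulation)) {
      stage <- "simulate"
      cohort <- simulate_cohort(config$simulation)
      written <- write_cohort(cohort, out)
      files <- c(files, unname(written))
      genotypes <- cohort$genotypes
      phenotypes <- cohort$phenotypes
      .stage_log(logf, stage, sprintf("simulated %d samples x %d SNPs",
                                      nrow(genotypes$dosages),
                                      ncol(genotypes$dosages)), t0)
    } else {
      stage <- "load"
      genotypes <- if (!is.null(config$vcf)) {
        read_vcf_genotypes(config$vcf)
      } else read_dosage_tsv(config$dosage_tsv)
      phenotypes <- read_phenotypes_tsv(config$phenotypes_tsv)
      .stage_log(logf, stage, sprintf("loaded %d samples x %d SNPs",
                                      nrow(genotypes$dosages),
                                      ncol(genotypes$dosages)), t0)
    }

    stage <- "qc"
    qc <- apply_qc(genotypes, config$thresholds)
    files <- c(files, unname(write_qc_report(qc$report, out)))
    genotypes <- qc$genotypes
    .stage_log(logf, stage, sprintf("%d samples, %d SNPs retained",
                                    qc$report$n_samples_retained,
                                    qc$report$n_snps_retained), t0)

    stage <- "scan"
    scan <- genome_scan(genotypes, phenotypes,
                        adjustments = config$adjustments,
                        threshold = config$genome_threshold,
                        outcome = config$outcome, mediator = config$mediator,
                        covariates = config$covariates,
                        log_outcome = config$log_outcome,
                        log_mediator = config$log_mediator)
    assoc_path <- file.path(out, "association.tsv")
    write_association_tsv(scan, assoc_path)
    files <- c(files, assoc_path)
    .stage_log(logf, stage, sprintf("%d records, %d genome-wide significant",
                                    nrow(scan), sum(scan$significant)), t0)

    stage <- "mediate"
    adj_label <- if ("base+mediator" %in% scan$adjustment) {
      "base+mediator"
    } else config$adjustments[1]
    adj <- scan[scan$adjustment == adj_label & !is.na(scan$p), , drop = FALSE]
    candidates <- adj$snp[adj$p < config$candidate_p]
    if (!is.null(config$simulation)) {
      candidates <- union(candidates,
                          intersect(config$simulation$focal_ids,
                                    genotypes$snp_meta$id))
    }
    med <- mediation_scan(genotypes, phenotypes, candidates,
                          outcome = config$outcome,
                          mediator = config$mediator,
                          covariates = config$covariates,
                          significance = config$significance,
                          log_outcome = config$log_outcome,
                          log_mediator = config$log_mediator)
    med_path <- file.path(out, "mediation.tsv")
    write_mediation_tsv(med, med_path)
    files <- c(files, med_path, paste0(med_path, ".json"))
    .stage_log(logf, stage, sprintf("%d candidate SNP(s) analysed",
                                    nrow(med)), t0)

    stage <- "haplo"
    haplo_snps <- config$haplo_snps
    if (is.null(haplo_snps) && !is.null(config$simulation)) {
      haplo_snps <- config$simulation$focal_ids
    }
    if (is.null(haplo_snps)) haplo_snps <- head(adj$snp, 2)
    haplo_snps <- intersect(haplo_snps, genotypes$snp_meta$id)
    hap <- NULL
    if (length(haplo_snps) == 2) {
      hap <- haplotype_association(genotypes, haplo_snps, phenotypes,
                                   outcome = config$outcome,
                                   covariates = config$covariates,
                                   log_outcome = config$log_outcome)
      hap_path <- file.path(out, "haplotype_ld.tsv")
      write_haplotype_tsv(hap, hap_path)
      files <- c(files, hap_path, paste0(hap_path, ".assoc.tsv"))
      .stage_log(logf, stage,
                 sprintf("pair %s: D' = %.3f, r2 = %.3f",
                         paste(haplo_snps, collapse = "/"),
                         hap$estimate$dprime, hap$estimate$r2), t0)
    } else {
      .stage_log(logf, stage, "skipped (no SNP pair available)", t0)
    }

    stage <- "manifest"
    rel <- sub(paste0("^", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", out), "/?"),
               "", files)
    hashes <- unname(tools::md5sum(files))
    manifest <- list(
      stages = c("simulate/load", "qc", "scan", "mediate", "haplo"),
      files = as.list(setNames(hashes, rel)),
      n_files = length(files)
    )
    manifest_path <- file.path(out, "manifest.json")
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    cat(manifest_path, "\n")
    invisible(c(manifest,
                list(paths = files, manifest_path = manifest_path,
                     scan = scan, mediation = med, haplotype = hap)))
  }, error = function(e) {
    if (inherits(e, "qc_empty_error")) {
      stop(sprintf("pipeline failed at stage '%s': %s", stage,
                   conditionMessage(e)), call. = FALSE)
    }
    stop(sprintf("pipeline failed at stage '%s': %s (partial outputs: %s)",
                 stage, conditionMessage(e),
                 paste(basename(files), collapse = ", ")), call. = FALSE)
  })
  invisible(result)
}
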