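#' Default per-sex phenotype location/scale table
#'
#' Means/SDs of age and BMI, smoking prevalence, and raw-scale target means
#' for adiponectin (mg/L) and HDL-C (mg/dL), by sex, emulating a Taiwanese
#' biobank cohort (986 men, 1213 women).
#' @keywords internal
.default_location_scale <- function() {
  list(
    male = list(age = c(mean = 48.6, sd = 11.1),
                bmi = c(mean = 25.1, sd = 3.4),
                smoking = 0.334,
                adiponectin = c(mean = 2.88, sd = 1.45),
                hdl_c = c(mean = 49.7, sd = 11.4)),
    female = list(age = c(mean = 48.2, sd = 10.7),
                  bmi = c(mean = 23.4, sd = 3.5),
                  smoking = 0.055,
                  adiponectin = c(mean = 4.01, sd = 1.97),
                  hdl_c = c(mean = 59.4, sd = 13.3))
  )
}

#' Simulation configuration for a synthetic suppression-scan cohort
#'
#' Bundles every generative parameter of the synthetic cohort: a focal SNP
#' pair in LD carrying the mediation structure (genotype -> mediator -> outcome
#' plus a direct path), a panel of null SNPs, per-sex covariate distributions,
#' and noise levels.
#'
#' The path-coefficient defaults (`alpha` = -0.079, `beta` = 0.21,
#' `gamma_prime` = 0.015) encode a suppression structure: the indirect effect
#' `alpha * beta` = -0.0166 opposes the direct effect 0.015, so the marginal
#' genotype-outcome association is near zero while the mediator-adjusted one
#' is strong. Residual SDs (`sigma_mediator` = 0.186, `sigma_outcome` = 0.087,
#' both on the log scale) are chosen so that at `n_samples` = 2199 the three
#' path-coefficient standard errors are approximately 0.006, 0.01 and 0.003.
#'
#' @param n_samples number of individuals.
#' @param maf_focal length-2 minor allele frequencies of the focal SNP pair.
#' @param ld_dprime normalized LD (D') in `[0, 1]` between the focal SNPs,
#'   with minor alleles on the same haplotype (positive coupling).
#' @param n_null_snps number of phenotype-independent SNPs.
#' @param maf_range_null MAF interval for null SNPs.
#' @param alpha genotype -> mediator coefficient per minor-allele copy, on the
#'   (log) mediator scale.
#' @param beta mediator -> outcome coefficient (transformed scales).
#' @param gamma_prime direct genotype -> outcome coefficient.
#' @param covariate_effects list with elements `mediator` and `outcome`, each
#'   a named vector of coefficients for `age` (per year), `bmi` (per kg/m2)
#'   and `smoking` (0/1), applied on the transformed phenotype scales.
#' @param sex_fraction fraction of females (sex coded 0 = male, 1 = female).
#' @param phenotype_location_scale per-sex list of covariate and phenotype
#'   distributions; see `suppscan:::.default_location_scale()` for the shape.
#' @param sigma_mediator residual SD of the (log) mediator.
#' @param sigma_outcome residual SD of the (log) outcome.
#' @param log_mediator,log_outcome simulate the phenotype on the log scale and
#'   exponentiate to the raw scale for output (default) or act additively on
#'   the raw scale.
#' @param missing_rate_genotype per-entry probability of a missing call.
#' @param focal_ids,focal_chrom,focal_pos identifiers for the focal pair.
#' @param seed integer seed governing all randomness.
#' @return An object of class `simulation_config` (a validated list).
#' @export
simulation_config <- function(n_samples = 2199,
                              maf_focal = c(0.32, 0.22),
                              ld_dprime = 0.9,
                              n_null_snps = 50,
                              maf_range_null = c(0.05, 0.5),
                              alpha = -0.079,
                              beta = 0.21,
                              gamma_prime = 0.015,
                              covariate_effects = list(
                                mediator = c(age = 0.004, bmi = -0.02,
                                             smoking = -0.05),
                                outcome = c(age = 0.001, bmi = -0.015,
                                            smoking = -0.05)),
                              sex_fraction = 1213 / 2199,
                              phenotype_location_scale =
                                .default_location_scale(),
                              sigma_mediator = 0.186,
                              sigma_outcome = 0.087,
                              log_mediator = TRUE,
                              log_outcome = TRUE,
                              missing_rate_genotype = 0.005,
                              focal_ids = c("rs4783244", "rs12051272"),
                              focal_chrom = "16",
                              focal_pos = c(82662268L, 82660399L),
                              seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples), maf_focal = maf_focal,
              ld_dprime = ld_dprime, n_null_snps = as.integer(n_null_snps),
              maf_range_null = maf_range_null, alpha = alpha, beta = beta,
              gamma_prime = gamma_prime, covariate_effects = covariate_effects,
              sex_fraction = sex_fraction,
              phenotype_location_scale = phenotype_location_scale,
              sigma_mediator = sigma_mediator, sigma_outcome = sigma_outcome,
              log_mediator = isTRUE(log_mediator),
              log_outcome = isTRUE(log_outcome),
              missing_rate_genotype = missing_rate_genotype,
              focal_ids = focal_ids, focal_chrom = focal_chrom,
              focal_pos = focal_pos, seed = as.integer(seed))
  .validate_sim_config(cfg)
  structure(cfg, class = "simulation_config")
}

.validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_samples >= 1L, cfg$n_null_snps >= 0L)
  if (any(cfg$maf_focal <= 0) || any(cfg$maf_focal >= 1)) {
    stop("focal MAFs must lie strictly in (0, 1)")
  }
  if (any(cfg$maf_focal > 0.5)) {
    stop("focal MAFs are minor-allele frequencies and must be <= 0.5")
  }
  if (cfg$ld_dprime < 0 || cfg$ld_dprime > 1) stop("ld_dprime must be in [0, 1]")
  if (any(cfg$maf_range_null <= 0) || any(cfg$maf_range_null >= 1) ||
      diff(cfg$maf_range_null) < 0) {
    stop("maf_range_null must be an interval within (0, 1)")
  }
  if (cfg$sex_fraction < 0 || cfg$sex_fraction > 1) {
    stop("sex_fraction must be in [0, 1]")
  }
  if (cfg$sigma_mediator <= 0 || cfg$sigma_outcome <= 0) {
    stop("noise SDs must be > 0")
  }
  for (s in c("male", "female")) {
    ls <- cfg$phenotype_location_scale[[s]]
    if (ls$age["sd"] <= 0 || ls$bmi["sd"] <= 0) stop("covariate SDs must be > 0")
    if (ls$smoking < 0 || ls$smoking > 1) stop("smoking rate must be in [0, 1]")
  }
  if (cfg$missing_rate_genotype < 0 || cfg$missing_rate_genotype >= 1) {
    stop("missing_rate_genotype must be in [0, 1)")
  }
  if (length(cfg$focal_ids) != 2L || length(cfg$maf_focal) != 2L) {
    stop("exactly two focal SNPs are required")
  }
  invisible(cfg)
}

#' Two-locus haplotype frequencies implied by MAFs and D'
#'
#' Under the positive-coupling convention (minor alleles T/T on the same
#' haplotype), D = D' * Dmax with Dmax = min(p1 (1 - p2), (1 - p1) p2).
#' Haplotypes are labelled by the allele at each site, major = G, minor = T.
#'
#' @param maf length-2 minor allele frequencies.
#' @param ld_dprime D' in `[0, 1]`.
#' @return named numeric vector of frequencies `c(GG, GT, TG, TT)` summing
#'   to 1.
#' @examples
#' haplotype_frequencies(c(0.32, 0.22), 0) # products of allele frequencies
#' haplotype_frequencies(c(0.3, 0.3), 1)   # only GG and TT segregate
#' @export
haplotype_frequencies <- function(maf, ld_dprime) {
  p1 <- maf[1]; p2 <- maf[2]
  dmax <- min(p1 * (1 - p2), (1 - p1) * p2)
  D <- ld_dprime * dmax
  f <- c(GG = (1 - p1) * (1 - p2) + D,
         GT = (1 - p1) * p2 - D,
         TG = p1 * (1 - p2) - D,
         TT = p1 * p2 + D)
  if (any(f < -1e-12)) {
    stop(sprintf(
      "infeasible (MAF, D') combination: haplotype frequency would be negative (%s)",
      paste(sprintf("%s=%.4g", names(f), f), collapse = ", ")))
  }
  f <- pmax(f, 0)
  f / sum(f)
}

# draw haplotype pairs without touching the seed (internal)
.draw_focal_pair <- function(n, maf, ld_dprime) {
  f <- haplotype_frequencies(maf, ld_dprime)
  h1 <- sample.int(4L, n, replace = TRUE, prob = f)
  h2 <- sample.int(4L, n, replace = TRUE, prob = f)
  # minor-allele (T) indicator per site for haplotypes GG, GT, TG, TT
  t1 <- c(0L, 0L, 1L, 1L)
  t2 <- c(0L, 1L, 0L, 1L)
  dosages <- cbind(t1[h1] + t1[h2], t2[h1] + t2[h2])
  list(haplotypes = cbind(h1 = h1, h2 = h2), dosages = dosages,
       freqs = f, labels = names(f))
}

#' Simulate the focal SNP pair
#'
#' Draws, for each sample, two haplotypes from the four-haplotype distribution
#' implied by (`maf_focal`, `ld_dprime`) under random mating, and derives
#' genotype dosages by counting minor alleles per site.
#'
#' @param config a [simulation_config()].
#' @return list with `haplotypes` (n x 2 matrix of haplotype codes 1..4 over
#'   `labels` GG/GT/TG/TT), `dosages` (n x 2 minor-allele counts), `freqs`
#'   (the generating haplotype frequencies) and `labels`.
#' @export
simulate_focal_pair <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  .draw_focal_pair(config$n_samples, config$maf_focal, config$ld_dprime)
}

# analytic variance of the transformed-mediator linear predictor, by sex
.sim_variances <- function(cfg) {
  vG <- 2 * cfg$maf_focal[1] * (1 - cfg$maf_focal[1])
  cem <- cfg$covariate_effects$mediator
  cey <- cfg$covariate_effects$outcome
  out <- list(vG = vG)
  for (s in c("male", "female")) {
    ls <- cfg$phenotype_location_scale[[s]]
    r <- ls$smoking
    vM <- cfg$alpha^2 * vG +
      cem[["age"]]^2 * ls$age[["sd"]]^2 +
      cem[["bmi"]]^2 * ls$bmi[["sd"]]^2 +
      cem[["smoking"]]^2 * r * (1 - r) +
      cfg$sigma_mediator^2
    vY <- cfg$beta^2 * vM + cfg$gamma_prime^2 * vG +
      2 * cfg$beta * cfg$gamma_prime * cfg$alpha * vG +
      cey[["age"]]^2 * ls$age[["sd"]]^2 +
      cey[["bmi"]]^2 * ls$bmi[["sd"]]^2 +
      cey[["smoking"]]^2 * r * (1 - r) +
      cfg$sigma_outcome^2
    out[[s]] <- c(vM = vM, vY = vY)
  }
  out
}

#' Simulate a full synthetic cohort
#'
#' Generates sex, age, BMI and smoking from per-sex distributions, the focal
#' SNP pair from its haplotype distribution, a panel of null SNPs under
#' Hardy-Weinberg equilibrium independent of all phenotypes, and then the
#' mediator and outcome from the linear structural model
#' \deqn{\log M = \mu_{sex} + \alpha G + c_M' X + \epsilon_M}
#' \deqn{\log Y = \nu_{sex} + \beta \log M + \gamma' G + c_Y' X + \epsilon_Y}
#' where G is the dosage of the first focal SNP and X the centered covariates.
#' Per-sex intercepts are calibrated analytically so the raw-scale means of
#' the mediator and outcome hit their configured targets. Genotype missingness
#' is applied completely at random. The run is fully reproducible from
#' `config$seed`.
#'
#' @param config a [simulation_config()].
#' @return An object of class `synthetic_cohort`: list with `genotypes`
#'   (a [genotype_matrix]; focal pair first, then null SNPs), `phenotypes`
#'   (data.frame: sample_id, sex, age, bmi, smoking, adiponectin, hdl_c) and
#'   `truth` (the generative parameters actually used, including per-SNP true
#'   effects, intercepts and haplotype frequencies).
#' @examples
#' cohort <- simulate_cohort(simulation_config(n_samples = 200,
#'                                             n_null_snps = 5, seed = 7))
#' cohort$genotypes
#' head(cohort$phenotypes)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  set.seed(cfg$seed)
  n <- cfg$n_samples
  pls <- cfg$phenotype_location_scale

  sex <- rbinom(n, 1L, cfg$sex_fraction) # 1 = female
  sx <- ifelse(sex == 1L, "female", "male")
  age <- rnorm(n,
               mean = ifelse(sex == 1L, pls$female$age[["mean"]], pls$male$age[["mean"]]),
               sd = ifelse(sex == 1L, pls$female$age[["sd"]], pls$male$age[["sd"]]))
  bmi <- rnorm(n,
               mean = ifelse(sex == 1L, pls$female$bmi[["mean"]], pls$male$bmi[["mean"]]),
               sd = ifelse(sex == 1L, pls$female$bmi[["sd"]], pls$male$bmi[["sd"]]))
  smoke_rate <- ifelse(sex == 1L, pls$female$smoking, pls$male$smoking)
  smoking <- rbinom(n, 1L, smoke_rate)

  fp <- .draw_focal_pair(n, cfg$maf_focal, cfg$ld_dprime)
  G1 <- fp$dosages[, 1]; G2 <- fp$dosages[, 2]

  p_null <- if (cfg$n_null_snps > 0) {
    runif(cfg$n_null_snps, cfg$maf_range_null[1], cfg$maf_range_null[2])
  } else numeric(0)
  Gnull <- if (cfg$n_null_snps > 0) {
    matrix(rbinom(n * cfg$n_null_snps, 2L, rep(p_null, each = n)),
           nrow = n)
  } else matrix(integer(0), nrow = n)

  # centered predictors: intercepts then control per-sex means exactly
  vv <- .sim_variances(cfg)
  Gc <- G1 - 2 * cfg$maf_focal[1]
  age_c <- age - ifelse(sex == 1L, pls$female$age[["mean"]], pls$male$age[["mean"]])
  bmi_c <- bmi - ifelse(sex == 1L, pls$female$bmi[["mean"]], pls$male$bmi[["mean"]])
  smk_c <- smoking - smoke_rate
  cem <- cfg$covariate_effects$mediator
  cey <- cfg$covariate_effects$outcome

  target_adipo <- c(male = pls$male$adiponectin[["mean"]],
                    female = pls$female$adiponectin[["mean"]])
  target_hdl <- c(male = pls$male$hdl_c[["mean"]],
                  female = pls$female$hdl_c[["mean"]])
  mu <- nu <- c(male = NA_real_, female = NA_real_)
  for (s in c("male", "female")) {
    if (cfg$log_mediator) {
      mu[s] <- log(target_adipo[s]) - vv[[s]][["vM"]] / 2
    } else mu[s] <- target_adipo[s]
    if (cfg$log_outcome) {
      nu[s] <- log(target_hdl[s]) - vv[[s]][["vY"]] / 2
    } else nu[s] <- target_hdl[s]
  }

  eta_M <- mu[sx] + cfg$alpha * Gc +
    cem[["age"]] * age_c + cem[["bmi"]] * bmi_c + cem[["smoking"]] * smk_c +
    rnorm(n, 0, cfg$sigma_mediator)
  mediator <- if (cfg$log_mediator) exp(eta_M) else eta_M

  med_centered <- eta_M - mu[sx]
  eta_Y <- nu[sx] + cfg$beta * med_centered + cfg$gamma_prime * Gc +
    cey[["age"]] * age_c + cey[["bmi"]] * bmi_c + cey[["smoking"]] * smk_c +
    rnorm(n, 0, cfg$sigma_outcome)
  outcome <- if (cfg$log_outcome) exp(eta_Y) else eta_Y

  dos <- cbind(fp$dosages, Gnull)
  if (cfg$missing_rate_genotype > 0) {
    miss <- matrix(runif(length(dos)) < cfg$missing_rate_genotype,
                   nrow = n)
    dos[miss] <- NA_integer_
  }

  null_ids <- if (cfg$n_null_snps > 0) {
    sprintf("null_%04d", seq_len(cfg$n_null_snps))
  } else character(0)
  null_chrom <- if (cfg$n_null_snps > 0) {
    as.character(rep_len(1:22, cfg$n_null_snps))
  } else character(0)
  meta <- data.frame(
    id = c(cfg$focal_ids, null_ids),
    chrom = c(rep(cfg$focal_chrom, 2), null_chrom),
    pos = c(cfg$focal_pos,
            if (cfg$n_null_snps > 0) 1000000L + 10000L * seq_len(cfg$n_null_snps) else integer(0)),
    minor = "T", major = "G", stringsAsFactors = FALSE
  )
  sample_ids <- sprintf("S%04d", seq_len(n))
  genotypes <- genotype_matrix(dos, sample_ids = sample_ids, snp_meta = meta)

  phenotypes <- data.frame(
    sample_id = sample_ids, sex = sex, age = age, bmi = bmi,
    smoking = smoking, adiponectin = mediator, hdl_c = outcome,
    stringsAsFactors = FALSE
  )

  truth <- list(
    config = unclass(cfg),
    haplotype_freqs = fp$freqs,
    intercepts = list(mediator = mu, outcome = nu),
    sigma_mediator = cfg$sigma_mediator,
    sigma_outcome = cfg$sigma_outcome,
    null_mafs = p_null,
    snp_effects = data.frame(
      id = meta$id,
      alpha = c(cfg$alpha, rep(0, 1 + cfg$n_null_snps)),
      gamma_prime = c(cfg$gamma_prime, rep(0, 1 + cfg$n_null_snps)),
      stringsAsFactors = FALSE
    )
  )
  structure(list(genotypes = genotypes, phenotypes = phenotypes,
                 truth = truth),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "synthetic_cohort: %d samples, %d SNPs (focal pair: %s), seed %d\n",
    nrow(x$genotypes$dosages), ncol(x$genotypes$dosages),
    paste(x$truth$config$focal_ids, collapse = ", "),
    x$truth$config$seed))
  invisible(x)
}

#' Write all cohort artifacts to a directory
#'
#' Emits `genotypes.vcf`, `genotypes.dosage.tsv` (+ metadata sidecar),
#' `phenotypes.tsv` and a `truth.json` sidecar recording the generative
#' parameters.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return character vector of the written file paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    vcf = file.path(dir, "genotypes.vcf"),
    dosage = file.path(dir, "genotypes.dosage.tsv"),
    pheno = file.path(dir, "phenotypes.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write_vcf_genotypes(cohort$genotypes, paths[["vcf"]])
  write_dosage_tsv(cohort$genotypes, paths[["dosage"]])
  write_phenotypes_tsv(cohort$phenotypes, paths[["pheno"]])
  jsonlite::write_json(cohort$truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(paths, meta = paste0(paths[["dosage"]], ".meta.tsv")))
}
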