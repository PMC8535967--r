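#' Construct a genotype matrix
#'
#' The central genotype container: a samples-by-SNPs dosage matrix (counts of
#' the minor allele, 0/1/2, `NA` = missing call) plus per-SNP metadata.
#' Only autosomal biallelic SNPs are accepted.
#'
#' @param dosages numeric/integer matrix, samples in rows, SNPs in columns;
#'   values must be 0, 1, 2 or `NA`.
#' @param sample_ids character vector of unique sample identifiers; defaults
#'   to `rownames(dosages)`.
#' @param snp_meta data.frame with one row per SNP and columns `id`, `chrom`,
#'   `pos` (1-based), `minor`, `major`. If `NULL`, placeholder metadata is
#'   generated from the column names.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosages`, `sample_ids`, `snp_meta`.
#' @examples
#' gm <- genotype_matrix(matrix(c(0, 1, 2, 0), 2, 2,
#'   dimnames = list(c("s1", "s2"), c("snpA", "snpB"))))
#' gm
#' @export
genotype_matrix <- function(dosages, sample_ids = rownames(dosages),
                            snp_meta = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  ok <- dosages %in% c(0L, 1L, 2L) | is.na(dosages)
  if (!all(ok)) {
    stop("dosages must be 0, 1, 2 or NA; found other values")
  }
  if (is.null(sample_ids)) sample_ids <- sprintf("S%04d", seq_len(nrow(dosages)))
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != nrow(dosages)) {
    stop("length(sample_ids) must equal nrow(dosages)")
  }
  if (anyDuplicated(sample_ids)) stop("sample ids must be unique")
  if (is.null(snp_meta)) {
    ids <- colnames(dosages)
    if (is.null(ids)) ids <- sprintf("snp%04d", seq_len(ncol(dosages)))
    snp_meta <- data.frame(
      id = ids, chrom = "1", pos = seq_len(ncol(dosages)),
      minor = "A", major = "C", stringsAsFactors = FALSE
    )
  }
  need <- c("id", "chrom", "pos", "minor", "major")
  if (!all(need %in% names(snp_meta))) {
    stop("snp_meta must have columns: ", paste(need, collapse = ", "))
  }
  snp_meta <- as.data.frame(snp_meta, stringsAsFactors = FALSE)
  snp_meta$id <- as.character(snp_meta$id)
  snp_meta$chrom <- as.character(snp_meta$chrom)
  if (nrow(snp_meta) != ncol(dosages)) {
    stop("nrow(snp_meta) must equal ncol(dosages)")
  }
  if (anyDuplicated(snp_meta$id)) stop("SNP ids must be unique")
  if (any(snp_meta$chrom %in% c("X", "Y", "MT", "chrX", "chrY", "chrM"))) {
    stop("only autosomal SNPs are supported; remove sex/mitochondrial markers")
  }
  rownames(dosages) <- sample_ids
  colnames(dosages) <- snp_meta$id
  rownames(snp_meta) <- NULL
  structure(list(dosages = dosages, sample_ids = sample_ids,
                 snp_meta = snp_meta),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d SNPs (%.2f%% missing)\n",
              nrow(x$dosages), ncol(x$dosages),
              100 * mean(is.na(x$dosages))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

.get_dosage <- function(genotypes, snp) {
  j <- match(snp, genotypes$snp_meta$id)
  if (is.na(j)) stop("SNP not found in genotype matrix: ", snp)
  genotypes$dosages[, j]
}

#' Read genotypes from a VCF file
#'
#' Parses a (possibly bgzipped) VCF with `vcfR` and converts GT calls to
#' minor-allele dosages. Non-biallelic and non-autosomal records are rejected
#' at load time (dropped with a warning). The ALT allele is taken as the
#' "minor" label in the metadata; actual frequencies are re-estimated by QC.
#'
#' @param path path to a VCF file.
#' @return A [genotype_matrix].
#' @export
read_vcf_genotypes <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  bi <- vcfR::is.biallelic(v)
  chrom <- vcfR::getCHROM(v)
  auto <- !(chrom %in% c("X", "Y", "MT", "chrX", "chrY", "chrM"))
  keep <- bi & auto
  if (!all(keep)) {
    warning(sum(!keep), " non-biallelic or non-autosomal record(s) dropped")
    v <- v[keep, ]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  gt[] <- gsub("|", "/", gt, fixed = TRUE)
  map <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)
  dos <- matrix(map[gt], nrow = nrow(gt), dimnames = dimnames(gt))
  dos <- t(dos) # samples x SNPs
  fix <- vcfR::getFIX(v)
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- sprintf(
    "%s_%s", fix[is.na(ids) | ids == ".", "CHROM"],
    fix[is.na(ids) | ids == ".", "POS"])
  meta <- data.frame(
    id = ids, chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
    minor = fix[, "ALT"], major = fix[, "REF"], stringsAsFactors = FALSE
  )
  genotype_matrix(dos, sample_ids = rownames(dos), snp_meta = meta)
}

#' Write genotypes to a VCF file
#'
#' Emits a minimal VCF v4.2 with GT-only FORMAT; the minor allele is written
#' as ALT and dosage d becomes 0/0, 0/1, 1/1 (`NA` as ./.). The output
#' round-trips through [read_vcf_genotypes()].
#'
#' @param genotypes a [genotype_matrix].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf_genotypes <- function(genotypes, path) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  m <- genotypes$snp_meta
  gt_code <- c("0/0", "0/1", "1/1")
  dos <- genotypes$dosages
  body <- vapply(seq_len(ncol(dos)), function(j) {
    g <- dos[, j]
    calls <- ifelse(is.na(g), "./.", gt_code[g + 1L])
    paste(c(m$chrom[j], m$pos[j], m$id[j], m$major[j], m$minor[j],
            ".", "PASS", ".", "GT", calls), collapse = "\t")
  }, character(1))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=suppscan",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", genotypes$sample_ids), collapse = "\t")
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write genotypes as a dosage TSV
#'
#' Plain table with samples in rows: first column `sample_id`, one column per
#' SNP holding 0/1/2/NA. A `<path>.meta.tsv` sidecar stores the SNP metadata.
#'
#' @param genotypes a [genotype_matrix].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_dosage_tsv <- function(genotypes, path) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  df <- data.frame(sample_id = genotypes$sample_ids,
                   genotypes$dosages, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(genotypes$snp_meta, paste0(path, ".meta.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a dosage TSV written by [write_dosage_tsv()]
#'
#' @param path TSV path; if a `<path>.meta.tsv` sidecar exists it supplies the
#'   SNP metadata, otherwise placeholders are used.
#' @return A [genotype_matrix].
#' @export
read_dosage_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  dos <- as.matrix(df[, -1, drop = FALSE])
  meta_path <- paste0(path, ".meta.tsv")
  meta <- if (file.exists(meta_path)) {
    read.delim(meta_path, stringsAsFactors = FALSE)
  } else NULL
  genotype_matrix(dos, sample_ids = df$sample_id, snp_meta = meta)
}

#' Write a phenotype table to TSV
#' @param phenotypes data.frame with a `sample_id` column.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_phenotypes_tsv <- function(phenotypes, path) {
  stopifnot(is.data.frame(phenotypes), "sample_id" %in% names(phenotypes))
  write.table(phenotypes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phenotype table from TSV
#' @param path TSV path with a header including `sample_id`.
#' @return data.frame.
#' @export
read_phenotypes_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df)) stop("phenotype TSV lacks sample_id column")
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids in phenotype TSV")
  df
}
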