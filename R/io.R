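#' Read genotypes from VCF or a dosage table
#'
#' VCF input accepts biallelic SNVs with `GT` or `DS` FORMAT fields; the
#' counted (effect) allele is ALT. Phasing separators are ignored for
#' dosage purposes. TSV input is a plain dosage table: a header row of
#' variant ids, first column `subject_id`, remaining cells additive
#' dosages in `[0, 2]`. Missing genotypes are mean-imputed per variant
#' (that is, to twice the effect-allele frequency) and the imputed count
#' is reported via a message, so sample size stays constant across
#' downstream score definitions.
#'
#' @param path Path to a `.vcf` or dosage `.tsv` file.
#' @param format `"vcf"` or `"tsv"`; `"auto"` guesses from the extension.
#' @param snp_meta Optional data frame of variant metadata for TSV input
#'   (columns as in [geno_matrix()]); when absent, placeholder alleles
#'   `A`/`B` are assigned and MAF is computed from the dosages.
#' @return A [geno_matrix()].
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "tsv"),
                           snp_meta = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "grsmr_io_error")
  }
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  }
  switch(format,
         vcf = read_genotypes_vcf(path),
         tsv = read_genotypes_tsv(path, snp_meta))
}

read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix_mat <- v@fix   # always a matrix, even for a single record
  fix <- as.data.frame(fix_mat[, 1:7, drop = FALSE],
                       stringsAsFactors = FALSE)
  if (nrow(fix) == 0) abort("VCF contains no records.", class = "grsmr_io_error")
  multi <- grepl(",", fix$ALT)
  if (any(multi)) {
    abort(paste0("multi-allelic VCF records are not supported: ",
                 paste(fix$ID[multi], collapse = ", ")),
          class = "grsmr_validation_error")
  }
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <-
    paste0(fix$CHROM, ":", fix$POS)[is.na(ids) | ids == "."]

  fmt <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  if (all(is.na(fmt))) {
    gt <- vcfR::extract.gt(v, element = "GT")
    fmt <- apply(gt, c(1, 2), gt_to_dosage)
  }
  dosages <- t(fmt)                       # subjects x variants
  n_miss <- sum(is.na(dosages))
  if (n_miss > 0) {
    dosages <- impute_column_mean(dosages)
    message(sprintf("read_genotypes: mean-imputed %d missing genotype(s).",
                    n_miss))
  }

  info_raw <- vcfR::extract.info(v, element = "INFO", as.numeric = TRUE)
  info <- if (is.null(info_raw)) rep(NA_real_, nrow(fix)) else as.numeric(info_raw)

  snps <- tibble(
    snp_id = ids, chrom = fix$CHROM, pos = as.integer(fix$POS),
    effect_allele = fix$ALT, other_allele = fix$REF, info = info)
  geno_matrix(dosages, snps, colnames(fmt))
}

gt_to_dosage <- function(gt) {
  if (is.na(gt) || gt %in% c(".", "./.", ".|.")) return(NA_real_)
  alleles <- strsplit(gt, "[/|]")[[1]]
  if (any(alleles == ".")) return(NA_real_)
  sum(alleles == "1")
}

impute_column_mean <- function(d) {
  for (j in seq_len(ncol(d))) {
    miss <- is.na(d[, j])
    if (any(miss)) d[miss, j] <- mean(d[!miss, j])
  }
  d
}

read_genotypes_tsv <- function(path, snp_meta = NULL) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (names(tab)[1] != "subject_id") {
    abort("dosage TSV must have `subject_id` as its first column.",
          class = "grsmr_io_error")
  }
  subject_ids <- as.character(tab$subject_id)
  d <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(d)) {
    abort("non-numeric dosage values in TSV.", class = "grsmr_io_error")
  }
  n_miss <- sum(is.na(d))
  if (n_miss > 0) {
    d <- impute_column_mean(d)
    message(sprintf("read_genotypes: mean-imputed %d missing genotype(s).",
                    n_miss))
  }
  if (any(d < 0 | d > 2)) {
    abort("dosage out of [0, 2] in TSV.", class = "grsmr_validation_error")
  }
  if (is.null(snp_meta) && file.exists(paste0(path, ".meta"))) {
    snp_meta <- readr::read_tsv(paste0(path, ".meta"),
                                show_col_types = FALSE, progress = FALSE)
  }
  if (is.null(snp_meta)) {
    snp_meta <- tibble(snp_id = colnames(d),
                       effect_allele = "A", other_allele = "B")
  }
  snp_meta <- as_tibble(snp_meta)
  snp_meta <- snp_meta[match(colnames(d), snp_meta$snp_id), ]
  if (anyNA(snp_meta$snp_id)) {
    abort("snp_meta does not cover all TSV variant columns.",
          class = "grsmr_validation_error")
  }
  geno_matrix(d, snp_meta, subject_ids)
}

#' Write genotypes as a dosage table with a metadata sidecar
#'
#' Writes the dosage matrix as TSV (first column `subject_id`) plus a
#' `<path>.meta` TSV carrying the variant metadata, so that
#' `read_genotypes()` round-trips hard-call input exactly.
#'
#' @param g A [geno_matrix()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path) {
  tab <- bind_cols(tibble(subject_id = g$subject_ids),
                   as_tibble(g$dosages))
  readr::write_tsv(tab, path, progress = FALSE)
  readr::write_tsv(g$snps, paste0(path, ".meta"), progress = FALSE)
  invisible(path)
}

#' Read a phenotype table and standardize the exposure
#'
#' Expects a CSV with columns `subject_id`, `apn` (raw plasma adiponectin,
#' positive, pg/mL-like scale) and `dr` (binary retinopathy status), plus
#' any risk-factor covariates. Adiponectin is natural-log transformed and
#' standardized to SD units (`apn_z`, sample-SD denominator `n - 1`) over
#' subjects with a non-missing value.
#'
#' @param path CSV path.
#' @return A tibble with `subject_id`, `apn_raw`, `apn_z`, `dr` and all
#'   covariate columns.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "grsmr_io_error")
  }
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("subject_id", "apn", "dr")
  miss <- setdiff(req, names(tab))
  if (length(miss)) {
    abort(paste0("phenotype CSV missing columns: ",
                 paste(miss, collapse = ", ")),
          class = "grsmr_io_error")
  }
  if (anyDuplicated(tab$subject_id)) {
    abort("duplicated subject_id in phenotype table.",
          class = "grsmr_validation_error")
  }
  standardize_phenotypes(dplyr::rename(tab, apn_raw = "apn"))
}

#' Standardize an in-memory phenotype table
#'
#' @param ph Data frame with at least `subject_id`, `apn_raw`, `dr`.
#' @return Tibble with `apn_z` added (mean 0, variance 1 over non-missing
#'   values) and `dr` coerced to integer 0/1.
#' @export
standardize_phenotypes <- function(ph) {
  ph <- as_tibble(ph)
  ok <- !is.na(ph$apn_raw)
  if (any(ph$apn_raw[ok] <= 0)) {
    abort("apn must be positive (log transform applied).",
          class = "grsmr_validation_error")
  }
  bad_dr <- !is.na(ph$dr) & !(ph$dr %in% c(0, 1))
  if (any(bad_dr)) {
    abort("dr must be 0, 1 or NA.", class = "grsmr_validation_error")
  }
  lg <- log(ph$apn_raw[ok])
  s <- sd(lg)
  if (!is.finite(s) || s == 0) {
    abort("zero variance exposure: all apn values identical.",
          class = "grsmr_validation_error")
  }
  ph$apn_z <- NA_real_
  ph$apn_z[ok] <- (lg - mean(lg)) / s
  ph$dr <- as.integer(ph$dr)
  ph$subject_id <- as.character(ph$subject_id)
  dplyr::relocate(ph, "subject_id", "apn_raw", "apn_z", "dr")
}

#' Read an external variant weight table
#'
#' Per-allele effects of each variant on log-adiponectin (SD units) from
#' external source studies, used to weight genetic risk scores.
#'
#' @param path TSV with columns `snp_id`, `effect_allele`, `weight` and
#'   optionally `source_p`, `source_tier`.
#' @return A tibble.
#' @export
read_weights <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("snp_id", "effect_allele", "weight")
  miss <- setdiff(req, names(tab))
  if (length(miss)) {
    abort(paste0("weight table missing columns: ",
                 paste(miss, collapse = ", ")),
          class = "grsmr_io_error")
  }
  if (!all(is.finite(tab$weight))) {
    abort("weights must be finite.", class = "grsmr_validation_error")
  }
  if ("source_p" %in% names(tab) &&
      any(tab$source_p <= 0 | tab$source_p > 1, na.rm = TRUE)) {
    abort("source_p must lie in (0, 1].", class = "grsmr_validation_error")
  }
  tab
}

#' Harmonize external weights with the genotype effect alleles
#'
#' When a weight's stated effect allele mismatches the genotype effect
#' allele but equals the other allele, the genotype column is flipped
#' (`2 - dosage`) so both refer to the same allele; when neither allele
#' matches, the variant is dropped with a warning.
#'
#' @param g A [geno_matrix()].
#' @param weights Weight table as from [read_weights()].
#' @return List with elements `genotypes` (possibly flipped), `weights`
#'   (tibble aligned to the retained variants), `flipped` and `dropped`
#'   (character vectors of variant ids).
#' @export
harmonize_weights <- function(g, weights) {
  weights <- as_tibble(weights)
  keep <- intersect(weights$snp_id, g$snps$snp_id)
  w <- weights[match(keep, weights$snp_id), ]
  meta <- g$snps[match(keep, g$snps$snp_id), ]

  same <- w$effect_allele == meta$effect_allele
  flip <- !same & w$effect_allele == meta$other_allele
  drop <- !same & !flip

  dropped <- c(setdiff(weights$snp_id, g$snps$snp_id), keep[drop])
  if (length(dropped)) {
    warn(paste0("harmonize_weights: dropping ",
                length(dropped), " variant(s) with unmatched alleles: ",
                paste(dropped, collapse = ", ")))
  }
  flipped <- keep[flip]
  if (length(flipped)) {
    g <- flip_alleles(g, flipped)
    message(sprintf("harmonize_weights: flipped %d variant(s) to the stated effect allele.",
                    length(flipped)))
  }
  list(genotypes = g,
       weights = w[!drop, , drop = FALSE],
       flipped = flipped,
       dropped = dropped)
}

#' Read a flat key-value pipeline configuration
#'
#' YAML-style flat mapping; see [run_pipeline()] for recognized keys and
#' defaults (quality-control and pruning thresholds default to
#' `maf_min = 0.005`, `info_min = 0.4`, `r2_threshold = 0.05`,
#' `gwas_p = 5e-8`).
#'
#' @param path YAML file path.
#' @return Named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("config not found: ", path), class = "grsmr_io_error")
  }
  yaml::read_yaml(path)
}
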