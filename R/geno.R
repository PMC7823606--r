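#' Genotype matrix container
#'
#' Bundles an `n_subjects x n_snps` additive dosage matrix (values in
#' `[0, 2]`, counted on the effect allele) with per-variant metadata and
#' subject identifiers. All downstream association, pruning and scoring
#' functions take this container as their genotype input.
#'
#' @param dosages Numeric matrix, subjects in rows, variants in columns.
#'   Values must lie in `[0, 2]`; `NA` is not allowed (impute on read).
#' @param snps Data frame of variant metadata with columns `snp_id`,
#'   `effect_allele`, `other_allele`, and optionally `chrom`, `pos`, `maf`,
#'   `info`. `maf` is recomputed from the dosages when absent.
#' @param subject_ids Character vector of unique subject identifiers, one
#'   per row of `dosages`.
#'
#' @return An object of class `geno_matrix`: a list with elements
#'   `dosages`, `snps` (tibble) and `subject_ids`.
#' @export
#' @examples
#' g <- geno_matrix(
#'   matrix(c(0, 1, 2, 1, 0, 1), nrow = 3,
#'          dimnames = list(NULL, c("rs1", "rs2"))),
#'   snps = data.frame(snp_id = c("rs1", "rs2"),
#'                     effect_allele = "A", other_allele = "G"),
#'   subject_ids = c("s1", "s2", "s3"))
#' g
geno_matrix <- function(dosages, snps, subject_ids) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  snps <- as_tibble(snps)

  if (!all(c("snp_id", "effect_allele", "other_allele") %in% names(snps))) {
    abort("`snps` needs columns snp_id, effect_allele, other_allele.",
          class = "grsmr_validation_error")
  }
  if (nrow(snps) != ncol(dosages)) {
    abort("`snps` rows must match dosage columns.",
          class = "grsmr_validation_error")
  }
  if (length(subject_ids) != nrow(dosages)) {
    abort("`subject_ids` length must match dosage rows.",
          class = "grsmr_validation_error")
  }
  if (anyDuplicated(snps$snp_id)) {
    abort("duplicated snp_id in genotype data.",
          class = "grsmr_validation_error")
  }
  if (anyDuplicated(subject_ids)) {
    abort("duplicated subject_id in genotype data.",
          class = "grsmr_validation_error")
  }
  if (anyNA(dosages)) {
    abort("dosages contain NA; impute missing genotypes first.",
          class = "grsmr_validation_error")
  }
  rng <- range(dosages)
  if (rng[1] < 0 || rng[2] > 2) {
    abort(sprintf("dosages out of [0, 2] (range %.3g to %.3g).",
                  rng[1], rng[2]),
          class = "grsmr_validation_error")
  }
  if (any(snps$effect_allele == snps$other_allele)) {
    abort("effect_allele must differ from other_allele.",
          class = "grsmr_validation_error")
  }
  colnames(dosages) <- snps$snp_id

  if (!"maf" %in% names(snps) || anyNA(snps$maf)) {
    eaf <- colMeans(dosages) / 2
    snps$maf <- pmin(eaf, 1 - eaf)
  }
  if (!"info" %in% names(snps)) snps$info <- NA_real_
  if (any(snps$maf < 0 | snps$maf > 0.5)) {
    abort("maf must lie in [0, 0.5].", class = "grsmr_validation_error")
  }
  ok_info <- is.na(snps$info) | (snps$info >= 0 & snps$info <= 1)
  if (!all(ok_info)) {
    abort("info must lie in [0, 1] when present.",
          class = "grsmr_validation_error")
  }

  structure(
    list(dosages = dosages, snps = snps,
         subject_ids = as.character(subject_ids)),
    class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("<geno_matrix> %d subjects x %d variants\n",
              nrow(x$dosages), ncol(x$dosages)))
  cat(sprintf("  MAF range: %.3f-%.3f; INFO present for %d variants\n",
              min(x$snps$maf), max(x$snps$maf), sum(!is.na(x$snps$info))))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosages)

#' Number of subjects / variants in a genotype matrix
#' @param g A [geno_matrix()].
#' @return Integer count.
#' @export
n_subjects <- function(g) nrow(g$dosages)

#' @rdname n_subjects
#' @export
n_snps <- function(g) ncol(g$dosages)

#' Subset a genotype matrix by variant id
#'
#' @param g A [geno_matrix()].
#' @param snp_ids Character vector of variant ids to keep, in the order
#'   given.
#' @return A [geno_matrix()] restricted to `snp_ids`.
#' @export
select_snps <- function(g, snp_ids) {
  missing <- setdiff(snp_ids, g$snps$snp_id)
  if (length(missing)) {
    abort(paste0("variants absent from genotype data: ",
                 paste(missing, collapse = ", ")),
          class = "grsmr_missing_snp_error")
  }
  idx <- match(snp_ids, g$snps$snp_id)
  geno_matrix(g$dosages[, idx, drop = FALSE], g$snps[idx, ],
              g$subject_ids)
}

#' Flip the counted allele of selected variants
#'
#' Recodes dosage as `2 - dosage` and swaps the effect/other allele labels,
#' so that the stored dosage always counts the stated effect allele.
#'
#' @param g A [geno_matrix()].
#' @param snp_ids Variants to flip.
#' @return A [geno_matrix()] with the listed columns flipped.
#' @export
flip_alleles <- function(g, snp_ids) {
  idx <- match(snp_ids, g$snps$snp_id)
  if (anyNA(idx)) {
    abort("cannot flip unknown variants.", class = "grsmr_missing_snp_error")
  }
  d <- g$dosages
  d[, idx] <- 2 - d[, idx]
  snps <- g$snps
  ea <- snps$effect_allele[idx]
  snps$effect_allele[idx] <- snps$other_allele[idx]
  snps$other_allele[idx] <- ea
  geno_matrix(d, snps, g$subject_ids)
}
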