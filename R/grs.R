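#' Greedy linkage-disequilibrium pruning
#'
#' Retains approximately independent variants: candidates are ranked by
#' the exposure variance they explain (descending, ties broken by
#' `snp_id` ascending) and accepted greedily if their squared Pearson
#' dosage correlation with every already-kept variant stays strictly
#' below `r2_threshold`. This keeps, within each correlated block, the
#' variant that explains the most exposure variance.
#'
#' @param g A [geno_matrix()].
#' @param exposure_assoc Tibble from [snp_exposure_assoc()] supplying the
#'   `r2` ranking.
#' @param r2_threshold Squared-correlation threshold (default 0.05).
#' @return Character vector of kept `snp_id`s, in acceptance order.
#' @export
ld_prune <- function(g, exposure_assoc, r2_threshold = 0.05) {
  ea <- exposure_assoc[match(g$snps$snp_id, exposure_assoc$snp_id), ]
  ok <- !is.na(ea$r2)
  ids <- g$snps$snp_id[ok]
  rank_r2 <- ea$r2[ok]
  ord <- order(-rank_r2, ids)
  ids <- ids[ord]
  if (!length(ids)) return(character(0))

  D <- g$dosages[, ids, drop = FALSE]
  ld <- suppressWarnings(cor(D))^2
  ld[is.na(ld)] <- 0

  kept <- integer(0)
  for (i in seq_along(ids)) {
    if (!length(kept) || all(ld[i, kept] < r2_threshold)) {
      kept <- c(kept, i)
    }
  }
  ids[kept]
}

#' Build a genetic risk score
#'
#' Per-subject weighted allele score `sum_j w_j * dosage_ij` over the
#' listed variants (unit weights when `weights` is `NULL`), then
#' standardized to mean 0, variance 1 over subjects. Because the score is
#' standardized, rescaling all weights by a constant leaves it unchanged.
#'
#' @param g A [geno_matrix()] already harmonized to the weight alleles
#'   (see [harmonize_weights()]).
#' @param snp_ids Variants to combine; all must be present in `g`.
#' @param weights `NULL` (unweighted), a numeric vector aligned to
#'   `snp_ids`, or a data frame with `snp_id` and `weight` columns.
#' @param name Label for the score definition.
#' @return A `grs_scores` tibble with columns `subject_id`, `score_raw`,
#'   `score_z`; the variant set, weights and name travel as attributes.
#' @export
build_grs <- function(g, snp_ids, weights = NULL, name = "GRS") {
  gs <- select_snps(g, snp_ids)
  if (is.null(weights)) {
    w <- rep(1, length(snp_ids))
  } else if (is.data.frame(weights)) {
    w <- weights$weight[match(snp_ids, weights$snp_id)]
    if (anyNA(w)) {
      abort(paste0("weights missing for: ",
                   paste(snp_ids[is.na(w)], collapse = ", ")),
            class = "grsmr_validation_error")
    }
  } else {
    stopifnot(length(weights) == length(snp_ids))
    w <- as.numeric(weights)
  }
  if (!all(is.finite(w))) {
    abort("weights must be finite.", class = "grsmr_validation_error")
  }
  raw <- drop(gs$dosages %*% w)
  s <- sd(raw)
  if (!is.finite(s) || s == 0) {
    abort("degenerate score: zero variance across subjects.",
          class = "grsmr_validation_error")
  }
  out <- tibble(subject_id = g$subject_ids,
                score_raw = raw,
                score_z = (raw - mean(raw)) / s)
  attr(out, "snp_ids") <- snp_ids
  attr(out, "weights") <- w
  attr(out, "name") <- name
  class(out) <- c("grs_scores", class(out))
  out
}

#' Score-exposure association and strength diagnostics
#'
#' Ordinary least squares of the standardized log-exposure on the
#' standardized score: the instrument leg of the score-based causal
#' estimate, in SD-exposure-per-SD-score units, with the 95% interval,
#' F statistic and variance explained.
#'
#' @param grs A `grs_scores` tibble from [build_grs()].
#' @param ph Phenotype tibble.
#' @return One-row tibble: `name`, `beta_apn`, `se`, `p`, `ci95_lo`,
#'   `ci95_hi`, `f_stat`, `r2`, `n_used`, `n_snps`.
#' @export
grs_exposure_assoc <- function(grs, ph) {
  al <- align_scores(grs, ph)
  y <- al$apn_z
  x <- al$score_z
  if (sd(x) == 0) {
    abort("degenerate score.", class = "grsmr_validation_error")
  }
  fit <- simple_ols_columns(matrix(x, ncol = 1), y)
  f <- (fit$beta / fit$se)^2
  tibble(name = attr(grs, "name") %||% "GRS",
         beta_apn = fit$beta, se = fit$se, p = fit$p,
         ci95_lo = fit$beta - Z95 * fit$se,
         ci95_hi = fit$beta + Z95 * fit$se,
         f_stat = f, r2 = fit$r2,
         n_used = length(y),
         n_snps = length(attr(grs, "snp_ids") %||% NA))
}

#' Score-outcome association
#'
#' Logistic regression of the binary outcome on the standardized score
#' (log-odds ratio per SD of score) with Wald standard error and
#' two-sided normal p-value.
#'
#' @inheritParams grs_exposure_assoc
#' @return One-row tibble: `name`, `beta`, `se`, `p`, `n_used`.
#' @export
grs_outcome_assoc <- function(grs, ph) {
  al <- align_scores(grs, ph)
  check_outcome_classes(al$dr)
  fit <- logistic_wald(cbind(1, al$score_z), al$dr)
  if (!is.null(fit$reason)) {
    abort(paste0("score-outcome model failed: ", fit$reason),
          class = "grsmr_model_error")
  }
  tibble(name = attr(grs, "name") %||% "GRS",
         beta = fit$beta[2], se = fit$se[2],
         p = 2 * pnorm(-abs(fit$beta[2] / fit$se[2])),
         n_used = length(al$dr))
}

align_scores <- function(grs, ph) {
  idx <- match(grs$subject_id, ph$subject_id)
  if (anyNA(idx)) {
    abort("score subjects missing from phenotype table.",
          class = "grsmr_validation_error")
  }
  out <- ph[idx, , drop = FALSE]
  out$score_z <- grs$score_z
  out
}

#' Assemble the three score definitions used in the analysis
#'
#' Given the pruned candidate set and its exposure associations, returns
#' the variant lists for the three conventional score definitions:
#' `all` (every pruned variant), `gwas_significant` (external source
#' p-value below `gwas_p`, genome-wide significance) and
#' `internally_significant` (in-sample exposure p-value below
#' `internal_p`).
#'
#' @param assoc Exposure association tibble for the pruned variants.
#' @param weights Optional external weight table with `source_p`.
#' @param gwas_p Genome-wide significance threshold (default 5e-8).
#' @param internal_p In-sample significance threshold (default 0.05).
#' @return Named list of character vectors of `snp_id`s.
#' @export
grs_definitions <- function(assoc, weights = NULL, gwas_p = 5e-8,
                            internal_p = 0.05) {
  defs <- list(all = assoc$snp_id)
  if (!is.null(weights) && "source_p" %in% names(weights)) {
    sig <- weights$snp_id[!is.na(weights$source_p) &
                            weights$source_p < gwas_p]
    defs$gwas_significant <- intersect(assoc$snp_id, sig)
  }
  defs$internally_significant <-
    assoc$snp_id[!is.na(assoc$p_exposure) & assoc$p_exposure < internal_p]
  defs
}
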