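#' Per-variant exposure associations
#'
#' Ordinary least squares of the standardized log-exposure on each
#' variant's additive dosage, one variant at a time. The base model is
#' unadjusted (the default for instrument discovery); the adjusted model
#' adds the named covariates. Effects are per effect allele, two-sided
#' p-values from the t distribution with `n - k - 1` degrees of freedom,
#' and the instrument F statistic is the squared t ratio of the dosage
#' term. In the base model `r2` is the squared Pearson correlation
#' between dosage and exposure; in the adjusted model it is the dosage
#' term's partial contribution.
#'
#' @param g A [geno_matrix()].
#' @param ph Phenotype tibble (see [read_phenotypes()]); matched to `g`
#'   by `subject_id`.
#' @param covariates Character vector of covariate column names for the
#'   adjusted model; `NULL` for the base model.
#' @return Tibble, one row per variant: `snp_id`, `effect_allele`,
#'   `beta_exposure`, `se_exposure`, `p_exposure`, `f_stat`, `r2`,
#'   `n_used`, `reason` (`NA` or why the estimate is absent).
#' @export
snp_exposure_assoc <- function(g, ph, covariates = NULL) {
  al <- align_cohort(g, ph)
  y <- al$ph$apn_z
  n <- length(y)
  if (sd(y) == 0) {
    abort("degenerate exposure: apn_z has zero variance.",
          class = "grsmr_validation_error")
  }
  k <- length(covariates)
  if (n < 10 + k) {
    abort("too few subjects for exposure association.",
          class = "grsmr_validation_error")
  }
  D <- al$g$dosages

  if (is.null(covariates)) {
    res <- simple_ols_columns(D, y)
  } else {
    miss <- setdiff(covariates, names(al$ph))
    if (length(miss)) {
      abort(paste0("unknown covariates: ", paste(miss, collapse = ", ")),
            class = "grsmr_validation_error")
    }
    X0 <- as.matrix(al$ph[covariates])
    res <- purrr::map(seq_len(ncol(D)), function(j) {
      x <- D[, j]
      if (var(x) == 0) {
        return(list(beta = NA_real_, se = NA_real_, p = NA_real_,
                    r2 = NA_real_, reason = "monomorphic"))
      }
      fit <- lm(y ~ x + X0)
      sm <- summary(fit)$coefficients["x", ]
      # partial R^2 of the dosage term given the covariates
      t2 <- sm[3]^2
      list(beta = unname(sm[1]), se = unname(sm[2]),
           p = unname(sm[4]),
           r2 = unname(t2 / (t2 + fit$df.residual)), reason = NA_character_)
    })
    res <- list(beta = map_dbl(res, "beta"), se = map_dbl(res, "se"),
                p = map_dbl(res, "p"), r2 = map_dbl(res, "r2"),
                reason = map_chr(res, "reason"))
  }

  tibble(snp_id = al$g$snps$snp_id,
         effect_allele = al$g$snps$effect_allele,
         beta_exposure = res$beta, se_exposure = res$se,
         p_exposure = res$p,
         f_stat = (res$beta / res$se)^2,
         r2 = res$r2, n_used = n, reason = res$reason)
}

# Closed-form simple regression of y on each column of D, vectorized.
# Cross-checked against stats::lm in the test suite.
simple_ols_columns <- function(D, y) {
  n <- length(y)
  yc <- y - mean(y)
  Dc <- sweep(D, 2, colMeans(D))
  sxx <- colSums(Dc^2)
  mono <- sxx == 0
  sxy <- colSums(Dc * yc)
  syy <- sum(yc^2)
  beta <- sxy / sxx
  sse <- syy - sxy^2 / sxx
  se <- sqrt(pmax(sse, 0) / (n - 2) / sxx)
  tval <- beta / se
  p <- 2 * pt(-abs(tval), df = n - 2)
  r2 <- sxy^2 / (sxx * syy)
  beta[mono] <- se[mono] <- p[mono] <- r2[mono] <- NA_real_
  list(beta = unname(beta), se = unname(se), p = unname(p),
       r2 = unname(r2),
       reason = unname(ifelse(mono, "monomorphic", NA_character_)))
}

#' Per-variant outcome associations
#'
#' Unadjusted logistic regression of the binary outcome on each
#' variant's dosage, fit by iteratively reweighted least squares
#' (converged when the score norm falls below `1e-8`, at most 50
#' iterations). Effects are log-odds ratios per effect allele with Wald
#' standard errors from the Fisher information at the maximum-likelihood
#' estimate and two-sided normal p-values. Variants showing separation
#' (`|beta| > 20` during iteration) are marked absent with a reason.
#'
#' @inheritParams snp_exposure_assoc
#' @return Tibble, one row per variant: `snp_id`, `effect_allele`,
#'   `beta_outcome`, `se_outcome`, `p_outcome`, `n_used`, `reason`.
#' @export
snp_outcome_assoc <- function(g, ph) {
  al <- align_cohort(g, ph)
  yv <- al$ph$dr
  check_outcome_classes(yv)
  D <- al$g$dosages

  res <- purrr::map(seq_len(ncol(D)), function(j) {
    x <- D[, j]
    if (var(x) == 0) {
      return(list(beta = NA_real_, se = NA_real_, p = NA_real_,
                  reason = "monomorphic"))
    }
    fit <- logistic_wald(cbind(1, x), yv)
    if (!is.null(fit$reason)) {
      return(list(beta = NA_real_, se = NA_real_, p = NA_real_,
                  reason = fit$reason))
    }
    list(beta = fit$beta[2], se = fit$se[2],
         p = 2 * pnorm(-abs(fit$beta[2] / fit$se[2])),
         reason = NA_character_)
  })

  tibble(snp_id = al$g$snps$snp_id,
         effect_allele = al$g$snps$effect_allele,
         beta_outcome = map_dbl(res, "beta"),
         se_outcome = map_dbl(res, "se"),
         p_outcome = map_dbl(res, "p"),
         n_used = length(yv),
         reason = map_chr(res, "reason"))
}

check_outcome_classes <- function(yv) {
  if (anyNA(yv)) {
    abort("outcome contains NA.", class = "grsmr_validation_error")
  }
  tab <- table(factor(yv, levels = c(0, 1)))
  if (any(tab == 0)) {
    abort("outcome has a single class; logistic regression refused.",
          class = "grsmr_validation_error")
  }
  if (any(tab < 5)) {
    abort("need at least 5 subjects in each outcome class.",
          class = "grsmr_validation_error")
  }
}

# Logistic MLE via glm.fit with tight IRLS control; Wald SEs from the
# observed Fisher information. Separation flagged at |beta| > 20.
logistic_wald <- function(X, y) {
  fit <- suppressWarnings(
    glm.fit(X, y, family = binomial(),
            control = list(epsilon = 1e-12, maxit = 50)))
  beta <- fit$coefficients
  if (anyNA(beta) || any(abs(beta) > 20)) {
    return(list(reason = "separation"))
  }
  mu <- fit$fitted.values
  W <- mu * (1 - mu)
  I <- crossprod(X, X * W)
  V <- tryCatch(solve(I), error = function(e) NULL)
  if (is.null(V)) return(list(reason = "singular_information"))
  list(beta = beta, se = sqrt(diag(V)))
}

#' Combined per-variant association table
#'
#' Runs [snp_exposure_assoc()] and [snp_outcome_assoc()] and joins them
#' into the per-variant summary table consumed by the causal estimators
#' ([mr_ivw()], [mr_egger()], [mr_weighted_median()], [wald_ratio()]).
#'
#' @inheritParams snp_exposure_assoc
#' @return Tibble with both exposure and outcome association columns.
#' @export
snp_assoc <- function(g, ph, covariates = NULL) {
  ex <- snp_exposure_assoc(g, ph, covariates)
  out <- snp_outcome_assoc(g, ph)
  dplyr::left_join(
    dplyr::rename(ex, reason_exposure = "reason"),
    dplyr::select(out, "snp_id", "beta_outcome", "se_outcome",
                  "p_outcome", reason_outcome = "reason"),
    by = "snp_id")
}

#' Instrument-strength diagnostics
#'
#' For a single-predictor model the instrument F statistic is the
#' squared t ratio `(beta/se)^2`, the exposure variance explained is
#' `r2 = F / (F + n - 2)`, and an instrument is conventionally called
#' strong when `F` exceeds 10 (strictly: `F = 10` exactly is weak).
#'
#' @param assoc Association tibble with `beta_exposure`, `se_exposure`
#'   and `n_used` (as from [snp_exposure_assoc()]), or a single `beta`.
#' @param se,n Standard error and sample size when `assoc` is a bare
#'   numeric effect size.
#' @return The input tibble with `f_stat`, `r2`, `is_strong` columns
#'   (recomputed), or a one-row tibble for scalar input.
#' @export
#' @examples
#' instrument_strength(0.1, se = 0.05, n = 1000)
instrument_strength <- function(assoc, se = NULL, n = NULL) {
  if (is.numeric(assoc)) {
    assoc <- tibble(beta_exposure = assoc, se_exposure = se, n_used = n)
  }
  f <- (assoc$beta_exposure / assoc$se_exposure)^2
  assoc$f_stat <- f
  assoc$r2 <- f / (f + assoc$n_used - 2)
  assoc$is_strong <- f > 10
  assoc
}

# Match genotype and phenotype tables on subject_id, preserving the
# genotype ordering; errors on subjects missing from either side.
align_cohort <- function(g, ph) {
  idx <- match(g$subject_ids, ph$subject_id)
  if (anyNA(idx)) {
    abort("subjects in genotype data missing from phenotype table.",
          class = "grsmr_validation_error")
  }
  list(g = g, ph = ph[idx, , drop = FALSE])
}
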