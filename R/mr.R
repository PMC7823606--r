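# Construct an mr_fit object from one or more (term, beta, se) rows.
# p-values use the normal reference unless df is finite (then t).
new_mr_fit <- function(method, term, beta, se, n_snps, df = Inf,
                       data = NULL, extra = list()) {
  stat <- beta / se
  p <- if (is.finite(df)) 2 * pt(-abs(stat), df) else 2 * pnorm(-abs(stat))
  est <- tibble(
    method = method, term = term, beta = beta, se = se,
    ci95_lo = beta - Z95 * se, ci95_hi = beta + Z95 * se,
    ci90_lo = beta - Z90 * se, ci90_hi = beta + Z90 * se,
    p = p, or = exp(beta), n_snps = n_snps)
  structure(list(estimates = est, method = method, data = data,
                 extra = extra),
            class = "mr_fit")
}

ratio_table <- function(assoc, second_order = FALSE) {
  ok <- !is.na(assoc$beta_exposure) & !is.na(assoc$beta_outcome)
  a <- assoc[ok, , drop = FALSE]
  if (!nrow(a)) {
    abort("no usable variants (missing association estimates).",
          class = "grsmr_estimation_error")
  }
  if (any(a$beta_exposure == 0)) {
    abort("undefined ratio: beta_exposure is zero for some variants.",
          class = "grsmr_estimation_error")
  }
  ratio <- a$beta_outcome / a$beta_exposure
  se <- if (second_order) {
    sqrt(a$se_outcome^2 / a$beta_exposure^2 +
           a$beta_outcome^2 * a$se_exposure^2 / a$beta_exposure^4)
  } else {
    a$se_outcome / abs(a$beta_exposure)
  }
  tibble(snp_id = a$snp_id, ratio = ratio, se = se,
         beta_exposure = a$beta_exposure, se_exposure = a$se_exposure,
         beta_outcome = a$beta_outcome, se_outcome = a$se_outcome)
}

#' Per-variant Wald ratio estimates
#'
#' The single-instrument causal estimate for each variant: the
#' variant-outcome log-odds ratio divided by the variant-exposure effect,
#' giving the log-odds ratio of outcome per SD of genetically determined
#' log-exposure. The default standard error is the first-order delta
#' method `se_outcome / |beta_exposure|`; `second_order = TRUE` adds the
#' exposure-leg uncertainty term.
#'
#' @param assoc Per-variant association tibble (see [snp_assoc()]).
#' @param second_order Use the second-order delta-method standard error.
#' @return Tibble, one row per variant, with `beta`, `se`, 95% and 90%
#'   intervals, two-sided normal `p` and `or = exp(beta)`.
#' @export
#' @examples
#' a <- tibble::tibble(snp_id = "rs1", beta_exposure = 0.5,
#'                     se_exposure = 0.05, beta_outcome = 0.3,
#'                     se_outcome = 0.1)
#' wald_ratio(a)
wald_ratio <- function(assoc, second_order = FALSE) {
  rt <- ratio_table(assoc, second_order)
  fit <- new_mr_fit("wald", rt$snp_id, rt$ratio, rt$se, n_snps = 1L,
                    data = rt)
  fit$estimates
}

#' Inverse-variance-weighted causal estimate
#'
#' Fixed-effect meta-analysis of the per-variant Wald ratios with
#' weights `1/se^2`: `beta = sum(w * ratio) / sum(w)`,
#' `se = 1/sqrt(sum(w))`. Algebraically identical to the slope of
#' zero-intercept weighted least squares of the outcome associations on
#' the exposure associations with weights `1/se_outcome^2`. With
#' `random_effects = TRUE` the standard error is inflated by
#' `max(1, sqrt(Q/(k-1)))` (multiplicative random effects).
#'
#' @inheritParams wald_ratio
#' @param random_effects Apply multiplicative random-effects inflation.
#' @return An `mr_fit`; see [tidy.mr_fit()].
#' @export
mr_ivw <- function(assoc, random_effects = FALSE, second_order = FALSE) {
  rt <- ratio_table(assoc, second_order)
  w <- 1 / rt$se^2
  beta <- sum(w * rt$ratio) / sum(w)
  se <- 1 / sqrt(sum(w))
  k <- nrow(rt)
  Q <- sum(w * (rt$ratio - beta)^2)
  if (random_effects && k > 1) {
    se <- se * max(1, sqrt(Q / (k - 1)))
  }
  new_mr_fit("ivw", "causal_effect", beta, se, n_snps = k, data = rt,
             extra = list(Q = Q, random_effects = random_effects))
}

#' Score-based two-stage causal estimate
#'
#' Treats a genetic risk score as a single instrument: the causal
#' log-odds ratio per SD log-exposure is the score-outcome log-odds
#' ratio divided by the score-exposure effect. The default standard
#' error is the first-order delta method (outcome-leg uncertainty only);
#' `include_exposure_uncertainty = TRUE` adds the second-order term.
#'
#' @param exp_leg One-row tibble from [grs_exposure_assoc()].
#' @param out_leg One-row tibble from [grs_outcome_assoc()].
#' @param include_exposure_uncertainty Add the exposure-leg variance
#'   term to the standard error.
#' @return An `mr_fit`.
#' @export
grs_two_stage <- function(exp_leg, out_leg,
                          include_exposure_uncertainty = FALSE) {
  be <- exp_leg$beta_apn[1]
  if (is.na(be) || be == 0) {
    abort("zero exposure-leg effect: two-stage ratio undefined.",
          class = "grsmr_estimation_error")
  }
  bo <- out_leg$beta[1]
  beta <- bo / be
  se <- if (include_exposure_uncertainty) {
    sqrt(out_leg$se[1]^2 / be^2 + bo^2 * exp_leg$se[1]^2 / be^4)
  } else {
    out_leg$se[1] / abs(be)
  }
  new_mr_fit("grs_two_stage", exp_leg$name[1] %||% "GRS", beta, se,
             n_snps = exp_leg$n_snps[1] %||% NA_integer_,
             extra = list(exp_leg = exp_leg, out_leg = out_leg))
}

#' MR-Egger regression
#'
#' Weighted least squares of the variant-outcome associations on the
#' variant-exposure associations with weights `1/se_outcome^2` and a
#' free intercept. Variants are first oriented so the exposure effect is
#' positive (both legs' signs flipped together; exact zeros are
#' excluded). The slope is the pleiotropy-adjusted causal estimate; the
#' intercept estimates the average directional pleiotropic effect, and
#' its test is the standard test for directional pleiotropy. Inference
#' uses the t distribution with `k - 2` degrees of freedom and
#' multiplicative random-effects scaling `max(1, sigma)` of the standard
#' errors. With `intercept = FALSE` the regression is forced through the
#' origin and the slope reproduces the inverse-variance-weighted
#' estimate exactly (internal consistency check).
#'
#' @inheritParams wald_ratio
#' @param intercept Fit the free intercept (the default; `FALSE` is the
#'   zero-intercept consistency mode).
#' @return An `mr_fit` with terms `causal_effect` (slope) and, when
#'   `intercept = TRUE`, `pleiotropy_intercept`.
#' @export
mr_egger <- function(assoc, intercept = TRUE) {
  rt <- ratio_table(assoc)
  zero <- rt$beta_exposure == 0
  rt <- rt[!zero, , drop = FALSE]
  k <- nrow(rt)
  if (k < 3) {
    abort("MR-Egger needs at least 3 variants.",
          class = "grsmr_estimation_error")
  }
  flip <- sign(rt$beta_exposure)
  bx <- rt$beta_exposure * flip
  by <- rt$beta_outcome * flip
  w <- 1 / rt$se_outcome^2

  if (intercept) {
    fit <- lm(by ~ bx, weights = w)
    df <- k - 2
  } else {
    fit <- lm(by ~ 0 + bx, weights = w)
    df <- k - 1
  }
  sm <- summary(fit)
  sigma <- sm$sigma
  # SEs with residual variance replaced by max(1, sigma^2): fixed-effect
  # weights when the model underfits less than expected, multiplicative
  # random effects otherwise.
  scale <- if (is.finite(sigma) && sigma > 0) max(1, sigma) / sigma else 1
  co <- sm$coefficients
  if (intercept) {
    est <- new_mr_fit("egger",
                      c("pleiotropy_intercept", "causal_effect"),
                      unname(co[, 1]), unname(co[, 2]) * scale,
                      n_snps = k, df = df,
                      data = rt,
                      extra = list(sigma = sigma))
  } else {
    est <- new_mr_fit("egger_no_intercept", "causal_effect",
                      unname(co[1, 1]), unname(co[1, 2]) * scale,
                      n_snps = k, df = df,
                      data = rt, extra = list(sigma = sigma))
  }
  est
}

#' Weighted-median causal estimate
#'
#' The weighted median of the per-variant Wald ratios: ratios are sorted
#' ascending, normalized inverse-variance weights accumulated, the
#' standardized cumulative weight `s_i = (cumsum(w) - w/2) / sum(w)`
#' formed, and the estimate read off by linear interpolation of the
#' ratios across `s` at 0.5. Consistent when at least half of the total
#' weight comes from valid instruments. The standard error is the
#' standard deviation of the estimate over `n_boot` parametric bootstrap
#' replicates, each leg resampled from its normal sampling distribution.
#'
#' @inheritParams wald_ratio
#' @param n_boot Number of parametric bootstrap replicates.
#' @param seed Integer seed for the bootstrap (required, so the reported
#'   standard error is reproducible).
#' @return An `mr_fit`.
#' @export
mr_weighted_median <- function(assoc, n_boot = 1000, seed) {
  if (missing(seed)) {
    abort("`seed` is required for the weighted-median bootstrap.",
          class = "grsmr_config_error")
  }
  rt <- ratio_table(assoc)
  k <- nrow(rt)
  if (k < 3) {
    abort("weighted median needs at least 3 variants.",
          class = "grsmr_estimation_error")
  }
  beta <- weighted_median_point(rt$ratio, 1 / rt$se^2)

  set.seed(seed)
  bx <- matrix(rnorm(n_boot * k, rt$beta_exposure, rt$se_exposure),
               n_boot, k, byrow = TRUE)
  by <- matrix(rnorm(n_boot * k, rt$beta_outcome, rt$se_outcome),
               n_boot, k, byrow = TRUE)
  boots <- vapply(seq_len(n_boot), function(i) {
    r <- by[i, ] / bx[i, ]
    w <- (bx[i, ] / rt$se_outcome)^2
    weighted_median_point(r, w)
  }, numeric(1))
  se <- sd(boots)
  new_mr_fit("weighted_median", "causal_effect", beta, se, n_snps = k,
             data = rt, extra = list(n_boot = n_boot, seed = seed))
}

# Interpolated weighted median: cumulative-weight midpoints against the
# sorted ratios, evaluated at probability 0.5.
weighted_median_point <- function(ratio, w) {
  ord <- order(ratio)
  b <- ratio[ord]
  w <- w[ord] / sum(w)
  s <- cumsum(w) - w / 2
  if (all(is.finite(b)) && length(b) > 1) {
    approx(s, b, xout = 0.5, rule = 2, ties = "ordered")$y
  } else {
    b[which.min(abs(s - 0.5))]
  }
}

#' Scan score-confounder associations
#'
#' Regresses each named risk-factor trait on the standardized genetic
#' score: linear regression for continuous traits, logistic for binary
#' sex. A score associated with measured confounders hints at pleiotropic
#' pathways. p-values are unadjusted two-sided, reported as-is.
#'
#' @param grs A `grs_scores` tibble from [build_grs()].
#' @param ph Phenotype tibble containing the trait columns.
#' @param traits Character vector of trait names (default: the standard
#'   risk-factor panel).
#' @return Tibble with one row per trait: `trait`, `model`, `beta`,
#'   `se`, `p`.
#' @export
confounder_scan <- function(grs, ph,
                            traits = c("sex", "sbp", "dbp", "glucose",
                                       "hba1c", "tg", "hdl", "ldl",
                                       "bmi")) {
  al <- align_scores(grs, ph)
  miss <- setdiff(traits, names(al))
  if (length(miss)) {
    abort(paste0("unknown traits: ", paste(miss, collapse = ", ")),
          class = "grsmr_validation_error")
  }
  purrr::map(traits, function(tr) {
    y <- al[[tr]]
    if (tr == "sex" || all(y %in% c(0, 1, NA))) {
      fit <- logistic_wald(cbind(1, al$score_z), y)
      if (!is.null(fit$reason)) {
        return(tibble(trait = tr, model = "logistic", beta = NA_real_,
                      se = NA_real_, p = NA_real_))
      }
      tibble(trait = tr, model = "logistic", beta = fit$beta[2],
             se = fit$se[2],
             p = 2 * pnorm(-abs(fit$beta[2] / fit$se[2])))
    } else {
      f <- simple_ols_columns(matrix(al$score_z, ncol = 1), y)
      tibble(trait = tr, model = "linear", beta = f$beta, se = f$se,
             p = f$p)
    }
  }) |> purrr::list_rbind()
}

#' Asymptotic power for binary-outcome Mendelian randomization
#'
#' Normal-approximation power for a two-sided Wald test of the causal
#' effect at level `alpha`:
#' \deqn{power = \Phi(\sqrt{n\,R^2_{xz}\,cf(1-cf)}\;|\ln OR| - z_{1-\alpha/2})}
#' where \eqn{R^2_{xz}} is the variance of the exposure explained by the
#' instrument, `cf` the case fraction and `OR` the odds ratio per SD of
#' exposure. One published convention among several; checked against a
#' full-pipeline simulation in the test suite.
#'
#' @param n Sample size.
#' @param r2_xz Instrument-explained exposure variance, in `(0, 1)`.
#' @param or_per_sd Odds ratio per SD of exposure, positive.
#' @param case_fraction Fraction of cases, in `(0, 1)`.
#' @param alpha Two-sided significance level.
#' @return Power as a fraction in `(0, 1)`.
#' @export
#' @examples
#' mr_power(n = 1251, r2_xz = 0.052, or_per_sd = 1.84,
#'          case_fraction = 438 / 1251)
mr_power <- function(n, r2_xz, or_per_sd, case_fraction, alpha = 0.05) {
  stopifnot(n > 0, r2_xz > 0, r2_xz < 1, or_per_sd > 0,
            case_fraction > 0, case_fraction < 1, alpha > 0, alpha < 1)
  ncp <- sqrt(n * r2_xz * case_fraction * (1 - case_fraction)) *
    abs(log(or_per_sd))
  pnorm(ncp - qnorm(1 - alpha / 2))
}

#' Reconstruct interval arithmetic from a published summary row
#'
#' Given a point estimate with printed 90% and 95% normal intervals,
#' recovers the implied standard error from the 90% interval
#' (`width / (2 * 1.644854)`) and recomputes the 95% bounds as
#' `beta ± 1.959964 * se`, for consistency checking of published tables
#' whose underlying data are unavailable.
#'
#' @param tbl Tibble with columns `beta`, `ci90_lo`, `ci90_hi`,
#'   `ci95_lo`, `ci95_hi`.
#' @param digits Rounding applied before comparison (published tables
#'   print 2 decimals).
#' @return The input with `se_implied`, `ci95_lo_calc`, `ci95_hi_calc`
#'   and logical `consistent` columns.
#' @export
check_ci_arithmetic <- function(tbl, digits = 2) {
  tbl <- as_tibble(tbl)
  se <- (tbl$ci90_hi - tbl$ci90_lo) / (2 * Z90)
  lo <- tbl$beta - Z95 * se
  hi <- tbl$beta + Z95 * se
  tbl$se_implied <- se
  tbl$ci95_lo_calc <- lo
  tbl$ci95_hi_calc <- hi
  tbl$consistent <- round(lo, digits) == round(tbl$ci95_lo, digits) &
    round(hi, digits) == round(tbl$ci95_hi, digits)
  tbl
}

#' Run every estimator on one association table
#'
#' Convenience wrapper producing the conventional summary block for a
#' variant set: inverse-variance-weighted, MR-Egger slope and intercept,
#' and weighted-median rows in one tibble.
#'
#' @inheritParams mr_weighted_median
#' @param label Instrument-set label attached to the output.
#' @return Tibble of estimates (one row per method/term).
#' @export
mr_all <- function(assoc, n_boot = 1000, seed, label = "SNP set") {
  rows <- list(tidy_est(mr_ivw(assoc)))
  k <- sum(!is.na(assoc$beta_exposure) & !is.na(assoc$beta_outcome))
  if (k >= 3) {
    rows <- c(rows, list(tidy_est(mr_egger(assoc)),
                         tidy_est(mr_weighted_median(assoc, n_boot, seed))))
  }
  out <- purrr::list_rbind(rows)
  out$instruments <- label
  dplyr::relocate(out, "instruments")
}

tidy_est <- function(fit) fit$estimates
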