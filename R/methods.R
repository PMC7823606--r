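#' @export
print.mr_fit <- function(x, ...) {
  cat(sprintf("<mr_fit> method: %s (%s variant%s)\n", x$method,
              x$estimates$n_snps[1],
              if (isTRUE(x$estimates$n_snps[1] == 1)) "" else "s"))
  est <- x$estimates
  for (i in seq_len(nrow(est))) {
    cat(sprintf(
      "  %-22s beta = %6.3f (95%% CI %.2f to %.2f; 90%% CI %.2f to %.2f), OR = %.2f, p = %.3g\n",
      est$term[i], est$beta[i], est$ci95_lo[i], est$ci95_hi[i],
      est$ci90_lo[i], est$ci90_hi[i], est$or[i], est$p[i]))
  }
  invisible(x)
}

#' Tidy a fitted causal estimate
#'
#' Broom-style one-row-per-term summary of an `mr_fit`.
#'
#' @param x An `mr_fit` from [mr_ivw()], [mr_egger()],
#'   [mr_weighted_median()] or [grs_two_stage()].
#' @param ... Unused.
#' @return Tibble with `method`, `term`, `estimate`, `std.error`,
#'   `statistic`, `p.value`, `conf.low`, `conf.high` (95%), `or`,
#'   `n_snps`.
#' @export
tidy.mr_fit <- function(x, ...) {
  est <- x$estimates
  tibble(method = est$method, term = est$term, estimate = est$beta,
         std.error = est$se, statistic = est$beta / est$se,
         p.value = est$p, conf.low = est$ci95_lo,
         conf.high = est$ci95_hi, or = est$or, n_snps = est$n_snps)
}

#' One-row model summary of a fitted causal estimate
#'
#' @param x An `mr_fit`.
#' @param ... Unused.
#' @return One-row tibble with the causal-effect estimate, its interval,
#'   the number of variants and (for the inverse-variance-weighted
#'   method) Cochran's Q.
#' @export
glance.mr_fit <- function(x, ...) {
  est <- x$estimates[x$estimates$term != "pleiotropy_intercept", ][1, ]
  tibble(method = x$method, beta = est$beta, se = est$se,
         p.value = est$p, or = est$or, n_snps = est$n_snps,
         Q = x$extra$Q %||% NA_real_)
}

#' Scatter diagnostic for ratio-based estimators
#'
#' Variant-outcome against variant-exposure associations with the fitted
#' causal slope (through the origin for the inverse-variance-weighted
#' method, free intercept for MR-Egger) and per-variant error bars.
#'
#' @param object An `mr_fit` carrying per-variant data ([mr_ivw()],
#'   [mr_egger()], [mr_weighted_median()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mr_fit <- function(object, ...) {
  rt <- object$data
  if (is.null(rt)) {
    abort("no per-variant data stored in this fit.",
          class = "grsmr_validation_error")
  }
  est <- object$estimates
  slope <- est$beta[est$term == "causal_effect"][1]
  icpt <- est$beta[est$term == "pleiotropy_intercept"]
  if (!length(icpt)) icpt <- 0
  flip <- sign(rt$beta_exposure)
  df <- tibble(bx = rt$beta_exposure * flip, by = rt$beta_outcome * flip,
               sx = rt$se_exposure, sy = rt$se_outcome)
  ggplot(df, aes(x = .data$bx, y = .data$by)) +
    geom_errorbar(aes(ymin = .data$by - .data$sy,
                      ymax = .data$by + .data$sy),
                  linewidth = 0.3, colour = "grey60") +
    geom_errorbarh(aes(xmin = .data$bx - .data$sx,
                       xmax = .data$bx + .data$sx),
                   linewidth = 0.3, colour = "grey60") +
    geom_point(size = 1.8) +
    geom_abline(intercept = icpt, slope = slope, colour = "firebrick") +
    labs(x = "variant-exposure effect (SD log-exposure per allele)",
         y = "variant-outcome effect (log-OR per allele)",
         title = sprintf("%s estimate: %.3f", object$method, slope)) +
    theme_minimal()
}

#' Forest plot of an estimate table
#'
#' One row per instrument-set/method combination, point estimate with
#' 95% interval, on the log-odds scale.
#'
#' @param tbl Estimate tibble as returned by [mr_all()] or assembled by
#'   [run_pipeline()].
#' @return A ggplot object.
#' @export
plot_mr_forest <- function(tbl) {
  tbl <- as_tibble(tbl)
  lab_col <- if ("instruments" %in% names(tbl)) tbl$instruments else tbl$method
  df <- tibble(label = paste(lab_col, tbl$method, tbl$term, sep = " / "),
               beta = tbl$beta, lo = tbl$ci95_lo, hi = tbl$ci95_hi)
  ggplot(df, aes(x = .data$beta, y = .data$label)) +
    geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    geom_errorbarh(aes(xmin = .data$lo, xmax = .data$hi), height = 0.2) +
    geom_point() +
    labs(x = "log-OR per SD log-exposure (95% CI)", y = NULL) +
    theme_minimal()
}
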