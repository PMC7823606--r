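mk_assoc <- function(bexp, se_exp, bout, se_out) {
  tibble::tibble(snp_id = sprintf("rs%02d", seq_along(bexp)),
                 beta_exposure = bexp, se_exposure = se_exp,
                 beta_outcome = bout, se_outcome = se_out)
}

test_that("Wald ratio arithmetic, null mapping and interval contracts", {
  a <- mk_assoc(0.5, 0.05, 0.3, 0.1)
  w <- wald_ratio(a)
  expect_equal(w$beta, 0.6)
  expect_equal(w$se, 0.2)
  expect_equal(w$ci95_lo, 0.6 - 1.959964 * 0.2, tolerance = 1e-9)
  expect_equal(w$ci90_hi, 0.6 + 1.644854 * 0.2, tolerance = 1e-9)
  expect_equal(w$or, exp(0.6), tolerance = 1e-12)
  # 90% interval nested in the 95% interval
  expect_lt(w$ci95_lo, w$ci90_lo)
  expect_gt(w$ci95_hi, w$ci90_hi)

  w0 <- wald_ratio(mk_assoc(0.5, 0.05, 0, 0.1))
  expect_equal(w0$beta, 0)
  expect_equal(w0$or, 1)

  expect_error(wald_ratio(mk_assoc(0, 0.05, 0.3, 0.1)),
               class = "grsmr_estimation_error")
})

test_that("second-order ratio SE agrees with a Monte-Carlo delta oracle", {
  a <- mk_assoc(0.5, 0.05, 0.3, 0.1)
  w2 <- wald_ratio(a, second_order = TRUE)
  expect_equal(w2$se, sqrt(0.1^2 / 0.5^2 + 0.3^2 * 0.05^2 / 0.5^4),
               tolerance = 1e-12)
  set.seed(99)
  mc <- sd(rnorm(1e6, 0.3, 0.1) / rnorm(1e6, 0.5, 0.05))
  expect_lt(abs(w2$se - mc) / mc, 0.02)
})

test_that("IVW reduces to the Wald ratio for one variant and averages by inverse variance", {
  a1 <- mk_assoc(0.5, 0.05, 0.3, 0.1)
  expect_equal(glance(mr_ivw(a1))$beta, wald_ratio(a1)$beta)
  expect_equal(glance(mr_ivw(a1))$se, wald_ratio(a1)$se)

  # two ratios 0.4 and 0.8, both se 0.2
  a2 <- mk_assoc(c(1, 1), c(0, 0), c(0.4, 0.8), c(0.2, 0.2))
  f <- glance(mr_ivw(a2))
  expect_equal(f$beta, 0.6, tolerance = 1e-12)
  expect_equal(f$se, sqrt(1 / 50), tolerance = 1e-6)
})

test_that("IVW is the zero-intercept WLS slope and Egger-through-origin reproduces it", {
  set.seed(17)
  k <- 12
  a <- mk_assoc(runif(k, 0.05, 0.3), runif(k, 0.01, 0.05),
                rnorm(k, 0.1, 0.1), runif(k, 0.05, 0.2))
  ivw <- glance(mr_ivw(a))$beta
  wls <- unname(coef(lm(a$beta_outcome ~ 0 + a$beta_exposure,
                        weights = 1 / a$se_outcome^2))[1])
  expect_equal(ivw, wls, tolerance = 1e-9)
  egger0 <- glance(mr_egger(a, intercept = FALSE))$beta
  expect_equal(egger0, ivw, tolerance = 1e-9)
})

test_that("Egger recovers an exact affine relation and orients exposure-positive", {
  bexp <- c(0.1, 0.2, 0.3, 0.4)
  bout <- 0.1 + 0.5 * bexp
  a <- mk_assoc(bexp, rep(0.01, 4), bout, rep(0.1, 4))
  eg <- tidy(suppressWarnings(mr_egger(a)))
  expect_equal(eg$estimate[eg$term == "pleiotropy_intercept"], 0.1,
               tolerance = 1e-9)
  expect_equal(eg$estimate[eg$term == "causal_effect"], 0.5,
               tolerance = 1e-9)

  # flipping an allele's sign on both legs leaves the fit unchanged
  a2 <- a
  a2$beta_exposure[2] <- -a2$beta_exposure[2]
  a2$beta_outcome[2] <- -a2$beta_outcome[2]
  eg2 <- tidy(suppressWarnings(mr_egger(a2)))
  expect_equal(eg2$estimate, eg$estimate, tolerance = 1e-9)

  expect_error(mr_egger(a[1:2, ]), class = "grsmr_estimation_error")
})

test_that("weighted median interpolates the cumulative-weight formula", {
  # equal weights, ratios 0.1 / 0.2 / 0.9: midpoint lands on 0.2
  a <- mk_assoc(c(1, 1, 1), c(0, 0, 0), c(0.1, 0.2, 0.9), c(1, 1, 1))
  wm <- glance(mr_weighted_median(a, n_boot = 50, seed = 1))
  expect_equal(wm$beta, 0.2, tolerance = 1e-12)

  # a variant with > 50% of the weight pins the estimate near its ratio
  a2 <- mk_assoc(c(1, 1, 1), c(0, 0, 0), c(0.1, 0.8, 0.9),
                 c(0.05, 1, 1))
  wm2 <- glance(mr_weighted_median(a2, n_boot = 50, seed = 1))
  expect_lt(abs(wm2$beta - 0.1), 0.1)

  expect_error(mr_weighted_median(a[1:2, ], n_boot = 10, seed = 1),
               class = "grsmr_estimation_error")
  expect_error(mr_weighted_median(a, n_boot = 10),
               class = "grsmr_config_error")
})

test_that("weighted-median bootstrap SE is reproducible under a fixed seed", {
  set.seed(18)
  a <- mk_assoc(runif(6, 0.1, 0.3), runif(6, 0.02, 0.05),
                rnorm(6, 0.15, 0.05), runif(6, 0.05, 0.1))
  s1 <- glance(mr_weighted_median(a, n_boot = 200, seed = 42))$se
  s2 <- glance(mr_weighted_median(a, n_boot = 200, seed = 42))$se
  expect_identical(s1, s2)
})

test_that("two-stage score estimate divides the legs and respects identities", {
  exp_leg <- tibble::tibble(name = "grs", beta_apn = 0.09, se = 0.015,
                            n_snps = 5)
  out_leg <- tibble::tibble(name = "grs", beta = 0.0549, se = 0.06)
  ts <- glance(grs_two_stage(exp_leg, out_leg))
  expect_equal(ts$beta, 0.61, tolerance = 1e-12)
  expect_equal(ts$se, 0.06 / 0.09, tolerance = 1e-12)

  exp1 <- tibble::tibble(name = "g", beta_apn = 1, se = 0.01, n_snps = 1)
  expect_equal(glance(grs_two_stage(exp1, out_leg))$beta, out_leg$beta)
  expect_error(grs_two_stage(dplyr::mutate(exp_leg, beta_apn = 0), out_leg),
               class = "grsmr_estimation_error")
})

test_that("every estimator is invariant to flipping all effect alleles", {
  res <- sim_assoc(19, n = 800, m = 6, r2 = 0.05)
  g <- res$sim$genotypes
  gf <- flip_alleles(g, g$snps$snp_id)
  af <- snp_assoc(gf, res$sim$phenotypes)
  expect_equal(af$beta_exposure, -res$assoc$beta_exposure,
               tolerance = 1e-6)
  expect_equal(glance(mr_ivw(af))$beta, glance(mr_ivw(res$assoc))$beta,
               tolerance = 1e-6)
  expect_equal(tidy(mr_egger(af))$estimate,
               tidy(mr_egger(res$assoc))$estimate, tolerance = 1e-6)
  expect_equal(glance(mr_weighted_median(af, n_boot = 50, seed = 5))$beta,
               glance(mr_weighted_median(res$assoc, n_boot = 50,
                                         seed = 5))$beta,
               tolerance = 1e-6)
})

test_that("confounder scan flags a trait equal to the score and rejects unknown traits", {
  set.seed(20)
  x <- rbinom(300, 2, 0.3)
  g <- toy_geno(matrix(x, ncol = 1), ids = "rs1")
  grs <- build_grs(g, "rs1")
  ph <- toy_pheno(rnorm(300),
                  extra = tibble::tibble(copy = as.numeric(scale(x)),
                                         noise = rnorm(300)))
  sc <- confounder_scan(grs, ph, traits = c("copy", "noise"))
  expect_lt(sc$p[sc$trait == "copy"], 1e-12)
  expect_gt(sc$p[sc$trait == "noise"], 1e-4)
  expect_error(confounder_scan(grs, ph, traits = "nonexistent"),
               class = "grsmr_validation_error")
})

test_that("power formula obeys its limits and is monotone", {
  expect_equal(mr_power(1251, 0.052, 1, 0.35), pnorm(-qnorm(0.975)),
               tolerance = 1e-12)
  expect_gt(mr_power(1e7, 0.05, 1.2, 0.35), 0.999)
  p1 <- mr_power(500, 0.05, 1.84, 0.35)
  p2 <- mr_power(1251, 0.05, 1.84, 0.35)
  p3 <- mr_power(1251, 0.05, 2.5, 0.35)
  expect_lt(p1, p2)
  expect_lt(p2, p3)
})

test_that("power formula roughly matches a full-pipeline rejection rate", {
  # The formula ignores logistic non-collapsibility, so the empirical
  # two-stage rejection rate runs a few points below it; the tolerance
  # covers that documented gap plus Monte-Carlo error at 400 replicates.
  formula_pow <- mr_power(1251, 0.052, 1.84, 438 / 1251)
  rej <- vapply(1:400, function(s) {
    cfg <- sim_config(n_subjects = 1251, n_snps = 5, target_r2 = 0.052,
                      confounder_exposure = 0, causal_beta = log(1.84),
                      confounder_outcome = 0,
                      baseline_prevalence = 438 / 1251, seed = s)
    sim <- simulate_cohort(cfg)
    grs <- build_grs(sim$genotypes, sim$genotypes$snps$snp_id,
                     sim$truth$snp_effects)
    ex <- grs_exposure_assoc(grs, sim$phenotypes)
    out <- grs_outcome_assoc(grs, sim$phenotypes)
    glance(grs_two_stage(ex, out))$p.value < 0.05
  }, logical(1))
  expect_lt(abs(mean(rej) - formula_pow), 0.13)
})

test_that("tidy, glance and autoplot expose the fit consistently", {
  res <- sim_assoc(23, n = 500, m = 5, r2 = 0.05)
  fit <- mr_ivw(res$assoc)
  td <- tidy(fit)
  expect_named(td, c("method", "term", "estimate", "std.error",
                     "statistic", "p.value", "conf.low", "conf.high",
                     "or", "n_snps"))
  gl <- glance(fit)
  expect_equal(gl$beta, td$estimate)
  expect_false(is.na(gl$Q))
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
  expect_s3_class(plot_mr_forest(mr_all(res$assoc, n_boot = 20, seed = 2)),
                  "ggplot")
})
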