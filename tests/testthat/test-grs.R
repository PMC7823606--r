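test_that("pruning keeps the top-ranked variant of a perfectly correlated pair", {
  set.seed(12)
  x <- rbinom(50, 2, 0.4)
  g <- toy_geno(cbind(x, x), ids = c("rsA", "rsB"))
  ea <- tibble::tibble(snp_id = c("rsA", "rsB"), r2 = c(0.05, 0.02))
  expect_equal(ld_prune(g, ea), "rsA")
  ea2 <- tibble::tibble(snp_id = c("rsA", "rsB"), r2 = c(0.01, 0.06))
  expect_equal(ld_prune(g, ea2), "rsB")
})

test_that("mutually uncorrelated variants all survive pruning", {
  cfg <- sim_config(n_subjects = 3000, n_snps = 6, target_r2 = 0.05,
                    seed = 13)
  sim <- simulate_cohort(cfg)
  ea <- snp_exposure_assoc(sim$genotypes, sim$phenotypes)
  kept <- ld_prune(sim$genotypes, ea)
  expect_setequal(kept, sim$genotypes$snps$snp_id)
})

test_that("two-block fixture prunes to the per-block top variants, matching exhaustive search", {
  cfg <- sim_config(n_subjects = 4000, n_snps = 6, target_r2 = 0.06,
                    ld_blocks = list(list(size = 3, rho = 0.85),
                                     list(size = 3, rho = 0.85)),
                    seed = 14)
  sim <- simulate_cohort(cfg)
  ea <- snp_exposure_assoc(sim$genotypes, sim$phenotypes)
  ld <- cor(sim$genotypes$dosages)^2
  expect_true(all(ld[1:3, 1:3][upper.tri(ld[1:3, 1:3])] > 0.05))

  kept <- ld_prune(sim$genotypes, ea)
  expect_length(kept, 2)
  top1 <- ea$snp_id[which.max(ea$r2 * (seq_len(6) <= 3))]
  top2 <- ea$snp_id[which.max(ea$r2 * (seq_len(6) > 3))]
  expect_setequal(kept, c(top1, top2))
  expect_equal(sort(kept),
               prune_oracle(sim$genotypes, ea$r2, 0.05))
})

test_that("pruned sets are maximal", {
  cfg <- sim_config(n_subjects = 1500, n_snps = 9, target_r2 = 0.05,
                    ld_blocks = list(list(size = 3, rho = 0.5),
                                     list(size = 3, rho = 0.3),
                                     list(size = 3, rho = 0)),
                    seed = 15)
  sim <- simulate_cohort(cfg)
  ea <- snp_exposure_assoc(sim$genotypes, sim$phenotypes)
  kept <- ld_prune(sim$genotypes, ea)
  removed <- setdiff(sim$genotypes$snps$snp_id, kept)
  ld <- cor(sim$genotypes$dosages)^2
  for (r in removed) {
    expect_true(any(ld[r, kept] >= 0.05))
  }
})

test_that("risk scores match hand computation, are scale invariant and order invariant", {
  d <- matrix(c(0, 1, 2, 1,
                2, 0, 1, 1,
                1, 1, 0, 2), nrow = 4)
  g <- toy_geno(d, ids = c("rs1", "rs2", "rs3"))
  w <- c(0.5, -0.2, 1)
  grs <- build_grs(g, c("rs1", "rs2", "rs3"), w)
  hand <- d %*% w
  expect_equal(grs$score_raw, drop(hand))
  expect_equal(mean(grs$score_z), 0, tolerance = 1e-10)
  expect_equal(var(grs$score_z), 1, tolerance = 1e-10)

  grs2 <- build_grs(g, c("rs1", "rs2", "rs3"), 2 * w)
  expect_equal(grs2$score_z, grs$score_z, tolerance = 1e-12)

  grs3 <- build_grs(g, c("rs3", "rs1", "rs2"),
                    tibble::tibble(snp_id = c("rs1", "rs2", "rs3"),
                                   weight = w))
  expect_equal(sort(grs3$score_raw), sort(grs$score_raw))
  expect_equal(grs3$score_z, grs$score_z, tolerance = 1e-12)

  expect_error(build_grs(g, c("rs1", "rs99")), "rs99")
})

test_that("single-variant unweighted score is the standardized dosage", {
  x <- c(0, 1, 2, 1, 0, 2, 1)
  g <- toy_geno(matrix(x, ncol = 1), ids = "rs1")
  grs <- build_grs(g, "rs1")
  expect_equal(grs$score_z, as.numeric(scale(x)))
})

test_that("score-exposure association is exact on identical series and r2 equals cor^2", {
  set.seed(16)
  x <- rbinom(60, 2, 0.3) + rbinom(60, 2, 0.4)
  g <- toy_geno(matrix(x %% 3, ncol = 1), ids = "rs1")
  grs <- build_grs(g, "rs1")
  ph <- toy_pheno(grs$score_z)
  ex <- grs_exposure_assoc(grs, ph)
  expect_equal(ex$beta_apn, 1, tolerance = 1e-9)
  expect_equal(ex$r2, 1, tolerance = 1e-9)

  ph2 <- toy_pheno(rnorm(60))
  ex2 <- grs_exposure_assoc(grs, ph2)
  expect_equal(ex2$r2, cor(grs$score_z, ph2$apn_z)^2, tolerance = 1e-9)
  expect_equal(ex2$f_stat, (ex2$beta_apn / ex2$se)^2, tolerance = 1e-9)
  expect_equal(ex2$ci95_lo, ex2$beta_apn - 1.959964 * ex2$se,
               tolerance = 1e-9)
})

test_that("true-weight scores recover the simulated explained variance", {
  r2hat <- vapply(1:60, function(s) {
    cfg <- sim_config(n_subjects = 1251, n_snps = 10, target_r2 = 0.032,
                      confounder_exposure = 0, causal_beta = 0, seed = s)
    sim <- simulate_cohort(cfg)
    grs <- build_grs(sim$genotypes, sim$genotypes$snps$snp_id,
                     sim$truth$snp_effects)
    grs_exposure_assoc(grs, sim$phenotypes)$r2
  }, numeric(1))
  expect_lt(abs(mean(r2hat) - 0.032), 0.005)
})

test_that("score-level F matches the closed-form relation at the study scale", {
  # (n-2) R2 / (1-R2) at R2 = 0.052, n = 1251: about 68.5
  f <- vapply(1:40, function(s) {
    cfg <- sim_config(n_subjects = 1251, n_snps = 10, target_r2 = 0.052,
                      confounder_exposure = 0, causal_beta = 0, seed = s)
    sim <- simulate_cohort(cfg)
    grs <- build_grs(sim$genotypes, sim$genotypes$snps$snp_id,
                     sim$truth$snp_effects)
    grs_exposure_assoc(grs, sim$phenotypes)$f_stat
  }, numeric(1))
  expect_lt(abs(mean(f) - 1249 * 0.052 / 0.948), 8)
})

test_that("score-outcome association approximates the attenuation identity", {
  # logit slope per SD score ~ beta_c * sqrt(R2) under the
  # linear-logistic approximation (0.139 at beta_c 0.61, R2 0.052),
  # slightly attenuated by non-collapsibility
  b <- vapply(1:60, function(s) {
    cfg <- sim_config(n_subjects = 1251, n_snps = 10, target_r2 = 0.052,
                      confounder_exposure = 0, causal_beta = 0.61,
                      confounder_outcome = 0, seed = s)
    sim <- simulate_cohort(cfg)
    grs <- build_grs(sim$genotypes, sim$genotypes$snps$snp_id,
                     sim$truth$snp_effects)
    grs_outcome_assoc(grs, sim$phenotypes)$beta
  }, numeric(1))
  expect_lt(abs(mean(b) - 0.61 * sqrt(0.052)), 0.02)
})

test_that("degenerate scores and single-class outcomes are refused", {
  g <- toy_geno(matrix(rep(1, 10), ncol = 1), ids = "rs1")
  expect_error(build_grs(g, "rs1"), class = "grsmr_validation_error")

  x <- rbinom(20, 2, 0.4)
  g2 <- toy_geno(matrix(x, ncol = 1), ids = "rs1")
  grs <- build_grs(g2, "rs1")
  ph <- toy_pheno(rnorm(20), dr = rep(1L, 20))
  expect_error(grs_outcome_assoc(grs, ph), class = "grsmr_validation_error")
})
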