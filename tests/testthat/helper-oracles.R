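# Shared helpers: small constructors and independent oracles used across
# the suite. Oracles are deliberately naive implementations kept separate
# from the package code paths they check.

# Minimal genotype container from a dosage matrix.
toy_geno <- function(d, maf = NULL, info = NULL, ids = NULL) {
  d <- as.matrix(d)
  m <- ncol(d)
  snps <- tibble::tibble(
    snp_id = ids %||% sprintf("rs%03d", seq_len(m)),
    effect_allele = "A", other_allele = "G")
  if (!is.null(maf)) snps$maf <- maf
  if (!is.null(info)) snps$info <- info
  geno_matrix(d, snps, sprintf("s%03d", seq_len(nrow(d))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Phenotype table whose apn_z equals a given standardized vector exactly.
toy_pheno <- function(z, dr = NULL, n = length(z), extra = NULL) {
  z <- (z - mean(z)) / stats::sd(z)
  ph <- tibble::tibble(subject_id = sprintf("s%03d", seq_len(n)),
                       apn_raw = exp(z), dr = dr %||% rep(0L, n))
  if (!is.null(extra)) ph <- dplyr::bind_cols(ph, extra)
  grsmr::standardize_phenotypes(ph)
}

# Brute-force Newton-Raphson logistic regression (intercept + slope),
# written from the log-likelihood derivatives directly.
newton_logistic <- function(x, y, tol = 1e-12, maxit = 100) {
  X <- cbind(1, x)
  b <- c(0, 0)
  for (i in seq_len(maxit)) {
    mu <- 1 / (1 + exp(-drop(X %*% b)))
    score <- drop(crossprod(X, y - mu))
    H <- crossprod(X, X * (mu * (1 - mu)))
    step <- solve(H, score)
    b <- b + step
    if (sqrt(sum(score^2)) < tol) break
  }
  mu <- 1 / (1 + exp(-drop(X %*% b)))
  V <- solve(crossprod(X, X * (mu * (1 - mu))))
  list(beta = unname(b), se = unname(sqrt(diag(V))))
}

# Exhaustive-search pruning oracle: among all subsets whose pairwise
# dosage r^2 stays below the threshold, pick the one maximizing summed
# exposure r2 (ties by lexicographic id order). Only usable for tiny m.
prune_oracle <- function(g, r2_rank, r2_threshold) {
  m <- ncol(g$dosages)
  ld <- suppressWarnings(stats::cor(g$dosages))^2
  ids <- g$snps$snp_id
  best <- character(0); best_score <- -Inf
  for (mask in 0:(2^m - 1)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(m) - 1)) > 0)
    if (length(sel) > 1) {
      sub <- ld[sel, sel]
      if (any(sub[upper.tri(sub)] >= r2_threshold)) next
    }
    sc <- sum(r2_rank[sel])
    if (sc > best_score + 1e-12) {
      best_score <- sc; best <- ids[sel]
    }
  }
  sort(best)
}

# Cohort + per-variant association table in one call (used by the
# simulation-based checks).
sim_assoc <- function(seed, n = 1251, m = 20, r2 = 0.05, beta_c = 0.61,
                      gamma = 0, delta = 0, pleiotropy = "none",
                      shares = NULL) {
  cfg <- sim_config(n_subjects = n, n_snps = m, target_r2 = r2,
                    confounder_exposure = gamma, causal_beta = beta_c,
                    confounder_outcome = delta, pleiotropy = pleiotropy,
                    seed = seed)
  if (!is.null(shares)) cfg$r2_shares <- shares
  sim <- simulate_cohort(cfg)
  list(sim = sim, assoc = snp_assoc(sim$genotypes, sim$phenotypes))
}

# Write a small single-sample-block VCF from genotype strings.
write_toy_vcf <- function(path, records, samples = c("S1", "S2", "S3")) {
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(hdr, records), path)
  path
}
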