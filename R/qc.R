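#' Variant quality-control filter
#'
#' Excludes variants with minor allele frequency strictly below `maf_min`
#' or, among those passing the frequency filter, an imputation INFO score
#' strictly below `info_min`. Variants without an INFO score pass the
#' INFO test (hard-typed variants). Exclusion is strict `<`, so a variant
#' sitting exactly at a threshold is kept. A variant failing both filters
#' is counted once, as a frequency failure.
#'
#' @param g A [geno_matrix()].
#' @param maf_min Minimum minor allele frequency (default 0.005, i.e.
#'   0.5%).
#' @param info_min Minimum imputation INFO score (default 0.4).
#' @return List with `genotypes` (filtered [geno_matrix()], possibly with
#'   zero variants) and `report`, a `qc_report`: a tibble of per-variant
#'   decisions with counts (`n_input`, `n_fail_maf`, `n_fail_info`,
#'   `n_pass`) as attributes.
#' @export
variant_qc <- function(g, maf_min = 0.005, info_min = 0.4) {
  snps <- g$snps
  fail_maf <- snps$maf < maf_min
  fail_info <- !fail_maf & !is.na(snps$info) & snps$info < info_min
  pass <- !fail_maf & !fail_info

  report <- tibble(
    snp_id = snps$snp_id, maf = snps$maf, info = snps$info,
    decision = dplyr::case_when(fail_maf ~ "fail_maf",
                                fail_info ~ "fail_info",
                                TRUE ~ "pass"))
  attr(report, "counts") <- c(n_input = nrow(snps),
                              n_fail_maf = sum(fail_maf),
                              n_fail_info = sum(fail_info),
                              n_pass = sum(pass))
  attr(report, "thresholds") <- c(maf_min = maf_min, info_min = info_min)
  class(report) <- c("qc_report", class(report))

  kept <- snps$snp_id[pass]
  g2 <- if (length(kept)) {
    select_snps(g, kept)
  } else {
    warn("variant_qc: no variants pass the filters.")
    g_empty <- g
    g_empty$dosages <- g$dosages[, 0, drop = FALSE]
    g_empty$snps <- g$snps[0, ]
    g_empty
  }
  list(genotypes = g2, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cts <- attr(x, "counts")
  thr <- attr(x, "thresholds")
  cat(sprintf(
    "<qc_report> %d variants in: %d pass, %d fail MAF < %g, %d fail INFO < %g\n",
    cts["n_input"], cts["n_pass"], cts["n_fail_maf"], thr["maf_min"],
    cts["n_fail_info"], thr["info_min"]))
  NextMethod()
}
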