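#' Derive an external-style weight table from simulation ground truth
#'
#' Packages the generator's realized per-allele exposure effects as if
#' they had been reported by an external discovery study of size
#' `n_external`: the source p-value is the two-sided normal p implied by
#' the effect and its external-study standard error
#' `1 / sqrt(n_external * 2 p (1 - p))`.
#'
#' @param sim Output of [simulate_cohort()].
#' @param n_external Nominal external discovery sample size.
#' @return Weight table tibble (`snp_id`, `effect_allele`, `weight`,
#'   `source_p`, `source_tier`).
#' @export
sim_weight_table <- function(sim, n_external = 35000) {
  p <- sim$truth$eaf
  a <- sim$truth$snp_effects
  se_ext <- 1 / sqrt(n_external * 2 * p * (1 - p))
  source_p <- pmax(2 * pnorm(-abs(a) / se_ext), 1e-300)
  tibble(snp_id = sim$genotypes$snps$snp_id,
         effect_allele = sim$genotypes$snps$effect_allele,
         weight = a,
         source_p = source_p,
         source_tier = ifelse(source_p < 5e-8, "gwas_genomewide", "other"))
}

pipeline_defaults <- function() {
  list(maf_min = 0.005, info_min = 0.4, r2_threshold = 0.05,
       gwas_p = 5e-8, internal_p = 0.05, grs_weighting = "weighted",
       n_boot = 1000, genotype_format = "auto")
}

#' Run the full causal-analysis pipeline
#'
#' Drives every stage from a flat configuration: data input (files or
#' simulation), variant quality control, per-variant exposure/outcome
#' associations, linkage-disequilibrium pruning, the three score
#' definitions, causal estimation (inverse-variance-weighted, MR-Egger,
#' weighted-median per variant set; two-stage per score), a confounder
#' scan, and the report. Every filter decision is logged with counts,
#' and a fixed seed makes the output files byte-identical across runs.
#'
#' Recognized configuration keys: `seed` (required); either `simulate:`
#' (a mapping of [sim_config()] arguments, or `true` for defaults) or
#' `genotypes`/`phenotypes` paths (plus optional `weights`,
#' `genotype_format`); thresholds `maf_min` (0.005), `info_min` (0.4),
#' `r2_threshold` (0.05), `gwas_p` (5e-8), `internal_p` (0.05);
#' `grs_weighting` (`weighted`/`unweighted`); `n_boot` (1000).
#'
#' @param config Path to a YAML configuration or an equivalent named
#'   list.
#' @param out_dir Output directory (created if needed).
#' @param stages Stages to write outputs for; later stages imply the
#'   computations of earlier ones.
#' @return Invisibly, a list with the computed tables and file paths.
#' @export
run_pipeline <- function(config, out_dir,
                         stages = c("simulate", "assoc", "grs", "mr",
                                    "report")) {
  if (is.character(config)) config <- read_config(config)
  stages <- match.arg(stages, several.ok = TRUE)
  cfg <- utils::modifyList(pipeline_defaults(), config)

  if (is.null(cfg$seed)) {
    abort("config key `seed` is required.", class = "grsmr_config_error")
  }
  has_files <- !is.null(cfg$genotypes) && !is.null(cfg$phenotypes)
  if (is.null(cfg$simulate) && !has_files) {
    abort("config must provide either `simulate` or `genotypes` + `phenotypes`.",
          class = "grsmr_config_error")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(
    sprintf("grsmr pipeline; seed=%d", as.integer(cfg$seed)),
    sprintf("thresholds: maf_min=%s info_min=%s r2_threshold=%s gwas_p=%s internal_p=%s",
            format(cfg$maf_min), format(cfg$info_min),
            format(cfg$r2_threshold), format(cfg$gwas_p),
            format(cfg$internal_p)))
  paths <- list()
  set.seed(cfg$seed)

  # ---- input stage -------------------------------------------------
  weights <- NULL
  if (!is.null(cfg$simulate)) {
    sim_args <- if (isTRUE(cfg$simulate)) list() else cfg$simulate
    sim_args$seed <- cfg$seed
    scfg <- do.call(sim_config, sim_args)
    sim <- simulate_cohort(scfg)
    g <- sim$genotypes
    ph <- sim$phenotypes
    weights <- sim_weight_table(sim)
    log_lines <- c(log_lines,
                   sprintf("simulated cohort: n=%d, m=%d, prevalence=%.3f",
                           n_subjects(g), n_snps(g), mean(ph$dr)))
    if ("simulate" %in% stages) {
      paths$genotypes <- file.path(out_dir, "simulated_genotypes.tsv")
      write_genotypes(g, paths$genotypes)
      paths$phenotypes <- file.path(out_dir, "simulated_phenotypes.csv")
      ph_out <- dplyr::rename(ph, apn = "apn_raw")
      readr::write_csv(dplyr::select(ph_out, -"apn_z"), paths$phenotypes,
                       progress = FALSE)
      paths$weights <- file.path(out_dir, "simulated_weights.tsv")
      readr::write_tsv(weights, paths$weights, progress = FALSE)
    }
  } else {
    g <- read_genotypes(cfg$genotypes, format = cfg$genotype_format)
    ph <- read_phenotypes(cfg$phenotypes)
    if (!is.null(cfg$weights)) weights <- read_weights(cfg$weights)
    log_lines <- c(log_lines,
                   sprintf("read cohort: n=%d, m=%d", n_subjects(g),
                           n_snps(g)))
  }

  # ---- harmonization + QC ------------------------------------------
  if (!is.null(weights)) {
    h <- harmonize_weights(g, weights)
    g <- h$genotypes
    weights <- h$weights
    log_lines <- c(log_lines,
                   sprintf("harmonization: %d flipped, %d dropped",
                           length(h$flipped), length(h$dropped)))
  }
  qc <- variant_qc(g, maf_min = cfg$maf_min, info_min = cfg$info_min)
  cts <- attr(qc$report, "counts")
  log_lines <- c(log_lines,
                 sprintf("variant QC: %d in, %d fail MAF, %d fail INFO, %d pass",
                         cts["n_input"], cts["n_fail_maf"],
                         cts["n_fail_info"], cts["n_pass"]))
  g <- qc$genotypes

  # ---- associations -------------------------------------------------
  assoc <- snp_assoc(g, ph)
  assoc <- instrument_strength(assoc)
  log_lines <- c(log_lines,
                 sprintf("associations: %d variants, %d strong (F > 10)",
                         nrow(assoc), sum(assoc$is_strong, na.rm = TRUE)))
  if (any(c("assoc", "grs", "mr", "report") %in% stages)) {
    paths$qc_report <- file.path(out_dir, "qc_report.tsv")
    readr::write_tsv(as_tibble(qc$report), paths$qc_report, progress = FALSE)
    paths$snp_assoc <- file.path(out_dir, "snp_assoc.tsv")
    readr::write_tsv(assoc, paths$snp_assoc, progress = FALSE)
  }
  if (all(stages %in% c("simulate", "assoc"))) {
    return(finish_pipeline(out_dir, log_lines, paths,
                           list(assoc = assoc, qc = qc$report)))
  }

  # ---- pruning + scores ---------------------------------------------
  kept <- ld_prune(g, assoc, r2_threshold = cfg$r2_threshold)
  log_lines <- c(log_lines,
                 sprintf("LD pruning (r2 < %s): kept %d of %d",
                         format(cfg$r2_threshold), length(kept),
                         nrow(assoc)))
  assoc_kept <- assoc[match(kept, assoc$snp_id), ]
  defs <- grs_definitions(assoc_kept, weights, gwas_p = cfg$gwas_p,
                          internal_p = cfg$internal_p)
  defs <- defs[vapply(defs, length, integer(1)) > 0]

  use_weights <- identical(cfg$grs_weighting, "weighted") &&
    !is.null(weights)
  grs_list <- imap(defs, function(ids, nm) {
    w <- if (use_weights) weights[match(ids, weights$snp_id), ] else NULL
    build_grs(g, ids, weights = w, name = nm)
  })
  diag_tbl <- imap(grs_list, function(sc, nm) {
    ex <- grs_exposure_assoc(sc, ph)
    out <- grs_outcome_assoc(sc, ph)
    bind_cols(ex, dplyr::select(out, beta_outcome = "beta",
                                se_outcome = "se", p_outcome = "p"))
  }) |> purrr::list_rbind()
  log_lines <- c(log_lines,
                 paste0("score definitions: ",
                        paste(sprintf("%s (%d variants)", names(defs),
                                      vapply(defs, length, integer(1))),
                              collapse = ", ")))
  if (any(c("grs", "mr", "report") %in% stages)) {
    scores_wide <- tibble(subject_id = g$subject_ids)
    for (nm in names(grs_list)) scores_wide[[nm]] <- grs_list[[nm]]$score_z
    paths$grs_scores <- file.path(out_dir, "grs_scores.tsv")
    readr::write_tsv(scores_wide, paths$grs_scores, progress = FALSE)
    paths$grs_diagnostics <- file.path(out_dir, "grs_diagnostics.tsv")
    readr::write_tsv(diag_tbl, paths$grs_diagnostics, progress = FALSE)
  }

  # ---- causal estimation --------------------------------------------
  est_rows <- imap(defs, function(ids, nm) {
    a <- assoc[match(ids, assoc$snp_id), ]
    mr_all(a, n_boot = cfg$n_boot, seed = cfg$seed + 1000L,
           label = sprintf("%d SNPs (%s)", length(ids), nm))
  })
  two_stage_rows <- imap(grs_list, function(sc, nm) {
    ex <- grs_exposure_assoc(sc, ph)
    out <- grs_outcome_assoc(sc, ph)
    ts <- tidy_est(grs_two_stage(ex, out))
    ts$instruments <- paste0("GRS_", nm)
    dplyr::relocate(ts, "instruments")
  })
  mr_tbl <- purrr::list_rbind(c(est_rows, two_stage_rows))

  scan_tbl <- imap(grs_list, function(sc, nm) {
    traits <- intersect(c("sex", "sbp", "dbp", "glucose", "hba1c", "tg",
                          "hdl", "ldl", "bmi"), names(ph))
    s <- confounder_scan(sc, ph, traits)
    s$grs <- nm
    dplyr::relocate(s, "grs")
  }) |> purrr::list_rbind()
  log_lines <- c(log_lines,
                 sprintf("confounder scan: %d of %d trait tests with p < 0.05",
                         sum(scan_tbl$p < 0.05, na.rm = TRUE),
                         nrow(scan_tbl)))

  if (any(c("mr", "report") %in% stages)) {
    paths$mr_estimates <- file.path(out_dir, "mr_estimates.tsv")
    readr::write_tsv(mr_tbl, paths$mr_estimates, progress = FALSE)
    paths$confounder_scan <- file.path(out_dir, "confounder_scan.tsv")
    readr::write_tsv(scan_tbl, paths$confounder_scan, progress = FALSE)
  }
  if ("report" %in% stages) {
    paths$report <- file.path(out_dir, "mr_report.txt")
    writeLines(format_report(mr_tbl), paths$report)
  }

  finish_pipeline(out_dir, log_lines, paths,
                  list(assoc = assoc, qc = qc$report, kept = kept,
                       definitions = defs, grs = grs_list,
                       grs_diagnostics = diag_tbl, estimates = mr_tbl,
                       confounder_scan = scan_tbl))
}

finish_pipeline <- function(out_dir, log_lines, paths, results) {
  paths$log <- file.path(out_dir, "run_log.txt")
  writeLines(log_lines, paths$log)
  invisible(c(results, list(paths = paths, log = log_lines)))
}

# Human-readable estimate table, 2 decimal places (the machine TSV keeps
# full precision).
format_report <- function(mr_tbl) {
  fmt <- function(x) sprintf("%.2f", x)
  hdr <- sprintf("%-28s %-18s %-22s %8s %14s %14s %8s",
                 "instruments", "method", "term", "beta",
                 "95% CI", "90% CI", "p")
  rows <- vapply(seq_len(nrow(mr_tbl)), function(i) {
    r <- mr_tbl[i, ]
    sprintf("%-28s %-18s %-22s %8s %14s %14s %8.3f",
            r$instruments, r$method, r$term, fmt(r$beta),
            paste0(fmt(r$ci95_lo), "-", fmt(r$ci95_hi)),
            paste0(fmt(r$ci90_lo), "-", fmt(r$ci90_hi)), r$p)
  }, character(1))
  c("Causal estimates: log-OR of outcome per SD of genetically determined log-exposure",
    hdr, rows)
}
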