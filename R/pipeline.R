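# End-to-end orchestration used by the analysis/ drivers and the acceptance
# script: simulate -> preprocess -> free 25OHD -> genetics QC -> observational
# battery -> MR battery.

#' Run the full pipeline on a simulated (or supplied) cohort
#'
#' Executes every stage in order and returns a bundle of results; when
#' `out_dir` is given, each table is also written as TSV plus a single JSON
#' bundle with the unrounded numbers and a small run manifest.
#'
#' Stage order: exclusion cascade; log transformation of the skewed panel;
#' single-pass 3.5-SD trimming (on the log scale for log-transformed
#' variables); free/bioavailable 25OHD; SNP QC and LD proxy selection;
#' per-SNP exposure associations for the independent non-instrument SNPs
#' (FDR family of its own); instrument-validity screen; observational
#' battery; quartile-group tests; instrument-strength diagnostics; MR
#' battery.
#'
#' @param config a [default_config()] list.
#' @param sim optional pre-built list with `cohort` and `genotypes` (rows
#'   aligned); when `NULL`, [simulate_cohort()] is run.
#' @param out_dir optional output directory.
#' @return list of class `"vitdmr_run"` with all stage outputs.
#' @export
run_pipeline <- function(config = default_config(), sim = NULL,
                         out_dir = NULL) {
  if (is.null(sim)) sim <- simulate_cohort(config)
  cohort0 <- sim$cohort
  G0 <- sim$genotypes

  casc <- apply_exclusion_cascade(cohort0)
  cohort <- casc$cohort
  G <- G0[match(cohort$subject_id, rownames(G0)), , drop = FALSE]

  cohort <- log_transform_skewed(cohort)
  trim <- trim_cohort(cohort, z = config$thresholds$trim_z)
  cohort <- trim$cohort
  cohort <- add_free_d_columns(cohort, k = config$binding)

  qc <- snp_qc_table(G, hwe_alpha = config$thresholds$hwe_alpha,
                     min_rate = config$thresholds$min_genotyping_rate,
                     snp_info = config$snps)
  iv_ids <- config$snps$snp[config$snps$instrument]
  other <- setdiff(qc$snp[qc$qc_pass], iv_ids)
  proxies <- select_proxies(G, iv_ids, other,
                            r2_threshold = config$thresholds$proxy_r2)
  independent <- setdiff(other, proxies$proxy)

  snp_assoc <- do.call(rbind, lapply(independent, function(s) {
    r <- snp_exposure_assoc(G[, s], cohort)
    data.frame(snp = s, beta = r$beta, se = r$se, ci_low = r$ci_low,
               ci_high = r$ci_high, p = r$p, n_used = r$n_used,
               stringsAsFactors = FALSE)
  }))
  if (!is.null(snp_assoc) && nrow(snp_assoc)) {
    snp_assoc$p_fdr <- fdr_bh(snp_assoc$p)
  }

  screen <- iv_validity_screen(G, cohort, iv_ids,
                               alpha = config$thresholds$alpha)

  obs <- observational_battery(cohort)
  groups <- quartile_groups(cohort$total_25ohd)
  quartile_tests <- do.call(rbind, lapply(
    c("bmd_l1l4", "bmd_fn", "bmd_th", "pth", "p1np", "beta_ctx"),
    function(y) {
      gt <- group_test(cohort[[y]], groups)
      data.frame(outcome = y, statistic = gt$statistic, p = gt$p,
                 method = gt$method, stringsAsFactors = FALSE)
    }))

  strength <- instrument_strength_table(cohort, G, config)
  battery <- run_mr_battery(cohort, G, config)

  bundle <- structure(list(
    config = config,
    exclusion_report = casc$report,
    n_trimmed = trim$n_trimmed,
    table1 = summarize_cohort(
      cohort, c("age", "height", "weight", "bmi", "total_25ohd", "dbp",
                "albumin", "bioavailable_25ohd", "free_25ohd", "pth",
                "p1np", "beta_ctx", "alp", "ca", "p", "cr", "bun",
                "bmd_l1l4", "bmd_fn", "bmd_th")),
    snp_qc = qc, proxies = proxies, snp_assoc = snp_assoc,
    validity_screen = screen,
    observational = obs, quartile_tests = quartile_tests,
    strength = strength, mr = battery,
    cohort = cohort, genotypes = G
  ), class = "vitdmr_run")

  if (!is.null(out_dir)) write_run(bundle, out_dir)
  bundle
}

#' Write a pipeline run to disk
#'
#' Rendered TSV tables plus one JSON bundle with the unrounded numbers and
#' a run manifest (seed, package version, n at each stage).
#'
#' @param run a `vitdmr_run` from [run_pipeline()].
#' @param out_dir directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(render_table1(run$table1), file.path(out_dir, "table1_descriptives.tsv"))
  write_tsv(run$snp_qc, file.path(out_dir, "table3_snp_qc.tsv"))
  if (!is.null(run$snp_assoc) && nrow(run$snp_assoc)) {
    write_tsv(run$snp_assoc, file.path(out_dir, "table4_snp_exposure.tsv"))
  }
  write_tsv(run$observational, file.path(out_dir, "table2_observational.tsv"))
  write_tsv(render_strength_table(run$strength),
            file.path(out_dir, "table5_instrument_strength.tsv"))
  write_tsv(render_mr_table(run$mr), file.path(out_dir, "table6_mr.tsv"))
  write_tsv(run$mr, file.path(out_dir, "mr_battery_full.tsv"))
  rep <- run$exclusion_report
  manifest <- list(
    seed = run$config$seed,
    package_version = as.character(utils::packageVersion("vitdmr")),
    n_enrolled = rep$n_enrolled, n_final = rep$n_final,
    n_trimmed = as.list(run$n_trimmed),
    exclusion_report = unclass(rep)
  )
  jsonlite::write_json(
    list(manifest = manifest,
         observational = run$observational,
         strength = run$strength,
         mr = run$mr,
         quartile_tests = run$quartile_tests),
    file.path(out_dir, "bundle.json"),
    auto_unbox = TRUE, digits = NA, na = "null")
  invisible(out_dir)
}

#' @export
print.vitdmr_run <- function(x, ...) {
  cat("vitdmr pipeline run\n")
  print(x$exclusion_report)
  cat(sprintf("trimmed values: %d across %d variables\n",
              sum(x$n_trimmed), length(x$n_trimmed)))
  cat("\nInstrument strength:\n")
  print(render_strength_table(x$strength), row.names = FALSE)
  cat("\nMR battery:\n")
  print(render_mr_table(x$mr), row.names = FALSE)
  invisible(x)
}
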