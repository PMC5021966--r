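# Study configuration: SNP panel, generator parameters, thresholds.

#' SNP panel of the study
#'
#' The ten vitamin-D-pathway SNPs with their gene labels, minor-allele
#' frequencies and instrument roles. Dosages are coded as counts of the
#' effect allele, defined throughout as the vitamin-D-*lowering* allele, so
#' per-allele effects on log-25OHD are negative. `beta` is the generator's
#' per-allele effect on log-25OHD; `weight` is the external per-allele weight
#' (GWAS-scale magnitude of 25OHD lowering) used by the weighted allele score.
#' Three SNPs are high-LD partners of instruments and serve as proxies.
#'
#' The instrument effects are calibrated so that, at n = 1824 and a log-25OHD
#' SD of about 0.43, the lead SNP explains about 1.1% of the exposure
#' variance while the unweighted four-SNP allele score explains about 0.7%
#' and the weighted score about 1.1% (the lead SNP dominates).
#'
#' @return data.frame with columns `snp`, `gene`, `maf`, `beta`,
#'   `instrument`, `weight`, `ld_partner`, `ld_r2`.
#' @export
default_snp_panel <- function() {
  data.frame(
    snp = c("rs4588", "rs7041", "rs2282679", "rs1155563", "rs2276360",
            "rs12785878", "rs2060793", "rs10741657", "rs10766197",
            "rs6013897"),
    gene = c("GC", "GC", "GC", "GC", "NADSYN1", "NADSYN1", "CYP2R1",
             "CYP2R1", "CYP2R1", "CYP24A1"),
    maf = c(0.333, 0.253, 0.338, 0.409, 0.461, 0.462, 0.379, 0.379,
            0.345, 0.162),
    beta = c(0, 0.010, -0.0674, -0.017, 0, -0.0134, 0, -0.0134, -0.016,
             -0.0134),
    instrument = c(FALSE, FALSE, TRUE, FALSE, FALSE, TRUE, FALSE, TRUE,
                   FALSE, TRUE),
    weight = c(NA, NA, 0.085, NA, NA, 0.032, NA, 0.027, NA, 0.019),
    ld_partner = c("rs2282679", NA, NA, NA, "rs12785878", NA, "rs10741657",
                   NA, NA, NA),
    ld_r2 = c(0.95, NA, NA, NA, 0.99, NA, 0.99, NA, NA, NA),
    stringsAsFactors = FALSE
  )
}

#' Outcome model of the synthetic cohort
#'
#' One row per outcome. `mean` is the population mean (meanlog for log-scale
#' outcomes), `causal_effect` the slope of log-25OHD on the (log-scale)
#' outcome, `confounder_effect` the slope of the latent confounder U,
#' `age_effect`/`bmi_effect` small covariate effects, `noise_sd` the residual
#' SD. Defaults put the causal effect at zero with confounding chosen so the
#' biased observational slopes land near 0.047/0.031/0.034 g/cm2 for BMD and
#' -0.103/-0.088/-0.023 for log PTH/P1NP/Beta-CTX, the magnitudes typical of
#' adjusted cross-sectional analyses at this cohort's scale.
#'
#' @return data.frame with one row per outcome.
#' @export
default_outcome_model <- function() {
  data.frame(
    outcome = c("bmd_l1l4", "bmd_fn", "bmd_th", "pth", "p1np", "beta_ctx"),
    log_scale = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE),
    mean = c(0.877, 0.722, 0.765, log(40.7), log(57.0), log(392.5)),
    causal_effect = c(0, 0, 0, 0, 0, 0),
    confounder_effect = c(0.058, 0.038, 0.042, -0.127, -0.108, -0.028),
    age_effect = c(-0.004, -0.004, -0.004, 0, 0, 0),
    bmi_effect = c(0.010, 0.008, 0.010, 0, 0, 0),
    noise_sd = c(0.119, 0.097, 0.099, 0.334, 0.376, 0.471),
    stringsAsFactors = FALSE
  )
}

#' Default pipeline configuration
#'
#' Assembles the full configuration: the SNP panel, the exposure model
#' (baseline log-25OHD centred on log(18.3) with SD about 0.43, a seasonal
#' cosine with late-summer peak, a standard-normal latent confounder entering
#' with slope 0.15), the outcome model, covariate and lab distributions
#' matching the descriptive table of a 1,824-subject postmenopausal cohort,
#' the two-stage exclusion design (158 disease/medication then 31
#' abnormal-lab exclusions out of 2,013 enrolled, in exact-count mode), the
#' binding constants for the free-25OHD calculation, and the QC thresholds.
#'
#' @param n_subjects number of enrolled subjects.
#' @param seed root seed; all module substreams are derived from it.
#' @param causal_effect optional single value recycled into
#'   `outcomes$causal_effect` (convenience for simulation studies).
#' @return a list of class `"vitdmr_config"`.
#' @export
default_config <- function(n_subjects = 2013, seed = 42, causal_effect = NULL) {
  cfg <- list(
    n_subjects = n_subjects,
    seed = seed,
    snps = default_snp_panel(),
    exposure = list(
      mean_log25ohd = log(18.3),   # ng/mL scale: median 18.3
      confounder_effect = 0.15,    # slope of latent U on log-25OHD
      noise_sd = 0.40,             # residual SD of log-25OHD
      season_amplitude = 0.10,     # cosine amplitude, peak in August
      season_peak_month = 8
    ),
    outcomes = default_outcome_model(),
    covariates = list(
      age_mean = 65.5, age_sd = 8.9,
      bmi_mean = 23.5, bmi_sd = 3.3,
      height_mean = 154.2, height_sd = 6.0,
      month_probs = rep(1 / 12, 12)
    ),
    labs = list(
      dbp_meanlog = log(152.9), dbp_sdlog = 0.646,  # mg/L, right-skewed
      albumin_mean = 46.0, albumin_sd = 2.97,       # g/L
      alp_mean = 72.9, alp_sd = 16.8,
      ca_mean = 2.33, ca_sd = 0.10,
      p_mean = 1.16, p_sd = 0.14,
      cr_mean = 58.9, cr_sd = 10.6,
      bun_mean = 5.1, bun_sd = 1.3
    ),
    exclusions = list(
      mode = "count",              # "count" (exact) or "rate" (Bernoulli)
      counts = c(158L, 31L),
      rates = c(158 / 2013, 31 / 1855)
    ),
    genotype_missing_rate = 0,
    binding = binding_constants(),
    thresholds = list(
      hwe_alpha = 0.05,
      min_genotyping_rate = 0.90,
      proxy_r2 = 0.80,
      trim_z = 3.5,
      alpha = 0.05
    ),
    season_mapping = default_season_mapping(),
    instruments = list(
      lead_snp = "rs2282679"       # single-instrument model; from external GWAS
    )
  )
  if (!is.null(causal_effect)) {
    cfg$outcomes$causal_effect <- rep(causal_effect,
                                      nrow(cfg$outcomes))[seq_len(nrow(cfg$outcomes))]
  }
  class(cfg) <- "vitdmr_config"
  validate_config(cfg)
  cfg
}

#' Validate a pipeline configuration
#'
#' @param cfg list as produced by [default_config()].
#' @return `cfg`, invisibly, after checking invariants; errors otherwise.
#' @export
validate_config <- function(cfg) {
  s <- cfg$snps
  if (any(s$maf < 0 | s$maf > 0.5)) stop("snps$maf must lie in [0, 0.5]")
  if (any(!is.na(s$ld_r2) & (s$ld_r2 < 0 | s$ld_r2 > 1))) {
    stop("LD target r2 must lie in [0, 1]")
  }
  bad_partner <- !is.na(s$ld_partner) & !(s$ld_partner %in% s$snp)
  if (any(bad_partner)) {
    stop("ld_partner refers to unknown SNP id(s): ",
         paste(s$snp[bad_partner], collapse = ", "))
  }
  inst <- s$instrument
  if (any(inst & is.na(s$weight))) stop("instrument SNPs need weights")
  if (cfg$exposure$noise_sd <= 0) stop("exposure noise_sd must be > 0")
  if (any(cfg$outcomes$noise_sd <= 0)) stop("outcome noise_sd must be > 0")
  mp <- cfg$covariates$month_probs
  if (length(mp) != 12L || abs(sum(mp) - 1) > 1e-8 || any(mp < 0)) {
    stop("month_probs must be 12 non-negative probabilities summing to 1")
  }
  ex <- cfg$exclusions
  if (!ex$mode %in% c("count", "rate")) stop("exclusions$mode must be 'count' or 'rate'")
  if (ex$mode == "rate" && (any(ex$rates < 0) || any(ex$rates >= 1))) {
    stop("exclusion rates must lie in [0, 1)")
  }
  if (ex$mode == "count" && any(ex$counts < 0)) stop("exclusion counts must be >= 0")
  if (cfg$n_subjects < 1) stop("n_subjects must be positive")
  invisible(cfg)
}

#' Read a configuration from YAML
#'
#' Reads a YAML file whose top-level keys override the corresponding entries
#' of [default_config()]; nested lists are merged shallowly, and a `snps`
#' block (list of per-SNP records) replaces the default panel.
#'
#' @param path YAML file path.
#' @return validated `vitdmr_config`.
#' @export
read_config_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- default_config(n_subjects = raw$n_subjects %||% 2013,
                        seed = raw$seed %||% 42)
  if (!is.null(raw$snps)) {
    cfg$snps <- do.call(rbind, lapply(raw$snps, function(r) {
      data.frame(snp = r$snp, gene = r$gene %||% NA_character_,
                 maf = r$maf, beta = r$beta %||% 0,
                 instrument = isTRUE(r$instrument),
                 weight = r$weight %||% NA_real_,
                 ld_partner = r$ld_partner %||% NA_character_,
                 ld_r2 = r$ld_r2 %||% NA_real_,
                 stringsAsFactors = FALSE)
    }))
  }
  for (key in intersect(names(raw), c("exposure", "covariates", "labs",
                                      "exclusions", "thresholds",
                                      "instruments"))) {
    cfg[[key]] <- utils::modifyList(cfg[[key]], raw[[key]])
  }
  if (!is.null(raw$causal_effect)) {
    cfg$outcomes$causal_effect <- rep(raw$causal_effect, nrow(cfg$outcomes))
  }
  if (!is.null(raw$season_mapping)) cfg$season_mapping <- unlist(raw$season_mapping)
  validate_config(cfg)
  cfg
}
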