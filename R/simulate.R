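# Synthetic-cohort generator: HWE genotypes with optional LD pairs, an
# exposure with weak genetic effects and a latent confounder, outcomes with a
# configurable causal effect, and the two-stage exclusion design.

#' Maximum attainable LD r-squared for two allele frequencies
#'
#' With effect-allele frequencies `p1`, `p2`, the two-locus disequilibrium D
#' is bounded by min(p1 (1 - p2), (1 - p1) p2) for positive association, so
#' r2 = D^2 / (p1 q1 p2 q2) has a hard ceiling below 1 unless p1 = p2.
#'
#' @param p1,p2 effect-allele frequencies in (0, 1).
#' @return the maximum attainable r2.
#' @export
max_ld_r2 <- function(p1, p2) {
  d_max <- min(p1 * (1 - p2), (1 - p1) * p2)
  d_max^2 / (p1 * (1 - p1) * p2 * (1 - p2))
}

# Sample n diploid dosage pairs for two loci in LD by drawing two-locus
# haplotypes whose frequencies imply the target r2 (positive association).
simulate_ld_pair <- function(n, p1, p2, r2) {
  stopifnot(r2 >= 0, r2 <= 1)
  r2_max <- max_ld_r2(p1, p2)
  if (r2 > r2_max + 1e-12) {
    stop(sprintf(
      "target r2 = %.3f infeasible for allele frequencies %.3f / %.3f; maximum attainable r2 = %.4f",
      r2, p1, p2, r2_max), call. = FALSE)
  }
  d <- sqrt(r2 * p1 * (1 - p1) * p2 * (1 - p2))
  hap <- c(ab = p1 * p2 + d,                 # effect alleles at both loci
           aB = p1 * (1 - p2) - d,
           Ab = (1 - p1) * p2 - d,
           AB = (1 - p1) * (1 - p2) + d)
  hap <- pmax(hap, 0)
  hap <- hap / sum(hap)
  h1 <- sample.int(4L, n, replace = TRUE, prob = hap)
  h2 <- sample.int(4L, n, replace = TRUE, prob = hap)
  carries1 <- c(1L, 1L, 0L, 0L)  # haplotypes carrying the effect allele at locus 1
  carries2 <- c(1L, 0L, 1L, 0L)
  list(a = carries1[h1] + carries1[h2],
       b = carries2[h1] + carries2[h2])
}

#' Generate Hardy-Weinberg genotype dosages
#'
#' Draws an n-by-SNP dosage matrix (counts of the effect allele, 0/1/2).
#' Independent SNPs are drawn from the HWE genotype frequencies
#' (1-p)^2, 2p(1-p), p^2 at the configured effect-allele frequency; SNP pairs
#' with an `ld_partner` are drawn jointly from two-locus haplotype
#' frequencies implying the target r2. Deterministic under the configured
#' root seed (substream "genotypes").
#'
#' @param config a [default_config()] list.
#' @return numeric matrix, subjects in rows (ids as rownames), SNP ids as
#'   column names, with the panel attached as attribute `"snps"`.
#' @export
generate_genotypes <- function(config) {
  validate_config(config)
  snps <- config$snps
  n <- config$n_subjects
  set.seed(substream_seed(config$seed, "genotypes"))
  G <- matrix(NA_real_, n, nrow(snps),
              dimnames = list(sprintf("S%04d", seq_len(n)), snps$snp))
  done <- logical(nrow(snps))
  for (i in seq_len(nrow(snps))) {
    if (done[i]) next
    partner <- snps$ld_partner[i]
    if (!is.na(partner)) {
      j <- match(partner, snps$snp)
      pair <- simulate_ld_pair(n, snps$maf[i], snps$maf[j], snps$ld_r2[i])
      G[, i] <- pair$a
      G[, j] <- pair$b
      done[c(i, j)] <- TRUE
    } else {
      p <- snps$maf[i]
      G[, i] <- sample(0:2, n, replace = TRUE,
                       prob = c((1 - p)^2, 2 * p * (1 - p), p^2))
      done[i] <- TRUE
    }
  }
  if (config$genotype_missing_rate > 0) {
    set.seed(substream_seed(config$seed, "genotype-missing"))
    drop <- matrix(stats::runif(length(G)) < config$genotype_missing_rate,
                   nrow(G), ncol(G))
    G[drop] <- NA_real_
  }
  attr(G, "snps") <- snps
  G
}

#' Generate phenotypes, covariates and lab values for a genotype matrix
#'
#' Realizes the structural model underlying the MR design. With latent
#' confounder U ~ N(0, 1):
#' \deqn{\log 25OHD = \mu_x + \sum_j \beta_j (d_j - 2 p_j) + s(month) + a U + e}
#' and for each outcome (log scale where configured)
#' \deqn{Y_k = \mu_k + \gamma_k (\log 25OHD - \mu_x) + b_k U +
#'       c^{age}_k (age - \bar{age}) + c^{bmi}_k (BMI - \bar{BMI}) + e_k,}
#' where \eqn{\gamma_k} is the causal effect and \eqn{b_k} the confounding
#' path. Genotype dosages are centred at their expectation so the configured
#' means are population means. Covariates, DBP, albumin and routine labs are
#' drawn independently from the configured distributions. U and the
#' generating parameters are returned in a `truth` side table that analysis
#' stages never read.
#'
#' @param genotypes matrix from [generate_genotypes()] (no missing dosages).
#' @param config a [default_config()] list.
#' @return list with `cohort` (data.frame, one row per subject) and `truth`.
#' @export
generate_phenotypes <- function(genotypes, config) {
  validate_config(config)
  snps <- config$snps
  n <- config$n_subjects
  if (nrow(genotypes) != n) {
    stop(sprintf("genotype matrix has %d rows but config$n_subjects is %d",
                 nrow(genotypes), n), call. = FALSE)
  }
  if (anyNA(genotypes)) {
    stop("phenotype generation requires complete genotypes; apply missingness afterwards")
  }
  set.seed(substream_seed(config$seed, "phenotypes"))

  cv <- config$covariates
  age <- rnorm(n, cv$age_mean, cv$age_sd)
  bmi <- rnorm(n, cv$bmi_mean, cv$bmi_sd)
  height <- rnorm(n, cv$height_mean, cv$height_sd)
  weight <- bmi * (height / 100)^2
  draw_month <- sample.int(12L, n, replace = TRUE, prob = cv$month_probs)

  ex <- config$exposure
  U <- rnorm(n)
  g <- as.vector(genotypes[, snps$snp, drop = FALSE] %*% snps$beta)
  g <- g - sum(snps$beta * 2 * snps$maf)
  season_term <- ex$season_amplitude *
    cos(2 * pi * (draw_month - ex$season_peak_month) / 12)
  log25 <- ex$mean_log25ohd + g + season_term +
    ex$confounder_effect * U + rnorm(n, 0, ex$noise_sd)

  lb <- config$labs
  out <- config$outcomes
  cohort <- data.frame(
    subject_id = rownames(genotypes) %||% sprintf("S%04d", seq_len(n)),
    age = age, height = height, weight = weight, bmi = bmi,
    draw_month = draw_month,
    season = season_of(draw_month, config$season_mapping),
    total_25ohd = exp(log25),
    dbp = exp(rnorm(n, lb$dbp_meanlog, lb$dbp_sdlog)),
    albumin = pmax(rnorm(n, lb$albumin_mean, lb$albumin_sd), 1),
    alp = rnorm(n, lb$alp_mean, lb$alp_sd),
    ca = rnorm(n, lb$ca_mean, lb$ca_sd),
    p = rnorm(n, lb$p_mean, lb$p_sd),
    cr = rnorm(n, lb$cr_mean, lb$cr_sd),
    bun = rnorm(n, lb$bun_mean, lb$bun_sd),
    stringsAsFactors = FALSE
  )
  for (k in seq_len(nrow(out))) {
    lin <- out$mean[k] +
      out$causal_effect[k] * (log25 - ex$mean_log25ohd) +
      out$confounder_effect[k] * U +
      out$age_effect[k] * (age - cv$age_mean) +
      out$bmi_effect[k] * (bmi - cv$bmi_mean) +
      rnorm(n, 0, out$noise_sd[k])
    cohort[[out$outcome[k]]] <- if (out$log_scale[k]) exp(lin) else lin
  }
  cohort$excl_disease_medication <- FALSE
  cohort$excl_abnormal_lab <- FALSE

  truth <- data.frame(subject_id = cohort$subject_id, U = U,
                      log25ohd = log25, stringsAsFactors = FALSE)
  attr(truth, "causal_effect") <- setNames(out$causal_effect, out$outcome)
  attr(truth, "confounder_effect_exposure") <- ex$confounder_effect
  list(cohort = cohort, truth = truth)
}

#' Flag subjects for the two-stage exclusion cascade
#'
#' Stage 1 flags disease/medication exclusions; stage 2 flags abnormal-lab
#' exclusions among stage-1 survivors only, so the flags are disjoint in
#' effect. In `"count"` mode exactly the configured numbers are flagged
#' (deterministic cascade size); in `"rate"` mode each subject is flagged
#' independently with the configured probability.
#'
#' @param cohort data.frame from [generate_phenotypes()].
#' @param config a [default_config()] list.
#' @return the cohort with `excl_disease_medication` / `excl_abnormal_lab` set.
#' @export
inject_exclusions <- function(cohort, config) {
  validate_config(config)
  n <- nrow(cohort)
  set.seed(substream_seed(config$seed, "exclusions"))
  ex <- config$exclusions
  flag1 <- logical(n)
  if (ex$mode == "count") {
    k1 <- min(ex$counts[1], n)
    if (k1 > 0) flag1[sample.int(n, k1)] <- TRUE
  } else {
    flag1 <- stats::runif(n) < ex$rates[1]
  }
  survivors <- which(!flag1)
  flag2 <- logical(n)
  if (ex$mode == "count") {
    k2 <- min(ex$counts[2], length(survivors))
    if (k2 > 0) flag2[sample(survivors, k2)] <- TRUE
  } else {
    flag2[survivors] <- stats::runif(length(survivors)) < ex$rates[2]
  }
  cohort$excl_disease_medication <- flag1
  cohort$excl_abnormal_lab <- flag2
  cohort
}

#' Simulate a full cohort
#'
#' Convenience wrapper: genotypes, phenotypes, exclusion flags.
#'
#' @param config a [default_config()] list.
#' @return list with `cohort`, `genotypes`, `truth`.
#' @export
simulate_cohort <- function(config = default_config()) {
  G <- generate_genotypes(config)
  ph <- generate_phenotypes(G, config)
  ph$cohort <- inject_exclusions(ph$cohort, config)
  list(cohort = ph$cohort, genotypes = G, truth = ph$truth)
}

#' Write / read the cohort and genotype files
#'
#' The cohort is written as TSV in a fixed, documented column order; the
#' genotype matrix as a TSV dosage table with subjects in rows and SNP ids
#' as header; the truth side table to its own file, never read by analysis
#' stages.
#'
#' @param cohort,genotypes,truth objects from [simulate_cohort()].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_cohort_tsv <- function(cohort, path) {
  write.table(cohort, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_tsv
#' @export
read_cohort_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname write_cohort_tsv
#' @export
write_dosage_tsv <- function(genotypes, path) {
  df <- data.frame(subject_id = rownames(genotypes), genotypes,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_tsv
#' @export
read_dosage_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  G <- as.matrix(df[, -1, drop = FALSE])
  rownames(G) <- df[[1]]
  storage.mode(G) <- "double"
  bad <- !(G %in% c(0, 1, 2) | is.na(G))
  if (any(bad)) stop("dosage file contains values outside {0, 1, 2, NA}")
  G
}

#' @rdname write_cohort_tsv
#' @export
write_truth_tsv <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
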