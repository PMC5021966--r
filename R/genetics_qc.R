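# SNP-level quality control, LD estimation, proxy selection, per-SNP
# exposure associations and instrument-validity screening.

#' Effect-allele frequency and MAF from dosages
#'
#' @param dosages vector of 0/1/2 effect-allele counts (NA allowed).
#' @return list with `eaf` (effect-allele frequency) and `maf`.
#' @export
allele_freq <- function(dosages) {
  d <- dosages[!is.na(dosages)]
  if (!length(d)) stop("all dosages missing")
  if (!all(d %in% c(0, 1, 2))) stop("dosages must be 0, 1 or 2")
  eaf <- sum(d) / (2 * length(d))
  list(eaf = eaf, maf = min(eaf, 1 - eaf))
}

#' Hardy-Weinberg chi-square test
#'
#' One-degree-of-freedom chi-square comparing observed genotype counts
#' (n0, n1, n2 copies of one allele) with the HWE expectation
#' (1-p)^2, 2p(1-p), p^2 at the sample allele frequency; no continuity
#' correction. A monomorphic locus has nothing to test: chi2 = 0 and p = 1,
#' with a warning.
#'
#' @param genotype_counts integer vector `c(n0, n1, n2)`.
#' @return list with `chi2`, `p`, `df = 1`.
#' @export
hwe_chisq <- function(genotype_counts) {
  stopifnot(length(genotype_counts) == 3L, all(genotype_counts >= 0))
  n <- sum(genotype_counts)
  if (n == 0) stop("no genotypes")
  p <- (genotype_counts[2] + 2 * genotype_counts[3]) / (2 * n)
  if (p == 0 || p == 1) {
    warning("monomorphic locus; HWE p defined as 1")
    return(list(chi2 = 0, p = 1, df = 1L))
  }
  expected <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  chi2 <- sum((genotype_counts - expected)^2 / expected)
  list(chi2 = chi2, p = pchisq(chi2, df = 1, lower.tail = FALSE), df = 1L)
}

#' Genotyping rate of a dosage column
#'
#' @param dosages vector with NA for missing calls.
#' @return fraction of non-missing calls.
#' @export
genotyping_rate <- function(dosages) {
  mean(!is.na(dosages))
}

#' Per-SNP quality-control table
#'
#' MAF, HWE chi-square p and genotyping rate per SNP; `qc_pass` requires
#' genotyping rate strictly above `min_rate` *and* HWE p above `hwe_alpha`.
#'
#' @param genotypes dosage matrix (subjects x SNPs).
#' @param hwe_alpha HWE significance threshold (default 0.05).
#' @param min_rate minimum genotyping rate (default 0.90, strict).
#' @param snp_info optional data.frame with `snp` and `gene` for labels.
#' @return data.frame with one row per SNP.
#' @export
snp_qc_table <- function(genotypes, hwe_alpha = 0.05, min_rate = 0.90,
                         snp_info = NULL) {
  rows <- lapply(colnames(genotypes), function(id) {
    d <- genotypes[, id]
    af <- allele_freq(d)
    obs <- d[!is.na(d)]
    counts <- c(sum(obs == 0), sum(obs == 1), sum(obs == 2))
    hw <- suppressWarnings(hwe_chisq(counts))
    rate <- genotyping_rate(d)
    data.frame(snp = id, eaf = af$eaf, maf = af$maf, hwe_chi2 = hw$chi2,
               hwe_p = hw$p, genotyping_rate = rate,
               qc_pass = rate > min_rate & hw$p > hwe_alpha,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(snp_info)) {
    out$gene <- snp_info$gene[match(out$snp, snp_info$snp)]
    out <- out[, c("snp", "gene", setdiff(names(out), c("snp", "gene")))]
  }
  out
}

# EM estimation of two-locus haplotype frequencies from unphased dosages
# (standard EM over the double-heterozygote phase ambiguity, HWE assumed).
em_haplotype_freqs <- function(a, b, tol = 1e-10, maxit = 1000L) {
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n < 2L) stop("need >= 2 subjects with both dosages non-missing")
  tab <- table(factor(a, 0:2), factor(b, 0:2))
  pA <- sum(a) / (2 * n)
  pB <- sum(b) / (2 * n)
  # haplotype order: (1,1), (1,0), (0,1), (0,0) in effect-allele carriage
  h <- c(pA * pB, pA * (1 - pB), (1 - pA) * pB, (1 - pA) * (1 - pB))
  # known haplotype counts from unambiguous genotype cells
  base <- c(
    2 * tab["2", "2"] + tab["2", "1"] + tab["1", "2"],
    2 * tab["2", "0"] + tab["2", "1"] + tab["1", "0"],
    2 * tab["0", "2"] + tab["0", "1"] + tab["1", "2"],
    2 * tab["0", "0"] + tab["0", "1"] + tab["1", "0"]
  )
  ndh <- tab["1", "1"]  # double heterozygotes: phase unknown
  for (it in seq_len(maxit)) {
    cis <- h[1] * h[4]
    trans <- h[2] * h[3]
    w <- if (cis + trans > 0) cis / (cis + trans) else 0.5
    counts <- base + ndh * c(w, 1 - w, 1 - w, w)
    h_new <- counts / (2 * n)
    if (max(abs(h_new - h)) < tol) {
      h <- h_new
      break
    }
    h <- h_new
  }
  names(h) <- c("ab", "aB", "Ab", "AB")
  h
}

#' Linkage-disequilibrium r-squared between two SNPs
#'
#' `method = "composite"` (default): squared Pearson correlation of the
#' dosage vectors — the standard unphased estimator. `method = "em"`:
#' r2 from EM-estimated two-locus haplotype frequencies under HWE.
#'
#' @param dosages_a,dosages_b dosage vectors.
#' @param method `"composite"` or `"em"`.
#' @return r-squared in \[0, 1\].
#' @export
ld_r2 <- function(dosages_a, dosages_b, method = c("composite", "em")) {
  method <- match.arg(method)
  ok <- !is.na(dosages_a) & !is.na(dosages_b)
  if (sum(ok) < 2L) stop("need >= 2 subjects with both dosages non-missing")
  a <- dosages_a[ok]; b <- dosages_b[ok]
  if (var(a) == 0 || var(b) == 0) stop("zero variance in a dosage vector")
  if (method == "composite") {
    min(cor(a, b)^2, 1)
  } else {
    h <- em_haplotype_freqs(a, b)
    pA <- h["ab"] + h["aB"]
    pB <- h["ab"] + h["Ab"]
    D <- h["ab"] - pA * pB
    r2 <- unname(D^2 / (pA * (1 - pA) * pB * (1 - pB)))
    min(r2, 1)
  }
}

#' Map high-LD SNPs to instrument proxies
#'
#' Every non-candidate SNP with r2 at or above the threshold to a candidate
#' instrument is mapped to that candidate (highest r2 wins; ties broken by
#' the alphabetically lower candidate id) and removed from independent
#' analysis.
#'
#' @param genotypes dosage matrix containing all SNPs.
#' @param candidate_ivs character vector of candidate instrument ids.
#' @param other_snps character vector of non-candidate ids to screen.
#' @param r2_threshold proxy threshold (default 0.8).
#' @param method LD method passed to [ld_r2()].
#' @return data.frame with `proxy`, `candidate`, `r2` (possibly 0 rows).
#' @export
select_proxies <- function(genotypes, candidate_ivs, other_snps,
                           r2_threshold = 0.8, method = "composite") {
  rows <- list()
  for (s in sort(other_snps)) {
    r2s <- vapply(sort(candidate_ivs), function(cand) {
      ld_r2(genotypes[, s], genotypes[, cand], method = method)
    }, numeric(1))
    best <- which(r2s == max(r2s))[1]  # sorted ids: lower id wins ties
    if (r2s[best] >= r2_threshold) {
      rows[[s]] <- data.frame(proxy = s, candidate = names(r2s)[best],
                              r2 = unname(r2s[best]), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(proxy = character(), candidate = character(),
                      r2 = numeric(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-SNP association with the log exposure
#'
#' Additive linear model of log-25OHD on the dosage, adjusted for the given
#' covariates (season entered as dummies with winter reference).
#'
#' @param dosages dosage vector aligned with `data` rows.
#' @param data data.frame holding the exposure and covariates.
#' @param exposure column name of the log exposure.
#' @param covariates covariate column names (default age, BMI, season).
#' @return a regression-result list (see [ols_adjusted()]).
#' @export
snp_exposure_assoc <- function(dosages, data, exposure = "total_25ohd_ln",
                               covariates = c("age", "bmi", "season")) {
  data$.dosage <- dosages
  ols_adjusted(data, outcome = exposure, exposure = ".dosage",
               covariates = covariates)
}

#' Instrument-validity screen
#'
#' Regresses each potential confounder and each outcome on each candidate
#' instrument (simple additive models), applies Benjamini-Hochberg FDR
#' across the whole screen, and flags any association surviving at `alpha`.
#' An instrument passes when none of its tests survive.
#'
#' @param genotypes dosage matrix.
#' @param cohort data.frame aligned with `genotypes` rows.
#' @param ivs candidate instrument ids.
#' @param confounders confounder column names.
#' @param outcomes outcome column names.
#' @param alpha significance level after FDR (default 0.05).
#' @return list with `tests` (every test, with raw and adjusted p) and
#'   `pass` (named logical per instrument); `alpha` echoed in attributes.
#' @export
iv_validity_screen <- function(genotypes, cohort, ivs,
                               confounders = c("age", "bmi", "ca", "p",
                                               "cr", "bun"),
                               outcomes = c("bmd_l1l4", "bmd_fn", "bmd_th",
                                            "pth_ln", "p1np_ln"),
                               alpha = 0.05) {
  vars <- c(confounders, outcomes)
  stop_if_not_cols(cohort, vars)
  rows <- list()
  for (iv in ivs) {
    for (v in vars) {
      fit <- lm(cohort[[v]] ~ genotypes[, iv])
      sm <- summary(fit)$coefficients
      rows[[paste(iv, v)]] <- data.frame(
        snp = iv, variable = v,
        kind = if (v %in% confounders) "confounder" else "outcome",
        beta = sm[2, 1], se = sm[2, 2], p = sm[2, 4],
        stringsAsFactors = FALSE)
    }
  }
  tests <- do.call(rbind, rows)
  rownames(tests) <- NULL
  tests$p_fdr <- fdr_bh(tests$p)
  tests$flagged <- tests$p_fdr < alpha
  pass <- !tapply(tests$flagged, tests$snp, any)[ivs]
  structure(list(tests = tests, pass = pass), alpha = alpha)
}

#' Read dosages from a plain-text VCF
#'
#' Minimal GT-field ingestion for small text VCFs: parses the GT subfield of
#' each sample column and counts the configured effect allele. No strand
#' flipping is inferred — the effect allele must be stated per SNP, as REF
#' or ALT, via `effect_allele`.
#'
#' @param path VCF file (uncompressed text).
#' @param effect_allele named character vector mapping SNP id -> effect
#'   allele base; SNPs absent from the map are coded on ALT.
#' @return dosage matrix, subjects in rows, SNP ids in columns.
#' @export
read_vcf_dosages <- function(path, effect_allele = NULL) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "##")]
  if (!length(lines) || !startsWith(lines[1], "#CHROM")) {
    stop("not a VCF: missing #CHROM header line")
  }
  header <- strsplit(sub("^#", "", lines[1]), "\t")[[1]]
  samples <- header[-(1:9)]
  body <- lines[-1]
  G <- matrix(NA_real_, length(samples), length(body),
              dimnames = list(samples, NULL))
  ids <- character(length(body))
  for (i in seq_along(body)) {
    f <- strsplit(body[i], "\t")[[1]]
    ids[i] <- f[3]
    fmt <- strsplit(f[9], ":")[[1]]
    gt_idx <- match("GT", fmt)
    if (is.na(gt_idx)) stop("VCF record without GT field: ", ids[i])
    gts <- vapply(strsplit(f[-(1:9)], ":"), `[`, character(1), gt_idx)
    alleles <- strsplit(gts, "[/|]")
    alt_dose <- vapply(alleles, function(a) {
      if (any(a == ".")) return(NA_real_)
      sum(a != "0")
    }, numeric(1))
    eff <- if (!is.null(effect_allele) && ids[i] %in% names(effect_allele)) {
      effect_allele[[ids[i]]]
    } else {
      f[5]
    }
    if (identical(eff, f[4])) {
      G[, i] <- 2 - alt_dose
    } else if (identical(eff, f[5])) {
      G[, i] <- alt_dose
    } else {
      stop(sprintf("effect allele '%s' for %s matches neither REF nor ALT",
                   eff, ids[i]))
    }
  }
  colnames(G) <- ids
  G
}
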