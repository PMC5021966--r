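# Synthetic-cohort generator: HWE structure, LD construction, determinism,
# exclusion design.

test_that("monomorphic and polymorphic loci have the designed allele frequencies", {
  cfg <- test_config(100, seed = 11)
  cfg$snps <- data.frame(snp = c("mono", "poly"), gene = "X",
                         maf = c(0, 0.338), beta = c(0, 0),
                         instrument = FALSE, weight = NA,
                         ld_partner = NA_character_, ld_r2 = NA,
                         stringsAsFactors = FALSE)
  G <- generate_genotypes(cfg)
  expect_true(all(G[, "mono"] == 0))

  cfg$n_subjects <- 100000
  G <- generate_genotypes(cfg)
  eaf <- sum(G[, "poly"]) / (2 * nrow(G))
  expect_lt(abs(eaf - 0.338), 0.005)  # ~4.7 binomial SEs at n = 1e5
})

test_that("LD pairs hit the target dosage correlation and infeasible targets error", {
  cfg <- test_config(100000, seed = 12)
  cfg$snps <- data.frame(snp = c("a", "b"), gene = "X", maf = c(0.3, 0.3),
                         beta = 0, instrument = FALSE, weight = NA,
                         ld_partner = c("b", NA), ld_r2 = c(1, NA),
                         stringsAsFactors = FALSE)
  G <- generate_genotypes(cfg)
  expect_gt(cor(G[, "a"], G[, "b"])^2, 0.99)  # duplicated-haplotype construction

  cfg$snps$maf <- c(0.05, 0.45)
  cfg$snps$ld_r2 <- c(0.95, NA)
  expect_error(generate_genotypes(cfg), "maximum attainable r2")
  expect_lt(max_ld_r2(0.05, 0.45), 0.95)
})

test_that("cohort regeneration under a fixed seed is identical", {
  cfg <- default_config(n_subjects = 300, seed = 99)
  cfg$exclusions$counts <- c(20L, 5L)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1$cohort, s2$cohort)
  expect_identical(s1$genotypes, s2$genotypes)
  expect_identical(s1$truth, s2$truth)
})

test_that("null model: no genetic effects and no causal effect leaves SNPs uncorrelated with outcomes", {
  cfg <- test_config(20000, seed = 13, causal_effect = 0)
  cfg$snps$beta <- 0
  sim <- simulate_cohort(cfg)
  r1 <- cor(sim$genotypes[, "rs2282679"], sim$cohort$bmd_l1l4)
  r2 <- cor(sim$genotypes[, "rs6013897"], log(sim$cohort$pth))
  expect_lt(abs(r1), 3 / sqrt(20000))
  expect_lt(abs(r2), 3 / sqrt(20000))
})

test_that("HWE chi-square rejects at about the nominal rate on generated loci", {
  cfg <- test_config(500, seed = 14)
  cfg$snps <- data.frame(snp = sprintf("s%03d", 1:300), gene = "X",
                         maf = 0.3, beta = 0, instrument = FALSE,
                         weight = NA, ld_partner = NA_character_,
                         ld_r2 = NA, stringsAsFactors = FALSE)
  G <- generate_genotypes(cfg)
  ps <- apply(G, 2, function(d) {
    hwe_chisq(c(sum(d == 0), sum(d == 1), sum(d == 2)))$p
  })
  rate <- mean(ps < 0.05)
  expect_gt(rate, 0.05 - 3 * sqrt(0.05 * 0.95 / 300))
  expect_lt(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / 300))
})

test_that("expected instrument R2 increases strictly with the per-allele effect", {
  r2_at <- function(beta) {
    cfg <- test_config(30000, seed = 15)
    cfg$snps <- cfg$snps[cfg$snps$snp == "rs2282679", , drop = FALSE]
    cfg$snps$beta <- -beta
    sim <- simulate_cohort(cfg)
    cor(sim$genotypes[, 1], log(sim$cohort$total_25ohd))^2
  }
  r2s <- vapply(c(0.02, 0.05, 0.08, 0.12), r2_at, numeric(1))
  expect_true(all(diff(r2s) > 0))
})

test_that("exclusion flagging honours rates, exact counts and disjointness", {
  cfg <- default_config(n_subjects = 400, seed = 16)
  cfg$exclusions <- list(mode = "count", counts = c(0L, 0L),
                         rates = c(0, 0))
  sim <- simulate_cohort(cfg)
  expect_false(any(sim$cohort$excl_disease_medication))
  expect_false(any(sim$cohort$excl_abnormal_lab))

  cfg <- default_config(n_subjects = 2013, seed = 17)  # exact-count cascade
  sim <- simulate_cohort(cfg)
  expect_equal(sum(sim$cohort$excl_disease_medication), 158)
  expect_equal(sum(sim$cohort$excl_abnormal_lab), 31)
  expect_false(any(sim$cohort$excl_disease_medication &
                     sim$cohort$excl_abnormal_lab))

  cfg$exclusions$counts <- c(2013L, 0L)  # degenerate: everyone excluded
  sim <- simulate_cohort(cfg)
  expect_error(apply_exclusion_cascade(sim$cohort), "empty cohort")
})

test_that("cohort and dosage TSV round-trips preserve the data", {
  cfg <- default_config(n_subjects = 50, seed = 18)
  sim <- simulate_cohort(cfg)
  tc <- tempfile(fileext = ".tsv"); tg <- tempfile(fileext = ".tsv")
  write_cohort_tsv(sim$cohort, tc)
  write_dosage_tsv(sim$genotypes, tg)
  co <- read_cohort_tsv(tc)
  G <- read_dosage_tsv(tg)
  expect_equal(co$total_25ohd, sim$cohort$total_25ohd, tolerance = 1e-8)
  expect_identical(unname(G), unname(sim$genotypes[, colnames(G)]))
  expect_identical(colnames(G), colnames(sim$genotypes))
})
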