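# SNP QC, LD estimation, proxy selection, per-SNP associations, validity
# screen, VCF ingestion.

test_that("allele frequency and MAF follow the hand counts", {
  expect_equal(allele_freq(rep(0, 10))$maf, 0)
  expect_equal(allele_freq(c(0, 1, 2))$eaf, 0.5)
  d <- c(rep(0, 45), rep(1, 40), rep(2, 15))
  af <- allele_freq(d)
  expect_equal(af$eaf, 0.35)   # (40 + 30) / 200
  expect_equal(af$maf, 0.35)
  expect_error(allele_freq(c(NA, NA)), "all dosages missing")
})

test_that("HWE chi-square matches hand computation and handles degenerate loci", {
  r <- hwe_chisq(c(25, 50, 25))
  expect_equal(r$chi2, 0)
  expect_equal(r$p, 1)
  r <- hwe_chisq(c(10, 10, 10))        # expected (7.5, 15, 7.5)
  expect_equal(r$chi2, 10 / 3, tolerance = 1e-12)
  expect_equal(r$p, pchisq(10 / 3, 1, lower.tail = FALSE))
  expect_warning(r <- hwe_chisq(c(30, 0, 0)), "monomorphic")
  expect_equal(r$p, 1)
  # internal allele frequency agrees with allele_freq on the same data
  d <- c(rep(0, 10), rep(1, 10), rep(2, 10))
  expect_equal(allele_freq(d)$eaf, (10 + 20) / 60)
})

test_that("genotyping-rate QC is strict at the boundary and conjunctive with HWE", {
  expect_equal(genotyping_rate(1:10 * 0), 1.0)
  d <- c(rep(0, 90), rep(NA, 10))
  expect_equal(genotyping_rate(d), 0.9)
  G <- cbind(boundary = c(rep(0, 45), rep(1, 30), rep(2, 15), rep(NA, 10)),
             hwe_fail = rep(1, 100))  # all heterozygous: extreme HWE violation
  qc <- suppressWarnings(snp_qc_table(G))
  expect_false(qc$qc_pass[qc$snp == "boundary"])   # rate == 0.90 fails strict >
  expect_lt(qc$hwe_p[qc$snp == "hwe_fail"], 0.05)
  expect_false(qc$qc_pass[qc$snp == "hwe_fail"])
})

test_that("composite and EM r2 agree with each other and with the generator truth", {
  cfg <- test_config(10000, seed = 21)
  cfg$snps <- data.frame(snp = c("proxy", "lead"), gene = "X",
                         maf = c(0.34, 0.34), beta = 0, instrument = FALSE,
                         weight = NA, ld_partner = c("lead", NA),
                         ld_r2 = c(0.95, NA), stringsAsFactors = FALSE)
  G <- generate_genotypes(cfg)
  r2_comp <- ld_r2(G[, "proxy"], G[, "lead"])
  r2_em <- ld_r2(G[, "proxy"], G[, "lead"], method = "em")
  expect_lt(abs(r2_comp - 0.95), 0.02)
  expect_lt(abs(r2_em - r2_comp), 0.02)

  expect_equal(ld_r2(G[, "lead"], G[, "lead"]), 1)
  set.seed(22)
  a <- sample(0:2, 1e5, TRUE, prob = c(0.49, 0.42, 0.09))
  b <- sample(0:2, 1e5, TRUE, prob = c(0.49, 0.42, 0.09))
  expect_lt(ld_r2(a, b), 0.001)
  expect_error(ld_r2(rep(1, 10), a[1:10]), "zero variance")
})

test_that("proxy selection maps by threshold with a deterministic tie rule", {
  set.seed(23)
  lead1 <- sample(0:2, 2000, TRUE, prob = c(0.44, 0.44, 0.12))
  lead2 <- sample(0:2, 2000, TRUE, prob = c(0.44, 0.44, 0.12))
  indep <- sample(0:2, 2000, TRUE, prob = c(0.44, 0.44, 0.12))
  G <- cbind(iv_a = lead1, iv_b = lead2, dup = lead1, far = indep)
  px <- select_proxies(G, c("iv_a", "iv_b"), c("dup", "far"), r2_threshold = 0.8)
  expect_equal(px$proxy, "dup")
  expect_equal(px$candidate, "iv_a")
  expect_equal(px$r2, 1)
  # tie: a proxy perfectly correlated with both candidates maps to the
  # alphabetically lower candidate id
  G2 <- cbind(iv_a = lead1, iv_b = lead1, dup = lead1)
  px2 <- select_proxies(G2, c("iv_b", "iv_a"), "dup")
  expect_equal(px2$candidate, "iv_a")
})

test_that("per-SNP exposure association recovers exact and simulated effects", {
  set.seed(24)
  n <- 4000
  d <- sample(0:2, n, TRUE, prob = c(0.36, 0.48, 0.16))
  co <- data.frame(y = 0.5 * d)
  r <- suppressWarnings(
    snp_exposure_assoc(d, co, exposure = "y", covariates = character(0)))
  expect_equal(r$beta, 0.5, tolerance = 1e-12)

  cfg <- test_config(20000, seed = 25, instruments_only = FALSE)
  sim <- simulate_cohort(cfg)
  co <- log_transform_skewed(sim$cohort)
  r <- snp_exposure_assoc(sim$genotypes[, "rs1155563"], co)
  expect_true(r$ci_low <= -0.017 && -0.017 <= r$ci_high)  # generator truth
  # null SNP: estimate centred on zero
  r0 <- snp_exposure_assoc(sim$genotypes[, "rs4588"] * 0 +
                             sample(0:2, 20000, TRUE), co)
  expect_lt(abs(r0$beta), 3 * r0$se)
})

test_that("instrument-validity screen passes null instruments and flags planted pleiotropy", {
  cfg <- test_config(8000, seed = 26)
  sim <- simulate_cohort(cfg)
  co <- log_transform_skewed(sim$cohort)
  ivs <- cfg$snps$snp[cfg$snps$instrument]
  scr <- iv_validity_screen(sim$genotypes, co, ivs)
  expect_true(all(scr$pass))
  expect_equal(attr(scr, "alpha"), 0.05)
  expect_equal(nrow(scr$tests), length(ivs) * 11)  # 6 confounders + 5 outcomes

  # wire one SNP directly into an outcome (pleiotropy)
  co2 <- co
  co2$bmd_l1l4 <- co2$bmd_l1l4 + 0.05 * sim$genotypes[, "rs6013897"]
  scr2 <- iv_validity_screen(sim$genotypes, co2, ivs)
  expect_false(scr2$pass[["rs6013897"]])
})

test_that("VCF GT ingestion maps to effect-allele dosages with explicit orientation", {
  vcf <- c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2\tS3",
    "4\t100\trsX\tT\tG\t.\tPASS\t.\tGT:DP\t0/0:10\t0/1:12\t1/1:9",
    "11\t200\trsY\tG\tA\t.\tPASS\t.\tGT\t0|1\t./.\t0/0"
  )
  path <- tempfile(fileext = ".vcf")
  writeLines(vcf, path)
  G <- read_vcf_dosages(path)  # effect = ALT by default
  expect_equal(unname(G[, "rsX"]), c(0, 1, 2))
  expect_equal(unname(G[, "rsY"]), c(1, NA, 0))
  # effect allele declared as REF flips the coding
  G2 <- read_vcf_dosages(path, effect_allele = c(rsX = "T"))
  expect_equal(unname(G2[, "rsX"]), c(2, 1, 0))
  expect_error(read_vcf_dosages(path, effect_allele = c(rsX = "C")),
               "neither REF nor ALT")
  # cross-check against vcfR's parsing of the same file
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  alt_counts <- t(apply(gt, 1, function(g) {
    vapply(strsplit(g, "[/|]"), function(a) {
      if (any(is.na(a)) || any(a == ".")) NA_real_ else sum(a != "0")
    }, numeric(1))
  }))
  expect_equal(unname(G[, "rsX"]), unname(alt_counts["rsX", ]))
})
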