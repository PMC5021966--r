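# Causal stage: allele scores, first stage, F/R2 conversions, 2SLS routes,
# Hausman tests, battery structure.

test_that("allele scores count, weight and propagate missingness", {
  G <- rbind(a = c(2, 1, 0, 1), b = c(0, 0, 0, 0), c = c(1, NA, 2, 0))
  colnames(G) <- c("s1", "s2", "s3", "s4")
  un <- build_allele_score(G, instrument_set(colnames(G), "unweighted"))
  expect_equal(as.numeric(un), c(4, 0, NA))
  expect_equal(attr(un, "n_missing"), 1L)
  w <- build_allele_score(
    G, instrument_set(colnames(G), "weighted", weights = c(0.3, 0.2, 0.1, 0.4)))
  expect_equal(unname(w[1]), 1.2)
  s <- build_allele_score(G, instrument_set("s3", "single"))
  expect_equal(as.numeric(s), c(0, 0, 2))
  expect_error(build_allele_score(G, instrument_set("nope", "single")),
               "unknown SNP")
  expect_error(instrument_set(c("a", "b"), "single"), "exactly one")
  expect_error(instrument_set(c("a", "b"), "weighted", weights = 1),
               "one weight per SNP")
  expect_error(instrument_set("a", "unweighted", weights = 1), "only allowed")
})

test_that("first stage returns incremental R2 and a partial F consistent with the conversion", {
  set.seed(41)
  n <- 3000
  s <- sample(0:2, n, TRUE, prob = c(0.44, 0.44, 0.12))
  x <- 0.07 * s + rnorm(n, 0, 0.43)
  df <- data.frame(x = x)
  fs <- first_stage(df, "x", s, covariates = character(0))
  # with no covariates the partial F and the analytic conversion coincide
  expect_equal(fs$partial_f, f_from_r2(fs$incremental_r2, n, 1),
               tolerance = 1e-10)

  df$x2 <- s * 1.0
  fs2 <- suppressWarnings(first_stage(df, "x2", s, covariates = character(0)))
  expect_equal(fs2$incremental_r2, 1, tolerance = 1e-12)

  s0 <- sample(0:2, n, TRUE)
  fs0 <- first_stage(df, "x", s0, covariates = character(0))
  expect_lt(fs0$incremental_r2, 0.005)
  expect_error(first_stage(df, "x", rep(1, n), character(0)), "zero-variance")
})

test_that("F conversion, relative bias and the SE/sample-size identity follow their closed forms", {
  expect_equal(f_from_r2(0, 1000, 1), 0)
  expect_error(f_from_r2(1, 1000, 1), "\\[0, 1\\)")
  expect_error(f_from_r2(0.1, 3, 2))
  rb <- relative_bias(10)
  expect_equal(as.numeric(rb), 0.1)
  expect_true(attr(rb, "weak"))
  expect_false(attr(relative_bias(10.01), "weak"))
  f <- c(5, 20, 100, 1000)
  expect_true(all(diff(as.numeric(relative_bias(f))) < 0))
  expect_error(relative_bias(0), "> 0")
  expect_equal(sample_size_inflation(0.8), 0.5625)
  expect_equal(sample_size_inflation(1), 0)
})

test_that("self-instrumented 2SLS equals OLS and both routes match the matrix oracle", {
  fx <- fixture8()
  # self-instrumenting: score == exposure
  ols <- ols_adjusted(fx, "y", "x", covariates = "c1")
  mr <- tsls(fx, "y", "x", fx$x, covariates = "c1")
  expect_equal(mr$beta, ols$beta, tolerance = 1e-10)

  mr2 <- tsls(fx, "y", "x", fx$z, covariates = "c1")
  X <- cbind(1, fx$c1, fx$x)
  Z <- cbind(1, fx$c1, fx$z)
  beta_oracle <- tsls_closed_form(fx$y, X, Z)
  expect_equal(mr2$beta, beta_oracle[3], tolerance = 1e-10)
  expect_equal(mr2$beta_cf, mr2$beta, tolerance = 1e-8)
})

test_that("control-function and matrix-2SLS estimates agree on random problems", {
  set.seed(42)
  for (i in 1:20) {
    n <- sample(50:200, 1)
    s <- sample(0:2, n, TRUE, prob = c(0.4, 0.45, 0.15))
    u <- rnorm(n)
    x <- 0.3 * s + 0.5 * u + rnorm(n)
    df <- data.frame(
      x = x, y = runif(1, -1, 1) * x + u + rnorm(n),
      age = rnorm(n, 60, 8), bmi = rnorm(n, 23, 3),
      season = sample(c("winter", "spring", "summer", "autumn"), n, TRUE))
    mr <- tsls(df, "y", "x", s)
    expect_equal(mr$beta_cf, mr$beta, tolerance = 1e-8)
  }
})

test_that("Hausman contrast statistic matches the plug-in arithmetic and guards degeneracy", {
  h0 <- hausman(list(beta = 0.5, se = 0.1), list(beta = 0.5, se = 0.2))
  expect_equal(h0$stat, 0)
  expect_equal(h0$p, 1)
  h <- hausman(list(beta = 0.047, se = 0.016), list(beta = -0.048, se = 0.056))
  expect_equal(h$stat, (-0.048 - 0.047)^2 / (0.056^2 - 0.016^2),
               tolerance = 1e-12)
  expect_identical(h$status, "ok")
  hd <- hausman(list(beta = 0.1, se = 0.05), list(beta = 0.2, se = 0.04))
  expect_identical(hd$status, "degenerate")
  expect_true(is.na(hd$p))
})

test_that("MR battery emits 15 rows, is deterministic, and keeps n constant across models", {
  cfg <- test_config(1200, seed = 43)
  sim <- simulate_cohort(cfg)
  co <- log_transform_skewed(sim$cohort)
  b1 <- run_mr_battery(co, sim$genotypes, cfg)
  b2 <- run_mr_battery(co, sim$genotypes, cfg)
  expect_identical(b1, b2)
  expect_equal(nrow(b1), 15)             # 5 outcomes x 3 models
  expect_setequal(unique(b1$model), c("single", "unweighted", "weighted"))
  expect_equal(length(unique(b1$n_used[b1$outcome == "bmd_l1l4"])), 1L)
})

test_that("weighted-score SEs beat single-instrument SEs when all instruments carry signal", {
  ses <- vapply(1:100, function(i) {
    cfg <- test_config(800, seed = 5000 + i)
    cfg$snps$beta <- -0.045                  # every instrument informative
    cfg$snps$weight <- c(0.05, 0.04, 0.045, 0.04)
    sim <- simulate_cohort(cfg)
    co <- log_transform_skewed(sim$cohort)
    single <- tsls(co, "bmd_l1l4", "total_25ohd_ln",
                   build_allele_score(sim$genotypes,
                                      instrument_set("rs2282679", "single")))
    weighted <- tsls(co, "bmd_l1l4", "total_25ohd_ln",
                     build_allele_score(
                       sim$genotypes,
                       instrument_set(cfg$snps$snp, "weighted",
                                      weights = cfg$snps$weight)))
    c(single = single$se, weighted = weighted$se)
  }, numeric(2))
  expect_lt(mean(ses["weighted", ]), mean(ses["single", ]))
})
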