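# Binding-equilibrium free/bioavailable 25OHD: unit conversion, both
# solvers, mass balance, monotonicity, trace-ligand convergence.

test_that("mass-to-molar conversion is exact for each supported unit", {
  expect_equal(to_molar(0, 400.6, "ng/mL"), 0)
  expect_equal(to_molar(58, 58000, "mg/L"), 1e-6)
  expect_equal(to_molar(46, 66430, "g/L"), 46 / 66430)
  expect_equal(46 / 66430, 6.924e-4, tolerance = 1e-3)
  expect_error(to_molar(1, 400.6, "mol/acre"))
  expect_error(to_molar(-1, 400.6, "ng/mL"), ">= 0")
})

test_that("no-carrier and albumin-free limits collapse to total and free", {
  for (m in c("linear", "exact")) {
    r <- free_25ohd(18.3, 0, 0, method = m)
    expect_equal(r$free_25ohd, 18.3 * 1000, tolerance = 1e-9)  # pg/mL
    expect_equal(r$bioavailable_25ohd, 18.3, tolerance = 1e-9)
    r <- free_25ohd(18.3, 152.9, 0, method = m)
    expect_equal(r$bioavailable_25ohd, r$free_25ohd / 1000, tolerance = 1e-12)
  }
  expect_error(free_25ohd(-1, 10, 40), ">= 0")
})

test_that("linear solver matches an independent closed-form evaluation at cohort-median inputs", {
  k <- binding_constants()
  T_m <- 18.3 * 1e-6 / k$mw_25ohd
  D_m <- 152.9 * 1e-3 / k$mw_dbp
  A_m <- 46 / k$mw_alb
  free_m <- T_m / (1 + k$ka_alb * A_m + k$ka_dbp * D_m)
  r <- free_25ohd(18.3, 152.9, 46, method = "linear")
  expect_equal(r$free_25ohd, free_m * k$mw_25ohd * 1e9, tolerance = 1e-12)
  expect_equal(r$bioavailable_25ohd,
               free_m * (1 + k$ka_alb * A_m) * k$mw_25ohd * 1e6,
               tolerance = 1e-12)
  # same order as the cohort medians (8.8 pg/mL, 3.7 ng/mL), not equality:
  # a median of per-subject ratios is not the ratio of medians
  expect_gt(r$free_25ohd, 4); expect_lt(r$free_25ohd, 18)
  expect_gt(r$bioavailable_25ohd, 1.5); expect_lt(r$bioavailable_25ohd, 8)
})

test_that("exact solver satisfies the mass balance against a bisection oracle", {
  set.seed(101)
  n <- 1000
  total <- runif(n, 2, 60)
  dbp <- runif(n, 40, 500)
  alb <- runif(n, 20, 55)
  r <- free_25ohd(total, dbp, alb, method = "exact")
  # components sum back to total
  lhs <- r$free_25ohd / 1000 + r$dbp_bound + r$albumin_bound
  expect_lt(max(abs(lhs - total) / total), 1e-9)
  # spot-check the root against bisection
  for (i in c(1, 500, 1000)) {
    F_oracle <- free_d_bisection(total[i], dbp[i], alb[i])
    expect_equal(r$free_25ohd[i], F_oracle * 400.6 * 1e9, tolerance = 1e-6)
  }
})

test_that("free fraction decreases monotonically in DBP and albumin", {
  dbp_grid <- seq(20, 500, by = 40)
  f_dbp <- free_25ohd(18.3, dbp_grid, 46)$free_25ohd
  expect_true(all(diff(f_dbp) < 0))
  alb_grid <- seq(10, 60, by = 5)
  f_alb <- free_25ohd(18.3, 152.9, alb_grid)$free_25ohd
  expect_true(all(diff(f_alb) < 0))
})

test_that("exact and linear solvers converge in the trace-ligand limit and diverge under saturation", {
  # trace regime: total at 1e-3 of the molar DBP pool -> <0.1% disagreement
  k0 <- binding_constants()
  D0 <- 152.9 * 1e-3 / k0$mw_dbp
  tot0 <- 1e-3 * D0 * k0$mw_25ohd * 1e6
  lin <- free_25ohd(tot0, 152.9, 46, method = "linear")
  exa <- free_25ohd(tot0, 152.9, 46, method = "exact")
  expect_lt(abs(exa$free_25ohd - lin$free_25ohd) / lin$free_25ohd, 1e-3)

  # relative difference bounded by the total/capacity ratio as it -> 0
  k <- binding_constants()
  for (ratio in c(1e-2, 1e-3, 1e-4)) {
    D_m <- 2.6e-6
    total <- ratio * D_m * k$mw_25ohd * 1e6   # ng/mL
    dbp <- D_m * k$mw_dbp * 1e3               # mg/L
    l <- free_25ohd(total, dbp, 46, method = "linear")$free_25ohd
    e <- free_25ohd(total, dbp, 46, method = "exact")$free_25ohd
    expect_lt(abs(e - l) / l, 2 * ratio)
  }

  # saturation: total at 10x the molar DBP concentration
  D_m <- 1e-9
  total <- 10 * D_m * k$mw_25ohd * 1e6
  dbp <- D_m * k$mw_dbp * 1e3
  l <- free_25ohd(total, dbp, 0, method = "linear")$free_25ohd
  e <- free_25ohd(total, dbp, 0, method = "exact")$free_25ohd
  expect_gt(e / l, 1.5)
})

test_that("cohort batch mode appends free and bioavailable columns, respecting missingness", {
  co <- data.frame(total_25ohd = c(18.3, NA, 25), dbp = c(152.9, 100, NA),
                   albumin = c(46, 44, 48))
  out <- add_free_d_columns(co)
  expect_false(is.na(out$free_25ohd[1]))
  expect_true(is.na(out$free_25ohd[2]))
  expect_true(is.na(out$bioavailable_25ohd[3]))
  expect_true(out$free_25ohd[1] / 1000 <= out$bioavailable_25ohd[1])
  expect_true(out$bioavailable_25ohd[1] <= out$total_25ohd[1])
})
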