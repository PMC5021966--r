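# Independent oracles and small fixtures shared across tests. Oracles are
# written from first principles and never call the package routines they
# check.

# Brute-force Benjamini-Hochberg step-up: adjusted p_i = min over j with
# rank >= rank(i) of p_(j) * m / j, capped at 1.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    vals <- vapply(seq(i, m), function(j) p[o[j]] * m / j, numeric(1))
    adj[o[i]] <- min(1, vals)
  }
  adj
}

# Bisection root-finder on the saturable binding mass balance; independent
# of the package's quadratic solver. Inputs in ng/mL, mg/L, g/L.
free_d_bisection <- function(total, dbp, albumin,
                             ka_dbp = 7e8, ka_alb = 6e5,
                             mw_dbp = 58000, mw_alb = 66430,
                             mw_25ohd = 400.6) {
  T_m <- total * 1e-6 / mw_25ohd
  D_m <- dbp * 1e-3 / mw_dbp
  A_m <- albumin / mw_alb
  g <- function(F) F * (1 + ka_alb * A_m) + ka_dbp * F * D_m / (1 + ka_dbp * F) - T_m
  if (T_m == 0) return(0)
  lo <- 0
  hi <- T_m
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2  # free 25OHD in mol/L
}

# Explicit 2SLS closed form beta = (X' Z (Z'Z)^-1 Z' X)^-1 X' Z (Z'Z)^-1 Z' y,
# written without the projection shortcut the package uses.
tsls_closed_form <- function(y, X, Z) {
  A <- t(X) %*% Z %*% solve(t(Z) %*% Z) %*% t(Z)
  solve(A %*% X) %*% (A %*% y)
}

# Deterministic 8-row fixture for the matrix-oracle checks: outcome y,
# endogenous exposure x, instrument z, one exogenous covariate c1.
fixture8 <- function() {
  data.frame(
    y  = c(3.10, 2.40, 5.60, 4.90, 1.20, 6.30, 3.30, 4.40),
    x  = c(1.00, 0.50, 2.20, 1.90, 0.10, 2.80, 1.10, 1.70),
    z  = c(0, 1, 2, 2, 0, 2, 1, 1),
    c1 = c(5.5, 6.2, 4.8, 7.0, 6.6, 5.1, 5.9, 6.3)
  )
}

# Compact study-scale configuration for simulation tests: instruments only,
# no exclusions, optional causal effect.
test_config <- function(n, seed, causal_effect = NULL,
                        instruments_only = TRUE) {
  cfg <- default_config(n_subjects = n, seed = seed,
                        causal_effect = causal_effect)
  if (instruments_only) {
    cfg$snps <- cfg$snps[cfg$snps$instrument, , drop = FALSE]
  }
  cfg$exclusions$mode <- "count"
  cfg$exclusions$counts <- c(0L, 0L)
  cfg
}

# Theoretical exposure variance (conditional on covariates) and the
# omitted-variable bias of the OLS exposure-outcome slope implied by a
# configuration, for parameter-recovery checks.
theoretical_var_x <- function(cfg) {
  s <- cfg$snps
  gvar <- sum(s$beta^2 * 2 * s$maf * (1 - s$maf))
  gvar + cfg$exposure$confounder_effect^2 + cfg$exposure$noise_sd^2
}

analytic_ols_bias <- function(cfg, outcome) {
  k <- match(outcome, cfg$outcomes$outcome)
  cfg$exposure$confounder_effect * cfg$outcomes$confounder_effect[k] /
    theoretical_var_x(cfg)
}
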