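# Causal stage: allele scores, two-stage least squares, weak-instrument
# diagnostics, Hausman endogeneity tests, and the model battery.

#' Define an instrument set
#'
#' @param snps instrument SNP ids.
#' @param type `"single"`, `"unweighted"` or `"weighted"`.
#' @param weights per-SNP per-effect-allele weights (required iff weighted).
#' @return list of class `"instrument_set"`.
#' @export
instrument_set <- function(snps, type = c("unweighted", "weighted", "single"),
                           weights = NULL) {
  type <- match.arg(type)
  if (type == "single" && length(snps) != 1L) {
    stop("single-instrument set must contain exactly one SNP")
  }
  if (type == "weighted") {
    if (is.null(weights) || length(weights) != length(snps)) {
      stop("weighted set needs one weight per SNP")
    }
  } else if (!is.null(weights)) {
    stop("weights are only allowed for the weighted score type")
  }
  structure(list(snps = snps, type = type, weights = weights),
            class = "instrument_set")
}

#' Build a per-subject allele score
#'
#' Single: the dosage of the one instrument. Unweighted: the plain count of
#' effect alleles across instruments. Weighted: the weight-weighted count.
#' Subjects with a missing dosage at any instrument get `NA` (dropped
#' listwise downstream); the number dropped is attached as attribute
#' `"n_missing"`.
#'
#' @param genotypes dosage matrix.
#' @param instruments an [instrument_set()].
#' @return numeric score vector aligned with the genotype rows.
#' @export
build_allele_score <- function(genotypes, instruments) {
  stopifnot(inherits(instruments, "instrument_set"))
  missing_snps <- setdiff(instruments$snps, colnames(genotypes))
  if (length(missing_snps)) {
    stop("unknown SNP id(s): ", paste(missing_snps, collapse = ", "))
  }
  Gi <- genotypes[, instruments$snps, drop = FALSE]
  w <- switch(instruments$type,
              single = 1,
              unweighted = rep(1, ncol(Gi)),
              weighted = instruments$weights)
  score <- as.vector(Gi %*% w)
  score[apply(Gi, 1L, anyNA)] <- NA_real_
  attr(score, "n_missing") <- sum(is.na(score))
  score
}

#' First-stage regression of the log exposure on the allele score
#'
#' Regresses the log exposure on the score plus covariates. `incremental_r2`
#' is the R-squared gained by adding the score over the covariates-only
#' model; `partial_f` is the 1-df F for the score term. Fitted values and
#' residuals are returned for the second stage.
#'
#' @param data data.frame with exposure and covariates.
#' @param exposure log-exposure column name.
#' @param score numeric score aligned with `data` rows.
#' @param covariates covariate column names.
#' @return list with `fitted`, `residuals`, `incremental_r2`, `partial_f`,
#'   `coef_score`, `n_used`.
#' @export
first_stage <- function(data, exposure, score,
                        covariates = c("age", "bmi", "season")) {
  data$.score <- score
  df <- model_frame(data, c(exposure, ".score", covariates))
  if (var(df$.score) == 0) stop("zero-variance allele score")
  rhs_cov <- if (length(covariates)) {
    paste(sprintf("`%s`", covariates), collapse = " + ")
  } else {
    "1"
  }
  f0 <- lm(stats::as.formula(sprintf("`%s` ~ %s", exposure, rhs_cov)),
           data = df)
  f1 <- lm(stats::as.formula(sprintf("`%s` ~ .score + %s", exposure, rhs_cov)),
           data = df)
  r2_0 <- summary(f0)$r.squared
  r2_1 <- summary(f1)$r.squared
  an <- anova(f0, f1)
  list(fitted = stats::fitted(f1), residuals = stats::residuals(f1),
       incremental_r2 = r2_1 - r2_0, partial_f = an$F[2],
       coef_score = unname(coef(f1)[".score"]), n_used = nrow(df))
}

#' First-stage F from incremental R-squared
#'
#' The analytic conversion \eqn{F = [(n - 1 - k)/k] \cdot R^2 / (1 - R^2)}
#' for k instruments and sample size n.
#'
#' @param r2 incremental R-squared in \[0, 1).
#' @param n sample size.
#' @param k number of instruments (default 1).
#' @return the F statistic.
#' @export
f_from_r2 <- function(r2, n, k = 1) {
  if (any(r2 < 0) || any(r2 >= 1)) stop("r2 must lie in [0, 1)")
  if (n <= k + 1) stop("need n > k + 1")
  if (k < 1) stop("k must be >= 1")
  (n - 1 - k) / k * r2 / (1 - r2)
}

#' Approximate relative TSLS/OLS bias
#'
#' The standard weak-instrument approximation 1/F: the expected bias of the
#' TSLS estimator toward OLS, as a fraction of the OLS bias. Instruments
#' with F <= 10 are flagged weak (attribute `"weak"`).
#'
#' @param f first-stage F statistic, > 0.
#' @return numeric bias ratio with logical attribute `"weak"`.
#' @export
relative_bias <- function(f) {
  if (any(f <= 0)) stop("F must be > 0")
  structure(1 / f, weak = f <= 10)
}

#' Sample-size inflation implied by an SE reduction
#'
#' Under sample-size proportional to SE^-2, reducing the SE by a factor
#' `se_ratio` (e.g. 0.8 for a 20% decrease) requires a fractional sample
#' increase of 1/se_ratio^2 - 1 (0.5625, i.e. 56%, for a 20% decrease).
#'
#' @param se_ratio new SE divided by old SE, in (0, 1].
#' @return fractional sample-size increase.
#' @export
sample_size_inflation <- function(se_ratio) {
  if (any(se_ratio <= 0)) stop("se_ratio must be > 0")
  1 / se_ratio^2 - 1
}

#' Two-stage least squares with an allele score
#'
#' Fits the structural model of an outcome on the log exposure, instrumented
#' by the allele score, with covariates included in both stages. Two routes
#' are computed and cross-asserted:
#'
#' * control-function: the outcome regressed on the *fitted* exposure from
#'   the first stage, the covariates, and the first-stage residual
#'   (point-identical to 2SLS for the exposure coefficient). The t-test on
#'   the residual term of this regression is the endogeneity test reported
#'   as `hausman_dwh_*`: the fitted exposure and the residual are
#'   orthogonal, so the residual coefficient captures the confounded slope
#'   carried by the non-genetic exposure variation, and its test is the
#'   high-power direction of the regression-based Durbin-Wu-Hausman family
#'   under a weak instrument (see the methods vignette).
#' * canonical matrix 2SLS, with homoskedastic variance computed from the
#'   structural residuals (outcome minus observed-exposure fit); the
#'   reported `se` and `p` come from this route.
#'
#' The two point estimates must agree to 1e-8 (algebraic identity); a
#' discrepancy beyond that is an internal error and is raised.
#'
#' @param data data.frame.
#' @param outcome outcome column name.
#' @param exposure log-exposure column name.
#' @param score numeric allele score aligned with `data` rows.
#' @param covariates covariate column names.
#' @param model_label label stored in the result.
#' @return list of class `"mr_result"`.
#' @export
tsls <- function(data, outcome, exposure, score,
                 covariates = c("age", "bmi", "season"),
                 model_label = "tsls") {
  data$.score <- score
  df <- model_frame(data, c(outcome, exposure, ".score", covariates))
  n <- nrow(df)
  if (var(df$.score) == 0) stop("zero-variance allele score")

  # design pieces: C includes the intercept and covariate dummies
  rhs_cov <- if (length(covariates)) {
    paste(sprintf("`%s`", covariates), collapse = " + ")
  } else {
    "1"
  }
  C <- stats::model.matrix(stats::as.formula(paste("~", rhs_cov)), data = df)
  x <- df[[exposure]]
  y <- df[[outcome]]
  z <- df$.score
  Z <- cbind(C, z)
  X <- cbind(C, x)

  # first stage (for the control function and diagnostics)
  fs_fit <- stats::lm.fit(Z, x)
  if (abs(coef(fs_fit)[["z"]]) < 1e-12) stop("weak-score degeneracy: zero first-stage coefficient")
  v <- stats::residuals(fs_fit)
  r2_full <- 1 - sum(v^2) / sum((x - mean(x))^2)
  fs_cov <- stats::lm.fit(C, x)
  r2_cov <- 1 - sum(stats::residuals(fs_cov)^2) / sum((x - mean(x))^2)
  incremental_r2 <- r2_full - r2_cov
  partial_f <- (sum(stats::residuals(fs_cov)^2) - sum(v^2)) /
    (sum(v^2) / (n - ncol(Z)))

  # (a) control function exactly as specified: y ~ xhat + C + v
  xhat <- x - v
  Xcf <- cbind(C, xhat = xhat, v = v)
  cf_fit <- stats::lm.fit(Xcf, y)
  beta_cf <- coef(cf_fit)[["xhat"]]
  cf_res <- stats::residuals(cf_fit)
  cf_sigma2 <- sum(cf_res^2) / (n - ncol(Xcf))
  XtX_inv_cf <- chol2inv(chol(crossprod(Xcf)))
  se_rho <- sqrt(cf_sigma2 * XtX_inv_cf[ncol(Xcf), ncol(Xcf)])
  rho <- coef(cf_fit)[["v"]]
  t_dwh <- rho / se_rho
  p_dwh <- 2 * pt(abs(t_dwh), df = n - ncol(Xcf), lower.tail = FALSE)

  # (b) canonical matrix 2SLS
  Xhat <- Z %*% solve(crossprod(Z), crossprod(Z, X))
  XtPzX <- crossprod(Xhat)
  beta_vec <- solve(XtPzX, crossprod(Xhat, y))
  beta_iv <- unname(beta_vec[ncol(X), 1])
  struct_res <- y - X %*% beta_vec
  sigma2 <- sum(struct_res^2) / (n - ncol(X))
  V <- sigma2 * solve(XtPzX)
  se_iv <- sqrt(V[ncol(X), ncol(X)])
  p_iv <- 2 * pnorm(abs(beta_iv / se_iv), lower.tail = FALSE)

  if (abs(beta_cf - beta_iv) > 1e-8 * max(1, abs(beta_iv))) {
    stop(sprintf(
      "internal error: control-function (%.10g) and matrix-2SLS (%.10g) estimates disagree",
      beta_cf, beta_iv))
  }

  f_stat <- f_from_r2(incremental_r2, n, 1)
  structure(list(
    model = model_label, outcome = outcome, exposure = exposure,
    beta = beta_iv, se = se_iv, p = p_iv, beta_cf = beta_cf,
    ci_low = beta_iv - qnorm(0.975) * se_iv,
    ci_high = beta_iv + qnorm(0.975) * se_iv,
    first_stage_r2 = incremental_r2, first_stage_f = f_stat,
    first_stage_partial_f = partial_f,
    relative_bias = as.numeric(relative_bias(f_stat)),
    weak_instrument = f_stat <= 10,
    hausman_dwh_stat = t_dwh, hausman_dwh_p = p_dwh,
    n_used = n
  ), class = "mr_result")
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("[%s] %s ~ %s (instrumented), n = %d\n", x$model, x$outcome,
              x$exposure, x$n_used))
  cat(sprintf("beta = %.4f (SE %.4f), p = %s\n", x$beta, x$se, fmt_p(x$p)))
  cat(sprintf("first stage: R2 = %.4f, F = %.2f%s, relative bias = %.3f\n",
              x$first_stage_r2, x$first_stage_f,
              if (x$weak_instrument) " (weak)" else "", x$relative_bias))
  cat(sprintf("DWH endogeneity: t = %.3f, p = %s\n", x$hausman_dwh_stat,
              fmt_p(x$hausman_dwh_p)))
  invisible(x)
}

#' Hausman estimator-contrast test
#'
#' The classical contrast form: \eqn{(\beta_{iv} - \beta_{ols})^2 /
#' (se_{iv}^2 - se_{ols}^2)} referred to chi-squared with 1 df. When the
#' variance difference is non-positive the statistic is undefined; the
#' status is `"degenerate"` and no p is returned.
#'
#' @param ols a `regression_result` from [ols_adjusted()], or a list with
#'   `beta` and `se`.
#' @param iv an `mr_result` from [tsls()], or a list with `beta` and `se`.
#' @return list with `stat`, `p`, `status` (`"ok"` or `"degenerate"`).
#' @export
hausman <- function(ols, iv) {
  d <- iv$beta - ols$beta
  vdiff <- iv$se^2 - ols$se^2
  if (vdiff <= 0) {
    return(list(stat = NA_real_, p = NA_real_, status = "degenerate"))
  }
  stat <- d^2 / vdiff
  list(stat = stat, p = pchisq(stat, df = 1, lower.tail = FALSE),
       status = "ok")
}

#' Run the full MR model battery
#'
#' For each outcome and each of the three model variants — single instrument
#' (the configured lead SNP), unweighted allele score and weighted allele
#' score — fits the OLS and 2SLS models and collects estimates, instrument
#' diagnostics and endogeneity tests. Subjects missing any instrument dosage
#' are dropped listwise for all models, so n is constant within a battery.
#' The regression-based Durbin-Wu-Hausman p-values are FDR-adjusted within
#' the battery (`hausman_p_fdr`); the estimator-contrast Hausman test is
#' also reported (`hausman_contrast_*`). Beta-CTX is excluded from the
#' default outcome set (no verified observational association to carry
#' forward), mirroring the study's causal-stage table.
#'
#' @param cohort analysed cohort (trimmed, log-transformed), rows aligned
#'   with `genotypes`.
#' @param genotypes dosage matrix.
#' @param config a [default_config()] list (instrument panel and weights).
#' @param outcomes outcome columns.
#' @param exposure log-exposure column.
#' @param covariates adjustment set.
#' @return data.frame with one row per outcome x model.
#' @export
run_mr_battery <- function(cohort, genotypes, config,
                           outcomes = c("bmd_l1l4", "bmd_fn", "bmd_th",
                                        "pth_ln", "p1np_ln"),
                           exposure = "total_25ohd_ln",
                           covariates = c("age", "bmi", "season")) {
  snps <- config$snps
  iv_ids <- snps$snp[snps$instrument]
  weights <- snps$weight[snps$instrument]
  lead <- config$instruments$lead_snp
  if (!lead %in% iv_ids) stop("lead SNP is not among the instruments")

  sets <- list(
    single = instrument_set(lead, type = "single"),
    unweighted = instrument_set(iv_ids, type = "unweighted"),
    weighted = instrument_set(iv_ids, type = "weighted", weights = weights)
  )
  # constant n across models: drop subjects missing any instrument dosage
  complete_geno <- !apply(genotypes[, iv_ids, drop = FALSE], 1L, anyNA)
  cohort <- cohort[complete_geno, , drop = FALSE]
  genotypes <- genotypes[complete_geno, , drop = FALSE]

  rows <- list()
  for (y in outcomes) {
    ols <- ols_adjusted(cohort, y, exposure, covariates)
    for (m in names(sets)) {
      score <- build_allele_score(genotypes, sets[[m]])
      mr <- tsls(cohort, y, exposure, score, covariates, model_label = m)
      hc <- hausman(ols, mr)
      rows[[paste(y, m)]] <- data.frame(
        outcome = y, model = m,
        beta_ols = ols$beta, se_ols = ols$se, p_ols = ols$p,
        beta_tsls = mr$beta, se_tsls = mr$se, p_tsls = mr$p,
        first_stage_r2 = mr$first_stage_r2,
        first_stage_f = mr$first_stage_f,
        first_stage_partial_f = mr$first_stage_partial_f,
        relative_bias = mr$relative_bias,
        weak_instrument = mr$weak_instrument,
        hausman_p = mr$hausman_dwh_p,
        hausman_contrast_stat = hc$stat, hausman_contrast_p = hc$p,
        hausman_contrast_status = hc$status,
        n_used = mr$n_used, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$hausman_p_fdr <- fdr_bh(out$hausman_p)
  out$p_tsls_fdr <- fdr_bh(out$p_tsls)
  out
}

#' Instrument-strength diagnostics table
#'
#' One row per model variant with the incremental first-stage R-squared, the
#' analytic F (from [f_from_r2()]), the regression partial F, and the
#' approximate relative TSLS/OLS bias (1/F on the analytic F).
#'
#' @inheritParams run_mr_battery
#' @return data.frame with one row per model.
#' @export
instrument_strength_table <- function(cohort, genotypes, config,
                                      exposure = "total_25ohd_ln",
                                      covariates = c("age", "bmi", "season")) {
  snps <- config$snps
  iv_ids <- snps$snp[snps$instrument]
  weights <- snps$weight[snps$instrument]
  lead <- config$instruments$lead_snp
  sets <- list(
    single = instrument_set(lead, type = "single"),
    unweighted = instrument_set(iv_ids, type = "unweighted"),
    weighted = instrument_set(iv_ids, type = "weighted", weights = weights)
  )
  complete_geno <- !apply(genotypes[, iv_ids, drop = FALSE], 1L, anyNA)
  cohort <- cohort[complete_geno, , drop = FALSE]
  genotypes <- genotypes[complete_geno, , drop = FALSE]
  rows <- lapply(names(sets), function(m) {
    score <- build_allele_score(genotypes, sets[[m]])
    fs <- first_stage(cohort, exposure, score, covariates)
    f_analytic <- f_from_r2(fs$incremental_r2, fs$n_used, 1)
    data.frame(model = m, r2 = fs$incremental_r2, f = f_analytic,
               partial_f = fs$partial_f,
               relative_bias = as.numeric(relative_bias(f_analytic)),
               weak = f_analytic <= 10, n_used = fs$n_used,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
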