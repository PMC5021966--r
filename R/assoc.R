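# Observational stage: covariate-adjusted OLS, FDR control, quartile-group
# tests.

# Build a model data.frame with season as a factor (winter reference) and
# only complete cases for the named columns.
model_frame <- function(data, cols) {
  stop_if_not_cols(data, cols)
  df <- data[, cols, drop = FALSE]
  if ("season" %in% names(df)) {
    lev <- c("winter", "spring", "summer", "autumn")
    df$season <- factor(df$season, levels = intersect(lev, unique(df$season)))
  }
  df[complete.cases(df), , drop = FALSE]
}

#' Covariate-adjusted OLS association
#'
#' Linear model of `outcome` on `exposure` plus covariates; season is
#' entered as categorical dummies with winter as the reference level.
#' Returns the exposure coefficient with model-based SE, 95% CI and
#' two-sided p.
#'
#' @param data data.frame.
#' @param outcome,exposure column names.
#' @param covariates covariate column names (may be empty).
#' @return list of class `"regression_result"`: `beta`, `se`, `ci_low`,
#'   `ci_high`, `p`, `n_used`, `r2`, `outcome`, `exposure`, `covariates`.
#' @export
ols_adjusted <- function(data, outcome, exposure,
                         covariates = c("age", "bmi", "season")) {
  df <- model_frame(data, c(outcome, exposure, covariates))
  if (nrow(df) < length(covariates) + 3L) stop("too few complete cases")
  rhs <- paste(c(sprintf("`%s`", exposure),
                 sprintf("`%s`", covariates)), collapse = " + ")
  fit <- lm(stats::as.formula(sprintf("`%s` ~ %s", outcome, rhs)), data = df)
  if (any(is.na(coef(fit)))) stop("rank-deficient model (collinear covariates)")
  sm <- summary(fit)
  i <- 2L  # exposure is the first term after the intercept
  est <- sm$coefficients[i, ]
  tcrit <- stats::qt(0.975, df = fit$df.residual)
  structure(list(
    beta = unname(est[1]), se = unname(est[2]),
    ci_low = unname(est[1] - tcrit * est[2]),
    ci_high = unname(est[1] + tcrit * est[2]),
    p = unname(est[4]), n_used = nrow(df), r2 = sm$r.squared,
    outcome = outcome, exposure = exposure, covariates = covariates,
    fit = fit
  ), class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("%s ~ %s (+ %s), n = %d\n", x$outcome, x$exposure,
              paste(x$covariates, collapse = ", "), x$n_used))
  cat(sprintf("beta = %.4f (SE %.4f, 95%% CI %.4f to %.4f), p = %s, R2 = %.4f\n",
              x$beta, x$se, x$ci_low, x$ci_high, fmt_p(x$p), x$r2))
  invisible(x)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment with enforced monotonicity; input order preserved.
#'
#' @param pvalues numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, same order as the input.
#' @export
fdr_bh <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Quartile group labels
#'
#' Labels 1..4 by the quartile cut-points of `x` (linear interpolation
#' between order statistics); values exactly at a cut-point go to the lower
#' group.
#'
#' @param x numeric vector (NA allowed; labelled NA).
#' @return integer vector of group labels.
#' @export
quartile_groups <- function(x) {
  obs <- x[!is.na(x)]
  if (length(unique(obs)) < 4L) stop("need at least 4 distinct values")
  cuts <- quantile(obs, probs = 0:4 / 4, type = 7, names = FALSE)
  as.integer(cut(x, breaks = unique(cuts), include.lowest = TRUE,
                 right = TRUE, labels = FALSE))
}

#' Across-group test (ANOVA or Kruskal-Wallis)
#'
#' One-way ANOVA when `y` passes the shared normality rule
#' (|sample skewness| <= 1), Kruskal-Wallis otherwise; the choice is
#' recorded in the result.
#'
#' @param y numeric response.
#' @param labels group labels.
#' @return list with `statistic`, `p`, `method`, `df`.
#' @export
group_test <- function(y, labels) {
  ok <- !is.na(y) & !is.na(labels)
  y <- y[ok]; g <- factor(labels[ok])
  if (nlevels(g) < 2L) stop("need at least 2 non-empty groups")
  sk <- skewness(y)
  if (!is.na(sk) && abs(sk) > 1) {
    kw <- kruskal.test(y, g)
    list(statistic = unname(kw$statistic), p = kw$p.value,
         method = "kruskal-wallis", df = unname(kw$parameter))
  } else {
    if (any(table(g) < 2L)) stop("ANOVA needs >= 2 observations per group")
    fit <- aov(y ~ g)
    tab <- summary(fit)[[1]]
    list(statistic = tab[1, "F value"], p = tab[1, "Pr(>F)"],
         method = "anova", df = tab[1, "Df"])
  }
}

#' Observational association battery
#'
#' For each outcome, the unadjusted and covariate-adjusted OLS association
#' with the log exposure, with BH-FDR applied to the adjusted p-values as
#' one family per battery. Mirrors the study's observational results table.
#'
#' @param cohort analysed cohort (after trimming/log transformation).
#' @param exposure log-exposure column (default `total_25ohd_ln`).
#' @param outcomes outcome columns (log-scale markers expected as `_ln`).
#' @param covariates adjustment set.
#' @return data.frame with one row per outcome.
#' @export
observational_battery <- function(cohort, exposure = "total_25ohd_ln",
                                  outcomes = c("bmd_l1l4", "bmd_fn",
                                               "bmd_th", "pth_ln",
                                               "beta_ctx_ln", "p1np_ln"),
                                  covariates = c("age", "bmi", "season")) {
  rows <- lapply(outcomes, function(y) {
    un <- ols_adjusted(cohort, y, exposure, covariates = character(0))
    ad <- ols_adjusted(cohort, y, exposure, covariates = covariates)
    data.frame(outcome = y,
               beta_unadj = un$beta, p_unadj = un$p,
               beta_adj = ad$beta, se_adj = ad$se, p_adj = ad$p,
               n_used = ad$n_used, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj_fdr <- fdr_bh(out$p_adj)
  out
}
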