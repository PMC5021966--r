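# Cohort preprocessing: exclusion cascade, extreme-value trimming, log
# transformation of skewed variables, season coding, descriptive summaries.

#' Default season mapping (Northern-Hemisphere meteorological)
#'
#' Months 3-5 spring, 6-8 summer, 9-11 autumn, 12-2 winter. Used for the
#' season covariate; overridable because the underlying convention is a
#' reporting choice, not biology.
#'
#' @return character vector of length 12, one season per month.
#' @export
default_season_mapping <- function() {
  c("winter", "winter", "spring", "spring", "spring", "summer", "summer",
    "summer", "autumn", "autumn", "autumn", "winter")
}

#' Map blood-draw month to season
#'
#' @param draw_month integer month(s) in 1..12.
#' @param mapping character vector of length 12 (month -> season label).
#' @return character vector of season labels.
#' @export
season_of <- function(draw_month, mapping = default_season_mapping()) {
  if (length(mapping) != 12L) stop("season mapping must have 12 entries")
  if (any(is.na(draw_month)) || any(draw_month < 1 | draw_month > 12) ||
      any(draw_month != floor(draw_month))) {
    stop("draw_month must be integers in 1..12")
  }
  mapping[draw_month]
}

#' Apply the two-stage subject-exclusion cascade
#'
#' Removes disease/medication-flagged subjects first, then abnormal-lab
#' flagged subjects among the survivors. Percentages in the report are of
#' the enrolled total, at one decimal (see [pct_one_dp()]).
#'
#' @param cohort data.frame with logical columns `excl_disease_medication`
#'   and `excl_abnormal_lab`.
#' @return list with `cohort` (survivors) and `report` (class
#'   `"exclusion_report"`).
#' @export
apply_exclusion_cascade <- function(cohort) {
  stop_if_not_cols(cohort, c("excl_disease_medication", "excl_abnormal_lab"))
  n0 <- nrow(cohort)
  s1 <- cohort[!cohort$excl_disease_medication, , drop = FALSE]
  n1 <- n0 - nrow(s1)
  s2 <- s1[!s1$excl_abnormal_lab, , drop = FALSE]
  n2 <- nrow(s1) - nrow(s2)
  if (nrow(s2) == 0L) {
    stop("empty cohort after exclusion cascade", call. = FALSE)
  }
  report <- structure(list(
    n_enrolled = n0,
    n_excluded_stage1 = n1,
    n_excluded_stage2 = n2,
    n_final = nrow(s2),
    pct_stage1 = pct_one_dp(n1 / n0),
    pct_stage2 = pct_one_dp(n2 / n0)
  ), class = "exclusion_report")
  list(cohort = s2, report = report)
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat(sprintf("Enrolled: %d\n", x$n_enrolled))
  cat(sprintf("Excluded, disease/medication: %d (%.1f%%)\n",
              x$n_excluded_stage1, x$pct_stage1))
  cat(sprintf("Excluded, abnormal labs:      %d (%.1f%%)\n",
              x$n_excluded_stage2, x$pct_stage2))
  cat(sprintf("Analysed: %d\n", x$n_final))
  invisible(x)
}

#' Single-pass extreme-value inclusion mask
#'
#' Marks values more than `z` sample SDs from the sample mean for exclusion.
#' The mean and SD are computed once on the full non-missing vector (single
#' pass, not iterative). Missing values stay missing — they are retained by
#' the mask, not excluded. A zero-variance vector keeps every value.
#'
#' @param values numeric vector.
#' @param z threshold in SD units (default 3.5).
#' @return logical mask, `TRUE` = keep.
#' @export
trim_extremes <- function(values, z = 3.5) {
  obs <- values[!is.na(values)]
  if (length(obs) < 2L) stop("need at least 2 non-missing values")
  m <- mean(obs)
  s <- sd(obs)
  keep <- rep(TRUE, length(values))
  if (s > 0) {
    idx <- !is.na(values)
    keep[idx] <- abs(values[idx] - m) / s <= z
  }
  keep
}

#' Add natural-log versions of skewed variables
#'
#' Appends `<var><suffix>` columns with the natural log of each listed
#' variable; originals are retained. The default list is the study's
#' skewed panel: total 25OHD, PTH, Beta-CTX and P1NP.
#'
#' @param cohort data.frame.
#' @param variables character vector of column names to transform.
#' @param suffix appended to the new column names.
#' @return the cohort with the log columns added.
#' @export
log_transform_skewed <- function(cohort,
                                 variables = c("total_25ohd", "pth",
                                               "beta_ctx", "p1np"),
                                 suffix = "_ln") {
  stop_if_not_cols(cohort, variables)
  for (v in variables) {
    x <- cohort[[v]]
    bad <- which(!is.na(x) & x <= 0)
    if (length(bad)) {
      ids <- if ("subject_id" %in% names(cohort)) {
        cohort$subject_id[bad]
      } else {
        bad
      }
      stop(sprintf("non-positive values of '%s' for subject(s): %s", v,
                   paste(utils::head(ids, 10), collapse = ", ")),
           call. = FALSE)
    }
    cohort[[paste0(v, suffix)]] <- log(x)
  }
  cohort
}

#' Descriptive summary table
#'
#' One row per variable with mean, SD, median, quartiles (linear
#' interpolation between order statistics), min and max, plus the reporting
#' branch: mean ± SD when |sample skewness| <= 1, median (Q1, Q3) otherwise.
#' The `formatted` column renders each variable in its branch's style.
#'
#' @param cohort data.frame.
#' @param variables columns to summarize (default: all numeric columns).
#' @return data.frame, one row per variable.
#' @export
summarize_cohort <- function(cohort, variables = NULL) {
  if (nrow(cohort) == 0L) stop("cannot summarize an empty cohort")
  if (is.null(variables)) {
    variables <- names(cohort)[vapply(cohort, is.numeric, logical(1))]
  }
  rows <- lapply(variables, function(v) {
    x <- cohort[[v]]
    x <- x[!is.na(x)]
    sk <- skewness(x)
    branch <- if (!is.na(sk) && abs(sk) > 1) "median_iqr" else "mean_sd"
    q <- quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(
      variable = v, n = length(x), branch = branch,
      mean = mean(x), sd = if (length(x) > 1) sd(x) else 0,
      median = q[2], q1 = q[1], q3 = q[3],
      min = min(x), max = max(x), skewness = sk,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$formatted <- ifelse(
    out$branch == "mean_sd",
    sprintf("%s ± %s", fmt_num(out$mean), fmt_num(out$sd)),
    sprintf("%s (%s–%s)", fmt_num(out$median), fmt_num(out$q1),
            fmt_num(out$q3))
  )
  out
}

#' Trim extreme values across the analysis variables
#'
#' Applies [trim_extremes()] per variable and sets trimmed values to `NA`
#' (subjects are then dropped per-analysis, not globally). Log-scale
#' variables are trimmed on their log columns.
#'
#' @param cohort data.frame (after [log_transform_skewed()]).
#' @param variables columns to trim.
#' @param z SD threshold.
#' @return list with `cohort` and `n_trimmed` (named counts per variable).
#' @export
trim_cohort <- function(cohort,
                        variables = c("total_25ohd_ln", "pth_ln",
                                      "beta_ctx_ln", "p1np_ln", "bmd_l1l4",
                                      "bmd_fn", "bmd_th", "age", "bmi",
                                      "dbp", "albumin", "ca", "p", "cr",
                                      "bun", "alp"),
                        z = 3.5) {
  variables <- intersect(variables, names(cohort))
  n_trimmed <- integer(0)
  for (v in variables) {
    keep <- trim_extremes(cohort[[v]], z = z)
    n_trimmed[v] <- sum(!keep)
    cohort[[v]][!keep] <- NA
    # keep the natural-scale twin consistent with its trimmed log column
    if (endsWith(v, "_ln")) {
      base <- sub("_ln$", "", v)
      if (base %in% names(cohort)) cohort[[base]][!keep] <- NA
    }
  }
  list(cohort = cohort, n_trimmed = n_trimmed)
}
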