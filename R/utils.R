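# Shared numeric and RNG helpers.

#' Round half away from zero
#'
#' Fixed-rule rounding used for all rendered tables, so that e.g. 0.0785
#' renders as 0.079 regardless of the platform's banker's rounding.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' One-decimal percentage for exclusion reporting
#'
#' Converts a proportion to a percentage with one decimal, rounding half away
#' from zero from the two-decimal value (i.e. 0.078490 -> 7.85 -> 7.9). The
#' two-step rule mirrors how such percentages are hand-transcribed in clinical
#' reports and is the convention used throughout the rendered tables.
#'
#' @param x proportion in \[0, 1\].
#' @return percentage rounded to one decimal.
#' @export
pct_one_dp <- function(x) {
  round_half_away(round_half_away(100 * x, 2), 1)
}

#' Sample skewness
#'
#' Moment-based skewness g1 = m3 / m2^(3/2); the shared normality rule
#' (|skewness| > 1 selects the nonparametric/median branch) is applied by
#' [summarize_cohort()] and [group_test()].
#'
#' @param x numeric vector; `NA`s dropped.
#' @return sample skewness (NA for fewer than 3 values or zero variance).
#' @export
skewness <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3L) return(NA_real_)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) return(NA_real_)
  mean((x - m)^3) / m2^1.5
}

# Deterministic per-module seed derived from the root seed: all randomness
# flows from one root through named substreams so each module can be
# regenerated independently. Kept below 2^31 - 1.
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  h <- 0
  for (k in utf8ToInt(name)) h <- (h * 131 + k) %% 1000003
  as.integer((abs(seed) %% 2000003) * 1009 + h) %% 2147483587L + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_cols <- function(df, cols, what = "cohort") {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}
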