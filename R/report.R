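# Number formatting and table rendering. Every rendered number is
# recoverable unrounded from the JSON bundle written by run_pipeline().

#' Formatting helpers for rendered tables
#'
#' `fmt_num` — general table value (3 decimals, trailing zeros trimmed for
#' integers-like values kept simple); `fmt_est` — estimates at 3 decimals;
#' `fmt_f` — F statistics at 2 decimals; `fmt_p` — p-values, scientific
#' notation below 0.001. All rounding is half away from zero.
#'
#' @param x numeric vector.
#' @return character vector.
#' @export
fmt_est <- function(x) sprintf("%.3f", round_half_away(x, 3))

#' @rdname fmt_est
#' @export
fmt_f <- function(x) sprintf("%.2f", round_half_away(x, 2))

#' @rdname fmt_est
#' @export
fmt_p <- function(x) {
  ifelse(is.na(x), "NA",
         ifelse(x < 0.001, sprintf("%.3E", x),
                sprintf("%.3f", round_half_away(x, 3))))
}

#' @rdname fmt_est
#' @export
fmt_num <- function(x) {
  out <- sprintf("%.3f", round_half_away(x, 3))
  big <- !is.na(x) & abs(x) >= 10
  out[big] <- sprintf("%.1f", round_half_away(x[big], 1))
  out
}

#' Render a descriptive (baseline-characteristics) table
#'
#' @param summary_df output of [summarize_cohort()].
#' @return data.frame with `variable`, `value` (formatted), `min`, `max`.
#' @export
render_table1 <- function(summary_df) {
  data.frame(variable = summary_df$variable,
             value = summary_df$formatted,
             min = fmt_num(summary_df$min),
             max = fmt_num(summary_df$max),
             stringsAsFactors = FALSE)
}

#' Render the MR battery in the causal-results table shape
#'
#' @param battery output of [run_mr_battery()].
#' @return data.frame with formatted beta, SE, p and Hausman p per row.
#' @export
render_mr_table <- function(battery) {
  data.frame(outcome = battery$outcome,
             model = battery$model,
             beta = fmt_est(battery$beta_tsls),
             se = fmt_est(battery$se_tsls),
             p = fmt_p(battery$p_tsls),
             hausman_p = fmt_p(battery$hausman_p_fdr),
             stringsAsFactors = FALSE)
}

#' Render the instrument-strength diagnostics table
#'
#' @param strength output of [instrument_strength_table()].
#' @return data.frame with formatted R2, F and relative bias.
#' @export
render_strength_table <- function(strength) {
  data.frame(model = strength$model,
             r2 = fmt_est(strength$r2),
             f = fmt_f(strength$f),
             relative_bias = fmt_est(strength$relative_bias),
             stringsAsFactors = FALSE)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
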