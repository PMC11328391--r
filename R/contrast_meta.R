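# Conventional contrast-based random-effects meta-analysis of the log odds
# ratio, sharing the pooling core with the arm-level proportion analysis.

#' Study-level log odds ratio from the 2x2 layout
#'
#' Orientation follows the prevention convention: OR < 1 means the
#' intervention reduces pneumonia. When any cell is zero, the continuity
#' correction (default 0.5) is added to all four cells; a study with no events
#' in either arm carries no information about the odds ratio and is reported
#' as excluded (`NULL`).
#'
#' @param tt A list or one-row data.frame with `tp`, `fn`, `fp`, `tn`
#'   (intervention events/non-events, control events/non-events) as produced
#'   by [to_dta_layout()].
#' @param correction Continuity correction, default 0.5.
#'
#' @return A list with `y` (log OR), `v` (variance, sum of reciprocal cells),
#'   `study_id`; or `NULL` for a double-zero study.
#' @export
study_log_or <- function(tt, correction = 0.5) {
  cells <- c(tt$tp, tt$fn, tt$fp, tt$tn)
  stopifnot(length(cells) == 4, all(cells >= 0))
  if (tt$tp == 0 && tt$fp == 0) {
    message("study ", tt$study_id %||% "?",
            " excluded: no events in either arm")
    return(NULL)
  }
  if (any(cells == 0)) cells <- cells + correction
  list(
    y = log((cells[1] * cells[4]) / (cells[2] * cells[3])),
    v = sum(1 / cells),
    study_id = as.character(tt$study_id %||% NA)
  )
}

#' Pool study log odds ratios
#'
#' Applies the same random-effects pooling machinery as [pool_arms()] to log
#' odds-ratio effects and reports the summary on the odds-ratio scale.
#'
#' @param effects List of effects from [study_log_or()] (`NULL` entries from
#'   excluded studies are dropped).
#' @param tau2_method `"REML"` (default) or `"DL"`.
#' @param level Confidence level.
#'
#' @return An object of class `contrast_pooled`: `k`, `or_summary`, `ci95`
#'   (OR scale), `Q`, `df`, `tau2`, `I2`, `H2`, with the log-scale panel under
#'   `$logor`.
#' @export
pool_log_or <- function(effects, tau2_method = c("REML", "DL"), level = 0.95) {
  effects <- Filter(Negate(is.null), effects)
  y <- vapply(effects, `[[`, numeric(1), "y")
  v <- vapply(effects, `[[`, numeric(1), "v")
  p <- pool_effects(y, v, tau2_method = tau2_method, level = level)
  structure(list(
    k = p$k,
    or_summary = exp(p$est),
    ci95 = exp(p$ci),
    pi95 = exp(p$pi),
    Q = p$Q, df = p$df, tau2 = p$tau2, I2 = p$I2, H2 = p$H2,
    logor = p
  ), class = "contrast_pooled")
}

#' @export
print.contrast_pooled <- function(x, ...) {
  cat(sprintf("<contrast_pooled> k=%d  OR %.2f (95%% CI %.2f-%.2f)\n",
              x$k, x$or_summary, x$ci95[1], x$ci95[2]))
  cat(sprintf("  Q=%.1f (df=%d)  tau2=%.3f  I2=%.1f%%  H2=%.1f\n",
              x$Q, x$df, x$tau2, x$I2, x$H2))
  invisible(x)
}

#' Contrast-based meta-analysis of an arm table
#'
#' Convenience wrapper: splits shared control groups across comparisons
#' (`dedupe_control_arms(mode = "split")` so no control patient is counted
#' twice), builds the 2x2 layout, and pools the log odds ratios.
#'
#' @param table An [arm_table].
#' @inheritParams pool_log_or
#' @return A `contrast_pooled` object.
#' @export
contrast_meta <- function(table, tau2_method = "REML", level = 0.95) {
  tab <- dedupe_control_arms(table, mode = "split")
  layout <- to_dta_layout(tab)
  effects <- lapply(seq_len(nrow(layout)), function(i) {
    study_log_or(layout[i, ])
  })
  pool_log_or(effects, tau2_method = tau2_method, level = level)
}
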