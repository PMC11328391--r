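# Publication-style figures: SROC plot with ellipses/curve/summary point and
# benchmark band, caterpillar plot of arm incidences, and L'Abbe plot.
# Each builder returns a ggplot whose underlying coordinates are attached as
# attribute "plot_data", so figures are testable (and exportable as sidecar
# CSV) without image comparison.

#' @importFrom ggplot2 ggplot aes geom_point geom_path geom_abline geom_line
#'   geom_errorbarh geom_rect geom_segment annotate labs coord_cartesian
#'   theme_minimal scale_size_area ggsave
NULL

#' SROC-style plot of paired arm incidences
#'
#' Scatter of control incidence (x, playing 1 - "specificity") against
#' intervention incidence (y, playing "sensitivity"), one point per study,
#' with the y = x no-effect diagonal, the summary point, 95% confidence and
#' prediction ellipses, the summary ROC curve, and an optional vertical
#' benchmark band.
#'
#' @param fit A converged [fit_bivariate()].
#' @param table Optional [arm_table] supplying per-study points; defaults to
#'   the data stored in the fit.
#' @param benchmark Optional [benchmark_range()] drawn as a vertical band.
#' @param show_curve,show_conf_ellipse,show_pred_ellipse,show_summary_point,
#'   show_diag_line Layer switches.
#' @param symbol_scale `"proportional_to_n"` (symbol area proportional to
#'   total group size) or `"fixed"`.
#' @return A ggplot; study coordinates in `attr(, "plot_data")`.
#' @export
plot_sroc <- function(fit, table = NULL, benchmark = NULL,
                      show_curve = TRUE, show_conf_ellipse = TRUE,
                      show_pred_ellipse = TRUE, show_summary_point = TRUE,
                      show_diag_line = TRUE,
                      symbol_scale = c("proportional_to_n", "fixed")) {
  symbol_scale <- match.arg(symbol_scale)
  pairs <- if (is.null(table)) fit$data else to_dta_layout(table)
  pts <- data.frame(
    study_id = pairs$study_id %||% seq_len(nrow(pairs)),
    x = pairs$fp / (pairs$fp + pairs$tn),
    y = pairs$tp / (pairs$tp + pairs$fn),
    n = pairs$tp + pairs$fn + pairs$fp + pairs$tn
  )

  p <- ggplot2::ggplot(pts, ggplot2::aes(x = x, y = y)) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1), expand = FALSE) +
    ggplot2::labs(
      x = "Control group incidence (as 1 - 'specificity')",
      y = "Intervention group incidence (as 'sensitivity')"
    ) +
    ggplot2::theme_minimal()

  if (!is.null(benchmark)) {
    p <- p + ggplot2::annotate("rect", xmin = benchmark$lo, xmax = benchmark$hi,
                               ymin = 0, ymax = 1, alpha = 0.08, fill = "orange")
  }
  if (show_diag_line) {
    p <- p + ggplot2::geom_abline(slope = 1, intercept = 0,
                                  linetype = "dashed", colour = "grey40")
  }
  p <- if (symbol_scale == "proportional_to_n") {
    p + ggplot2::geom_point(ggplot2::aes(size = n), alpha = 0.6,
                            colour = "steelblue") +
      ggplot2::scale_size_area(max_size = 8)
  } else {
    p + ggplot2::geom_point(alpha = 0.6, colour = "steelblue")
  }
  if (show_pred_ellipse) {
    pe <- prediction_ellipse(fit)
    p <- p + ggplot2::geom_path(data = as.data.frame(pe), colour = "purple",
                                linetype = "dotted")
  }
  if (show_conf_ellipse) {
    ce <- confidence_ellipse(fit)
    p <- p + ggplot2::geom_path(data = as.data.frame(ce), colour = "red",
                                linetype = "dotted")
  }
  if (show_curve) {
    cu <- sroc_curve(fit)
    p <- p + ggplot2::geom_line(data = as.data.frame(cu), colour = "darkgreen")
  }
  if (show_summary_point) {
    p <- p + ggplot2::annotate("point", x = expit(fit$mu_C), y = expit(fit$mu_I),
                               shape = 15, colour = "red", size = 3)
  }
  attr(p, "plot_data") <- pts
  p
}

#' Caterpillar plot of arm incidences
#'
#' Forest-style plot of per-group incidence with exact (Clopper-Pearson) 95%
#' binomial confidence intervals, canonically ordered by increasing incidence
#' regardless of input order, with an optional benchmark band.
#'
#' @param arms Data.frame of arm records (columns `study_id`, `events`,
#'   `total`), e.g. the control rows of an [arm_table].
#' @param benchmark Optional [benchmark_range()].
#' @return A ggplot; the sorted coordinates in `attr(, "plot_data")`.
#' @export
plot_caterpillar <- function(arms, benchmark = NULL) {
  stopifnot(nrow(arms) >= 1)
  ci <- t(mapply(function(e, n) {
    lo <- if (e == 0) 0 else stats::qbeta(0.025, e, n - e + 1)
    hi <- if (e == n) 1 else stats::qbeta(0.975, e + 1, n - e)
    c(lo, hi)
  }, arms$events, arms$total))
  df <- data.frame(
    study_id = arms$study_id, inc = arms$events / arms$total,
    lo = ci[, 1], hi = ci[, 2]
  )
  df <- df[order(df$inc, df$study_id), ]
  df$rank <- seq_len(nrow(df))

  p <- ggplot2::ggplot(df, ggplot2::aes(x = inc, y = rank)) +
    ggplot2::labs(x = "Incidence", y = "Groups (ordered by incidence)") +
    ggplot2::theme_minimal()
  if (!is.null(benchmark)) {
    p <- p + ggplot2::annotate("rect", xmin = benchmark$lo, xmax = benchmark$hi,
                               ymin = 0, ymax = nrow(df) + 1,
                               alpha = 0.08, fill = "orange")
  }
  p <- p +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = lo, xmax = hi), height = 0,
                            colour = "grey55") +
    ggplot2::geom_point(size = 1, colour = "steelblue") +
    ggplot2::coord_cartesian(xlim = c(0, 1))
  attr(p, "plot_data") <- df
  p
}

#' Iso-effect locus for a L'Abbe plot
#'
#' The locus of (control incidence x, intervention incidence y) sharing one
#' effect size: `y = x + d` for a risk difference, `y = r x` for a risk
#' ratio, and `y = o x / (1 - x + o x)` for an odds ratio.
#'
#' @param es_type `"OR"`, `"RR"` or `"RD"`.
#' @param es_value The effect size (odds ratio, risk ratio, or risk
#'   difference).
#' @param x Control incidences at which to evaluate.
#' @return Data.frame with `x` and `y` (clamped to `[0, 1]`).
#' @export
labbe_locus <- function(es_type = c("OR", "RR", "RD"), es_value,
                        x = seq(0.001, 0.999, length.out = 200)) {
  es_type <- match.arg(es_type)
  y <- switch(es_type,
    RD = x + es_value,
    RR = es_value * x,
    OR = es_value * x / (1 - x + es_value * x)
  )
  data.frame(x = x, y = clamp(y, 0, 1))
}

#' L'Abbe plot with an iso-effect locus
#'
#' @param table An [arm_table] (one control and one intervention arm per
#'   study).
#' @param es_type,es_value Effect measure and value for the iso-effect locus
#'   (see [labbe_locus()]).
#' @return A ggplot; study coordinates in `attr(, "plot_data")`.
#' @export
plot_labbe <- function(table, es_type = "OR", es_value = 1) {
  pairs <- to_dta_layout(table)
  pts <- data.frame(
    study_id = pairs$study_id,
    x = pairs$fp / (pairs$fp + pairs$tn),
    y = pairs$tp / (pairs$tp + pairs$fn),
    n = pairs$tp + pairs$fn + pairs$fp + pairs$tn
  )
  locus <- labbe_locus(es_type, es_value)
  p <- ggplot2::ggplot(pts, ggplot2::aes(x = x, y = y)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey40") +
    ggplot2::geom_line(data = locus, colour = "darkred") +
    ggplot2::geom_point(ggplot2::aes(size = n), alpha = 0.6,
                        colour = "steelblue") +
    ggplot2::scale_size_area(max_size = 8) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1), expand = FALSE) +
    ggplot2::labs(x = "Control group incidence",
                  y = "Intervention group incidence",
                  title = sprintf("L'Abbe plot (%s = %.3g)", es_type, es_value)) +
    ggplot2::theme_minimal()
  attr(p, "plot_data") <- pts
  p
}

#' Save a figure with its sidecar coordinate CSV
#'
#' Writes the image (format from the file extension, png or svg) and a
#' `<path>.csv` sidecar holding the plotted coordinates so the figure can be
#' regenerated or checked without image comparison.
#'
#' @param plot A ggplot from this package (carrying `attr(, "plot_data")`).
#' @param path Image path ending in `.png` or `.svg`.
#' @param width,height Device size in inches.
#' @return `path`, invisibly.
#' @export
save_plot_with_data <- function(plot, path, width = 6, height = 5) {
  ggplot2::ggsave(path, plot, width = width, height = height, dpi = 150)
  pd <- attr(plot, "plot_data")
  if (!is.null(pd)) {
    utils::write.csv(pd, paste0(path, ".csv"), row.names = FALSE)
  }
  invisible(path)
}
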