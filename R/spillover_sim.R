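# Count-perturbation spillover simulation engine: inject uniform or partial,
# positive or negative spillover into observed control-arm counts and
# recompute the arm-level, contrast-based and bivariate summaries.

#' Specify a spillover perturbation scenario
#'
#' @param direction `"positive"` (events added to control arms, mimicking
#'   harmful spillover) or `"negative"` (events removed, beneficial).
#' @param delta_per_100 Events added/removed per 100 control-group patients
#'   (> 0). The grid 2.5 / 5 / 10 / 20 reproduces the published scenarios,
#'   but any positive value is legal.
#' @param coverage_fraction Fraction of control groups perturbed, in (0, 1];
#'   1 = uniform spillover.
#' @param seed Seed for the random selection of control groups when
#'   `coverage_fraction < 1`.
#' @param label Optional scenario label for tables.
#'
#' @return A list of class `spillover_scenario`.
#' @export
spillover_scenario <- function(direction = c("positive", "negative"),
                               delta_per_100, coverage_fraction = 1,
                               seed = 1L, label = NULL) {
  direction <- match.arg(direction)
  stopifnot(delta_per_100 > 0, coverage_fraction > 0, coverage_fraction <= 1)
  if (is.null(label)) {
    label <- sprintf(
      "%s%.3g spillover%s",
      if (direction == "positive") "+" else "-", delta_per_100 / 100,
      if (coverage_fraction < 1) {
        sprintf(" (%.3g of groups)", coverage_fraction)
      } else {
        ""
      }
    )
  }
  structure(list(
    direction = direction, delta_per_100 = delta_per_100,
    coverage_fraction = coverage_fraction, seed = as.integer(seed),
    label = label
  ), class = "spillover_scenario")
}

#' The published eight-scenario spillover grid
#'
#' Uniform positive spillover of +2.5, +5 and +10 events per 100 control
#' patients; partial positive spillover of +10 in half, +10 in a quarter and
#' +20 in a quarter of control groups; uniform negative spillover of -2.5 and
#' -5.
#'
#' @param seed Seed used for the partial-coverage random selections.
#' @return List of [spillover_scenario()] objects.
#' @export
default_scenario_grid <- function(seed = 1L) {
  list(
    spillover_scenario("positive", 2.5, 1, seed),
    spillover_scenario("positive", 5, 1, seed),
    spillover_scenario("positive", 10, 1, seed),
    spillover_scenario("positive", 10, 0.5, seed,
                       label = "+0.1 spillover (half)"),
    spillover_scenario("positive", 10, 0.25, seed,
                       label = "+0.1 spillover (quarter)"),
    spillover_scenario("positive", 20, 0.25, seed,
                       label = "+0.2 spillover (quarter)"),
    spillover_scenario("negative", 2.5, 1, seed),
    spillover_scenario("negative", 5, 1, seed)
  )
}

#' Apply a spillover perturbation to control-arm counts
#'
#' For each selected control arm the event count becomes
#' `clamp(events +/- round_half_away(delta_per_100 * total / 100), 0, total)`
#' (rounding half away from zero); totals and intervention arms are untouched.
#' When `coverage_fraction < 1`, `round(coverage_fraction * k)` control groups
#' are selected without replacement using the scenario seed; uniform coverage
#' is seed-free. Clamped arms are reported in a message.
#'
#' @param table An [arm_table] (the no-spillover baseline).
#' @param scenario A [spillover_scenario()].
#'
#' @return A list with `table` (the perturbed [arm_table]) and `affected`
#'   (character vector of perturbed study_ids).
#' @export
apply_spillover <- function(table, scenario) {
  stopifnot(inherits(scenario, "spillover_scenario"))
  df <- as.data.frame(table)
  ctrl_idx <- which(df$arm_role == "control")
  k <- length(ctrl_idx)
  if (scenario$coverage_fraction < 1) {
    n_sel <- round(scenario$coverage_fraction * k)
    sel <- ctrl_idx[with_seed(scenario$seed, sample.int(k, n_sel))]
  } else {
    sel <- ctrl_idx
  }
  sign <- if (scenario$direction == "positive") 1 else -1
  add <- sign * round_half_away(scenario$delta_per_100 * df$total[sel] / 100)
  new_events <- df$events[sel] + add
  clamped <- new_events < 0 | new_events > df$total[sel]
  if (any(clamped)) {
    message(sum(clamped), " control arm(s) clamped to [0, total] under ",
            scenario$label)
  }
  df$events[sel] <- as.integer(clamp(new_events, 0, df$total[sel]))
  list(
    table = arm_table(df, provenance = paste0(
      attr(table, "provenance") %||% "", " + ", scenario$label
    )),
    affected = sort(unique(df$study_id[sel]))
  )
}

#' Run a grid of spillover scenarios
#'
#' For the baseline table and after each perturbation, recomputes the pooled
#' control-arm logit proportion ([pool_arms()]), the contrast-based pooled
#' odds ratio ([contrast_meta()]) and, optionally, the bivariate model and
#' its summary odds ratio. A failing stage is recorded for its scenario
#' without aborting the rest of the grid.
#'
#' @param table The no-spillover baseline [arm_table].
#' @param scenarios List of [spillover_scenario()]; default the published
#'   eight-scenario grid.
#' @param fit_bivariate_model Fit the bivariate model per scenario (slower);
#'   default TRUE.
#' @param tau2_method Passed to the pooling functions.
#'
#' @return A list of class `scenario_grid`: per scenario a list with
#'   `scenario`, `pooled_ctrl`, `contrast`, `bivariate` (or NULL),
#'   `affected_studies`, `error` (NULL unless a stage failed); the baseline
#'   row comes first. `as.data.frame()` renders the results table.
#' @export
run_scenario_grid <- function(table, scenarios = default_scenario_grid(),
                              fit_bivariate_model = TRUE,
                              tau2_method = "REML") {
  run_one <- function(tab, label, affected) {
    res <- list(label = label, affected_studies = affected,
                pooled_ctrl = NULL, contrast = NULL, bivariate = NULL,
                error = NULL)
    tryCatch({
      ctrl <- tab[tab$arm_role == "control", ]
      eff <- Map(logit_effect, ctrl$events, ctrl$total,
                 study_id = ctrl$study_id)
      res$pooled_ctrl <- pool_arms(eff, tau2_method = tau2_method)
      res$contrast <- contrast_meta(tab, tau2_method = tau2_method)
      if (fit_bivariate_model) {
        res$bivariate <- fit_bivariate(to_dta_layout(
          dedupe_control_arms(tab, "include_once")
        ))
      }
    }, error = function(e) res$error <<- conditionMessage(e))
    res
  }

  out <- list(run_one(table, "No spillover", character(0)))
  for (sc in scenarios) {
    pert <- apply_spillover(table, sc)
    row <- run_one(pert$table, sc$label, pert$affected)
    row$scenario <- sc
    out[[length(out) + 1]] <- row
  }
  class(out) <- "scenario_grid"
  out
}

#' @export
as.data.frame.scenario_grid <- function(x, ...) {
  rows <- lapply(x, function(r) {
    pc <- r$pooled_ctrl
    ct <- r$contrast
    dor <- if (!is.null(r$bivariate) && r$bivariate$converged) {
      summary_dor(r$bivariate)
    } else {
      list(or = NA_real_, ci95 = c(NA_real_, NA_real_))
    }
    data.frame(
      scenario = r$label,
      or = if (is.null(ct)) NA else ct$or_summary,
      or_lo = if (is.null(ct)) NA else ct$ci95[1],
      or_hi = if (is.null(ct)) NA else ct$ci95[2],
      dor = dor$or, dor_lo = dor$ci95[1], dor_hi = dor$ci95[2],
      summary_prop = if (is.null(pc)) NA else pc$summary_prop,
      se_logit = if (is.null(pc)) NA else pc$se_logit,
      ci_lo = if (is.null(pc)) NA else pc$ci95[1],
      ci_hi = if (is.null(pc)) NA else pc$ci95[2],
      Q = if (is.null(pc)) NA else pc$Q,
      df = if (is.null(pc)) NA else pc$df,
      tau2 = if (is.null(pc)) NA else pc$tau2,
      I2 = if (is.null(pc)) NA else pc$I2,
      H2 = if (is.null(pc)) NA else pc$H2,
      pi_lo = if (is.null(pc)) NA else pc$pi95[1],
      pi_hi = if (is.null(pc)) NA else pc$pi95[2],
      n_affected = length(r$affected_studies),
      error = if (is.null(r$error)) "" else r$error,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
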