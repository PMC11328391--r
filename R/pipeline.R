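# Full-analysis orchestration: generate or ingest the arm tables, run the
# arm-level and contrast-based meta-analyses, fit the bivariate model per
# category, run the spillover scenario grid, issue the diagnosis, and write
# tables, figures and a run log to an output directory.

#' Run the complete spillover analysis
#'
#' Executes the whole workflow on synthetic cohorts (default) or on a
#' user-supplied arm-level CSV, writing:
#'
#' * `table1.csv` — per category: contrast-based pooled OR with
#'   heterogeneity, and the bivariate summary (diagnostic) OR;
#' * `table2.csv` — arm-level pooled incidences and heterogeneity
#'   (overall + per category x arm role);
#' * `table3.csv` — the spillover scenario grid run on the
#'   reference (no-spillover) category;
#' * `diagnosis.json` — the three-comparator spillover verdict for the
#'   scrutinized category;
#' * `figures/` — SROC plots per category, caterpillar and L'Abbe plots,
#'   each with a sidecar coordinate CSV;
#' * `run.log` — seed, package version, and every default in effect.
#'
#' @param output_dir Directory to create/write into.
#' @param input `"synthetic"` (default) or a path to an arm-level CSV read by
#'   [read_arm_table()].
#' @param cohort_specs Named list of [cohort_spec()] used when
#'   `input = "synthetic"`; default [default_cohort_specs()] seeded from
#'   `seed`.
#' @param seed Global seed; per-stage seeds are derived from it.
#' @param scrutiny_category Category diagnosed for spillover (default
#'   `"antimicrobial"`), compared against `reference_category` (default
#'   `"non_antimicrobial"`).
#' @param reference_category See above.
#' @param scenarios Spillover scenario list for the grid; default
#'   [default_scenario_grid()].
#' @param benchmark A [benchmark_range()].
#' @param thresholds Diagnosis thresholds, default [diagnosis_thresholds()].
#' @param tau2_method `"REML"` or `"DL"`.
#' @param make_figures Set `FALSE` to skip figure rendering.
#'
#' @return Invisibly, a list with all fitted objects (`tables`, `arm_summary`,
#'   `contrast`, `bivariate`, `grid`, `diagnosis`) and the output paths.
#' @export
run_full_analysis <- function(output_dir,
                              input = "synthetic",
                              cohort_specs = NULL,
                              seed = 2024L,
                              scrutiny_category = "antimicrobial",
                              reference_category = "non_antimicrobial",
                              scenarios = NULL,
                              benchmark = benchmark_range("liberal"),
                              thresholds = diagnosis_thresholds(),
                              tau2_method = "REML",
                              make_figures = TRUE) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  fig_dir <- file.path(output_dir, "figures")
  if (make_figures) dir.create(fig_dir, showWarnings = FALSE)
  log_path <- file.path(output_dir, "run.log")
  logf <- function(...) {
    cat(sprintf(...), "\n", sep = "", file = log_path, append = TRUE)
  }
  cat("", file = log_path)
  logf("spillroc %s | seed=%d | input=%s | tau2_method=%s | benchmark=%s",
       as.character(utils::packageVersion("spillroc")), seed, input,
       tau2_method, benchmark$label)

  # ---- data ----
  if (identical(input, "synthetic")) {
    if (is.null(cohort_specs)) cohort_specs <- default_cohort_specs(seed)
    cohorts <- lapply(cohort_specs, generate_cohort)
    tab <- do.call(rbind, lapply(cohorts, function(co) as.data.frame(co$table)))
    table_all <- arm_table(tab, provenance = "synthetic cohorts")
    for (nm in names(cohort_specs)) {
      logf("cohort %s: k=%d condition=%s seed=%d", nm,
           cohort_specs[[nm]]$k_studies, cohort_specs[[nm]]$condition,
           cohort_specs[[nm]]$seed)
    }
  } else {
    table_all <- read_arm_table(input)
    logf("read %d arms from %s", nrow(table_all), input)
  }
  categories <- intersect(ARM_CATEGORIES, unique(table_all$category))
  if (!scrutiny_category %in% categories) {
    stop("scrutiny category '", scrutiny_category, "' absent from the data")
  }

  table_once <- dedupe_control_arms(table_all, "include_once")

  # ---- arm-level summary (table2) ----
  arm_tab <- arm_summary_table(table_once, grouping = "category",
                               tau2_method = tau2_method)
  utils::write.csv(arm_tab, file.path(output_dir, "table2.csv"),
                   row.names = FALSE)
  pooled <- attr(arm_tab, "pooled")

  # ---- contrast + bivariate per category (table1) ----
  contrast <- list()
  bivar <- list()
  rows <- list()
  for (cat_i in categories) {
    sub <- table_all[table_all$category == cat_i, ]
    sub <- arm_table(as.data.frame(sub), provenance = cat_i)
    ct <- contrast_meta(sub, tau2_method = tau2_method)
    bv <- fit_bivariate(to_dta_layout(dedupe_control_arms(sub, "include_once")))
    dor <- summary_dor(bv)
    contrast[[cat_i]] <- ct
    bivar[[cat_i]] <- bv
    rows[[cat_i]] <- data.frame(
      category = cat_i, k = ct$k,
      or = ct$or_summary, or_lo = ct$ci95[1], or_hi = ct$ci95[2],
      Q = ct$Q, df = ct$df, tau2 = ct$tau2, I2 = ct$I2, H2 = ct$H2,
      dor = dor$or, dor_lo = dor$ci95[1], dor_hi = dor$ci95[2],
      bivar_converged = bv$converged
    )
    logf("category %s: contrast OR %.3f (%.3f-%.3f), DOR %.3f (%.3f-%.3f)",
         cat_i, ct$or_summary, ct$ci95[1], ct$ci95[2], dor$or, dor$ci95[1],
         dor$ci95[2])
  }
  table1 <- do.call(rbind, rows)
  rownames(table1) <- NULL
  utils::write.csv(table1, file.path(output_dir, "table1.csv"),
                   row.names = FALSE)

  # ---- spillover grid on the reference category (table3) ----
  grid <- NULL
  if (reference_category %in% categories) {
    ref_tab <- arm_table(
      as.data.frame(table_all[table_all$category == reference_category, ]),
      provenance = reference_category
    )
    if (is.null(scenarios)) {
      scenarios <- default_scenario_grid(derive_seed(seed, "spillover"))
    }
    grid <- run_scenario_grid(ref_tab, scenarios, tau2_method = tau2_method)
    utils::write.csv(as.data.frame(grid), file.path(output_dir, "table3.csv"),
                     row.names = FALSE)
  }

  # ---- diagnosis ----
  key <- function(g, role) paste(g, role, sep = ".")
  diag <- NULL
  tc <- pooled[[key(scrutiny_category, "control")]]
  ti <- pooled[[key(scrutiny_category, "intervention")]]
  rc <- pooled[[key(reference_category, "control")]]
  if (!is.null(tc) && !is.null(ti)) {
    diag <- diagnose_spillover(tc, ti, reference_ctrl = rc,
                               range = benchmark, thresholds = thresholds)
    diagnosis_to_json(diag, file.path(output_dir, "diagnosis.json"))
    logf("diagnosis: %s", diag$verdict)
  } else {
    logf("diagnosis skipped: scrutiny category rows uncomputable (k < 2)")
  }

  # ---- figures ----
  if (make_figures) {
    for (cat_i in categories) {
      bv <- bivar[[cat_i]]
      if (isTRUE(bv$converged)) {
        save_plot_with_data(
          plot_sroc(bv, benchmark = benchmark),
          file.path(fig_dir, paste0("sroc_", cat_i, ".png"))
        )
      }
    }
    ctrl_scrut <- table_once[table_once$arm_role == "control" &
                               table_once$category == scrutiny_category, ]
    if (nrow(ctrl_scrut) >= 1) {
      save_plot_with_data(
        plot_caterpillar(ctrl_scrut, benchmark = benchmark),
        file.path(fig_dir, "caterpillar_control.png")
      )
    }
    scrut_tab <- arm_table(
      as.data.frame(table_once[table_once$category == scrutiny_category, ]),
      provenance = scrutiny_category
    )
    or_est <- contrast[[scrutiny_category]]$or_summary
    save_plot_with_data(
      plot_labbe(scrut_tab, es_type = "OR", es_value = or_est),
      file.path(fig_dir, "labbe.png")
    )
  }

  logf("done")
  invisible(list(
    table = table_all, arm_summary = arm_tab, contrast = contrast,
    bivariate = bivar, table1 = table1, grid = grid, diagnosis = diag,
    output_dir = output_dir
  ))
}
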