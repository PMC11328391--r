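#!/usr/bin/env Rscript
# Step 2 — arm-level meta-analysis of incidence proportions.
#
# Pools the logit-transformed incidences per category and arm role (controls
# separately from interventions), reporting summary proportion, Q, tau2, I2,
# H2 and the 95% prediction interval. This is the arm-based view that makes
# control-group dispersion — the footprint of spillover — visible at all.
# Reads results/cohorts/*.csv (step 1) and writes results/table2.csv plus a
# caterpillar plot of the antimicrobial control groups.

suppressPackageStartupMessages(library(spillroc))

in_dir <- file.path("results", "cohorts")
stopifnot(dir.exists(in_dir))
files <- list.files(in_dir, pattern = "\\.csv$", full.names = TRUE)
tabs <- lapply(files[!grepl("_truth", files)], read_arm_table)
corpus <- arm_table(do.call(rbind, lapply(tabs, as.data.frame)))
corpus <- dedupe_control_arms(corpus, "include_once")

out <- arm_summary_table(corpus, grouping = "category")
utils::write.csv(out, file.path("results", "table2.csv"), row.names = FALSE)

fmt <- out
num <- vapply(fmt, is.numeric, logical(1))
fmt[num] <- lapply(fmt[num], round, 2)
print(fmt[, c("group", "arm_role", "k", "summary_prop", "tau2", "I2", "H2",
              "pi_lo", "pi_hi")], row.names = FALSE)

ctrl_anti <- corpus[corpus$arm_role == "control" &
                      corpus$category == "antimicrobial", ]
save_plot_with_data(
  plot_caterpillar(ctrl_anti, benchmark = benchmark_range("liberal")),
  file.path("results", "caterpillar_antimicrobial_control.png")
)

anti_ctrl <- out[out$group == "antimicrobial" & out$arm_role == "control", ]
anti_int <- out[out$group == "antimicrobial" & out$arm_role == "intervention", ]
cat(sprintf(
  "\nantimicrobial control groups: tau2 %.2f vs intervention %.2f (ratio %.2f); control 95%% PI %.0f-%.0f%%\n",
  anti_ctrl$tau2, anti_int$tau2, anti_ctrl$tau2 / anti_int$tau2,
  anti_ctrl$pi_lo, anti_ctrl$pi_hi
))
cat("arm-level summary written to results/table2.csv\n")
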