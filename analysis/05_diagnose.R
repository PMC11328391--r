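#!/usr/bin/env Rscript
# Step 5 — three-comparator spillover diagnosis.
#
# Applies the rule-based verdict to the antimicrobial category: control-group
# dispersion compared (1) to the category's own intervention groups, (2) to
# the control groups of the non-antimicrobial reference, and (3) to the
# clinically relevant incidence benchmark (5-40%). Also reports how many
# groups of each arm fall below / within / above the benchmark.
# Reads results/cohorts/*.csv and writes results/diagnosis.json.

suppressPackageStartupMessages(library(spillroc))

in_dir <- file.path("results", "cohorts")
anti <- read_arm_table(file.path(in_dir, "antimicrobial.csv"))
ref <- read_arm_table(file.path(in_dir, "non_antimicrobial.csv"))

pool_role <- function(tab, role) {
  sub <- tab[tab$arm_role == role, ]
  pool_arms(Map(logit_effect, sub$events, sub$total, study_id = sub$study_id))
}

rng <- benchmark_range("liberal")
report <- diagnose_spillover(
  target_ctrl = pool_role(anti, "control"),
  target_int = pool_role(anti, "intervention"),
  reference_ctrl = pool_role(ref, "control"),
  range = rng
)
print(report)
cat("\nbenchmark coverage (control arms): ")
print(report$range_counts$control)
cat("benchmark coverage (intervention arms): ")
print(report$range_counts$intervention)

diagnosis_to_json(report, file.path("results", "diagnosis.json"))
cat("verdict written to results/diagnosis.json\n")
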