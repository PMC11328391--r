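# Count-perturbation engine: arithmetic, clamping, selection, conservation,
# grid behaviour.

test_that("perturbation adds the rounded count and clamps at the support", {
  tab <- arm_table(data.frame(
    study_id = rep(c("A", "B"), each = 2), review_id = "r",
    category = "non_antimicrobial", subcategory = "s",
    arm_role = rep(c("control", "intervention"), 2),
    events = c(10, 4, 1, 3), total = c(200, 200, 40, 40),
    shared_control_of = NA
  ))
  up <- apply_spillover(tab, spillover_scenario("positive", 2.5))
  expect_equal(up$table$events[up$table$study_id == "A" &
                                 up$table$arm_role == "control"], 15L)
  # intervention arms and totals untouched
  expect_equal(up$table$events[up$table$arm_role == "intervention"], c(4L, 3L))
  expect_equal(up$table$total, tab$total)

  # negative spillover clamps at zero with a message
  expect_message(
    dn <- apply_spillover(tab, spillover_scenario("negative", 5)),
    "clamped"
  )
  expect_equal(dn$table$events[dn$table$study_id == "B" &
                                 dn$table$arm_role == "control"], 0L)

  # rounding is half away from zero: 2.5/100 * 50 = 1.25 -> 1; *60 = 1.5 -> 2
  tab2 <- arm_table(data.frame(
    study_id = rep(c("C", "D"), each = 2), review_id = "r",
    category = "non_antimicrobial", subcategory = "s",
    arm_role = rep(c("control", "intervention"), 2),
    events = c(5, 5, 5, 5), total = c(50, 50, 60, 60),
    shared_control_of = NA
  ))
  up2 <- apply_spillover(tab2, spillover_scenario("positive", 2.5))
  expect_equal(up2$table$events[up2$table$arm_role == "control"], c(6L, 7L))
})

test_that("uniform coverage is seed-free; partial selection is seeded", {
  spec <- cohort_spec(k_studies = 40, seed = 15)
  tab <- generate_cohort(spec)$table
  u1 <- apply_spillover(tab, spillover_scenario("positive", 10, 1, seed = 1))
  u2 <- apply_spillover(tab, spillover_scenario("positive", 10, 1, seed = 999))
  expect_identical(u1$table, u2$table)
  expect_equal(length(u1$affected), 40L)

  p1 <- apply_spillover(tab, spillover_scenario("positive", 10, 0.25, seed = 7))
  p2 <- apply_spillover(tab, spillover_scenario("positive", 10, 0.25, seed = 7))
  p3 <- apply_spillover(tab, spillover_scenario("positive", 10, 0.25, seed = 8))
  expect_identical(p1$table, p2$table)
  expect_equal(length(p1$affected), 10L)  # round(0.25 * 40)
  expect_false(identical(p1$affected, p3$affected))
})

test_that("perturbation conserves totals and changes only selected controls", {
  spec <- cohort_spec(k_studies = 60, seed = 21)
  tab <- generate_cohort(spec)$table
  sc <- spillover_scenario("positive", 10, 0.5, seed = 3)
  out <- apply_spillover(tab, sc)
  expect_equal(out$table$total, tab$total)
  changed <- tab$study_id[out$table$events != tab$events]
  expect_true(all(changed %in% out$affected))
  # unchanged arms are bit-identical
  keep <- !(tab$study_id %in% out$affected & tab$arm_role == "control")
  expect_identical(out$table$events[keep], tab$events[keep])
  # the injected amount is exactly the rounded delta unless clamped
  sel <- tab$arm_role == "control" & tab$study_id %in% out$affected
  raw <- tab$events[sel] + spillroc:::round_half_away(10 * tab$total[sel] / 100)
  expect_equal(out$table$events[sel], pmin(pmax(raw, 0), tab$total[sel]))
})

test_that("the scenario grid reproduces the qualitative spillover pattern", {
  spec <- default_cohort_specs(3)$non_antimicrobial
  spec$k_studies <- 60L
  tab <- generate_cohort(spec)$table
  grid <- suppressMessages(run_scenario_grid(
    tab, default_scenario_grid(seed = 5), fit_bivariate_model = FALSE
  ))
  df <- as.data.frame(grid)
  expect_equal(nrow(df), 9L)  # baseline + 8 scenarios
  expect_equal(df$scenario[1], "No spillover")

  upos <- df[df$scenario %in% c("No spillover", "+0.025 spillover",
                                "+0.05 spillover", "+0.1 spillover"), ]
  # increasing uniform positive spillover: OR strictly decreasing, pooled
  # control proportion strictly increasing
  expect_true(all(diff(upos$or) < 0))
  expect_true(all(diff(upos$summary_prop) > 0))

  uneg <- df[df$scenario %in% c("No spillover", "-0.025 spillover",
                                "-0.05 spillover"), ]
  expect_true(all(diff(uneg$or) > 0))           # OR moves toward/past 1
  expect_true(all(diff(uneg$summary_prop) < 0)) # control incidence falls
})

test_that("a failing stage is recorded without aborting the grid", {
  # a 1-study table: pooling needs k >= 2, so every stage errors per scenario
  tab <- arm_table(data.frame(
    study_id = c("A", "A"), review_id = "r",
    category = "non_antimicrobial", subcategory = "s",
    arm_role = c("control", "intervention"),
    events = c(10, 5), total = c(50, 50), shared_control_of = NA
  ))
  grid <- run_scenario_grid(tab, list(spillover_scenario("positive", 10)),
                            fit_bivariate_model = FALSE)
  df <- as.data.frame(grid)
  expect_equal(nrow(df), 2L)
  expect_true(all(nzchar(df$error)))
})
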