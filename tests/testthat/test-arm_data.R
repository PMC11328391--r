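# Data model: CSV round-trip, 2x2 layout, control deduplication, incidence
# filtering.

test_that("CSV round-trip preserves records and validates counts", {
  tab <- mini_table()
  path <- withr::local_tempfile(fileext = ".csv")
  write_arm_table(tab, path)
  back <- read_arm_table(path)
  expect_s3_class(back, "arm_table")
  expect_equal(nrow(back), 8L)
  expect_equal(length(unique(back$study_id)), 4L)
  expect_equal(back$events, tab$events)
  expect_equal(back$total, tab$total)

  # events > total rejected with the study named
  bad <- as.data.frame(tab)
  bad$events[1] <- bad$total[1] + 2L
  expect_error(arm_table(bad), "events outside.*A")

  # header-only file: zero records plus a warning
  empty <- as.data.frame(tab)[0, ]
  path2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(empty, path2, row.names = FALSE)
  expect_warning(tab0 <- read_arm_table(path2), "zero records")
  expect_equal(nrow(tab0), 0L)
})

test_that("malformed rows and incomplete studies are rejected by name", {
  df <- as.data.frame(mini_table())
  solo <- df[df$study_id == "A" & df$arm_role == "control", ]
  expect_error(arm_table(rbind(df, transform(solo, study_id = "E"))),
               "study E lacks")
  df2 <- df
  df2$shared_control_of[1] <- "ZZZ"
  expect_error(arm_table(df2), "unknown study ZZZ")

  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "study_id,review_id,category,subcategory,arm_role,events,total,shared_control_of",
    "A,r,non_antimicrobial,s,control,ten,20,"
  ), path)
  expect_error(read_arm_table(path), "malformed row 2")
})

test_that("2x2 layout maps intervention to tp/fn and control to fp/tn", {
  tab <- arm_table(data.frame(
    study_id = rep(c("A", "B"), each = 2), review_id = "r",
    category = "antimicrobial", subcategory = "s",
    arm_role = rep(c("intervention", "control"), 2),
    events = c(12, 20, 0, 30), total = c(60, 55, 30, 30),
    shared_control_of = NA
  ))
  layout <- to_dta_layout(tab)
  expect_equal(layout$study_id, c("A", "B"))
  expect_equal(unlist(layout[1, c("tp", "fn", "fp", "tn")], use.names = FALSE),
               c(12, 48, 20, 35))
  # boundary: zero intervention events, all-event control
  expect_equal(unlist(layout[2, c("tp", "fn", "fp", "tn")], use.names = FALSE),
               c(0, 30, 30, 0))

  # reconstructing incidences from the 2x2 is lossless
  expect_equal(layout$tp + layout$fn, c(60, 30))
  expect_equal(layout$fp, tab$events[tab$arm_role == "control"])

  # a study missing an arm is named
  df <- as.data.frame(tab)[-2, ]
  expect_error(to_dta_layout(df), "study A")
})

multiarm_table <- function(events = 40L, total = 100L) {
  arm_table(data.frame(
    study_id = c("M1", "M1", "M1b", "M1b"),
    review_id = "r", category = "antimicrobial", subcategory = "s",
    arm_role = rep(c("control", "intervention"), 2),
    events = c(events, 10L, events, 12L), total = c(total, 50L, total, 55L),
    shared_control_of = c(NA, NA, "M1", NA)
  ))
}

test_that("split deduplication conserves control events and totals", {
  # even split
  split_even <- dedupe_control_arms(multiarm_table(40L, 100L), "split")
  ctrl <- split_even[split_even$arm_role == "control", ]
  expect_equal(ctrl$events, c(20L, 20L))
  expect_equal(ctrl$total, c(50L, 50L))

  # odd counts: larger share to the first comparison in input order
  split_odd <- dedupe_control_arms(multiarm_table(41L, 101L), "split")
  ctrl <- split_odd[split_odd$arm_role == "control", ]
  expect_equal(ctrl$events, c(21L, 20L))
  expect_equal(ctrl$total, c(51L, 50L))
  expect_equal(sum(ctrl$events), 41L)
  expect_equal(sum(ctrl$total), 101L)

  # include_once keeps one physical control and both interventions
  once <- dedupe_control_arms(multiarm_table(), "include_once")
  expect_equal(sum(once$arm_role == "control"), 1L)
  expect_equal(sum(once$arm_role == "intervention"), 2L)
})

test_that("incidence filter partitions studies with boundary excluded", {
  tab <- arm_table(data.frame(
    study_id = rep(c("LO", "AT", "HI"), each = 2), review_id = "r",
    category = "antimicrobial", subcategory = "s",
    arm_role = rep(c("control", "intervention"), 3),
    events = c(10, 5, 40, 20, 50, 22), total = c(100, 100, 100, 100, 100, 100),
    shared_control_of = NA
  ))
  above <- filter_by_control_incidence(tab, 0.4, "above")
  expect_message(
    below <- filter_by_control_incidence(tab, 0.4, "below"),
    "exactly 0.4"
  )
  expect_equal(unique(above$study_id), "HI")
  expect_equal(unique(below$study_id), "LO")
  # above + below + boundary recovers the original study set
  expect_setequal(c(unique(above$study_id), unique(below$study_id), "AT"),
                  unique(tab$study_id))
})
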