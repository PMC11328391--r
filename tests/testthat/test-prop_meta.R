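# Logit-proportion effects and the shared random-effects pooling core.

test_that("logit effects follow the boundary-only continuity correction", {
  e <- logit_effect(10, 20)
  expect_equal(e$y, 0)
  expect_equal(e$v, 0.2)

  # boundary count: 0.5 added to both cells
  e0 <- logit_effect(0, 20, correction = 0.5)
  expect_equal(e0$y, log(0.5 / 20.5))
  expect_equal(e0$v, 1 / 0.5 + 1 / 20.5)

  e15 <- logit_effect(15, 20)
  expect_equal(e15$y, log(3))
  expect_equal(e15$v, 1 / 15 + 1 / 5)

  expect_error(logit_effect(1, 0), "total")
})

test_that("hand-computable 3-study pooling matches closed forms", {
  p <- spillroc:::pool_effects(c(0, 1, 2), c(0.2, 0.2, 0.2), "DL")
  # Q = sum 5 (y_i - 1)^2 = 10; DL tau2 = (10-2)/(15-75/15) = 0.8
  expect_equal(p$Q, 10)
  expect_equal(p$df, 2L)
  expect_equal(p$tau2, 0.8)
  # s2 = 2*15/(225-75) = 0.2 -> I2 = 80, H2 = 5
  expect_equal(p$I2, 80)
  expect_equal(p$H2, 5)
  # equal weights: estimate 1, SE sqrt(1/sum(1/(v+tau2)))
  expect_equal(p$est, 1)
  expect_equal(p$se, sqrt(1 / 3))
  expect_equal(p$pi, 1 + c(-1, 1) * qt(0.975, 1) * sqrt(0.8 + 1 / 3))
})

test_that("identical effects give zero dispersion and symmetric summary", {
  eff <- list(
    list(y = 0, v = 0.2, events = 10, total = 20, study_id = "a"),
    list(y = 0, v = 0.2, events = 10, total = 20, study_id = "b")
  )
  fit <- pool_arms(eff)
  expect_equal(fit$Q, 0)
  expect_equal(fit$tau2, 0)
  expect_equal(fit$I2, 0)
  expect_equal(fit$H2, 1)
  expect_equal(fit$summary_prop, 50)
})

test_that("pooling agrees with metafor for REML and DL on random sets", {
  skip_if_not_installed("metafor")
  set.seed(42)
  for (rep in 1:8) {
    k <- sample(3:6, 1)
    y <- rnorm(k, sd = 1.2)
    v <- runif(k, 0.05, 0.5)
    for (m in c("REML", "DL")) {
      mine <- spillroc:::pool_effects(y, v, m)
      ref <- metafor::rma(yi = y, vi = v, method = m,
                          control = list(tol = 1e-10))
      expect_equal(mine$tau2, ref$tau2, tolerance = 1e-4)
      expect_equal(mine$Q, ref$QE, tolerance = 1e-10)
      expect_equal(mine$I2, ref$I2, tolerance = 1e-3)
      expect_equal(mine$H2, ref$H2, tolerance = 1e-3)
      expect_equal(mine$est, as.numeric(ref$beta), tolerance = 1e-4)
    }
  }
})

test_that("I2/H2 stay mutually consistent and back-transform is monotone", {
  set.seed(7)
  for (rep in 1:20) {
    k <- sample(3:9, 1)
    eff <- Map(logit_effect, rbinom(k, 50, 0.3), rep(50, k),
               study_id = as.character(seq_len(k)))
    fit <- pool_arms(eff, tau2_method = sample(c("REML", "DL"), 1))
    expect_equal(fit$H2, 1 / (1 - fit$I2 / 100), tolerance = 1e-9)
    expect_true(fit$I2 >= 0 && fit$I2 < 100)
    # PI contains CI whenever tau2 > 0; both map monotonically to percent
    if (fit$tau2 > 0) {
      expect_lt(fit$pi95[1], fit$ci95[1])
      expect_gt(fit$pi95[2], fit$ci95[2])
    }
    expect_true(all(diff(c(fit$pi95[1], fit$ci95[1], fit$summary_prop,
                           fit$ci95[2], fit$pi95[2])) >= 0))
  }
})

test_that("tau2 = 0 leaves the PI wider than the CI only via the t quantile", {
  eff <- Map(logit_effect, c(10, 11, 10, 11), c(30, 30, 30, 30),
             study_id = letters[1:4])
  fit <- pool_arms(eff)
  expect_equal(fit$tau2, 0)
  p <- fit$logit
  expect_equal(diff(p$pi) / diff(p$ci), qt(0.975, 2) / qnorm(0.975),
               tolerance = 1e-10)
})

test_that("arm summary table lays out groups with control before intervention", {
  specs <- default_cohort_specs(11)
  specs <- lapply(specs, function(s) {
    s$k_studies <- 12L
    s
  })
  tab <- do.call(rbind, lapply(specs, function(s) {
    as.data.frame(generate_cohort(s)$table)
  }))
  out <- arm_summary_table(arm_table(tab))
  expect_equal(nrow(out), 8L)  # all + 3 categories, x 2 arms
  expect_equal(out$group[1:2], c("all", "all"))
  expect_equal(out$arm_role[seq(1, 8, 2)], rep("control", 4))
  expect_false(any(out$flagged))

  # a single-study group is flagged, not computed
  one <- tab[tab$study_id %in% tab$study_id[1], ]
  both <- arm_table(rbind(
    tab[tab$category == "non_antimicrobial", ],
    transform(one, category = "antimicrobial_duplex",
              study_id = paste0(study_id, "x"))
  ))
  out2 <- arm_summary_table(both)
  flagged <- out2[out2$group == "antimicrobial_duplex", ]
  expect_true(all(flagged$flagged))
  expect_true(all(is.na(flagged$summary_prop)))
})
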