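# Bivariate binomial-normal model: quadrature accuracy, symmetries,
# degenerate limits, DOR, ellipses and the SROC curve.

test_that("adaptive quadrature matches dense brute-force integration", {
  pairs <- toy_pairs()[1:3, ]
  grid <- list(
    c(mu_I = -1.2, mu_C = -0.6, sigma_I = 0.7, sigma_C = 0.9, rho = 0.4),
    c(mu_I = 0.3, mu_C = -1.5, sigma_I = 0.3, sigma_C = 1.4, rho = -0.7),
    c(mu_I = -2.0, mu_C = -2.2, sigma_I = 1.1, sigma_C = 0.4, rho = 0.0)
  )
  for (p in grid) {
    ll_q <- bivariate_loglik(pairs, p["mu_I"], p["mu_C"], p["sigma_I"],
                             p["sigma_C"], p["rho"], quad_order = 7)
    ll_b <- brute_bivariate_loglik(pairs, p["mu_I"], p["mu_C"], p["sigma_I"],
                                   p["sigma_C"], p["rho"])
    expect_lt(abs(ll_q - ll_b), 1e-5)
  }
})

test_that("mirror-symmetric data give symmetric parameter estimates", {
  pairs <- toy_pairs()
  mir <- rbind(pairs, swap_arms(pairs))
  mir$study_id <- paste0("m", seq_len(nrow(mir)))
  fit <- suppressWarnings(fit_bivariate(mir))
  expect_equal(fit$mu_I, fit$mu_C, tolerance = 1e-4)
  expect_equal(fit$sigma_I, fit$sigma_C, tolerance = 1e-4)
})

test_that("swapped-arm refit inverts the diagnostic odds ratio", {
  spec <- cohort_spec(k_studies = 30, seed = 5)
  pairs <- to_dta_layout(generate_cohort(spec)$table)
  f1 <- fit_bivariate(pairs)
  f2 <- fit_bivariate(swap_arms(pairs))
  expect_equal(log(summary_dor(f1)$or) + log(summary_dor(f2)$or), 0,
               tolerance = 1e-5)
  expect_equal(f2$rho, f1$rho, tolerance = 1e-4)
})

test_that("common-incidence cohorts are recovered in the degenerate limit", {
  # sigma_I = sigma_C = 0 truth: every study shares incidences 0.2 / 0.4
  set.seed(31)
  n <- 500L
  k <- 50L
  pairs <- data.frame(
    study_id = as.character(seq_len(k)),
    tp = rbinom(k, n, 0.2), fp = rbinom(k, n, 0.4)
  )
  pairs$fn <- n - pairs$tp
  pairs$tn <- n - pairs$fp
  fit <- fit_bivariate(pairs)
  se <- sqrt(diag(fit$vcov_fixed))
  expect_lt(abs(fit$mu_I - qlogis(0.2)), 3 * se[1] + 0.02)
  expect_lt(abs(fit$mu_C - qlogis(0.4)), 3 * se[2] + 0.02)
  expect_lt(fit$sigma_I, 0.08)
  expect_lt(fit$sigma_C, 0.08)
})

test_that("maximized likelihood dominates an independent (Laplace) fitter", {
  skip_if_not_installed("lme4")
  spec <- cohort_spec(k_studies = 30, seed = 5)
  pairs <- to_dta_layout(generate_cohort(spec)$table)
  long <- data.frame(
    study = rep(pairs$study_id, 2),
    role = rep(c("int", "ctrl"), each = nrow(pairs)),
    e = c(pairs$tp, pairs$fp),
    n = c(pairs$tp + pairs$fn, pairs$fp + pairs$tn)
  )
  gm <- lme4::glmer(cbind(e, n - e) ~ 0 + role + (0 + role | study),
                    data = long, family = binomial)
  vc <- lme4::VarCorr(gm)$study
  fe <- lme4::fixef(gm)
  ll_at_glmer <- bivariate_loglik(
    pairs, fe[["roleint"]], fe[["rolectrl"]],
    sqrt(vc["roleint", "roleint"]), sqrt(vc["rolectrl", "rolectrl"]),
    attr(vc, "correlation")["roleint", "rolectrl"]
  )
  fit <- fit_bivariate(pairs)
  expect_gte(fit$loglik, ll_at_glmer - 1e-6)
  # and the two fitters agree on the means to Laplace accuracy
  expect_equal(fit$mu_I, unname(fe[["roleint"]]), tolerance = 0.05)
  expect_equal(fit$mu_C, unname(fe[["rolectrl"]]), tolerance = 0.05)
})

test_that("summary DOR follows mu_I - mu_C with the stated variance", {
  fit <- structure(list(
    mu_I = qlogis(0.2), mu_C = qlogis(0.5),
    vcov_fixed = matrix(c(0.04, 0.01, 0.01, 0.09), 2), k = 10,
    Sigma = diag(2) * 0.2, sigma_I = sqrt(0.2), sigma_C = sqrt(0.2), rho = 0
  ), class = "bivariate_fit")
  d <- summary_dor(fit)
  expect_equal(d$or, 0.25)
  expect_equal(d$se_log, sqrt(0.04 + 0.09 - 0.02))
  fit$mu_I <- fit$mu_C
  d2 <- summary_dor(fit)
  expect_equal(d2$or, 1)
  expect_true(d2$ci95[1] < 1 && 1 < d2$ci95[2])
})

test_that("ellipses have chi-squared radius, nest, and centre correctly", {
  fit <- structure(list(
    mu_I = 0, mu_C = 0, vcov_fixed = diag(2), Sigma = diag(2) * 0.5,
    sigma_I = sqrt(0.5), sigma_C = sqrt(0.5), rho = 0, k = 20
  ), class = "bivariate_fit")
  ce <- confidence_ellipse(fit)
  # identity covariance: logit-plane radius sqrt(qchisq(.95, 2)) everywhere
  r <- sqrt(qlogis(ce$x)^2 + qlogis(ce$y)^2)
  expect_equal(max(abs(r - sqrt(qchisq(0.95, 2)))), 0, tolerance = 1e-8)
  expect_equal(ce[1, ], ce[nrow(ce), ], ignore_attr = TRUE)
  expect_true(all(ce$x > 0 & ce$x < 1 & ce$y > 0 & ce$y < 1))

  # prediction ellipse encloses the confidence ellipse (logit plane)
  pe <- prediction_ellipse(fit)
  expect_true(all(sqrt(qlogis(pe$x)^2 + qlogis(pe$y)^2) > max(r) - 1e-9))

  # centre of the back-transformed path is the summary point
  fit2 <- fit
  fit2$mu_I <- qlogis(0.3)
  fit2$mu_C <- qlogis(0.6)
  ce2 <- confidence_ellipse(fit2)
  th <- seq(0, 2 * pi, length.out = nrow(ce2))
  expect_equal(mean(qlogis(ce2$x[-1])), qlogis(0.6), tolerance = 1e-6)
  expect_equal(mean(qlogis(ce2$y[-1])), qlogis(0.3), tolerance = 1e-6)

  # F-scaling radius exceeds chi-squared for small k
  ceF <- confidence_ellipse(fit, scaling = "F")
  expect_gt(max(qlogis(ceF$x)), max(qlogis(ce$x)))
})

test_that("SROC curve is the conditional-mean line through the summary point", {
  fit <- structure(list(
    mu_I = qlogis(0.25), mu_C = qlogis(0.4),
    sigma_I = 0.6, sigma_C = 0.8, rho = 0.5,
    vcov_fixed = diag(2) * 0.01, Sigma = diag(2), k = 10,
    data = data.frame(tp = c(5, 10), fn = c(15, 10), fp = c(4, 12),
                      tn = c(16, 8))
  ), class = "bivariate_fit")
  cu <- sroc_curve(fit, x_grid = seq(0.05, 0.95, by = 0.05))
  expect_true(all(diff(cu$x) > 0))
  expect_true(all(diff(cu$y) > 0))  # monotone since rho * sigma_I > 0
  # passes through the summary point
  expect_equal(cu$y[cu$x == 0.4], 0.25, tolerance = 1e-12)

  # rho = 0: horizontal at expit(mu_I)
  fit$rho <- 0
  cu0 <- sroc_curve(fit, x_grid = c(0.1, 0.5, 0.9))
  expect_equal(cu0$y, rep(0.25, 3), tolerance = 1e-12)

  # sigma_C = 0 degenerates to a vertical reference with a warning
  fit$sigma_C <- 0
  expect_warning(cuv <- sroc_curve(fit), "vertical")
  expect_equal(unique(cuv$x), 0.4, tolerance = 1e-12)
})

test_that("few-study fits warn about weak identification", {
  pairs <- toy_pairs()[1:3, ]
  expect_warning(fit_bivariate(pairs), "weakly")
})
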