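# Independent oracles and small fixture builders shared across test files.

# Brute-force marginal log-likelihood of the bivariate binomial-normal model
# by dense 2-D trapezoid integration over [-lim, lim]^2. Completely
# independent of the package's quadrature path; factorizes the bivariate
# normal as phi(eta_I) * phi(eta_C | eta_I) so each study costs one
# grid x grid pass.
brute_bivariate_loglik <- function(pairs, mu_I, mu_C, sigma_I, sigma_C, rho,
                                   step = 0.01, lim = 10) {
  eta <- seq(-lim, lim, by = step)
  w <- rep(step, length(eta))
  w[1] <- w[length(eta)] <- step / 2
  condsd <- sigma_C * sqrt(1 - rho^2)
  total <- 0
  for (i in seq_len(nrow(pairs))) {
    tt <- pairs[i, ]
    nI <- tt$tp + tt$fn
    nC <- tt$fp + tt$tn
    aI <- dbinom(tt$tp, nI, plogis(eta)) * dnorm(eta, mu_I, sigma_I) * w
    aC <- dbinom(tt$fp, nC, plogis(eta))
    condm <- mu_C + rho * sigma_C / sigma_I * (eta - mu_I)
    inner <- vapply(condm, function(m) sum(aC * dnorm(eta, m, condsd) * w),
                    numeric(1))
    total <- total + log(sum(aI * inner))
  }
  total
}

# four tiny paired-count studies used across bivariate tests
toy_pairs <- function() {
  data.frame(
    study_id = c("t1", "t2", "t3", "t4"),
    tp = c(3, 10, 1, 7), fn = c(17, 30, 9, 13),
    fp = c(6, 14, 4, 11), tn = c(14, 26, 6, 9),
    stringsAsFactors = FALSE
  )
}

swap_arms <- function(pairs) {
  data.frame(
    study_id = pairs$study_id,
    tp = pairs$fp, fn = pairs$tn, fp = pairs$tp, tn = pairs$fn,
    stringsAsFactors = FALSE
  )
}

# minimal arm table: two categories, two-arm studies, from explicit counts
mini_table <- function() {
  arm_table(data.frame(
    study_id = rep(c("A", "B", "C", "D"), each = 2),
    review_id = "r1",
    category = rep(c("non_antimicrobial", "non_antimicrobial",
                     "antimicrobial", "antimicrobial"), each = 2),
    subcategory = "s",
    arm_role = rep(c("control", "intervention"), 4),
    events = c(20, 12, 15, 9, 30, 12, 25, 10),
    total = c(55, 60, 50, 48, 60, 58, 64, 61),
    shared_control_of = NA_character_
  ))
}

# pool one arm role of an arm table into an arm_pooled object
pool_role <- function(table, role, tau2_method = "REML") {
  sub <- table[table$arm_role == role, ]
  pool_arms(Map(logit_effect, sub$events, sub$total, study_id = sub$study_id),
            tau2_method = tau2_method)
}

# a hand-built arm_pooled stub for rule tests (logit-scale fields unused)
pooled_stub <- function(tau2, pi_lo_pct, pi_hi_pct, I2 = 50,
                        incidences = c(0.2, 0.3)) {
  structure(list(
    k = length(incidences), summary_prop = 100 * mean(incidences),
    se_logit = 0.1,
    ci95 = c(pi_lo_pct, pi_hi_pct), pi95 = c(pi_lo_pct, pi_hi_pct),
    Q = NA, df = length(incidences) - 1, tau2 = tau2, I2 = I2,
    H2 = 1 / (1 - I2 / 100),
    data = data.frame(
      study_id = paste0("s", seq_along(incidences)),
      y = qlogis(incidences), v = 0.1,
      events = round(100 * incidences), total = 100
    )
  ), class = "arm_pooled")
}
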