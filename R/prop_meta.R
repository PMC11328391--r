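# Arm-level random-effects meta-analysis of logit-transformed incidence
# proportions, with the heterogeneity statistics (Q, tau2, I2, H2) and 95%
# prediction interval reported per arm group.
#
# The same inverse-variance pooling core serves the contrast-based log
# odds-ratio analysis (contrast_meta.R); only the effect construction and the
# back-transformation differ.

#' Logit-transformed incidence effect for one arm
#'
#' Computes the logit proportion and its large-sample variance for one group's
#' event count. A continuity correction (default 0.5) is added to both cells
#' only when the count sits on the boundary (`events = 0` or `events = total`).
#'
#' @param events Non-negative event count.
#' @param total Positive group size.
#' @param correction Continuity correction for boundary counts; default 0.5.
#' @param study_id Optional label carried through to pooling errors.
#'
#' @return A list with `y` (logit proportion), `v` (variance of `y`,
#'   `1/e' + 1/(n'-e')`), `events`, `total`, `study_id`.
#' @export
logit_effect <- function(events, total, correction = 0.5, study_id = NA_character_) {
  if (total < 1) stop("total must be >= 1")
  stopifnot(events >= 0, events <= total, correction >= 0)
  e <- events
  n <- total
  if (events == 0 || events == total) {
    e <- events + correction
    n <- total + 2 * correction
  }
  list(
    y = log(e / (n - e)),
    v = 1 / e + 1 / (n - e),
    events = events, total = total, study_id = study_id
  )
}

# Restricted (REML) profile log-likelihood for the between-study variance of a
# random-effects model y_i ~ N(mu, v_i + tau2).
reml_tau2 <- function(y, v) {
  nll <- function(tau2) {
    w <- 1 / (v + tau2)
    mu <- sum(w * y) / sum(w)
    0.5 * (sum(log(v + tau2)) + log(sum(w)) + sum(w * (y - mu)^2))
  }
  ub <- max(10 * stats::var(y), 4 * max(v), 0.01)
  opt <- stats::optimize(nll, interval = c(0, ub))
  # optimize never evaluates exactly at the boundary; snap near-zero optima
  if (opt$minimum < 1e-8 || nll(0) <= opt$objective) return(0)
  opt$minimum
}

# Shared inverse-variance pooling core on the working scale (logit proportion
# or log odds ratio). Returns the full heterogeneity panel.
pool_effects <- function(y, v, tau2_method = c("REML", "DL"), level = 0.95) {
  tau2_method <- match.arg(tau2_method)
  k <- length(y)
  if (k < 2) stop("pooling requires k >= 2 effects")
  if (any(!is.finite(y)) || any(!is.finite(v)) || any(v <= 0)) {
    stop("non-finite effect or non-positive variance at position ",
         which(!is.finite(y) | !is.finite(v) | v <= 0)[1])
  }

  w <- 1 / v
  y_fe <- sum(w * y) / sum(w)
  Q <- sum(w * (y - y_fe)^2)
  df <- k - 1L
  c_dl <- sum(w) - sum(w^2) / sum(w)
  tau2_dl <- max(0, (Q - df) / c_dl)
  tau2 <- if (tau2_method == "DL") tau2_dl else reml_tau2(y, v)

  # Higgins-Thompson "typical" within-study variance; I2 defined from tau2 and
  # s2 so that I2 and H2 stay mutually consistent for any tau2 estimator.
  s2 <- df * sum(w) / (sum(w)^2 - sum(w^2))
  I2 <- 100 * tau2 / (tau2 + s2)
  H2 <- 1 / (1 - I2 / 100)

  wr <- 1 / (v + tau2)
  est <- sum(wr * y) / sum(wr)
  se <- sqrt(1 / sum(wr))
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- est + c(-1, 1) * z * se
  # prediction interval with t quantile on k - 2 degrees of freedom
  if (k >= 3) {
    tq <- stats::qt(1 - (1 - level) / 2, df = k - 2)
    pi <- est + c(-1, 1) * tq * sqrt(tau2 + se^2)
  } else {
    pi <- c(NA_real_, NA_real_)
  }

  list(
    k = k, est = est, se = se, ci = ci, pi = pi,
    Q = Q, df = df, tau2 = tau2, tau2_dl = tau2_dl,
    I2 = I2, H2 = H2, s2 = s2, level = level, tau2_method = tau2_method
  )
}

#' Pool arm-level logit proportions
#'
#' Random-effects pooling of logit-transformed incidence proportions with
#' Cochran's Q (fixed-effect weights), between-study variance tau2 (REML by
#' default, DerSimonian-Laird available in closed form), the Higgins-Thompson
#' I2 and H2 derived from tau2 and the typical within-study variance, a 95%
#' confidence interval, and a 95% prediction interval using the t quantile on
#' k-2 degrees of freedom. Summary, CI and PI are back-transformed to percent.
#'
#' @param effects List of effects from [logit_effect()].
#' @param tau2_method `"REML"` (default) or `"DL"`.
#' @param level Confidence level, default 0.95.
#'
#' @return An object of class `arm_pooled`: list with `k`, `summary_prop`
#'   (percent), `se_logit`, `ci95` and `pi95` (percent), `Q`, `df`, `tau2`,
#'   `I2`, `H2`, plus the logit-scale panel under `$logit` and the per-study
#'   data under `$data`.
#' @export
pool_arms <- function(effects, tau2_method = c("REML", "DL"), level = 0.95) {
  y <- vapply(effects, `[[`, numeric(1), "y")
  v <- vapply(effects, `[[`, numeric(1), "v")
  ids <- vapply(effects, function(e) as.character(e$study_id %||% NA), character(1))
  bad <- which(!is.finite(y) | !is.finite(v))
  if (length(bad)) stop("non-finite effect for study ", ids[bad[1]])
  p <- pool_effects(y, v, tau2_method = tau2_method, level = level)

  structure(list(
    k = p$k,
    summary_prop = 100 * expit(p$est),
    se_logit = p$se,
    ci95 = 100 * expit(p$ci),
    pi95 = 100 * expit(p$pi),
    Q = p$Q, df = p$df, tau2 = p$tau2, I2 = p$I2, H2 = p$H2,
    logit = p,
    data = data.frame(
      study_id = ids, y = y, v = v,
      events = vapply(effects, `[[`, numeric(1), "events"),
      total = vapply(effects, `[[`, numeric(1), "total"),
      stringsAsFactors = FALSE
    )
  ), class = "arm_pooled")
}

#' @export
print.arm_pooled <- function(x, ...) {
  cat(sprintf(
    "<arm_pooled> k=%d  summary %.1f%% (95%% CI %.1f-%.1f)  PI %.1f-%.1f\n",
    x$k, x$summary_prop, x$ci95[1], x$ci95[2], x$pi95[1], x$pi95[2]
  ))
  cat(sprintf("  Q=%.1f (df=%d)  tau2=%.3f  I2=%.1f%%  H2=%.1f\n",
              x$Q, x$df, x$tau2, x$I2, x$H2))
  invisible(x)
}

#' Arm-level summary table across groups
#'
#' Pools each arm role within each grouping (overall, per category, or per
#' subcategory), mirroring a per-category incidence/heterogeneity table:
#' the overall rows first, then per-group rows, control before intervention.
#'
#' @param table An [arm_table], already deduplicated with
#'   `dedupe_control_arms(mode = "include_once")` so no patient is pooled
#'   twice.
#' @param grouping `"category"` (default), `"subcategory"`, or `"all"`.
#' @param tau2_method Passed to [pool_arms()].
#'
#' @return A data.frame with one row per group x arm role: `group`,
#'   `arm_role`, `k`, `summary_prop`, `se_logit`, `ci_lo`, `ci_hi`, `Q`, `df`,
#'   `tau2`, `I2`, `H2`, `pi_lo`, `pi_hi`, `flagged` (TRUE when k < 2 made the
#'   row uncomputable), and the fitted objects as attribute `"pooled"`.
#' @export
arm_summary_table <- function(table, grouping = c("category", "subcategory", "all"),
                              tau2_method = "REML") {
  grouping <- match.arg(grouping)
  df <- as.data.frame(table)
  groups <- switch(grouping,
    all = list(),
    category = {
      present <- ARM_CATEGORIES[ARM_CATEGORIES %in% df$category]
      stats::setNames(lapply(present, function(g) df[df$category == g, ]), present)
    },
    subcategory = split(df, df$subcategory)
  )
  blocks <- c(list(all = df), groups)

  fits <- list()
  rows <- list()
  for (g in names(blocks)) {
    for (role in ARM_ROLES) {
      sub <- blocks[[g]][blocks[[g]]$arm_role == role, ]
      key <- paste(g, role, sep = ".")
      if (nrow(sub) < 2) {
        rows[[key]] <- data.frame(
          group = g, arm_role = role, k = nrow(sub),
          summary_prop = NA, se_logit = NA, ci_lo = NA, ci_hi = NA,
          Q = NA, df = NA, tau2 = NA, I2 = NA, H2 = NA,
          pi_lo = NA, pi_hi = NA, flagged = TRUE
        )
        next
      }
      eff <- Map(logit_effect, sub$events, sub$total,
                 study_id = sub$study_id)
      fit <- pool_arms(eff, tau2_method = tau2_method)
      fits[[key]] <- fit
      rows[[key]] <- data.frame(
        group = g, arm_role = role, k = fit$k,
        summary_prop = fit$summary_prop, se_logit = fit$se_logit,
        ci_lo = fit$ci95[1], ci_hi = fit$ci95[2],
        Q = fit$Q, df = fit$df, tau2 = fit$tau2, I2 = fit$I2, H2 = fit$H2,
        pi_lo = fit$pi95[1], pi_hi = fit$pi95[2], flagged = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "pooled") <- fits
  out
}
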