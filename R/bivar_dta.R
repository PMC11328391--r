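# Bivariate binomial-normal random-effects model over paired arm counts,
# the arm-based analogue of the diagnostic-test-assessment (DTA) model.
#
# Per study i the model is
#   e_Ii ~ Binomial(n_Ii, expit(eta_Ii)),  e_Ci ~ Binomial(n_Ci, expit(eta_Ci))
#   (eta_Ii, eta_Ci) ~ N2((mu_I, mu_C), Sigma),
# with Sigma = [[sigma_I^2, rho sigma_I sigma_C], [., sigma_C^2]].
# Under the DTA mapping the intervention incidence expit(eta_I) plays
# "sensitivity" and the control incidence expit(eta_C) plays 1 - "specificity",
# so exp(mu_I - mu_C) is the diagnostic odds ratio of the layout.
#
# The marginal likelihood integrates the paired binomials over the bivariate
# normal random effects by adaptive Gauss-Hermite quadrature: per study the
# integrand is recentred at its mode and rescaled by its curvature (both exact
# in closed form for the binomial-logit + Gaussian integrand), then a tensor
# product Gauss-Hermite rule is applied.

# Gauss-Hermite nodes/weights for weight exp(-x^2) (physicists' convention),
# by Golub-Welsch on the symmetric tridiagonal Jacobi matrix.
gauss_hermite <- function(n) {
  stopifnot(n >= 1)
  if (n == 1) return(list(nodes = 0, weights = sqrt(pi)))
  J <- matrix(0, n, n)
  off <- sqrt(seq_len(n - 1) / 2)
  J[cbind(seq_len(n - 1), seq_len(n - 1) + 1)] <- off
  J[cbind(seq_len(n - 1) + 1, seq_len(n - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord], weights = sqrt(pi) * e$vectors[1, ord]^2)
}

# Validate/extract count matrices from a dta layout data.frame.
dta_counts <- function(pairs) {
  stopifnot(all(c("tp", "fn", "fp", "tn") %in% names(pairs)))
  with(pairs, {
    stopifnot(all(tp + fn >= 1), all(fp + tn >= 1),
              all(c(tp, fn, fp, tn) >= 0))
    list(
      eI = as.numeric(tp), nI = as.numeric(tp + fn),
      eC = as.numeric(fp), nC = as.numeric(fp + tn)
    )
  })
}

#' Marginal log-likelihood of the bivariate binomial-normal model
#'
#' Evaluates the marginal log-likelihood at fixed parameter values by adaptive
#' Gauss-Hermite quadrature. Exposed so the quadrature can be validated
#' against brute-force integration and so profile likelihoods can be drawn.
#'
#' @param pairs Data.frame in the 2x2 layout of [to_dta_layout()] (columns
#'   `tp`, `fn`, `fp`, `tn`).
#' @param mu_I,mu_C Mean logit intervention / control incidence.
#' @param sigma_I,sigma_C Between-study SDs of the logit incidences (>= 0).
#' @param rho Correlation of the paired random effects, in (-1, 1).
#' @param quad_order Nodes per dimension (default 7).
#'
#' @return The log-likelihood (sum over studies), including binomial
#'   normalizing constants.
#' @export
bivariate_loglik <- function(pairs, mu_I, mu_C, sigma_I, sigma_C, rho,
                             quad_order = 7) {
  sum(bivariate_loglik_terms(
    dta_counts(pairs), mu_I, mu_C, sigma_I, sigma_C, rho, quad_order
  ))
}

# Per-study log-likelihood contributions, vectorized over studies.
bivariate_loglik_terms <- function(cnt, mu_I, mu_C, sigma_I, sigma_C, rho,
                                   quad_order = 7) {
  stopifnot(quad_order >= 3, abs(rho) < 1)
  sigma_I <- max(sigma_I, 1e-6)
  sigma_C <- max(sigma_C, 1e-6)
  k <- length(cnt$eI)

  # precision matrix of the random effects, order (eta_I, eta_C)
  det_S <- sigma_I^2 * sigma_C^2 * (1 - rho^2)
  P11 <- sigma_C^2 / det_S
  P22 <- sigma_I^2 / det_S
  P12 <- -rho * sigma_I * sigma_C / det_S
  log_norm <- -log(2 * pi) - 0.5 * log(det_S)
  const <- lchoose(cnt$nI, cnt$eI) + lchoose(cnt$nC, cnt$eC) + log_norm

  g_val <- function(hI, hC) {
    dI <- hI - mu_I
    dC <- hC - mu_C
    cnt$eI * hI - cnt$nI * log1p(exp(hI)) +
      cnt$eC * hC - cnt$nC * log1p(exp(hC)) -
      0.5 * (P11 * dI^2 + 2 * P12 * dI * dC + P22 * dC^2) + const
  }

  # damped Newton for the per-study posterior mode (integrand is log-concave)
  hI <- rep(mu_I, k)
  hC <- rep(mu_C, k)
  for (iter in 1:100) {
    pI <- expit(hI)
    pC <- expit(hC)
    gI <- cnt$eI - cnt$nI * pI - (P11 * (hI - mu_I) + P12 * (hC - mu_C))
    gC <- cnt$eC - cnt$nC * pC - (P12 * (hI - mu_I) + P22 * (hC - mu_C))
    a <- cnt$nI * pI * (1 - pI) + P11
    b <- rep(P12, k)
    cc <- cnt$nC * pC * (1 - pC) + P22
    det_A <- a * cc - b^2
    sI <- (cc * gI - b * gC) / det_A
    sC <- (-b * gI + a * gC) / det_A
    # cap the step to keep Newton monotone on very flat tails
    norm <- pmax(sqrt(sI^2 + sC^2), 1e-300)
    scale <- pmin(1, 4 / norm)
    hI <- hI + scale * sI
    hC <- hC + scale * sC
    if (max(abs(gI), abs(gC)) < 1e-10) break
  }

  # curvature at the mode
  pI <- expit(hI)
  pC <- expit(hC)
  a <- cnt$nI * pI * (1 - pI) + P11
  b <- rep(P12, k)
  cc <- cnt$nC * pC * (1 - pC) + P22
  det_A <- a * cc - b^2
  # lower Cholesky factor of A^{-1}
  l11 <- sqrt(cc / det_A)
  l21 <- -b / sqrt(cc * det_A)
  l22 <- 1 / sqrt(cc)

  gh <- gauss_hermite(quad_order)
  z1 <- rep(gh$nodes, times = quad_order)
  z2 <- rep(gh$nodes, each = quad_order)
  lw <- log(rep(gh$weights, times = quad_order)) +
    log(rep(gh$weights, each = quad_order)) + z1^2 + z2^2

  # k x m node grids: eta = mode + sqrt(2) L z
  etaI <- hI + sqrt(2) * outer(l11, z1)
  etaC <- hC + sqrt(2) * (outer(l21, z1) + outer(l22, z2))
  G <- g_val(etaI, etaC) + matrix(lw, nrow = k, ncol = length(lw), byrow = TRUE)
  gmax <- apply(G, 1, max)
  log(2) - 0.5 * log(det_A) + gmax + log(rowSums(exp(G - gmax)))
}

#' Fit the bivariate binomial-normal model
#'
#' Maximizes the adaptive Gauss-Hermite marginal likelihood over
#' (mu_I, mu_C, log sigma_I, log sigma_C, atanh rho); the SDs are optimized on
#' the log scale and the correlation on the Fisher-z scale so the optimizer
#' stays interior. The covariance of the fixed effects is obtained from the
#' numerically differentiated observed information.
#'
#' @param pairs Data.frame in the 2x2 layout of [to_dta_layout()].
#' @param quad_order Quadrature nodes per dimension, default 7.
#' @param starts Optional named list overriding the default starting values
#'   (`mu_I`, `mu_C` crude pooled logits; `sigma_I = sigma_C = 0.5`;
#'   `rho = 0`).
#'
#' @return Object of class `bivariate_fit`: `mu_I`, `mu_C`, `sigma_I`,
#'   `sigma_C`, `rho`, `Sigma` (2x2 random-effect covariance, order
#'   intervention/control), `vcov_fixed` (2x2 for (mu_I, mu_C)), `loglik`,
#'   `converged`, `k`, `data`.
#' @export
fit_bivariate <- function(pairs, quad_order = 7, starts = NULL) {
  pairs <- as.data.frame(pairs)
  cnt <- dta_counts(pairs)
  k <- length(cnt$eI)
  if (k < 4) {
    warning("k = ", k, " studies: bivariate random-effects model is weakly ",
            "identified below 4 studies")
  }

  crude_logit <- function(e, n) log((sum(e) + 0.5) / (sum(n) - sum(e) + 0.5))
  st <- list(
    mu_I = crude_logit(cnt$eI, cnt$nI),
    mu_C = crude_logit(cnt$eC, cnt$nC),
    sigma_I = 0.5, sigma_C = 0.5, rho = 0
  )
  st[names(starts)] <- starts
  th0 <- c(st$mu_I, st$mu_C, log(st$sigma_I), log(st$sigma_C), atanh(st$rho))

  nll <- function(th) {
    -sum(bivariate_loglik_terms(
      cnt, th[1], th[2], exp(th[3]), exp(th[4]), tanh(th[5]), quad_order
    ))
  }
  lower <- c(-20, -20, -7, -7, -6)
  upper <- c(20, 20, 3, 3, 6)
  ctrl <- list(maxit = 500, factr = 1e4)
  opt <- stats::optim(th0, nll, method = "L-BFGS-B", lower = lower,
                      upper = upper, control = ctrl)
  # one polishing restart: L-BFGS-B stops on relative progress, and a cold
  # restart from the optimum recovers another decimal or two in the parameters
  opt2 <- stats::optim(opt$par, nll, method = "L-BFGS-B", lower = lower,
                       upper = upper, control = ctrl)
  if (opt2$value <= opt$value) opt <- opt2
  th <- opt$par
  if (abs(tanh(th[5])) > tanh(5.9)) {
    warning("correlation estimate at the boundary (|rho| ~ 1); ",
            "random-effect covariance is degenerate")
  }

  vcov_fixed <- matrix(NA_real_, 2, 2)
  ok_vcov <- TRUE
  H <- try(stats::optimHess(th, nll), silent = TRUE)
  if (!inherits(H, "try-error")) {
    Hi <- try(solve(H), silent = TRUE)
    if (!inherits(Hi, "try-error") && all(diag(Hi)[1:2] > 0)) {
      vcov_fixed <- Hi[1:2, 1:2]
    } else {
      ok_vcov <- FALSE
    }
  } else {
    ok_vcov <- FALSE
  }
  dimnames(vcov_fixed) <- list(c("mu_I", "mu_C"), c("mu_I", "mu_C"))

  sigma_I <- exp(th[3])
  sigma_C <- exp(th[4])
  rho <- tanh(th[5])
  Sigma <- matrix(c(sigma_I^2, rho * sigma_I * sigma_C,
                    rho * sigma_I * sigma_C, sigma_C^2), 2, 2,
                  dimnames = list(c("mu_I", "mu_C"), c("mu_I", "mu_C")))

  structure(list(
    mu_I = th[1], mu_C = th[2],
    sigma_I = sigma_I, sigma_C = sigma_C, rho = rho,
    Sigma = Sigma, vcov_fixed = vcov_fixed,
    loglik = -opt$value,
    converged = opt$convergence == 0 && ok_vcov,
    k = k, quad_order = quad_order,
    data = pairs
  ), class = "bivariate_fit")
}

#' @export
print.bivariate_fit <- function(x, ...) {
  cat(sprintf(
    "<bivariate_fit> k=%d  loglik=%.2f  converged=%s\n", x$k, x$loglik,
    x$converged
  ))
  cat(sprintf(
    "  intervention incidence %.1f%% (mu_I=%.3f, sigma_I=%.3f)\n",
    100 * expit(x$mu_I), x$mu_I, x$sigma_I
  ))
  cat(sprintf(
    "  control incidence      %.1f%% (mu_C=%.3f, sigma_C=%.3f)\n",
    100 * expit(x$mu_C), x$mu_C, x$sigma_C
  ))
  cat(sprintf("  rho=%.3f  DOR=%.3f\n", x$rho, exp(x$mu_I - x$mu_C)))
  invisible(x)
}

#' Summary (diagnostic) odds ratio of a bivariate fit
#'
#' The log odds ratio is `mu_I - mu_C` with variance
#' `v_II + v_CC - 2 v_IC` from the fixed-effect covariance; in DTA terms this
#' is the diagnostic odds ratio of the layout since logit specificity equals
#' `-mu_C`.
#'
#' @param fit A converged [fit_bivariate()] object.
#' @param level Confidence level.
#' @return List with `or` and `ci95`.
#' @export
summary_dor <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "bivariate_fit"))
  lo <- fit$mu_I - fit$mu_C
  v <- fit$vcov_fixed[1, 1] + fit$vcov_fixed[2, 2] - 2 * fit$vcov_fixed[1, 2]
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(or = exp(lo), ci95 = exp(lo + c(-1, 1) * z * sqrt(v)), se_log = sqrt(v))
}

# shared ellipse machinery on the logit plane, (control, intervention) order
make_ellipse <- function(center_CI, C2, level, k, scaling, n_points, kind) {
  if (any(!is.finite(C2))) stop("ellipse covariance contains non-finite values")
  ev <- eigen(C2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) stop("ellipse covariance is not positive semi-definite")
  C2 <- C2 + diag(2) * max(0, -min(ev) + 1e-12)
  r <- switch(scaling,
    chisq = sqrt(stats::qchisq(level, df = 2)),
    F = sqrt(2 * stats::qf(level, 2, max(k - 2, 1)))
  )
  L <- t(chol(C2))
  t_grid <- seq(0, 2 * pi, length.out = n_points)
  pts <- center_CI + r * (L %*% rbind(cos(t_grid), sin(t_grid)))
  out <- data.frame(x = expit(pts[1, ]), y = expit(pts[2, ]))
  out[n_points, ] <- out[1, ]  # numerically closed
  structure(out, kind = kind, level = level, scaling = scaling,
            class = c("ellipse_path", "data.frame"))
}

#' Confidence and prediction ellipses of the summary point
#'
#' On the logit plane the 95% region of the summary (control, intervention)
#' logit incidences is an ellipse: the radius is the square root of the
#' chi-squared (2 df) quantile (default) or of `2 F(2, k-2)` for small-sample
#' scaling; the shape matrix is the fixed-effect covariance (confidence) or
#' the fixed-effect covariance plus the random-effect covariance (prediction,
#' describing where a new comparable study's true arm pair should lie).
#' Back-transformation through the inverse logit is applied pointwise, so the
#' paths lose their elliptical shape on the incidence scale.
#'
#' @param fit A converged [fit_bivariate()].
#' @param level Coverage level, default 0.95.
#' @param scaling `"chisq"` (default) or `"F"`.
#' @param n_points Polyline resolution (first point repeated at the end).
#' @return A data.frame of class `ellipse_path` with columns `x` (control
#'   incidence) and `y` (intervention incidence), closed.
#' @export
confidence_ellipse <- function(fit, level = 0.95, scaling = c("chisq", "F"),
                               n_points = 361) {
  scaling <- match.arg(scaling)
  Cmat <- fit$vcov_fixed[c(2, 1), c(2, 1)]
  make_ellipse(c(fit$mu_C, fit$mu_I), Cmat, level, fit$k, scaling, n_points,
               "confidence")
}

#' @rdname confidence_ellipse
#' @export
prediction_ellipse <- function(fit, level = 0.95, scaling = c("chisq", "F"),
                               n_points = 361) {
  scaling <- match.arg(scaling)
  Cmat <- (fit$vcov_fixed + fit$Sigma)[c(2, 1), c(2, 1)]
  make_ellipse(c(fit$mu_C, fit$mu_I), Cmat, level, fit$k, scaling, n_points,
               "prediction")
}

#' Summary ROC curve of a bivariate fit
#'
#' The default curve is the conditional-mean regression line on the logit
#' plane, `eta_I(eta_C) = mu_I + rho (sigma_I / sigma_C) (eta_C - mu_C)`,
#' evaluated over the observed range of control incidences and
#' back-transformed pointwise.
#'
#' @param fit A converged [fit_bivariate()].
#' @param x_grid Optional vector of control incidences at which to evaluate;
#'   default 200 points across the observed control-incidence range.
#' @return A data.frame of class `sroc_curve` with strictly increasing `x`
#'   (control incidence) and `y` (intervention incidence); attribute
#'   `"parameterization_note"` records the variant.
#' @export
sroc_curve <- function(fit, x_grid = NULL) {
  stopifnot(inherits(fit, "bivariate_fit"))
  if (fit$sigma_C < 1e-5) {
    warning("sigma_C ~ 0: SROC curve undefined; returning vertical reference ",
            "through the summary point")
    y <- seq(0.01, 0.99, length.out = 99)
    out <- data.frame(x = rep(expit(fit$mu_C), 99), y = y)
    attr(out, "parameterization_note") <-
      "degenerate (sigma_C = 0): vertical reference line"
    class(out) <- c("sroc_curve", "data.frame")
    return(out)
  }
  if (is.null(x_grid)) {
    xc <- fit$data$fp / (fit$data$fp + fit$data$tn)
    rng <- clamp(range(xc), 0.001, 0.999)
    x_grid <- expit(seq(logit(rng[1]), logit(rng[2]), length.out = 200))
  }
  x_grid <- sort(unique(x_grid))
  eta_C <- logit(x_grid)
  eta_I <- fit$mu_I + fit$rho * (fit$sigma_I / fit$sigma_C) * (eta_C - fit$mu_C)
  out <- data.frame(x = x_grid, y = expit(eta_I))
  attr(out, "parameterization_note") <-
    "conditional-mean regression of logit intervention on logit control incidence"
  class(out) <- c("sroc_curve", "data.frame")
  out
}
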