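# Maturity ogives and allometric length-weight fits.
#
# The logistic ogive is fitted by iteratively reweighted least squares
# written here (Newton-Raphson on the Bernoulli-logit likelihood with
# step-halving), so that convergence, separation and the covariance matrix
# are under the package's control.

#' Binarize a 7-stage maturity score
#'
#' Collapses the elasmobranch 7-stage maturity scale to binary
#' mature/immature. Under the default scheme stages 1-2 (immature /
#' developing) are immature and stages 3-7 (developing oocytes through
#' spent) are mature; the cut is a named, overridable parameter because
#' staging conventions differ between protocols.
#'
#' @param stage integer vector of stages in 1-7 (`NA` passed through).
#' @param mature_stages integer set defining maturity; default `3:7`.
#' @return logical vector: `TRUE` = mature.
#' @export
binarize_maturity <- function(stage, mature_stages = 3:7) {
  ok <- is.na(stage) | (stage %in% 1:7)
  tn_assert(all(ok), "maturity stage outside 1-7", "tn_domain_error")
  ifelse(is.na(stage), NA, stage %in% mature_stages)
}

#' Fit a logistic maturity ogive
#'
#' Maximum-likelihood logistic regression of binary maturity on total
#' length, fitted by Newton-Raphson/IRLS with step-halving, run to a
#' gradient max-norm below `tol` or `max_iter` iterations. The length at
#' 50% maturity is `l50 = -beta0/beta1` and the length at 95% maturity is
#' `l95 = (logit(0.95) - beta0)/beta1`. The coefficient covariance is the
#' inverse observed information at the optimum. Quasi-separation (divergent
#' slope) is flagged, not silently reported as a fit.
#'
#' @param length numeric vector of total lengths (cm), all positive.
#' @param mature logical (or 0/1) vector of the same length.
#' @param tol convergence tolerance on the gradient max-norm.
#' @param max_iter maximum Newton iterations.
#' @return object of class `"ogive_fit"`: list with `beta0`, `beta1`,
#'   `l50`, `l95`, `vcov` (2x2), `converged`, `separation`, `n_used`,
#'   `n_mature`, `iterations`, `log_lik`.
#' @examples
#' set.seed(1)
#' tl <- runif(500, 13, 66)
#' mat <- runif(500) < plogis(-12.5 + 0.25 * tl)
#' fit_maturity_ogive(tl, mat)
#' @export
fit_maturity_ogive <- function(length, mature, tol = 1e-8, max_iter = 100L) {
  keep <- !is.na(length) & !is.na(mature)
  length <- length[keep]; mature <- as.numeric(mature[keep])
  tn_assert(all(length > 0), "lengths must be positive", "tn_domain_error")
  tn_assert(all(mature %in% c(0, 1)), "mature must be binary",
            "tn_domain_error")
  n <- length(length)
  tn_assert(sum(mature == 1) >= 2 && sum(mature == 0) >= 2,
            "need at least 2 records of each maturity class",
            "tn_degenerate_data_error")
  tn_assert(stats::sd(length) > 0, "lengths are all equal",
            "tn_degenerate_data_error")

  # centre lengths for conditioning; map coefficients back at the end
  mu <- mean(length)
  x <- length - mu
  X <- cbind(1, x)
  y <- mature

  # deterministic start: intercept at the logit of the observed fraction
  beta <- c(stats::qlogis(mean(y)), 0)
  loglik <- function(b) {
    eta <- X %*% b
    sum(y * eta - log1p(exp(eta)))
  }
  ll <- loglik(beta)
  converged <- FALSE
  separation <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    grad <- drop(crossprod(X, y - p))
    if (max(abs(grad)) < tol) { converged <- TRUE; break }
    if (iter > max_iter) break
    w <- pmax(p * (1 - p), .Machine$double.eps)
    info <- crossprod(X, X * w)
    step <- tryCatch(solve(info, grad), error = function(e) NULL)
    if (is.null(step)) { separation <- TRUE; break }
    # step-halving safeguard: the likelihood never decreases across an
    # accepted step
    lambda <- 1
    repeat {
      cand <- unname(beta + lambda * step)
      llc <- loglik(cand)
      if (is.finite(llc) && llc >= ll - 1e-12) break
      lambda <- lambda / 2
      if (lambda < 1e-10) { cand <- beta; llc <- ll; break }
    }
    beta <- cand; ll <- llc
    # divergent slope on the cm scale indicates (quasi-)separation
    if (abs(beta[2]) > 50 || abs(beta[1]) > 1e4) { separation <- TRUE; break }
  }
  # quasi-separation can also satisfy the gradient criterion at a finite
  # but extreme solution: every observation perfectly classified with the
  # logistic squashed to a step
  p_fit <- stats::plogis(drop(X %*% beta))
  if (all((y == 1) == (p_fit > 0.5)) && max(p_fit * (1 - p_fit)) < 1e-4)
    separation <- TRUE
  if (separation) converged <- FALSE

  p <- stats::plogis(drop(X %*% beta))
  w <- pmax(p * (1 - p), .Machine$double.eps)
  info <- crossprod(X, X * w)
  vc <- tryCatch(solve(info), error = function(e) matrix(NA_real_, 2, 2))
  # uncentre: beta0_raw = beta0_c - beta1 * mu; slope unchanged
  A <- matrix(c(1, 0, -mu, 1), 2, 2)
  beta_raw <- unname(c(beta[1] - beta[2] * mu, beta[2]))
  vc_raw <- A %*% vc %*% t(A)

  out <- list(
    beta0 = beta_raw[1], beta1 = beta_raw[2],
    l50 = if (beta_raw[2] > 0) -beta_raw[1] / beta_raw[2] else NA_real_,
    l95 = if (beta_raw[2] > 0)
      (stats::qlogis(0.95) - beta_raw[1]) / beta_raw[2] else NA_real_,
    vcov = vc_raw,
    converged = converged,
    separation = separation,
    n_used = n,
    n_mature = sum(y == 1),
    iterations = iter,
    log_lik = ll
  )
  class(out) <- "ogive_fit"
  out
}

#' @export
print.ogive_fit <- function(x, ...) {
  cat("Logistic maturity ogive",
      if (!x$converged) "(NOT CONVERGED)" else "", "\n")
  if (x$separation) cat("  warning: quasi-separation detected\n")
  cat(sprintf("  beta0 = %.4f, beta1 = %.4f (per cm)\n", x$beta0, x$beta1))
  cat(sprintf("  L50 = %.2f cm, L95 = %.2f cm\n", x$l50, x$l95))
  cat(sprintf("  n = %d (%d mature), %d iterations\n",
              x$n_used, x$n_mature, x$iterations))
  invisible(x)
}

#' Predict proportion mature at length
#'
#' @param fit a converged [fit_maturity_ogive()] result.
#' @param length lengths (cm) at which to predict.
#' @return proportions mature in (0, 1).
#' @export
predict_maturity <- function(fit, length) {
  tn_assert(inherits(fit, "ogive_fit"), "fit must be an ogive_fit",
            "tn_config_error")
  tn_assert(isTRUE(fit$converged), "ogive fit did not converge",
            "tn_invalid_fit_error")
  stats::plogis(fit$beta0 + fit$beta1 * length)
}

#' Bootstrap confidence interval for L50
#'
#' Nonparametric percentile interval: records are resampled with
#' replacement `n_boot` times, the ogive refitted on each resample, and the
#' interval taken as the percentile pair of the converged resample L50
#' values. Resamples that fail to converge (or are single-class) are
#' dropped and counted.
#'
#' @inheritParams fit_maturity_ogive
#' @param n_boot number of bootstrap resamples (>= 1).
#' @param level confidence level, default 0.95.
#' @param seed integer seed for the resampling.
#' @return list with `lo`, `hi` (cm), `level`, `n_boot`, `n_failed`, and
#'   `l50_boot` (the converged resample values).
#' @export
l50_ci_bootstrap <- function(length, mature, n_boot = 500L, level = 0.95,
                             seed = 1L) {
  tn_assert(n_boot >= 1, "n_boot must be at least 1", "tn_config_error")
  fit0 <- fit_maturity_ogive(length, mature)
  tn_assert(isTRUE(fit0$converged), "full-data fit did not converge",
            "tn_invalid_fit_error")
  keep <- !is.na(length) & !is.na(mature)
  length <- length[keep]; mature <- mature[keep]
  n <- length(length)
  set.seed(tn_seed(seed, 0))
  l50s <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    fb <- tryCatch(fit_maturity_ogive(length[idx], mature[idx]),
                   tn_error = function(e) NULL)
    if (!is.null(fb) && isTRUE(fb$converged) && is.finite(fb$l50))
      l50s[b] <- fb$l50
  }
  ok <- is.finite(l50s)
  tn_assert(mean(!ok) <= 0.5,
            "more than half of bootstrap resamples failed to converge",
            "tn_unstable_fit_error")
  a <- (1 - level) / 2
  qs <- stats::quantile(l50s[ok], c(a, 1 - a), names = FALSE)
  list(lo = qs[1], hi = qs[2], level = level, n_boot = n_boot,
       n_failed = sum(!ok), l50_boot = l50s[ok])
}

#' Delta-method confidence interval for L50
#'
#' Cross-check utility: a Wald interval for `l50 = -beta0/beta1` using the
#' gradient of the ratio and the coefficient covariance from the observed
#' information.
#'
#' @param fit a converged [fit_maturity_ogive()] result.
#' @param level confidence level.
#' @return list with `lo`, `hi`, `se`.
#' @export
l50_ci_delta <- function(fit, level = 0.95) {
  tn_assert(inherits(fit, "ogive_fit") && isTRUE(fit$converged),
            "need a converged ogive_fit", "tn_invalid_fit_error")
  g <- c(-1 / fit$beta1, fit$beta0 / fit$beta1^2)
  se <- sqrt(drop(t(g) %*% fit$vcov %*% g))
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(lo = fit$l50 - z * se, hi = fit$l50 + z * se, se = se)
}

#' Fit an allometric length-weight relationship
#'
#' Ordinary least squares of `ln(W)` on `ln(TL)`: the power-law model
#' `W = a * TL^b` with multiplicative lognormal error, the standard model
#' for fish weight-length data. Reported coefficients are on the
#' natural-log scale (`log_a` = intercept, `b` = allometric exponent);
#' `r2` is the coefficient of determination on the log-log scale.
#'
#' @param length total lengths, cm, all positive.
#' @param weight weights, g, all positive; same length as `length`.
#' @return object of class `"lw_fit"`: list with `log_a`, `b`, `r2`,
#'   `n_used`, `residual_sd`.
#' @export
fit_length_weight <- function(length, weight) {
  keep <- !is.na(length) & !is.na(weight)
  length <- length[keep]; weight <- weight[keep]
  tn_assert(all(length > 0) && all(weight > 0),
            "lengths and weights must be positive", "tn_domain_error")
  tn_assert(length(length) >= 3, "need at least 3 (length, weight) pairs",
            "tn_insufficient_data_error")
  fit <- stats::lm(log(weight) ~ log(length))
  s <- summary(fit)
  out <- list(
    log_a = unname(stats::coef(fit)[1]),
    b = unname(stats::coef(fit)[2]),
    r2 = s$r.squared,
    n_used = length(length),
    residual_sd = s$sigma
  )
  class(out) <- "lw_fit"
  out
}

#' @export
print.lw_fit <- function(x, ...) {
  cat("Allometric length-weight fit: ln W =",
      sprintf("%.3f + %.3f ln TL", x$log_a, x$b), "\n")
  cat(sprintf("  a = %.3g g cm^-b, r2 (log scale) = %.3f, n = %d\n",
              exp(x$log_a), x$r2, x$n_used))
  invisible(x)
}

#' Predict weight at length from a length-weight fit
#'
#' @param fit an [fit_length_weight()] result.
#' @param length lengths (cm).
#' @return predicted weights (g), `exp(log_a + b * ln length)`.
#' @export
predict_weight <- function(fit, length) {
  tn_assert(inherits(fit, "lw_fit"), "fit must be an lw_fit", "tn_config_error")
  exp(fit$log_a + fit$b * log(length))
}
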