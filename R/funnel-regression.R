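# Weighted least squares on an arbitrary design, unrestricted error variance.
# Returns coefficients, their SEs, residual df, and the weighted residual
# mean square. SEs use sigma2 = weighted RSS / (n - p), the WLS convention of
# the funnel meta-regression literature.
wls_design_fit <- function(X, y, w) {
  n <- length(y)
  p <- ncol(X)
  fit <- stats::lm.wfit(x = X, y = y, w = w)
  if (any(is.na(fit$coefficients)))
    return(list(ok = FALSE, reason = "rank-deficient design"))
  rdf <- n - p
  rss <- sum(w * fit$residuals^2)
  sigma2 <- if (rdf > 0) rss / rdf else 0
  R <- qr.R(fit$qr)
  XtWXinv <- chol2inv(R)
  ses <- sqrt(pmax(diag(XtWXinv), 0) * sigma2)
  list(ok = TRUE, coef = unname(fit$coefficients), se = unname(ses),
       rdf = rdf, sigma2 = sigma2)
}

#' Precision-effect test (PET) regression
#'
#' WLS regression of effect estimates on an intercept and the standard error,
#' with weights \eqn{1/SE_i^2}. The intercept estimates the
#' selection-corrected mean effect; the slope captures funnel asymmetry. The
#' one-tailed p-value for H0: \eqn{\mu \le 0} (t distribution, N - 2 df) is
#' returned in `aux$p_one_tailed`.
#'
#' @param sample an [effect_sample] with N >= 3 and non-constant SEs.
#' @return a [new_estimate]; non-converged when the SEs are all identical
#'   (intercept and SE regressor collinear).
#' @export
pet_fit <- function(sample) {
  n <- length(sample$effects)
  if (n < 3L) stop("pet_fit: need N >= 3")
  if (diff(range(sample$ses)) < .Machine$double.eps^0.5 * max(sample$ses))
    return(non_converged("PET", aux = list(reason = "constant SEs")))
  X <- cbind(1, sample$ses)
  fit <- wls_design_fit(X, sample$effects, 1 / sample$ses^2)
  if (!fit$ok) return(non_converged("PET", aux = list(reason = fit$reason)))
  mu <- fit$coef[1L]; se <- fit$se[1L]
  tstat <- mu / se
  p1 <- stats::pt(tstat, df = fit$rdf, lower.tail = FALSE)
  crit <- stats::qt(0.975, df = fit$rdf)
  new_estimate("PET", mu_hat = mu, se_hat = se,
               ci_low = mu - crit * se, ci_high = mu + crit * se,
               converged = is.finite(mu) && is.finite(se), df = fit$rdf,
               aux = list(rho_hat = unname(fit$coef[2L]),
                          p_one_tailed = p1, t_stat = tstat))
}

# PEESE stage: same weights, SE^2 regressor.
peese_fit <- function(sample) {
  n <- length(sample$effects)
  X <- cbind(1, sample$ses^2)
  fit <- wls_design_fit(X, sample$effects, 1 / sample$ses^2)
  if (!fit$ok) return(non_converged("PEESE", aux = list(reason = fit$reason)))
  mu <- fit$coef[1L]; se <- fit$se[1L]
  crit <- stats::qt(0.975, df = fit$rdf)
  new_estimate("PEESE", mu_hat = mu, se_hat = se,
               ci_low = mu - crit * se, ci_high = mu + crit * se,
               converged = is.finite(mu) && is.finite(se), df = fit$rdf,
               aux = list(rho_hat = unname(fit$coef[2L])))
}

#' PET-PEESE estimator
#'
#' Two-step conditional estimator: run the PET regression and test H0:
#' \eqn{\mu = 0} one-tailed at the 5 percent level (t, N - 2 df). If the test
#' fails to reject, report the PET intercept; if it rejects, re-fit with
#' \eqn{SE_i^2} in place of \eqn{SE_i} (same weights) and report that
#' intercept.
#'
#' @param sample an [effect_sample] with N >= 3.
#' @return a [new_estimate]; `aux$stage` records which branch was taken.
#' @export
pet_peese_estimate <- function(sample) {
  pet <- pet_fit(sample)
  if (!pet$converged) {
    pet$estimator <- "PP"
    return(pet)
  }
  if (pet$aux$p_one_tailed >= 0.05) {
    out <- pet
    out$estimator <- "PP"
    out$aux$stage <- "PET"
    return(out)
  }
  out <- peese_fit(sample)
  out$estimator <- "PP"
  out$aux$stage <- "PEESE"
  out$aux$pet_p_one_tailed <- pet$aux$p_one_tailed
  out
}

#' Weighted average of adequately powered estimates (WAAP)
#'
#' Computes the full-sample WLS mean \eqn{\hat\mu}, the 80-percent-power
#' threshold \eqn{\delta = |\hat\mu|/2.8}, and the subset of estimates with
#' \eqn{SE_i < \delta} ("adequately powered"). If at least two estimates
#' qualify, returns the WLS mean of that subset; otherwise falls back to the
#' full-sample WLS estimate. `aux` records `M` (count qualifying) and `delta`.
#' The absolute value in \eqn{\delta} keeps the rule well-defined when the
#' first-stage mean is negative.
#'
#' @param sample an [effect_sample].
#' @return a [new_estimate].
#' @export
waap_estimate <- function(sample) {
  n <- length(sample$effects)
  full <- wls_fe_estimate(sample,
                          se_mode = if (n >= 2L) "unrestricted" else "fixed")
  delta <- abs(full$mu_hat) / 2.8
  keep <- sample$ses < delta
  m <- sum(keep)
  if (m >= 2L) {
    sub <- effect_sample(sample$effects[keep], sample$ses[keep])
    out <- wls_fe_estimate(sub, se_mode = "unrestricted")
  } else {
    out <- full
  }
  out$estimator <- "WAAP"
  out$aux$M <- m
  out$aux$delta <- delta
  out
}

#' Endogenous-kink SE cutoff
#'
#' Solves \eqn{\hat\mu - 1.96\sqrt{SE^2+\hat\tau^2} = 1.96\,SE} for the SE
#' value `a` below which essentially all estimates are significant and
#' selection is assumed absent. The left side minus the right,
#' \eqn{g(SE)}, is strictly decreasing, so the root is unique when
#' \eqn{g(0) > 0}; when \eqn{g(0) \le 0} (i.e. \eqn{\hat\mu \le 1.96\hat\tau})
#' the cutoff is 0. With \eqn{\hat\tau^2 = 0} the root is
#' \eqn{\hat\mu/3.92} in closed form.
#'
#' @param mu_pet positive first-stage (PET) estimate of the mean effect.
#' @param tau2 heterogeneity variance, >= 0.
#' @return the cutoff `a` in `[0, mu_pet/1.96]`, found by bisection to
#'   absolute tolerance 1e-10.
#' @export
ek_cutoff <- function(mu_pet, tau2) {
  if (mu_pet <= 0) stop("ek_cutoff: mu_pet must be positive")
  stopifnot(tau2 >= 0)
  g <- function(se) mu_pet - 1.96 * sqrt(se^2 + tau2) - 1.96 * se
  if (g(0) <= 0) return(0)
  lo <- 0
  hi <- mu_pet / 1.96
  while (hi - lo > 1e-10) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Endogenous-kink (EK) estimator
#'
#' First stage: PET regression for \eqn{\hat\mu} with the one-tailed 5
#' percent significance gate, and \eqn{\hat\tau^2} from the random-effects
#' model on the full sample. If the PET intercept is significantly positive,
#' the SE cutoff `a` is computed via [ek_cutoff()] and the second stage fits a
#' WLS regression (weights \eqn{1/SE_i^2}) of the effects on an intercept and
#' the hinge regressor \eqn{\max(SE_i - a, 0)}; otherwise `a = 0` and the
#' hinge equals the PET specification. When every SE falls below `a`, the
#' hinge is identically zero and the fit degenerates to the precision-weighted
#' mean (flagged in `aux$degenerate`).
#'
#' @param sample an [effect_sample] with N >= 3.
#' @return a [new_estimate]; `aux` records `cutoff_a`, `rho_hat`, and the
#'   first-stage gate outcome.
#' @export
ek_estimate <- function(sample) {
  pet <- pet_fit(sample)
  if (!pet$converged) {
    pet$estimator <- "EK"
    return(pet)
  }
  tau2 <- re_reml_estimate(sample)$tau2_hat
  gate <- pet$aux$p_one_tailed < 0.05 && pet$mu_hat > 0
  a <- if (gate) ek_cutoff(pet$mu_hat, tau2) else 0
  hinge <- pmax(sample$ses - a, 0)
  if (all(hinge == 0)) {
    out <- wls_fe_estimate(sample, se_mode = "unrestricted")
    out$estimator <- "EK"
    out$aux <- c(out$aux, list(cutoff_a = a, degenerate = TRUE,
                               first_stage_significant = gate))
    return(out)
  }
  X <- cbind(1, hinge)
  fit <- wls_design_fit(X, sample$effects, 1 / sample$ses^2)
  if (!fit$ok) return(non_converged("EK", aux = list(reason = fit$reason)))
  mu <- fit$coef[1L]; se <- fit$se[1L]
  crit <- stats::qt(0.975, df = fit$rdf)
  new_estimate("EK", mu_hat = mu, se_hat = se,
               ci_low = mu - crit * se, ci_high = mu + crit * se,
               converged = is.finite(mu) && is.finite(se),
               tau2_hat = tau2, df = fit$rdf,
               aux = list(cutoff_a = a, rho_hat = unname(fit$coef[2L]),
                          first_stage_significant = gate, degenerate = FALSE))
}
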