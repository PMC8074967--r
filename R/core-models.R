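#' Fixed-effect / WLS estimate of the mean effect
#'
#' The precision-weighted mean with weights \eqn{w_i = 1/SE_i^2}. With
#' `se_mode = "fixed"` the standard error is the classical fixed-effect one,
#' \eqn{(\sum w_i)^{-1/2}}, with a normal 95 percent interval. With
#' `se_mode = "unrestricted"` the standard error is multiplied by the square
#' root of the weighted residual mean square (the WLS convention of the
#' meta-regression literature) and the interval uses a t distribution with
#' N - 1 degrees of freedom.
#'
#' @param sample an [effect_sample].
#' @param se_mode `"fixed"` or `"unrestricted"`.
#' @return a [new_estimate] with `aux$wrms` (weighted residual mean square).
#' @export
wls_fe_estimate <- function(sample, se_mode = c("fixed", "unrestricted")) {
  se_mode <- match.arg(se_mode)
  n <- length(sample$effects)
  if (se_mode == "unrestricted" && n < 2L)
    stop("wls_fe_estimate: unrestricted variance needs N >= 2")
  w <- 1 / sample$ses^2
  mu <- sum(w * sample$effects) / sum(w)
  se_fixed <- 1 / sqrt(sum(w))
  wrms <- if (n >= 2L) sum(w * (sample$effects - mu)^2) / (n - 1L) else 0
  if (se_mode == "fixed") {
    se <- se_fixed
    crit <- stats::qnorm(0.975)
    df <- Inf
  } else {
    se <- se_fixed * sqrt(wrms)
    crit <- stats::qt(0.975, df = n - 1L)
    df <- n - 1L
  }
  new_estimate("WLS", mu_hat = mu, se_hat = se,
               ci_low = mu - crit * se, ci_high = mu + crit * se,
               converged = is.finite(mu) && is.finite(se),
               tau2_hat = 0, df = df, aux = list(wrms = wrms))
}

# Restricted log-likelihood of the random-effects model, profiled over mu.
# effects ~ N(mu, v_i + tau2); constants dropped consistently across tau2.
reml_loglik <- function(tau2, effects, v) {
  vi <- v + tau2
  w <- 1 / vi
  mu <- sum(w * effects) / sum(w)
  -0.5 * (sum(log(vi)) + log(sum(w)) + sum(w * (effects - mu)^2))
}

#' Random-effects estimate via restricted maximum likelihood
#'
#' Fits \eqn{\hat\beta_i \sim N(\mu, SE_i^2 + \tau^2)} by maximizing the
#' restricted (profiled) log-likelihood over \eqn{\tau^2 \ge 0} on
#' \eqn{[0, 10\,\mathrm{var}(\hat\beta)]}, then returns the precision-weighted
#' mean with weights \eqn{1/(SE_i^2+\hat\tau^2)}, its standard error
#' \eqn{(\sum 1/(SE_i^2+\hat\tau^2))^{-1/2}}, and a normal 95 percent
#' interval.
#'
#' @param sample an [effect_sample] with at least two estimates.
#' @return a [new_estimate] with `tau2_hat` filled in.
#' @export
re_reml_estimate <- function(sample) {
  n <- length(sample$effects)
  if (n < 2L) stop("re_reml_estimate: need N >= 2")
  v <- sample$ses^2
  upper <- max(10 * stats::var(sample$effects), 10 * max(v), 1e-8)
  opt <- stats::optimize(reml_loglik, interval = c(0, upper), maximum = TRUE,
                         effects = sample$effects, v = v, tol = 1e-8)
  tau2 <- opt$maximum
  # optimize() never returns the exact boundary; snap to zero when the
  # restricted likelihood is no worse there.
  if (reml_loglik(0, sample$effects, v) >= opt$objective - 1e-10) tau2 <- 0
  w <- 1 / (v + tau2)
  mu <- sum(w * sample$effects) / sum(w)
  se <- 1 / sqrt(sum(w))
  crit <- stats::qnorm(0.975)
  new_estimate("RE", mu_hat = mu, se_hat = se,
               ci_low = mu - crit * se, ci_high = mu + crit * se,
               converged = is.finite(mu) && is.finite(se),
               tau2_hat = tau2, df = Inf)
}

#' Heterogeneity statistics (I-squared)
#'
#' Computes the typical within-study variance
#' \eqn{\hat\sigma^2 = \sum w_i (N-1) / ((\sum w_i)^2 - \sum w_i^2)} with
#' \eqn{w_i = 1/SE_i^2}, and
#' \eqn{I^2 = \hat\tau^2 / (\hat\tau^2 + \hat\sigma^2)}.
#'
#' @param sample an [effect_sample] with at least two estimates.
#' @param tau2 heterogeneity variance estimate (e.g. from
#'   [re_reml_estimate()]).
#' @return list with `tau2_hat`, `sigma2_hat`, `i2`, `weights`.
#' @export
i_squared <- function(sample, tau2) {
  n <- length(sample$effects)
  if (n < 2L) stop("i_squared: need N >= 2")
  stopifnot(tau2 >= 0)
  w <- 1 / sample$ses^2
  denom <- sum(w)^2 - sum(w^2)
  if (denom <= 0) stop("i_squared: degenerate weights (denominator <= 0)")
  sigma2 <- sum(w) * (n - 1L) / denom
  list(tau2_hat = tau2, sigma2_hat = sigma2,
       i2 = tau2 / (tau2 + sigma2), weights = w)
}

#' Classify a meta-analytic sample into size and heterogeneity bins
#'
#' Heterogeneity bins are the half-open intervals low: \eqn{I^2 \le 0.25},
#' moderate: \eqn{0.25 < I^2 \le 0.75}, high: \eqn{I^2 > 0.75}. The size bin
#' is the nearest member of the declared bin list not exceeded by rounding
#' midpoints: n is assigned to the bin whose value is closest (ties to the
#' larger bin).
#'
#' @param n sample size (number of estimates).
#' @param i2 I-squared in `[0, 1]`.
#' @param size_bins numeric vector of declared size bins.
#' @return list with `size_bin` (numeric) and `het_bin` (character).
#' @export
classify_cell <- function(n, i2,
                          size_bins = c(10, 30, 60, 100, 200, 400, 800)) {
  stopifnot(n >= 1, i2 >= 0, i2 <= 1)
  het <- if (i2 <= 0.25) "low" else if (i2 <= 0.75) "moderate" else "high"
  d <- abs(size_bins - n)
  size_bin <- size_bins[max(which(d == min(d)))]
  list(size_bin = size_bin, het_bin = het)
}
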