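# p-curve and p-uniform: estimators built on the conditional p-values of
# statistically significant positive estimates. Under the true mean effect,
# the conditional probability of observing an estimate at least as large,
# given that it cleared the significance threshold, is Uniform(0, 1); both
# estimators choose the mu that makes the observed conditional p-values look
# uniform.

#' Significant positive subset of a sample
#'
#' Retains the estimates with \eqn{\hat\beta_i/SE_i \ge 1.96} (positive and
#' statistically significant at the two-sided 5 percent level).
#'
#' @param sample an [effect_sample].
#' @return an [effect_sample] of the retained estimates, with attribute `k`
#'   (count retained); `NULL` when none qualify.
#' @export
significant_subset <- function(sample) {
  keep <- sample$effects / sample$ses >= 1.96
  if (!any(keep)) return(NULL)
  out <- effect_sample(sample$effects[keep], sample$ses[keep],
                       true_mu = sample$true_mu)
  attr(out, "k") <- sum(keep)
  out
}

#' Conditional p-value of a significant estimate
#'
#' The probability, under true mean `mu` with normal sampling, of an estimate
#' at least as large as the one observed given that it is significant:
#' \eqn{q = P(\hat\beta \ge b \mid \hat\beta \ge 1.96\,SE) =
#' [1-\Phi((b-\mu)/SE)] / [1-\Phi(1.96-\mu/SE)]}. Computed on the log scale
#' to survive deep-tail underflow and clamped to (1e-300, 1).
#'
#' @param effect,se the estimate and its standard error (vectorized);
#'   requires `effect/se >= 1.96`.
#' @param mu candidate true mean effect.
#' @return vector of conditional p-values in (0, 1].
#' @export
conditional_p <- function(effect, se, mu) {
  if (any(effect / se < 1.96 - 1e-12))
    stop("conditional_p: estimates must be significant (effect/se >= 1.96)")
  lnum <- stats::pnorm(effect, mean = mu, sd = se,
                       lower.tail = FALSE, log.p = TRUE)
  lden <- stats::pnorm(1.96 * se, mean = mu, sd = se,
                       lower.tail = FALSE, log.p = TRUE)
  pmin(pmax(exp(lnum - lden), 1e-300), 1)
}

# Kolmogorov-Smirnov distance between a sample of values in (0,1] and the
# Uniform(0,1) distribution.
ks_uniform <- function(q) {
  q <- sort(q)
  k <- length(q)
  i <- seq_len(k)
  max(pmax(abs(i / k - q), abs(q - (i - 1) / k)))
}

#' p-curve estimator
#'
#' Chooses the mean true effect minimizing the Kolmogorov-Smirnov distance
#' between the conditional p-values of the significant positive estimates and
#' Uniform(0, 1). Searches mu on \[-2, 5\] effect-size units: a 500-point
#' coarse scan (ties toward the smaller mu) followed by golden-section
#' refinement around the grid minimum. p-curve produces no standard error or
#' confidence interval in any code path.
#'
#' @param sample an [effect_sample].
#' @return a [new_estimate] with `se_hat`/CI absent; non-converged when fewer
#'   than two significant positive estimates exist or the minimizer sits on
#'   the search boundary.
#' @export
pcurve_estimate <- function(sample) {
  sub <- significant_subset(sample)
  k <- if (is.null(sub)) 0L else attr(sub, "k")
  if (k < 2L)
    return(non_converged("pC", aux = list(k = k, reason = "k < 2")))
  obj <- function(mu) ks_uniform(conditional_p(sub$effects, sub$ses, mu))
  lo <- -2; hi <- 5
  grid <- seq(lo, hi, length.out = 500L)
  vals <- vapply(grid, obj, numeric(1L))
  i <- which.min(vals)  # first minimum: ties broken toward smaller mu
  bl <- grid[max(i - 1L, 1L)]
  bu <- grid[min(i + 1L, length(grid))]
  ref <- stats::optimize(obj, interval = c(bl, bu), tol = 1e-8)
  mu_hat <- if (ref$objective <= vals[i]) ref$minimum else grid[i]
  interior <- mu_hat > lo + 1e-6 && mu_hat < hi - 1e-6
  new_estimate("pC", mu_hat = mu_hat, se_hat = NA_real_,
               converged = interior,
               aux = list(k = k, ks_dist = obj(mu_hat)))
}

#' Irwin-Hall distribution function
#'
#' CDF of the sum of `k` independent Uniform(0,1) variables. Uses the exact
#' alternating-sum formula for `k <= 50` and the normal approximation (mean
#' k/2, variance k/12) above.
#'
#' @param x quantile.
#' @param k number of uniform summands.
#' @return P(S_k <= x).
#' @export
irwin_hall_cdf <- function(x, k) {
  if (x <= 0) return(0)
  if (x >= k) return(1)
  if (k > 50L)
    return(stats::pnorm(x, mean = k / 2, sd = sqrt(k / 12)))
  # the alternating sum cancels catastrophically for x > k/2; use the
  # symmetry of the distribution to keep the summation short
  if (x > k / 2) return(1 - irwin_hall_cdf(k - x, k))
  j <- 0:floor(x)
  val <- sum((-1)^j * choose(k, j) * (x - j)^k) / factorial(k)
  min(max(val, 0), 1)
}

# Quantile of the Irwin-Hall distribution by bisection on the CDF.
irwin_hall_q <- function(p, k) {
  if (k > 50L)
    return(stats::qnorm(p, mean = k / 2, sd = sqrt(k / 12)))
  stats::uniroot(function(x) irwin_hall_cdf(x, k) - p,
                 lower = 0, upper = k, tol = 1e-10)$root
}

# Root of sum(q_i(mu)) = target in mu; sum is strictly increasing in mu.
# Bracket expanded geometrically until a sign change, bounded at +-50.
puniform_root <- function(effects, ses, target) {
  f <- function(mu) sum(conditional_p(effects, ses, mu)) - target
  lo <- -1; hi <- 1
  while (f(lo) > 0 && lo > -50) lo <- lo * 2
  while (f(hi) < 0 && hi < 50) hi <- hi * 2
  if (f(lo) > 0 || f(hi) < 0) return(NA_real_)
  stats::uniroot(f, lower = lo, upper = hi, tol = 1e-9)$root
}

#' p-uniform estimator
#'
#' Solves \eqn{\sum_i q_i(\mu) = k/2} (the Irwin-Hall mean) for mu over the
#' significant positive estimates; the 95 percent confidence bounds solve the
#' same equation at the 0.025 and 0.975 Irwin-Hall quantiles. The reported
#' standard error, `(ci_high - ci_low)/(2 * 1.96)`, is bookkeeping for the
#' evaluation harness; coverage uses the interval itself.
#'
#' @param sample an [effect_sample].
#' @return a [new_estimate]; non-converged when no estimate is significant or
#'   no root exists within +-50 effect-size units.
#' @export
puniform_estimate <- function(sample) {
  sub <- significant_subset(sample)
  k <- if (is.null(sub)) 0L else attr(sub, "k")
  if (k < 1L)
    return(non_converged("pU", aux = list(k = k, reason = "k = 0")))
  mu <- puniform_root(sub$effects, sub$ses, k / 2)
  if (!is.finite(mu))
    return(non_converged("pU", aux = list(k = k, reason = "no root")))
  ci_low <- puniform_root(sub$effects, sub$ses, irwin_hall_q(0.025, k))
  ci_high <- puniform_root(sub$effects, sub$ses, irwin_hall_q(0.975, k))
  se <- if (is.finite(ci_low) && is.finite(ci_high))
    (ci_high - ci_low) / (2 * stats::qnorm(0.975)) else NA_real_
  new_estimate("pU", mu_hat = mu, se_hat = se,
               ci_low = ci_low, ci_high = ci_high,
               converged = TRUE, df = Inf, aux = list(k = k))
}
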