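# Step-function selection models estimated by maximum likelihood.
#
# The observed effects are modelled as draws from beta ~ N(mu, SE^2 + tau2)
# that survive publication with a relative probability depending only on the
# group of the z-statistic z = beta/SE. With group weights w_g (reference
# group fixed at 1), the published-data density is the weighted normal
# density renormalized by A_i = sum_g w_g P(group g | mu, tau2, SE_i), where
# the group probabilities come from the normal CDF evaluated at the
# effect-scale cutpoints cut_z * SE_i.

#' Step-selection specification
#'
#' Defines the z-statistic grouping of a step-function selection model.
#' `kind = "signed"` partitions the real line at the cutpoints (membership
#' half-open, ties at a cutpoint going to the higher group); `kind =
#' "absolute"` partitions |z| (used by the symmetric-selection model). The
#' reference group -- always the top group, i.e. significant (positive)
#' estimates -- has its relative publication probability fixed at 1.
#'
#' @param cut_z strictly increasing cutpoints on the z (or |z|) scale.
#' @param kind `"signed"` or `"absolute"`.
#' @return a `step_spec` object; `n_groups = length(cut_z) + 1`.
#' @export
step_spec <- function(cut_z, kind = c("signed", "absolute")) {
  kind <- match.arg(kind)
  cut_z <- as.numeric(cut_z)
  if (is.unsorted(cut_z, strictly = TRUE))
    stop("step_spec: cutpoints must be strictly increasing")
  if (kind == "absolute" && any(cut_z < 0))
    stop("step_spec: absolute cutpoints must be non-negative")
  structure(list(cut_z = cut_z, kind = kind,
                 n_groups = length(cut_z) + 1L,
                 ref_group = length(cut_z) + 1L),
            class = "step_spec")
}

# Group membership of each observation (1 = lowest, n_groups = reference).
step_groups <- function(sample, spec) {
  z <- sample$effects / sample$ses
  if (spec$kind == "absolute") z <- abs(z)
  1L + colSums(outer(spec$cut_z, z, FUN = `<=`))
}

# n x n_groups matrix of group probabilities P(group g | mu, tau2, SE_i).
step_group_probs <- function(ses, spec, mu, tau2) {
  s <- sqrt(ses^2 + tau2)
  k <- length(spec$cut_z)
  # CDF of beta at each effect-scale cutpoint, n x k
  cdf_at <- function(cz) stats::pnorm((cz * ses - mu) / s)
  if (spec$kind == "signed") {
    # F[, j] = P(z < cut_j); group j = F_j - F_{j-1} with F_0 = 0, F_{k+1} = 1
    F <- matrix(vapply(spec$cut_z, cdf_at, numeric(length(ses))),
                nrow = length(ses))
    cbind(F, 1) - cbind(0, F)
  } else {
    # groups on |z|: I[, j] = P(|z| < cut_j)
    I <- matrix(vapply(spec$cut_z, function(cz) cdf_at(cz) - cdf_at(-cz),
                       numeric(length(ses))),
                nrow = length(ses))
    cbind(I, 1) - cbind(0, I)
  }
}

#' Step-selection log-likelihood
#'
#' Log-likelihood of a published sample under the weighted-density
#' step-selection model: \eqn{\sum_i [\ln w_{g(i)} + \ln\phi((\hat\beta_i -
#' \mu)/s_i) - \ln s_i - \ln A_i]} with \eqn{s_i = \sqrt{SE_i^2+\tau^2}} and
#' \eqn{A_i} the probability-weighted normalizer. With all relative
#' probabilities equal to 1 this is exactly the unweighted random-effects
#' log-likelihood.
#'
#' @param sample an [effect_sample].
#' @param spec a [step_spec].
#' @param mu mean true effect.
#' @param tau2 heterogeneity variance, >= 0.
#' @param probs relative publication probabilities, one per group, with the
#'   reference (top) group equal to 1.
#' @return scalar log-likelihood; `-Inf` signals an invalid parameter point.
#' @export
step_loglik <- function(sample, spec, mu, tau2, probs) {
  if (length(probs) != spec$n_groups)
    stop("step_loglik: probs must have one entry per group")
  if (!is.finite(mu) || !is.finite(tau2) || tau2 < 0 ||
      any(!is.finite(probs)) || any(probs <= 0)) return(-Inf)
  g <- step_groups(sample, spec)
  s <- sqrt(sample$ses^2 + tau2)
  P <- step_group_probs(sample$ses, spec, mu, tau2)
  A <- as.numeric(P %*% probs)
  if (any(A <= 0)) return(-Inf)
  sum(log(probs[g]) +
        stats::dnorm(sample$effects, mean = mu, sd = s, log = TRUE) - log(A))
}

# transform keeping relative probabilities in (1e-4, 100)
.prob_lo <- 1e-4
.prob_hi <- 100
prob_fwd <- function(p) stats::qlogis((p - .prob_lo) / (.prob_hi - .prob_lo))
prob_inv <- function(u) .prob_lo + (.prob_hi - .prob_lo) * stats::plogis(u)

# Central-difference Hessian of f at x (f returns a scalar).
num_hessian <- function(f, x, eps = NULL) {
  p <- length(x)
  if (is.null(eps)) eps <- pmax(1e-4, 1e-3 * abs(x))
  H <- matrix(NA_real_, p, p)
  f0 <- f(x)
  for (i in seq_len(p)) {
    for (j in i:p) {
      ei <- ej <- numeric(p)
      ei[i] <- eps[i]; ej[j] <- eps[j]
      if (i == j) {
        H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / eps[i]^2
      } else {
        H[i, j] <- H[j, i] <-
          (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) +
             f(x - ei - ej)) / (4 * eps[i] * eps[j])
      }
    }
  }
  H
}

# Multi-start MLE of (mu, tau2, free probs). Reference group probability is
# fixed at 1. Returns a bb_estimate with aux$probs, aux$loglik.
fit_step_model <- function(sample, spec, estimator, min_n, df_resid) {
  n <- length(sample$effects)
  if (n < min_n)
    stop(sprintf("%s: requires at least %d observations", estimator, min_n))
  g <- step_groups(sample, spec)
  counts <- tabulate(g, nbins = spec$n_groups)
  if (any(counts == 0L))
    return(non_converged(estimator,
                         aux = list(reason = "empty z-statistic group",
                                    group_counts = counts)))
  m <- spec$n_groups - 1L  # free probabilities
  full_probs <- function(pf) c(pf, 1)

  negll <- function(theta) {
    mu <- theta[1L]
    tau2 <- exp(theta[2L])
    pf <- prob_inv(theta[2L + seq_len(m)])
    ll <- step_loglik(sample, spec, mu, tau2, full_probs(pf))
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  re <- re_reml_estimate(sample)
  lt0 <- log(max(re$tau2_hat, 1e-4))
  sd_eff <- stats::sd(sample$effects)
  starts <- list(
    c(re$mu_hat, lt0, rep(prob_fwd(1), m)),
    c(re$mu_hat - 0.5 * sd_eff, lt0, rep(prob_fwd(0.2), m)),
    c(re$mu_hat + 0.25 * sd_eff, log(max(2 * re$tau2_hat, 1e-3)),
      rep(prob_fwd(3), m))
  )
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      stats::optim(st, negll, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-10)),
      error = function(e) NULL)
    if (is.null(fit))
      fit <- tryCatch(
        stats::optim(st, negll, method = "Nelder-Mead",
                     control = list(maxit = 2000)),
        error = function(e) NULL)
    if (!is.null(fit) && is.finite(fit$value) &&
        (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best) || best$value >= 1e10)
    return(non_converged(estimator, aux = list(reason = "optimizer failure")))

  mu <- best$par[1L]
  tau2 <- exp(best$par[2L])
  probs <- prob_inv(best$par[2L + seq_len(m)])
  ll <- -best$value

  # Observed information on the untransformed scale. Parameters pinned at
  # their boundary (tau2 ~ 0, probs at the transform limits) are profiled
  # out of the Hessian; mu is always retained.
  raw <- c(mu, tau2, probs)
  active <- c(TRUE, tau2 > 1e-6,
              probs > 2 * .prob_lo & probs < 0.99 * .prob_hi)
  negll_raw <- function(x) {
    full <- raw
    full[active] <- x
    ll <- step_loglik(sample, spec, full[1L], max(full[2L], 0),
                      full_probs(full[2L + seq_len(m)]))
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  ses <- rep(NA_real_, m + 2L)
  H <- tryCatch(num_hessian(negll_raw, raw[active]), error = function(e) NULL)
  if (!is.null(H) && all(is.finite(H))) {
    V <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(V)) {
      d <- diag(V)
      if (all(d > 0)) ses[active] <- sqrt(d)
    }
  }
  se_mu <- ses[1L]
  conv <- best$convergence == 0 && is.finite(se_mu)
  crit <- if (is.finite(df_resid)) stats::qt(0.975, df = df_resid)
          else stats::qnorm(0.975)
  new_estimate(estimator, mu_hat = mu, se_hat = se_mu,
               ci_low = mu - crit * se_mu, ci_high = mu + crit * se_mu,
               converged = conv, tau2_hat = tau2, df = df_resid,
               aux = list(probs = probs, loglik = ll,
                          group_counts = counts, se_all = ses))
}

#' Three-parameter selection model (3PSM)
#'
#' Maximum-likelihood step-selection model with two z-statistic groups split
#' at 1.96: positive-and-significant estimates (reference, relative
#' publication probability 1) versus everything else (probability `p1`).
#' Parameters: mu, tau2, p1. Inference uses normal critical values.
#'
#' @param sample an [effect_sample] with N >= 3.
#' @return a [new_estimate] with `aux$probs = c(p1, 1)`.
#' @export
psm3_estimate <- function(sample) {
  fit_step_model(sample, step_spec(1.96, "signed"), "3PSM",
                 min_n = 3L, df_resid = Inf)
}

#' Four-parameter selection model (4PSM)
#'
#' As [psm3_estimate()] with three groups: negative (`p2`), positive but
#' insignificant (`p1`), and positive-significant (reference). Parameters:
#' mu, tau2, p1, p2.
#'
#' @param sample an [effect_sample] with N >= 3.
#' @return a [new_estimate] with `aux$probs = c(p2, p1, 1)` ordered from the
#'   lowest z group upward.
#' @export
psm4_estimate <- function(sample) {
  fit_step_model(sample, step_spec(c(0, 1.96), "signed"), "4PSM",
                 min_n = 3L, df_resid = Inf)
}

#' Symmetric-selection maximum-likelihood model (AK1)
#'
#' Groups estimates by |z| without regard to sign: significant (reference)
#' versus insignificant (`p1`). Requires at least 4 observations; p-values
#' and confidence intervals use a t distribution with N - 3 degrees of
#' freedom.
#'
#' @param sample an [effect_sample] with N >= 4.
#' @return a [new_estimate].
#' @export
ak1_estimate <- function(sample) {
  n <- length(sample$effects)
  if (n < 4L) stop("AK1: requires at least 4 observations")
  fit_step_model(sample, step_spec(1.96, "absolute"), "AK1",
                 min_n = 4L, df_resid = n - 3L)
}

#' Asymmetric-selection maximum-likelihood model (AK2)
#'
#' Four signed z-statistic groups split at -1.96, 0, and 1.96 with relative
#' publication probabilities (p1, p2, p3) and the positive-significant group
#' as reference. Requires at least 6 observations; t inference with N - 5
#' degrees of freedom.
#'
#' @param sample an [effect_sample] with N >= 6.
#' @return a [new_estimate].
#' @export
ak2_estimate <- function(sample) {
  n <- length(sample$effects)
  if (n < 6L) stop("AK2: requires at least 6 observations")
  fit_step_model(sample, step_spec(c(-1.96, 0, 1.96), "signed"), "AK2",
                 min_n = 6L, df_resid = n - 5L)
}
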