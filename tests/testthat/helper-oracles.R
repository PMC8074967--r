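# Shared fixtures and independent oracles for the test suite. Oracles here
# deliberately avoid the package's own computational paths: closed-form
# normal-equation solves, dense grid searches, and quadrature.

# Weighted least squares by explicit normal equations.
oracle_wls <- function(X, y, w) {
  XtW <- t(X * w)
  beta <- solve(XtW %*% X, XtW %*% y)[, 1L]
  res <- y - X %*% beta
  sigma2 <- sum(w * res^2) / (nrow(X) - ncol(X))
  V <- solve(XtW %*% X) * sigma2
  list(coef = beta, se = sqrt(diag(V)))
}

# Dense grid search for the REML tau2 (restricted likelihood written out
# independently of the package's reml_loglik).
oracle_reml_tau2 <- function(effects, v, upper = 10, npts = 1e4) {
  grid <- seq(0, upper, length.out = npts)
  ll <- vapply(grid, function(t2) {
    vi <- v + t2
    w <- 1 / vi
    mu <- sum(w * effects) / sum(w)
    -0.5 * (sum(log(vi)) + log(sum(w)) + sum(w * (effects - mu)^2))
  }, numeric(1L))
  grid[which.max(ll)]
}

# Step-selection log-likelihood with the normalizer A_i computed by
# numerical quadrature of the weighted density (signed grouping).
oracle_step_loglik_quadrature <- function(effects, ses, cut_z, mu, tau2,
                                          probs) {
  s <- sqrt(ses^2 + tau2)
  gidx <- function(z) 1L + sum(z >= cut_z)
  sum(vapply(seq_along(effects), function(i) {
    A <- stats::integrate(function(b) {
      w <- probs[vapply(b / ses[i], gidx, integer(1L))]
      w * stats::dnorm(b, mu, s[i])
    }, lower = mu - 12 * s[i], upper = mu + 12 * s[i],
    subdivisions = 2000L, rel.tol = 1e-10)$value
    z <- effects[i] / ses[i]
    log(probs[gidx(z)]) + stats::dnorm(effects[i], mu, s[i], log = TRUE) -
      log(A)
  }, numeric(1L)))
}

# Random-effects log-likelihood (unrestricted, observation-level).
oracle_re_loglik <- function(effects, ses, mu, tau2) {
  sum(stats::dnorm(effects, mu, sqrt(ses^2 + tau2), log = TRUE))
}

# Fixed small samples used across files.
fix_sample_5 <- function() {
  effect_sample(c(0.12, 0.45, 0.30, 0.62, 0.05),
                c(0.10, 0.20, 0.15, 0.30, 0.08))
}

fix_sample_20 <- function(seed = 11) {
  set.seed(seed)
  ses <- runif(20, 0.05, 0.4)
  effect_sample(rnorm(20, 0.3, sqrt(0.02 + ses^2)), ses)
}

# Sample drawn under the step-selection model itself by rejection sampling:
# true (mu, tau, p1) with significance cut at z = 1.96 (3PSM world).
draw_psm3_sample <- function(n, mu, tau, p1, se_range = c(0.05, 0.5)) {
  eff <- numeric(n); ses <- numeric(n)
  got <- 0L
  while (got < n) {
    se <- runif(1L, se_range[1L], se_range[2L])
    b <- rnorm(1L, mu, sqrt(tau^2 + se^2))
    keep <- if (b / se >= 1.96) TRUE else runif(1L) < p1
    if (keep) {
      got <- got + 1L
      eff[got] <- b; ses[got] <- se
    }
  }
  effect_sample(eff, ses, true_mu = mu)
}

# Significant-positive-only sample (pure significance selection, tau = 0).
draw_sig_only_sample <- function(k, mu, se_range = c(0.1, 0.5)) {
  eff <- numeric(k); ses <- numeric(k)
  got <- 0L
  while (got < k) {
    se <- runif(1L, se_range[1L], se_range[2L])
    b <- rnorm(1L, mu, se)
    if (b / se >= 1.96) {
      got <- got + 1L
      eff[got] <- b; ses[got] <- se
    }
  }
  effect_sample(eff, ses, true_mu = mu)
}
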