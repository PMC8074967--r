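test_that("step log-likelihood reduces to the RE log-likelihood when all
          probabilities are 1", {
  s <- fix_sample_20()
  specs <- list(step_spec(1.96, "signed"),
                step_spec(c(0, 1.96), "signed"),
                step_spec(1.96, "absolute"),
                step_spec(c(-1.96, 0, 1.96), "signed"))
  for (sp in specs) {
    for (pars in list(c(0.2, 0.05), c(0, 0.01), c(-0.4, 0.2))) {
      expect_equal(
        step_loglik(s, sp, pars[1], pars[2], rep(1, sp$n_groups)),
        oracle_re_loglik(s$effects, s$ses, pars[1], pars[2]),
        tolerance = 1e-10)
    }
  }
})

test_that("step log-likelihood matches a hand calculation and quadrature", {
  # single observation, mu = 0, tau2 = 0, cut at 1.96, p1 = 0.5:
  # z = 1 -> insignificant group, weight 0.5;
  # A = 0.5 * P(z < 1.96) + 1 * P(z >= 1.96)
  s1 <- effect_sample(1, 1)
  A <- 0.5 * pnorm(1.96) + (1 - pnorm(1.96))
  by_hand <- log(0.5) + dnorm(1, 0, 1, log = TRUE) - log(A)
  expect_equal(step_loglik(s1, step_spec(1.96, "signed"), 0, 0, c(0.5, 1)),
               by_hand, tolerance = 1e-12)

  # quadrature oracle for the normalizer on random parameter points
  set.seed(21)
  s <- fix_sample_5()
  for (i in 1:10) {
    mu <- runif(1, -0.5, 0.8)
    tau2 <- runif(1, 0, 0.2)
    p1 <- runif(1, 0.05, 2)
    expect_equal(
      step_loglik(s, step_spec(1.96, "signed"), mu, tau2, c(p1, 1)),
      oracle_step_loglik_quadrature(s$effects, s$ses, 1.96, mu, tau2,
                                    c(p1, 1)),
      tolerance = 1e-6)
  }
})

test_that("3PSM MLE agrees with a dense grid search on a small sample", {
  set.seed(3)
  s <- draw_psm3_sample(30, mu = 0.3, tau = 0.2, p1 = 0.3)
  fit <- psm3_estimate(s)
  expect_true(fit$converged)
  sp <- step_spec(1.96, "signed")
  grid_mu <- seq(fit$mu_hat - 0.3, fit$mu_hat + 0.3, length.out = 41)
  grid_t2 <- seq(max(0, fit$tau2_hat - 0.05), fit$tau2_hat + 0.05,
                 length.out = 41)
  grid_p1 <- seq(max(0.01, fit$aux$probs[1] - 0.3), fit$aux$probs[1] + 0.3,
                 length.out = 41)
  best <- -Inf; arg <- NULL
  for (m in grid_mu) for (t2 in grid_t2) for (p in grid_p1) {
    ll <- step_loglik(s, sp, m, t2, c(p, 1))
    if (ll > best) { best <- ll; arg <- c(m, t2, p) }
  }
  # the optimizer should not be beaten by the grid, and should sit within
  # one grid step of the grid argmax
  expect_gte(fit$aux$loglik, best - 1e-6)
  expect_lt(abs(fit$mu_hat - arg[1]), 0.3 / 20)
  expect_lt(abs(fit$tau2_hat - arg[2]), 0.05 / 20 + 1e-6)
})

test_that("selection-model MLE is scale-equivariant", {
  set.seed(8)
  s <- draw_psm3_sample(40, mu = 0.4, tau = 0.15, p1 = 0.5)
  c0 <- 2.5
  s_scaled <- effect_sample(s$effects * c0, s$ses * c0)
  f1 <- psm3_estimate(s)
  f2 <- psm3_estimate(s_scaled)
  expect_equal(f2$mu_hat, c0 * f1$mu_hat, tolerance = 1e-4)
  expect_equal(f2$tau2_hat, c0^2 * f1$tau2_hat, tolerance = 1e-3)
  expect_equal(f2$aux$probs, f1$aux$probs, tolerance = 1e-3)
})

test_that("observed-information SEs match an independent central-difference
          Hessian", {
  set.seed(13)
  s <- draw_psm3_sample(60, mu = 0.3, tau = 0.2, p1 = 0.4)
  fit <- psm3_estimate(s)
  expect_true(fit$converged)
  sp <- step_spec(1.96, "signed")
  th <- c(fit$mu_hat, fit$tau2_hat, fit$aux$probs[1])
  nll <- function(x) -step_loglik(s, sp, x[1], x[2], c(x[3], 1))
  # Richardson-style two-step central differences, independent of the
  # package's num_hessian step choice
  h <- pmax(5e-4, 5e-4 * abs(th))
  H <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    ei <- ej <- numeric(3); ei[i] <- h[i]; ej[j] <- h[j]
    H[i, j] <- (nll(th + ei + ej) - nll(th + ei - ej) -
                  nll(th - ei + ej) + nll(th - ei - ej)) / (4 * h[i] * h[j])
  }
  se_oracle <- sqrt(diag(solve(H)))
  expect_equal(fit$se_hat, se_oracle[1], tolerance = 1e-3)
})

test_that("4PSM and AK wrappers enforce their observation minima and
          degenerate cases", {
  expect_error(ak1_estimate(effect_sample(c(1, 2, 3), c(1, 1, 1))),
               "at least 4")
  expect_error(ak2_estimate(effect_sample(rnorm(5), rep(0.2, 5))),
               "at least 6")

  # empty negative group -> 4PSM unidentified -> non-converged
  s_pos <- effect_sample(c(0.5, 0.6, 0.7, 0.8, 0.9, 1.0) + 2,
                         rep(0.1, 6))
  f <- psm4_estimate(s_pos)
  if (!f$converged) expect_match(f$aux$reason, "empty")
  # here every z >> 1.96, so both lower groups are empty
  expect_false(f$converged)
})

test_that("AK1 grid-search agreement and RE collapse without selection", {
  set.seed(17)
  ses <- runif(60, 0.05, 0.4)
  s <- effect_sample(rnorm(60, 0.3, sqrt(0.04 + ses^2)), ses)

  # no selection: fitted p1 should be near 1 and mu near the RE fit
  f <- ak1_estimate(s)
  re <- re_reml_estimate(s)
  expect_true(f$converged)
  expect_lt(abs(f$mu_hat - re$mu_hat), 0.05)

  # grid search over (mu, tau2) at the fitted p1 cannot beat the MLE
  sp <- step_spec(1.96, "absolute")
  lls <- outer(seq(f$mu_hat - 0.2, f$mu_hat + 0.2, length.out = 31),
               seq(max(0, f$tau2_hat - 0.03), f$tau2_hat + 0.03,
                   length.out = 31),
               Vectorize(function(m, t2)
                 step_loglik(s, sp, m, t2, c(f$aux$probs[1], 1))))
  expect_gte(f$aux$loglik, max(lls) - 1e-6)
})

test_that("bias of the selection-model mean shrinks with sample size", {
  set.seed(23)
  reps <- 60
  err <- function(n) {
    mean(vapply(seq_len(reps), function(r) {
      s <- draw_psm3_sample(n, mu = 0.3, tau = 0.2, p1 = 0.3)
      f <- psm3_estimate(s)
      if (f$converged) f$mu_hat - 0.3 else NA_real_
    }, numeric(1)), na.rm = TRUE)
  }
  expect_lt(abs(err(400)), abs(err(50)) + 0.02)
})

test_that("AK2 detects asymmetric selection qualitatively", {
  # strong selection under which negative-significant estimates almost never
  # survive: fitted p1 (negative-significant group) should sit below p3
  # (positive-insignificant). A small survival probability keeps the group
  # occupied, since an empty group is (correctly) reported non-converged.
  set.seed(29)
  draw_ak2 <- function(n) {
    eff <- numeric(n); ses <- numeric(n); got <- 0
    while (got < n) {
      se <- runif(1, 0.05, 0.5)
      b <- rnorm(1, 0.1, sqrt(0.09 + se^2))
      z <- b / se
      keep <- if (z >= 1.96) TRUE
        else if (z <= -1.96) runif(1) < 0.05
        else runif(1) < 0.4
      if (keep) { got <- got + 1; eff[got] <- b; ses[got] <- se }
    }
    effect_sample(eff, ses)
  }
  p1s <- c(); p3s <- c()
  for (r in 1:25) {
    f <- ak2_estimate(draw_ak2(120))
    if (f$converged) { p1s <- c(p1s, f$aux$probs[1]); p3s <- c(p3s, f$aux$probs[3]) }
  }
  expect_gt(length(p1s), 5)
  expect_lt(median(p1s), median(p3s))
})
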