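test_that("primary draws have the analytic SE at the null", {
  set.seed(71)
  # Cohen's d, alpha1 = 0, no heterogeneity, n = 50 per group
  cfg <- env_config("sdi_cohend", alpha1 = 0, sigma2_h = 0,
                    primary_n_pool = 50)
  d <- do.call(rbind, replicate(4000, draw_primary_estimate(cfg),
                                simplify = FALSE))
  expect_lt(abs(mean(d$effect)), 4 * sd(d$effect) / sqrt(4000))
  expect_equal(mean(d$se), sqrt(2 / 50), tolerance = 0.02)

  # log OR at the null: SE near sqrt(sum of reciprocal expected cells)
  cfg2 <- env_config("sdi_logor", alpha1 = 0, sigma2_h = 0,
                     primary_n_pool = 250)
  d2 <- do.call(rbind, replicate(3000, draw_primary_estimate(cfg2),
                                 simplify = FALSE))
  se_analytic <- sqrt(2 / (250 * 0.1) + 2 / (250 * 0.9))
  expect_lt(abs(mean(d2$effect)), 4 * sd(d2$effect) / sqrt(3000))
  expect_equal(mean(d2$se), se_analytic, tolerance = 0.05)
})

test_that("Cohen's d draws match the small-sample expectation of d", {
  set.seed(73)
  cfg <- env_config("sdi_cohend", alpha1 = 0.5, sigma2_h = 0,
                    primary_n_pool = 50)
  d <- do.call(rbind, replicate(20000, draw_primary_estimate(cfg),
                                simplify = FALSE))
  # E[d] = delta * sqrt(df/2) * Gamma((df-1)/2)/Gamma(df/2), df = 2n-2
  df <- 98
  e_d <- 0.5 * sqrt(df / 2) * exp(lgamma((df - 1) / 2) - lgamma(df / 2))
  expect_lt(abs(mean(d$effect) - e_d), 4 * sd(d$effect) / sqrt(20000))
})

test_that("omitted-variable draws are unbiased when the regressors are
          orthogonal", {
  set.seed(79)
  cfg <- env_config("br_omv", alpha1 = 0.3, sigma2_h = 0.5,
                    primary_n_pool = 100, extra = list(rho_x = 0))
  d <- do.call(rbind, replicate(3000, draw_primary_estimate(cfg),
                                simplify = FALSE))
  expect_lt(abs(mean(d$effect) - 0.3), 4 * sd(d$effect) / sqrt(3000))
})

test_that("published effects are unbiased without selection in every
          environment", {
  set.seed(83)
  for (env in c("sdi_cohend", "sdi_logor", "ar_re", "br_omv", "ar_panel",
                "csgh")) {
    cfg <- env_config(env, alpha1 = 0.3, sigma2_h = 0.02, n_target = 40,
                      primary_n_pool = c(64, 125, 250))
    eff <- unlist(replicate(60, apply_selection(cfg)$effects,
                            simplify = FALSE))
    mc <- sd(eff) / sqrt(length(eff))
    # logOR estimates carry small-sample bias of order 1/n; allow for it
    expect_lt(abs(mean(eff) - 0.3), 4 * mc + 0.01)
  }
})

test_that("selection regimes enforce their publication rules", {
  base <- function(sel) env_config("sdi_cohend", alpha1 = 0.2,
                                   sigma2_h = 0.02, selection = sel,
                                   n_target = 60,
                                   primary_n_pool = c(16, 32, 64))
  # incidence 1: every published estimate positive and significant
  set.seed(89)
  s <- apply_selection(base(sel_incidence(1)))
  expect_true(all(s$effects / s$ses >= 1.96))
  expect_true(all(s$effects > 0))

  # 75/100% regime: all published estimates positive
  for (r in 1:5) {
    s2 <- apply_selection(base(sel_always_positive(0.75)))
    expect_gt(min(s2$effects), 0)
  }

  # incidence 0 is a no-op regime: published effects share the raw draw
  # distribution (KS test on pooled draws)
  set.seed(97)
  raw_eff <- do.call(rbind, replicate(2000,
    draw_primary_estimate(base(sel_none())), simplify = FALSE))$effect
  zero_eff <- unlist(replicate(33, apply_selection(base(sel_incidence(0)))$effects,
                               simplify = FALSE))
  expect_gt(suppressWarnings(ks.test(raw_eff, zero_eff)$p.value), 0.01)

  # selection never alters the SEs: published (effect, se) pairs are a
  # subset of the raw draw stream under matched seeds
  cfg_pool <- base(sel_ar_prob(0.1))
  set.seed(101); raw <- do.call(rbind, replicate(60,
    draw_primary_estimate(cfg_pool), simplify = FALSE))
  set.seed(101); pub <- apply_selection(cfg_pool)
  expect_true(all(pub$ses %in% raw$se))
})

test_that("endogenous sample size grows with the true effect under
          pool-based selection", {
  set.seed(103)
  n_pub <- function(a1) {
    cfg <- env_config("ar_re", alpha1 = a1, sigma2_h = 0.01,
                      selection = sel_ar_prob(0.1), n_target = 100,
                      primary_n_pool = c(64, 125))
    mean(vapply(1:30, function(r) length(apply_selection(cfg)$effects),
                numeric(1)))
  }
  expect_gt(n_pub(0.5), n_pub(0.05) + 5)
})

test_that("fixed seed gives bit-identical samples", {
  cfg <- env_config("csgh", alpha1 = 0.2, sigma2_h = 0.05,
                    selection = sel_csgh("medium"), n_target = 25)
  a <- simulate_meta_sample(cfg, seed = 7)
  b <- simulate_meta_sample(cfg, seed = 7)
  expect_identical(a$effects, b$effects)
  expect_identical(a$ses, b$ses)
})

test_that("QRPs pass through honest studies and inflate significance for
          practicing ones", {
  set.seed(107)
  raw <- draw_csgh_raw(0.1, 40)
  honest <- apply_qrp(raw, practice = FALSE)
  sp <- sqrt((39 * var(raw$y1_t) + 39 * var(raw$y1_c)) / 78)
  d_hand <- (mean(raw$y1_t) - mean(raw$y1_c)) / sp
  expect_equal(unname(honest[["effect"]]), d_hand, tolerance = 1e-12)

  # under mu = 0 the significant-positive rate among QRP-practicing studies
  # exceeds the nominal 2.5%
  set.seed(109)
  n_stud <- 4000  # scaled down from the 1e4-study check
  hits <- vapply(seq_len(n_stud), function(i) {
    est <- apply_qrp(draw_csgh_raw(0, 24), practice = TRUE)
    est[["effect"]] / est[["se"]] >= 1.96
  }, logical(1))
  expect_gt(mean(hits), 0.025 + 3 * sqrt(0.025 * 0.975 / n_stud))

  # optional stopping is capped at 3x the original per-group n: the
  # implied per-group size n = (2 + d^2/4)/se^2 can never exceed the cap
  set.seed(113)
  for (i in 1:50) {
    est <- apply_qrp(draw_csgh_raw(0, 12), practice = TRUE)
    n_implied <- (2 + est[["effect"]]^2 / 4) / est[["se"]]^2
    expect_lte(n_implied, 3 * 12 + 1)
  }
})

test_that("heterogeneity calibration hits a target I2", {
  cfg <- env_config("csgh", alpha1 = 0, sigma2_h = 0, n_target = 60)
  s2h <- calibrate_sigma2h(cfg, target_i2 = 0.6, nsim = 30, seed = 5,
                           tol = 0.02)
  cfg$sigma2_h <- s2h
  set.seed(11)
  i2 <- mean(vapply(1:40, function(r) {
    s <- apply_selection(cfg)
    i_squared(s, re_reml_estimate(s)$tau2_hat)$i2
  }, numeric(1)))
  expect_lt(abs(i2 - 0.6), 0.07)
})
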