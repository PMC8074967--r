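# Synthetic-data generators for the four Monte Carlo environments and their
# publication-selection and QRP mechanisms.
#
# Environments:
#   sdi_logor  - two-group binary-outcome studies, log odds ratio effects
#   sdi_cohend - two-group continuous-outcome studies, Cohen's d effects
#   ar_re      - univariate regressions, one estimate per study
#   ar_panel   - univariate regressions, 10 within-correlated estimates/study
#   br_omv     - univariate regressions with an omitted correlated regressor
#   csgh       - two-group Cohen's d studies, optionally distorted by
#                questionable research practices (QRPs)

#' Selection regimes
#'
#' Constructors for the publication-selection mechanisms applied to the
#' stream of primary-study estimates.
#'
#' * `sel_none()`: every draw is published.
#' * `sel_incidence(incidence)`: each publication slot is "selected" with
#'   probability `incidence`; a selected slot redraws until a positive,
#'   statistically significant estimate appears, an unselected slot publishes
#'   the next draw regardless of sign or significance.
#' * `sel_always_positive(prob)`: positive-significant draws are accepted
#'   with probability `prob`; every published estimate is constrained to be
#'   positive (negative draws are always rejected).
#' * `sel_ar_prob(publish_prob_insig)`: a fixed pre-selection pool of
#'   `n_target` draws is generated; significant-and-positive results publish
#'   with probability 1, all others with probability `publish_prob_insig`, so
#'   the published sample size is endogenous. For the panel environment the
#'   unit of selection is the study: a study publishes outright when at least
#'   `extra$accept_k` of its estimates are significant and positive, and with
#'   probability `publish_prob_insig` otherwise.
#' * `sel_csgh(level)`: per-estimate publication probability by result class:
#'   significant-positive always publishes; insignificant-positive and
#'   negative results publish with class probabilities (defaults: medium
#'   0.20/0.05, strong 0.05/0.00 -- configurable placeholders).
#'
#' @param incidence,prob,publish_prob_insig probabilities in `[0, 1]`.
#' @param level `"medium"` or `"strong"`.
#' @param prob_insig_pos,prob_neg override the class probabilities.
#' @return a `selection_regime` object.
#' @name selection_regimes
NULL

#' @rdname selection_regimes
#' @export
sel_none <- function() {
  structure(list(kind = "none"), class = "selection_regime")
}

#' @rdname selection_regimes
#' @export
sel_incidence <- function(incidence = 0.5) {
  stopifnot(incidence >= 0, incidence <= 1)
  structure(list(kind = "incidence", incidence = incidence),
            class = "selection_regime")
}

#' @rdname selection_regimes
#' @export
sel_always_positive <- function(prob = 0.75) {
  stopifnot(prob >= 0, prob <= 1)
  structure(list(kind = "always_positive_75", prob = prob),
            class = "selection_regime")
}

#' @rdname selection_regimes
#' @export
sel_ar_prob <- function(publish_prob_insig = 0.10) {
  stopifnot(publish_prob_insig >= 0, publish_prob_insig <= 1)
  structure(list(kind = "ar_prob", publish_prob_insig = publish_prob_insig),
            class = "selection_regime")
}

#' @rdname selection_regimes
#' @export
sel_csgh <- function(level = c("medium", "strong"),
                     prob_insig_pos = NULL, prob_neg = NULL) {
  level <- match.arg(level)
  defaults <- switch(level,
                     medium = c(insig_pos = 0.20, neg = 0.05),
                     strong = c(insig_pos = 0.05, neg = 0.00))
  structure(list(kind = "csgh_prob", level = level,
                 prob_sig_pos = 1,
                 prob_insig_pos = if (is.null(prob_insig_pos))
                   defaults[["insig_pos"]] else prob_insig_pos,
                 prob_neg = if (is.null(prob_neg))
                   defaults[["neg"]] else prob_neg),
            class = "selection_regime")
}

#' Environment configuration
#'
#' One cell of the simulation world: which data-generating environment, the
#' true mean effect, the heterogeneity variance, the selection and QRP
#' regimes, and the intended meta-sample size.
#'
#' @param environment one of `"sdi_logor"`, `"sdi_cohend"`, `"ar_re"`,
#'   `"ar_panel"`, `"br_omv"`, `"csgh"`.
#' @param alpha1 true mean effect (log odds ratio, Cohen's d, or slope
#'   units).
#' @param sigma2_h heterogeneity variance of the study-level true effects,
#'   >= 0.
#' @param selection a [selection_regimes] object.
#' @param qrp `"none"`, `"medium"`, or `"high"` (csgh environment only);
#'   the fraction of QRP-practicing studies is 0, 0.5, and 0.9 respectively.
#' @param n_target intended number of published estimates.
#' @param primary_n_pool per-group (two-group designs) or per-study
#'   (regression designs) sample sizes drawn uniformly for each primary
#'   study; entries >= 4.
#' @param extra environment-specific parameters: `rho_x` (X1-X2 correlation,
#'   br_omv, default 0.5), `sigma_eps` (regression error SD, default 1),
#'   `estimates_per_study` (ar_panel, default 10), `accept_k` (ar_panel
#'   study-acceptance threshold, default 7), `rho_within` (ar_panel
#'   intra-study correlation of true effects, default 0.5), `redraw_cap`
#'   (selection redraw limit per slot, default 1e5).
#' @return an `env_config` object.
#' @export
env_config <- function(environment, alpha1, sigma2_h,
                       selection = sel_none(), qrp = "none",
                       n_target = 100L,
                       primary_n_pool = c(16, 32, 64, 125, 250, 500),
                       extra = list()) {
  environment <- match.arg(environment,
                           c("sdi_logor", "sdi_cohend", "ar_re", "ar_panel",
                             "br_omv", "csgh"))
  qrp <- match.arg(qrp, c("none", "medium", "high"))
  stopifnot(sigma2_h >= 0, n_target >= 1, all(primary_n_pool >= 4))
  if (qrp != "none" && environment != "csgh")
    stop("env_config: QRPs are only modelled in the csgh environment")
  defaults <- list(rho_x = 0.5, sigma_eps = 1, estimates_per_study = 10L,
                   accept_k = 7L, rho_within = 0.5, redraw_cap = 1e5,
                   qrp_frac = c(none = 0, medium = 0.5, high = 0.9)[[qrp]])
  extra <- utils::modifyList(defaults, extra)
  structure(list(environment = environment, alpha1 = alpha1,
                 sigma2_h = sigma2_h, selection = selection, qrp = qrp,
                 n_target = as.integer(n_target),
                 primary_n_pool = primary_n_pool, extra = extra),
            class = "env_config")
}

# -- primary-study draws -----------------------------------------------------

# Cohen's d from a two-group study with per-group size n and true
# standardized difference delta: d = t * sqrt(2/n) with t noncentral t
# (2n - 2 df, ncp delta * sqrt(n/2)); conventional SE.
draw_cohend <- function(delta, n) {
  t <- stats::rt(1L, df = 2 * n - 2, ncp = delta * sqrt(n / 2))
  d <- t * sqrt(2 / n)
  se <- sqrt(2 / n + d^2 / (4 * n))
  c(effect = d, se = se)
}

# Log odds ratio from a two-group binary study: control success probability
# 0.10, treatment probability shifted on the logit scale so the study-level
# true log OR is theta. 0.5 added to every cell when any cell is empty.
draw_logor <- function(theta, n) {
  p0 <- 0.10
  p1 <- stats::plogis(stats::qlogis(p0) + theta)
  a <- stats::rbinom(1L, n, p1)  # treatment successes
  c <- stats::rbinom(1L, n, p0)  # control successes
  cells <- c(a, n - a, c, n - c)
  if (any(cells == 0L)) cells <- cells + 0.5
  lor <- log(cells[1L] * cells[4L] / (cells[2L] * cells[3L]))
  se <- sqrt(sum(1 / cells))
  c(effect = lor, se = se)
}

# OLS slope and SE from a univariate regression with intercept.
ols_slope <- function(x, y) {
  n <- length(x)
  xc <- x - mean(x)
  b <- sum(xc * y) / sum(xc^2)
  res <- y - mean(y) - b * xc
  s2 <- sum(res^2) / (n - 2)
  c(effect = b, se = sqrt(s2 / sum(xc^2)))
}

draw_regression <- function(slope, n, sigma_eps) {
  x <- stats::rnorm(n)
  y <- slope * x + stats::rnorm(n, sd = sigma_eps)
  ols_slope(x, y)
}

draw_omv_regression <- function(alpha1, alpha2, n, rho_x, sigma_eps) {
  x1 <- stats::rnorm(n)
  x2 <- rho_x * x1 + sqrt(1 - rho_x^2) * stats::rnorm(n)
  y <- alpha1 * x1 + alpha2 * x2 + stats::rnorm(n, sd = sigma_eps)
  ols_slope(x1, y)  # X2 omitted: heterogeneity enters via alpha2 * rho_x
}

#' Draw one primary-study estimate
#'
#' Simulates a single study under `config` (advancing the R random number
#' generator) and returns its estimate and standard error. In the panel
#' environment one call returns the whole study block of estimates.
#'
#' @param config an [env_config].
#' @return a data.frame with columns `effect`, `se` (one row, or
#'   `estimates_per_study` rows for `ar_panel`).
#' @export
draw_primary_estimate <- function(config) {
  pool <- config$primary_n_pool
  n <- pool[sample.int(length(pool), 1L)]
  h <- stats::rnorm(1L, sd = sqrt(config$sigma2_h))
  ex <- config$extra
  out <- switch(config$environment,
    sdi_logor = draw_logor(config$alpha1 + h, n),
    sdi_cohend = draw_cohend(config$alpha1 + h, n),
    csgh = {
      if (ex$qrp_frac > 0 && stats::runif(1L) < ex$qrp_frac) {
        raw <- draw_csgh_raw(config$alpha1 + h, n)
        apply_qrp(raw, practice = TRUE)
      } else {
        draw_cohend(config$alpha1 + h, n)
      }
    },
    ar_re = draw_regression(config$alpha1 + h, n, ex$sigma_eps),
    br_omv = draw_omv_regression(config$alpha1, h, n, ex$rho_x,
                                 ex$sigma_eps),
    ar_panel = {
      m <- ex$estimates_per_study
      b_study <- config$alpha1 +
        stats::rnorm(1L, sd = sqrt(ex$rho_within * config$sigma2_h))
      b_est <- b_study +
        stats::rnorm(m, sd = sqrt((1 - ex$rho_within) * config$sigma2_h))
      t(vapply(b_est, draw_regression, numeric(2L),
               n = n, sigma_eps = ex$sigma_eps))
    })
  out <- matrix(out, ncol = 2L, dimnames = list(NULL, c("effect", "se")))
  as.data.frame(out)
}

# note: in br_omv the study-level heterogeneity is the omitted-variable
# coefficient alpha2 ~ N(0, sigma2_h) itself, so `h` is passed as alpha2.

# -- questionable research practices ----------------------------------------

# Raw two-group study data for the QRP pathway: two correlated outcome
# variables sharing the same true standardized effect, and a binary
# moderator. Groups of size n each.
draw_csgh_raw <- function(delta, n, r12 = 0.5) {
  z1t <- stats::rnorm(n); z1c <- stats::rnorm(n)
  z2t <- r12 * z1t + sqrt(1 - r12^2) * stats::rnorm(n)
  z2c <- r12 * z1c + sqrt(1 - r12^2) * stats::rnorm(n)
  list(delta = delta, n = n,
       y1_t = z1t + delta, y1_c = z1c,
       y2_t = z2t + delta, y2_c = z2c,
       mod_t = stats::rbinom(n, 1L, 0.5), mod_c = stats::rbinom(n, 1L, 0.5))
}

cohend_from_groups <- function(yt, yc) {
  n1 <- length(yt); n2 <- length(yc)
  if (n1 < 3L || n2 < 3L) return(NULL)
  sp <- sqrt(((n1 - 1) * stats::var(yt) + (n2 - 1) * stats::var(yc)) /
               (n1 + n2 - 2))
  d <- (mean(yt) - mean(yc)) / sp
  se <- sqrt((n1 + n2) / (n1 * n2) + d^2 / (2 * (n1 + n2)))
  c(effect = d, se = se)
}

is_sig_pos <- function(est) !is.null(est) && est[["effect"]] / est[["se"]] >= 1.96

#' Apply questionable research practices to a raw study
#'
#' Models a study willing to exploit analytic flexibility: it reports the
#' first statistically significant positive result found along the sequence
#' (1) full-sample analysis of the primary outcome, (2) the second outcome,
#' (3) moderator subgroups on either outcome, (4) removal of within-group
#' outliers beyond |z| > 2, (5) optional stopping -- extending both groups in
#' increments of the original group size up to three times the original n and
#' re-testing after each increment. If nothing turns significant, the
#' original full-sample estimate is reported. With `practice = FALSE` the
#' straightforward full-sample estimate of the primary outcome is returned
#' unchanged.
#'
#' @param raw a raw study as produced internally (two outcomes, moderator,
#'   per-group data).
#' @param practice whether the study engages in QRPs.
#' @return named numeric vector `c(effect, se)`.
#' @export
apply_qrp <- function(raw, practice = TRUE) {
  base <- cohend_from_groups(raw$y1_t, raw$y1_c)
  if (!practice) return(base)
  if (is_sig_pos(base)) return(base)
  # (b) second outcome
  alt <- cohend_from_groups(raw$y2_t, raw$y2_c)
  if (is_sig_pos(alt)) return(alt)
  # (c) moderator subgroups
  for (y in list(list(raw$y1_t, raw$y1_c, raw$mod_t, raw$mod_c),
                 list(raw$y2_t, raw$y2_c, raw$mod_t, raw$mod_c))) {
    for (lev in 0:1) {
      est <- cohend_from_groups(y[[1L]][y[[3L]] == lev],
                                y[[2L]][y[[4L]] == lev])
      if (is_sig_pos(est)) return(est)
    }
  }
  # (a) outlier removal beyond |z| > 2 within group
  zt <- abs(scale(raw$y1_t)[, 1L]); zc <- abs(scale(raw$y1_c)[, 1L])
  est <- cohend_from_groups(raw$y1_t[zt <= 2], raw$y1_c[zc <= 2])
  if (is_sig_pos(est)) return(est)
  # (d) optional stopping: extend in increments of n up to 3n per group
  yt <- raw$y1_t; yc <- raw$y1_c
  while (length(yt) < 3L * raw$n) {
    yt <- c(yt, stats::rnorm(raw$n) + raw$delta)
    yc <- c(yc, stats::rnorm(raw$n))
    est <- cohend_from_groups(yt, yc)
    if (is_sig_pos(est)) return(est)
  }
  base
}

# -- selection ---------------------------------------------------------------

#' Apply a publication-selection regime
#'
#' Draws primary-study estimates under `config` and filters them through the
#' configured selection regime until the published sample is complete (or,
#' for the pre-selection-pool regime, until the pool is exhausted). Selection
#' operates on (effect, SE) pairs only; standard errors are never altered.
#'
#' @param config an [env_config].
#' @return an [effect_sample] with `true_mu = alpha1`; panel draws carry
#'   `study_id`.
#' @export
apply_selection <- function(config) {
  regime <- config$selection
  n_target <- config$n_target
  cap <- config$extra$redraw_cap
  draw1 <- function() draw_primary_estimate(config)

  if (config$environment == "ar_panel")
    return(select_panel(config, regime, cap))

  sig_pos <- function(d) d$effect / d$se >= 1.96
  redraw_until <- function(pred) {
    for (i in seq_len(cap)) {
      d <- draw1()
      if (pred(d)) return(d)
    }
    stop("apply_selection: redraw cap exceeded; selection criterion may be ",
         "unsatisfiable under this configuration")
  }

  rows <- switch(regime$kind,
    none = {
      do.call(rbind, replicate(n_target, draw1(), simplify = FALSE))
    },
    incidence = {
      out <- vector("list", n_target)
      for (j in seq_len(n_target)) {
        out[[j]] <- if (stats::runif(1L) < regime$incidence)
          redraw_until(sig_pos) else draw1()
      }
      do.call(rbind, out)
    },
    always_positive_75 = {
      out <- vector("list", n_target)
      for (j in seq_len(n_target)) {
        out[[j]] <- if (stats::runif(1L) < regime$prob)
          redraw_until(sig_pos) else redraw_until(function(d) d$effect > 0)
      }
      do.call(rbind, out)
    },
    ar_prob = {
      pool <- do.call(rbind, replicate(n_target, draw1(), simplify = FALSE))
      sig <- pool$effect / pool$se >= 1.96
      keep <- sig | stats::runif(nrow(pool)) < regime$publish_prob_insig
      if (sum(keep) < 1L) keep[1L] <- TRUE  # degenerate guard
      pool[keep, , drop = FALSE]
    },
    csgh_prob = {
      accept_prob <- function(d) {
        if (d$effect <= 0) regime$prob_neg
        else if (d$effect / d$se >= 1.96) regime$prob_sig_pos
        else regime$prob_insig_pos
      }
      out <- vector("list", n_target)
      for (j in seq_len(n_target))
        out[[j]] <- redraw_until(function(d) stats::runif(1L) < accept_prob(d))
      do.call(rbind, out)
    },
    stop("apply_selection: unknown regime kind: ", regime$kind))

  effect_sample(rows$effect, rows$se, true_mu = config$alpha1)
}

# Panel environment: the unit of publication is the study.
select_panel <- function(config, regime, cap) {
  accept_k <- config$extra$accept_k
  m <- config$extra$estimates_per_study
  p_insig <- if (regime$kind == "ar_prob") regime$publish_prob_insig else NA
  eff <- numeric(0); ses <- numeric(0); sid <- integer(0)
  study <- 0L
  for (i in seq_len(cap)) {
    d <- draw_primary_estimate(config)
    publish <- if (regime$kind == "none") {
      TRUE
    } else if (regime$kind == "ar_prob") {
      n_sig <- sum(d$effect / d$se >= 1.96)
      n_sig >= accept_k || stats::runif(1L) < p_insig
    } else {
      stop("apply_selection: regime '", regime$kind,
           "' is not defined for the panel environment")
    }
    if (publish) {
      study <- study + 1L
      eff <- c(eff, d$effect); ses <- c(ses, d$se)
      sid <- c(sid, rep(study, nrow(d)))
      if (length(eff) >= config$n_target) break
    }
  }
  if (length(eff) < config$n_target && regime$kind == "none")
    stop("apply_selection: could not reach n_target")
  keep <- seq_len(min(length(eff), config$n_target))
  effect_sample(eff[keep], ses[keep], study_id = sid[keep],
                true_mu = config$alpha1)
}

#' Simulate one published meta-analytic sample
#'
#' Convenience wrapper: optionally seeds the RNG, then draws and selects one
#' published sample under `config`.
#'
#' @param config an [env_config].
#' @param seed optional integer seed.
#' @return an [effect_sample].
#' @export
simulate_meta_sample <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  apply_selection(config)
}

#' Calibrate heterogeneity to a target I-squared
#'
#' Finds the heterogeneity variance `sigma2_h` at which the mean
#' published-sample I-squared (REML tau2 over tau2 plus typical sampling
#' variance) matches `target_i2`, by bisection on the log scale. The mean is
#' estimated from `nsim` simulated samples per candidate value; the same seed
#' block is reused for every candidate so the objective is monotone and
#' deterministic given `seed`.
#'
#' @param config an [env_config]; its `sigma2_h` is ignored.
#' @param target_i2 target mean I-squared in (0, 1).
#' @param nsim simulated samples per candidate value.
#' @param seed integer seed for the calibration draws.
#' @param tol absolute tolerance on the achieved mean I-squared.
#' @return the calibrated `sigma2_h` (scalar).
#' @export
calibrate_sigma2h <- function(config, target_i2, nsim = 60L, seed = 1L,
                              tol = 0.005) {
  stopifnot(target_i2 > 0, target_i2 < 1)
  mean_i2 <- function(s2h) {
    cfg <- config
    cfg$sigma2_h <- s2h
    set.seed(seed)
    mean(vapply(seq_len(nsim), function(i) {
      s <- apply_selection(cfg)
      i_squared(s, re_reml_estimate(s)$tau2_hat)$i2
    }, numeric(1L)))
  }
  lo <- 1e-4; hi <- 0.05
  while (mean_i2(hi) < target_i2 && hi < 50) hi <- hi * 4
  for (i in seq_len(30L)) {
    mid <- sqrt(lo * hi)
    m <- mean_i2(mid)
    if (abs(m - target_i2) < tol) return(mid)
    if (m < target_i2) lo <- mid else hi <- mid
  }
  sqrt(lo * hi)
}
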