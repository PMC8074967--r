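# Experiment runner: replication loop, performance measurement, aggregation,
# and the performance meta-regression.

#' Estimator registry
#'
#' The eleven benchmarked estimators under their conventional labels, each a
#' function from an [effect_sample] to a [new_estimate]. `estimators =
#' "all"` in the harness resolves to this set in this order.
#'
#' @return named list of estimator functions.
#' @export
estimator_registry <- function() {
  list(
    TF   = trim_fill_estimate,
    pC   = pcurve_estimate,
    pU   = puniform_estimate,
    RE   = re_reml_estimate,
    `3PSM` = psm3_estimate,
    `4PSM` = psm4_estimate,
    AK1  = ak1_estimate,
    AK2  = ak2_estimate,
    WAAP = waap_estimate,
    PP   = pet_peese_estimate,
    EK   = ek_estimate
  )
}

# Estimators with no usable standard-error-based test (excluded from
# coverage and Type I aggregation).
.no_inference <- "pC"

# Child seed for (base seed, replication): a simple counter scheme keeps the
# generated data identical no matter which estimators are requested, and the
# result below 2^31.
rep_seed <- function(seed, rep) {
  as.integer((as.numeric(seed) * 1000003 + rep * 7919) %% 2147483563 + 1)
}

#' Run one Monte Carlo experiment
#'
#' For each replication: generate one published sample under `config`, run
#' each requested estimator, and record the replication-level results. An
#' estimator error in a replication is caught and recorded as non-converged;
#' it never aborts the experiment. Summaries average over converged
#' replications only, with the convergence rate reported alongside.
#'
#' @param config an [env_config].
#' @param reps number of simulated meta-analyses.
#' @param seed base seed; each replication derives an independent child seed.
#' @param estimators character vector of registry names, `"all"`, or a named
#'   list of estimator functions.
#' @param experiment_id label copied into the output rows.
#' @return list with `reps` (replication-level data.frame) and `summary`
#'   (one row per estimator, see [summarize_experiment()]).
#' @export
run_experiment <- function(config, reps = 3000L, seed = 1L,
                           estimators = "all", experiment_id = "exp1") {
  stopifnot(reps >= 1)
  fns <- if (is.list(estimators)) estimators
         else if (identical(estimators, "all")) estimator_registry()
         else estimator_registry()[estimators]
  if (any(vapply(fns, is.null, logical(1L))))
    stop("run_experiment: unknown estimator name")
  ne <- length(fns)
  nm <- names(fns)

  rows <- vector("list", reps)
  for (r in seq_len(reps)) {
    set.seed(rep_seed(seed, r))
    s <- apply_selection(config)
    i2 <- tryCatch(
      i_squared(s, re_reml_estimate(s)$tau2_hat)$i2,
      error = function(e) NA_real_)
    res <- lapply(fns, function(f)
      tryCatch(f(s), error = function(e) non_converged("err")))
    rows[[r]] <- data.frame(
      rep = r,
      estimator = nm,
      mu_hat = vapply(res, function(x) x$mu_hat, numeric(1L)),
      se_hat = vapply(res, function(x) x$se_hat, numeric(1L)),
      ci_low = vapply(res, function(x) x$ci_low, numeric(1L)),
      ci_high = vapply(res, function(x) x$ci_high, numeric(1L)),
      df = vapply(res, function(x) x$df, numeric(1L)),
      converged = vapply(res, function(x) x$converged, logical(1L)),
      i2 = i2,
      stringsAsFactors = FALSE)
  }
  reps_df <- do.call(rbind, rows)
  reps_df <- data.frame(experiment_id = experiment_id,
                        environment = config$environment,
                        alpha1 = config$alpha1,
                        sigma2_h = config$sigma2_h,
                        selection = config$selection$kind,
                        qrp = config$qrp,
                        n_target = config$n_target,
                        reps_df, stringsAsFactors = FALSE)
  list(reps = reps_df,
       summary = summarize_experiment(reps_df, true_mu = config$alpha1))
}

#' Summarize replication-level results into performance measures
#'
#' Per estimator, over converged replications only: signed mean error
#' (`bias_k`), mean squared error (`mse_k`), coverage of the 95 percent
#' interval and its absolute deviation from 0.95, the Type I error rate
#' (only when the true effect is zero; the test statistic `mu_hat/se_hat` is
#' referred to each estimator's own reference distribution), the convergence
#' rate, and the mean published-sample I-squared. Estimators without a
#' standard error (p-curve) have coverage and Type I reported as `NA`.
#'
#' @param reps_df replication-level rows from [run_experiment()].
#' @param true_mu the experiment's true mean effect.
#' @return data.frame, one row per estimator.
#' @export
summarize_experiment <- function(reps_df, true_mu) {
  split_l <- split(reps_df, reps_df$estimator)
  out <- lapply(split_l, function(d) {
    conv <- d[d$converged, , drop = FALSE]
    rate <- nrow(conv) / nrow(d)
    est <- d$estimator[1L]
    if (nrow(conv) == 0L) {
      return(data.frame(
        experiment_id = d$experiment_id[1L], environment = d$environment[1L],
        alpha1 = d$alpha1[1L], sigma2_h = d$sigma2_h[1L],
        selection = d$selection[1L], qrp = d$qrp[1L],
        n_target = d$n_target[1L], estimator = est,
        bias_k = NA_real_, mse_k = NA_real_, coverage = NA_real_,
        coverage_dev = NA_real_, type1 = NA_real_,
        convergence_rate = rate, mean_i2 = mean(d$i2, na.rm = TRUE),
        n_converged = 0L, stringsAsFactors = FALSE))
    }
    err <- conv$mu_hat - true_mu
    no_inf <- est %in% .no_inference
    cover <- if (no_inf) NA_real_ else
      mean(conv$ci_low <= true_mu & true_mu <= conv$ci_high, na.rm = TRUE)
    type1 <- NA_real_
    if (!no_inf && isTRUE(all.equal(true_mu, 0))) {
      crit <- ifelse(is.finite(conv$df), stats::qt(0.975, df = conv$df),
                     stats::qnorm(0.975))
      type1 <- mean(abs(conv$mu_hat / conv$se_hat) > crit, na.rm = TRUE)
    }
    data.frame(
      experiment_id = d$experiment_id[1L], environment = d$environment[1L],
      alpha1 = d$alpha1[1L], sigma2_h = d$sigma2_h[1L],
      selection = d$selection[1L], qrp = d$qrp[1L],
      n_target = d$n_target[1L], estimator = est,
      bias_k = mean(err), mse_k = mean(err^2), coverage = cover,
      coverage_dev = if (is.na(cover)) NA_real_ else abs(cover - 0.95),
      type1 = type1, convergence_rate = rate,
      mean_i2 = mean(d$i2, na.rm = TRUE),
      n_converged = nrow(conv), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Convergence tier labels of the reporting convention: >= 99%, 90-99%, < 90%.
convergence_tier <- function(rate) {
  ifelse(rate >= 0.99, ">=99%", ifelse(rate >= 0.90, "90-99%", "<90%"))
}

#' Aggregate experiment summaries into a ranking table
#'
#' Within each facet cell, per estimator: the mean absolute experiment-level
#' bias (the absolute values are averaged, so +0.1 and -0.1 give 0.1), mean
#' MSE, mean coverage deviation, mean Type I error rate (over true-effect-
#' zero experiments), the mean convergence rate with its tier label, and the
#' number of experiments. Rows are ordered ascending by `rank_by` within each
#' cell.
#'
#' @param summaries experiment-level summary rows (from [run_experiment()]
#'   calls, row-bound).
#' @param by `"overall"`, `"environment"`, or `"size_het"` (sample-size bin
#'   crossed with the I-squared bin of [classify_cell()]).
#' @param rank_by measure used for ordering: `"mse"`, `"abs_bias"`,
#'   `"coverage_dev"`, or `"type1"`.
#' @return data.frame with one row per (cell, estimator).
#' @export
aggregate_results <- function(summaries,
                              by = c("overall", "environment", "size_het"),
                              rank_by = c("mse", "abs_bias", "coverage_dev",
                                          "type1")) {
  by <- match.arg(by)
  rank_by <- match.arg(rank_by)
  if (nrow(summaries) == 0L) stop("aggregate_results: empty summaries")
  cell <- switch(by,
    overall = rep("all", nrow(summaries)),
    environment = summaries$environment,
    size_het = {
      bins <- Map(classify_cell, summaries$n_target,
                  pmin(pmax(summaries$mean_i2, 0), 1))
      paste0("n", vapply(bins, `[[`, numeric(1L), "size_bin"), "/",
             vapply(bins, `[[`, character(1L), "het_bin"))
    })
  summaries$.cell <- cell
  key <- interaction(cell, summaries$estimator, drop = TRUE)
  agg <- lapply(split(summaries, key), function(d) {
    zero <- d[!is.na(d$alpha1) & d$alpha1 == 0, , drop = FALSE]
    data.frame(
      cell = d$.cell[1L],
      estimator = d$estimator[1L],
      n_experiments = nrow(d),
      abs_bias = mean(abs(d$bias_k), na.rm = TRUE),
      mse = mean(d$mse_k, na.rm = TRUE),
      coverage_dev = mean(d$coverage_dev, na.rm = TRUE),
      type1 = if (nrow(zero)) mean(zero$type1, na.rm = TRUE) else NA_real_,
      convergence_rate = mean(d$convergence_rate),
      stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, agg)
  res$tier <- convergence_tier(res$convergence_rate)
  res <- res[order(res$cell, res[[rank_by]]), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Performance meta-regression
#'
#' For each estimator, an OLS regression of the experiment-level performance
#' measure (absolute bias or MSE) on sample size / 1000 and the mean
#' published-sample I-squared, with standard errors and p-values from a
#' nonparametric bootstrap over experiments.
#'
#' @param summaries experiment-level summary rows.
#' @param measure `"bias"` (absolute experiment-level bias) or `"mse"`.
#' @param n_boot bootstrap resamples.
#' @param seed seed for the bootstrap.
#' @return data.frame with columns estimator, term, estimate, boot_se,
#'   p_value, n.
#' @export
performance_metaregression <- function(summaries, measure = c("bias", "mse"),
                                       n_boot = 2000L, seed = 1L) {
  measure <- match.arg(measure)
  out <- lapply(split(summaries, summaries$estimator), function(d) {
    d <- d[is.finite(d$bias_k) & is.finite(d$mean_i2), , drop = FALSE]
    if (nrow(d) < 10L)
      stop("performance_metaregression: need >= 10 experiments per estimator")
    y <- if (measure == "bias") abs(d$bias_k) else d$mse_k
    X <- cbind(intercept = 1, sample_size = d$n_target / 1000,
               i2 = d$mean_i2)
    if (qr(X)$rank < ncol(X))
      stop("performance_metaregression: rank-deficient design")
    beta <- solve(crossprod(X), crossprod(X, y))[, 1L]
    set.seed(seed)
    bs <- replicate(n_boot, {
      idx <- sample.int(nrow(d), replace = TRUE)
      Xb <- X[idx, , drop = FALSE]
      if (qr(Xb)$rank < ncol(Xb)) rep(NA_real_, ncol(X))
      else solve(crossprod(Xb), crossprod(Xb, y[idx]))[, 1L]
    })
    boot_se <- apply(bs, 1L, stats::sd, na.rm = TRUE)
    p <- 2 * stats::pnorm(abs(beta / boot_se), lower.tail = FALSE)
    data.frame(estimator = d$estimator[1L], term = names(beta),
               estimate = unname(beta), boot_se = unname(boot_se),
               p_value = unname(p), n = nrow(d), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
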