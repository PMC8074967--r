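#' Construct a meta-analytic sample of effect estimates
#'
#' An `effect_sample` is the common currency of the package: a flat collection
#' of effect estimates (Cohen's d, log odds ratios, or regression slopes) with
#' their standard errors, an optional study label per estimate, and -- in
#' simulation settings -- the known true mean effect.
#'
#' @param effects numeric vector of effect estimates.
#' @param ses numeric vector of standard errors, strictly positive and finite,
#'   same length as `effects`.
#' @param study_id optional integer vector of study labels, same length.
#' @param true_mu optional scalar, the true mean effect (simulation truth).
#' @return an object of class `effect_sample` with fields `effects`, `ses`,
#'   `study_id`, `true_mu`.
#' @examples
#' s <- effect_sample(c(0.2, 0.5, 0.4), c(0.1, 0.2, 0.15))
#' s$effects
#' @export
effect_sample <- function(effects, ses, study_id = NULL, true_mu = NULL) {
  effects <- as.numeric(effects)
  ses <- as.numeric(ses)
  if (length(effects) < 1L) stop("effect_sample: need at least one estimate")
  if (length(effects) != length(ses))
    stop("effect_sample: effects and ses must have the same length")
  if (!all(is.finite(effects))) stop("effect_sample: non-finite effect")
  if (!all(is.finite(ses)) || any(ses <= 0))
    stop("effect_sample: standard errors must be finite and strictly positive")
  if (!is.null(study_id)) {
    study_id <- as.integer(study_id)
    if (length(study_id) != length(effects))
      stop("effect_sample: study_id length mismatch")
  }
  if (!is.null(true_mu)) {
    true_mu <- as.numeric(true_mu)[1L]
    stopifnot(is.finite(true_mu))
  }
  structure(
    list(effects = effects, ses = ses, study_id = study_id, true_mu = true_mu),
    class = "effect_sample"
  )
}

#' @export
print.effect_sample <- function(x, ...) {
  cat(sprintf("effect_sample: %d estimates", length(x$effects)))
  if (!is.null(x$study_id))
    cat(sprintf(" in %d studies", length(unique(x$study_id))))
  if (!is.null(x$true_mu)) cat(sprintf(" (true mu = %g)", x$true_mu))
  cat("\n")
  cat(sprintf("  effects: [%.4g, %.4g], ses: [%.4g, %.4g]\n",
              min(x$effects), max(x$effects), min(x$ses), max(x$ses)))
  invisible(x)
}

#' @export
length.effect_sample <- function(x) length(x$effects)

#' Read an effect table from CSV
#'
#' Expects header columns `effect,se` and optionally `study_id`; UTF-8 with
#' "." as the decimal separator.
#'
#' @param path path to a CSV file.
#' @return an [effect_sample].
#' @export
read_effects_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("effect", "se")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(miss, collapse = ", ")))
  bad <- which(!is.finite(df$se) | df$se <= 0 | !is.finite(df$effect))
  if (length(bad))
    stop(sprintf("%s: invalid effect/se at data row %d", path, bad[1L]))
  effect_sample(df$effect, df$se,
                study_id = if ("study_id" %in% names(df)) df$study_id else NULL)
}

#' Write an effect sample to CSV
#'
#' Writes the `effect,se[,study_id]` dialect read by [read_effects_csv()].
#'
#' @param sample an [effect_sample].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_effects_csv <- function(sample, path) {
  df <- data.frame(effect = sample$effects, se = sample$ses)
  if (!is.null(sample$study_id)) df$study_id <- sample$study_id
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct an estimator result
#'
#' Uniform return value of all estimators: a point estimate of the mean true
#' effect, a standard error and 95 percent confidence interval when the
#' estimator provides them, a convergence flag, the heterogeneity estimate
#' when applicable, the reference distribution used for the estimator's own
#' inference (`df = Inf` means normal), and estimator-specific nuisance values
#' in `aux`.
#'
#' @param estimator short estimator label ("RE", "PP", ...).
#' @param mu_hat point estimate (NA when not converged).
#' @param se_hat standard error of `mu_hat`, or NA.
#' @param ci_low,ci_high 95 percent confidence bounds, or NA.
#' @param converged logical convergence flag.
#' @param tau2_hat heterogeneity variance estimate, or NA.
#' @param df degrees of freedom of the reference t distribution (Inf = normal).
#' @param aux named list of nuisance values.
#' @return object of class `bb_estimate`.
#' @export
new_estimate <- function(estimator, mu_hat = NA_real_, se_hat = NA_real_,
                         ci_low = NA_real_, ci_high = NA_real_,
                         converged = FALSE, tau2_hat = NA_real_,
                         df = Inf, aux = list()) {
  if (!is.na(tau2_hat) && tau2_hat < 0) stop("tau2_hat must be >= 0")
  structure(
    list(estimator = estimator, mu_hat = mu_hat, se_hat = se_hat,
         ci_low = ci_low, ci_high = ci_high, converged = isTRUE(converged),
         tau2_hat = tau2_hat, df = df, aux = aux),
    class = "bb_estimate"
  )
}

#' @export
print.bb_estimate <- function(x, ...) {
  if (!x$converged) {
    cat(sprintf("%s: did not converge\n", x$estimator))
    return(invisible(x))
  }
  cat(sprintf("%s: mu_hat = %.4f", x$estimator, x$mu_hat))
  if (is.finite(x$se_hat)) cat(sprintf(" (SE %.4f)", x$se_hat))
  if (is.finite(x$ci_low))
    cat(sprintf(", 95%% CI [%.4f, %.4f]", x$ci_low, x$ci_high))
  if (is.finite(x$tau2_hat)) cat(sprintf(", tau2 = %.4f", x$tau2_hat))
  cat("\n")
  invisible(x)
}

# Mark a result non-converged while keeping the estimator label.
non_converged <- function(estimator, aux = list()) {
  new_estimate(estimator, converged = FALSE, aux = aux)
}
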