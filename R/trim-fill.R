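# Duval-Tweedie trim-and-fill with random-effects trimming and filling and
# the L0 estimator of the number of suppressed studies.

# L0 for a given side. centered = effects - center. The "excess" side is the
# side opposite to where studies are missing: with side = "left" (suppressed
# small/negative estimates), the excess ranks are those of the positive
# deviations.
l0_count <- function(centered, side) {
  n <- length(centered)
  r <- rank(abs(centered), ties.method = "average")
  s_rank <- if (side == "left") sum(r[centered > 0]) else sum(r[centered < 0])
  k0 <- (4 * s_rank - n * (n + 1)) / (2 * n - 1)
  max(0L, as.integer(round(k0)))
}

#' Trim-and-fill estimator
#'
#' Iteratively trims the most extreme estimates on the excess side until the
#' rank-based L0 estimate of the number of suppressed studies, k0,
#' stabilizes; the center is re-estimated by the random-effects model at each
#' iteration. The trimmed estimates are then reinstated together with k0
#' mirror-image pseudo-estimates (effect `2*mu_hat - effect`, same SE), and
#' the random-effects estimate on the filled sample is returned. `side` is
#' the side where studies are presumed missing; `"auto"` picks the side with
#' the larger rank statistic.
#'
#' @param sample an [effect_sample] with N >= 3.
#' @param side `"left"` (default; selection favoring positive estimates
#'   suppresses the left side), `"right"`, or `"auto"`.
#' @return a [new_estimate]; `aux$k0` records the estimated number of
#'   suppressed studies. Non-converged if k0 fails to stabilize within 50
#'   iterations.
#' @export
trim_fill_estimate <- function(sample, side = c("left", "right", "auto")) {
  side <- match.arg(side)
  n <- length(sample$effects)
  if (n < 3L) stop("trim_fill_estimate: need N >= 3")
  if (side == "auto") {
    ctr <- re_reml_estimate(sample)$mu_hat
    r <- rank(abs(sample$effects - ctr), ties.method = "average")
    side <- if (sum(r[sample$effects - ctr > 0]) >=
                sum(r[sample$effects - ctr < 0])) "left" else "right"
  }
  ord <- order(sample$effects, decreasing = (side == "left"))
  eff <- sample$effects[ord]  # most extreme excess-side estimates first
  ses <- sample$ses[ord]

  k0 <- 0L
  for (iter in seq_len(50L)) {
    keep <- seq.int(k0 + 1L, n)
    if (length(keep) < 2L) break
    fit <- re_reml_estimate(effect_sample(eff[keep], ses[keep]))
    if (!fit$converged)
      return(non_converged("TF", aux = list(reason = "inner RE failure")))
    k0_new <- l0_count(sample$effects - fit$mu_hat, side)
    k0_new <- min(k0_new, n - 2L)
    if (k0_new == k0) break
    k0 <- k0_new
    if (iter == 50L)
      return(non_converged("TF", aux = list(reason = "k0 did not stabilize")))
  }

  if (k0 == 0L) {
    out <- re_reml_estimate(sample)
    out$estimator <- "TF"
    out$aux$k0 <- 0L
    return(out)
  }
  center <- re_reml_estimate(effect_sample(eff[-seq_len(k0)],
                                           ses[-seq_len(k0)]))$mu_hat
  fill_eff <- 2 * center - eff[seq_len(k0)]
  fill_ses <- ses[seq_len(k0)]
  filled <- effect_sample(c(sample$effects, fill_eff),
                          c(sample$ses, fill_ses))
  out <- re_reml_estimate(filled)
  out$estimator <- "TF"
  out$aux$k0 <- k0
  out$aux$side <- side
  out
}
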