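---
title: "Benchmarking publication-bias-correcting meta-analysis estimators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking publication-bias-correcting meta-analysis estimators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biasbench)
```

## The problem

A meta-analyst collects $N$ effect estimates $\hat\beta_i$ with standard
errors $SE_i$ and wants the population mean effect $\mu$ under the
random-effects model

$$\hat\beta_i \sim N(\mu,\; SE_i^2 + \tau^2),$$

where $\tau^2$ is the variance of true effects across studies. Publication
selection — journals and authors preferring positive, statistically
significant results — filters which estimates reach the literature, so naive
averages are biased. Many corrections exist; none dominates. Which one to
use depends on observable features of the sample (its size $N$, its
heterogeneity $I^2$) and on unobservable ones (the selection mechanism, the
prevalence of questionable research practices). `biasbench` makes that
choice empirical: it simulates meta-analytic samples under explicit
selection mechanisms, runs eleven correction estimators on each, scores them
on bias, mean squared error (MSE), coverage, and Type I error, and reports a
ranked recommendation for a given $\{N, I^2\}$ cell.

## The estimators

All estimators share one signature: `effect_sample -> estimate`. The
significance threshold everywhere is $z = \hat\beta/SE \ge 1.96$ (positive
side of the two-sided 5% test).

* **RE** — random effects; $\tau^2$ by restricted maximum likelihood
  (REML), profiled over $\tau^2 \in [0, 10\,\mathrm{var}(\hat\beta)]$,
  normal 95% interval. No selection correction beyond precision weighting.
* **WLS / fixed effect** — precision-weighted mean with $w_i = 1/SE_i^2$;
  "unrestricted" variance (residual mean square multiplier) when used
  inside meta-regression estimators, classical fixed-effect SE otherwise.
* **TF** — Duval–Tweedie trim-and-fill: RE trim, RE fill, the rank-based
  `L0` estimator of the number of suppressed studies, missing side "left"
  by default because every simulated selection regime favors positive
  estimates.
* **pC / pU** — p-curve and p-uniform operate only on significant positive
  estimates. Both choose $\mu$ making the conditional p-values
  $q_i(\mu) = \frac{1-\Phi((\hat\beta_i-\mu)/SE_i)}{1-\Phi(1.96-\mu/SE_i)}$
  uniform: p-curve minimizes the Kolmogorov–Smirnov distance to
  Uniform(0,1) (it returns no standard error and is excluded from coverage
  and Type I aggregation); p-uniform solves $\sum_i q_i(\mu) = k/2$, the
  Irwin–Hall mean, with confidence limits at the 0.025/0.975 Irwin–Hall
  quantiles.
* **3PSM / 4PSM / AK1 / AK2** — maximum-likelihood step-selection models:
  the normal density is reweighted by relative publication probabilities
  over $z$-statistic groups (3PSM: split at 1.96; 4PSM: at 0 and 1.96;
  AK1: $|z|$ at 1.96, the "symmetric" case; AK2: at $-1.96$, 0, 1.96, the
  "asymmetric" case), with the positive-significant group as the reference
  at probability 1. AK1/AK2 require 4 and 6 observations and use t
  inference with $N-3$ and $N-5$ degrees of freedom; 3PSM/4PSM use normal
  critical values.
* **WAAP** — weighted average of adequately powered estimates: keep
  $SE_i < |\hat\mu_{WLS}|/2.8$ (the 80%-power threshold); fall back to
  full-sample WLS when fewer than two qualify.
* **PP** — PET-PEESE: WLS of $\hat\beta$ on $SE$ (PET); if the one-tailed
  $t$ test of $\mu = 0$ at 5% rejects, re-fit on $SE^2$ (PEESE) and report
  that intercept.
* **EK** — endogenous kink: a PET-style regression whose $SE$ regressor is
  the hinge $\max(SE - a, 0)$, with the cutoff $a$ solving
  $\hat\mu - 1.96\sqrt{SE^2 + \hat\tau^2} = 1.96\,SE$ (below $a$
  essentially every estimate is significant, so selection cannot bite).

## What the generators emulate

Four simulation worlds reproduce published Monte Carlo designs:

* `sdi_logor` / `sdi_cohend` — two-group primary studies (binary outcome
  with 10% control success probability and a logit-shifted treatment
  probability; or a continuous outcome summarized as Cohen's *d* drawn via
  the noncentral *t*). Selection regimes: none, "incidence" selection (a
  slot is selected with probability 0.5 and then requires a
  positive-significant redraw), and the 75/100% regime (significant results
  accepted with probability 0.75, all published results positive).
* `ar_re` / `ar_panel` — univariate regressions, one (or ten correlated)
  estimates per study, with a fixed pre-selection pool: significant
  positive results always publish, the rest with probability 0.10, so the
  published sample size is endogenous. Panel studies publish when at least
  7 of 10 estimates are significant positive.
* `br_omv` — regressions whose heterogeneity comes from an omitted
  variable correlated with the regressor of interest (correlation 0.5 by
  default), so selection converts symmetric omitted-variable noise into
  bias.
* `csgh` — Cohen's *d* studies with probabilistic selection by result
  class (significant-positive always; insignificant-positive / negative
  with band probabilities 0.20/0.05 under medium and 0.05/0.00 under
  strong bias) and optional questionable research practices: a practicing
  study tries, in order, a second outcome, moderator subgroups, outlier
  removal at $|z|>2$, and optional stopping capped at three times the
  original group size, reporting the first significant positive result.

Defaults the source designs do not pin down (they live in unpublished
appendices) are package-level choices, stated once and not revisited:
per-group primary sample sizes drawn uniformly from
$\{16, 32, 64, 125, 250, 500\}$; QRP-practicing fractions 0 / 0.5 / 0.9 for
none / medium / high; the `csgh` class probabilities above; regression error
SD 1; within-study correlation 0.5 in the panel design. Because the
published experiments are indexed by their achieved $I^2$ rather than by
$\sigma^2_h$, `calibrate_sigma2h()` tunes the heterogeneity variance until
the mean published-sample $I^2$ matches the printed value — that calibration
is part of the stated experimental world, not a free dial.

What a green simulation test does **not** establish: the generators draw
idealized normal (or exact binomial/noncentral-*t*) primary data with
independent estimates (outside `ar_panel`), a single selection mechanism at
a time, and study sizes from a stylized pool. Real literatures mix selection
mechanisms, have dependent estimates, non-normal effects, and
rounding/reporting artifacts none of which are modelled here.

## Numerical choices

* REML: scalar profiled likelihood, `optimize()` with relative tolerance
  1e-8; $\hat\tau^2$ snapped to 0 when the boundary value is no worse.
* Selection-model MLEs: BFGS on transformed parameters
  ($\log\tau^2$; probabilities mapped to $(10^{-4}, 100)$ by a scaled
  logistic) from three deterministic starts (the RE fit with probabilities
  1, and two fixed perturbations), Nelder–Mead fallback. Standard errors
  from the inverse central-difference observed information on the original
  scale; parameters pinned at a boundary are profiled out. Convergence =
  optimizer success *and* a finite SE for $\hat\mu$; an empty $z$ group is
  reported non-converged, never silently dropped, because its probability
  is unidentified.
* The conditional p-values are computed on the log scale and clamped to
  $(10^{-300}, 1]$; the Irwin–Hall CDF uses the exact alternating sum for
  $k \le 50$ (with the symmetry $F(x) = 1 - F(k-x)$ to avoid catastrophic
  cancellation past the mean) and the normal approximation above.
* p-curve: 500-point coarse scan of $\mu \in [-2, 5]$ with ties toward the
  smaller $\mu$, then golden-section refinement; a boundary minimizer is
  non-converged.
* EK cutoff: bisection to 1e-10 on a strictly decreasing function, closed
  form $\hat\mu/3.92$ when $\hat\tau^2 = 0$; a non-significant or negative
  first stage uses $a = 0$ (the PET specification) and flags the gate in
  `aux` — the source design is silent on that branch.
* WAAP's threshold uses $|\hat\mu|$ so the rule is well defined for
  negative first-stage means.
* Ties at group cutpoints go to the higher $z$ group ($\ge$), matching the
  printed group definitions; the hinge $\max(SE-a,0)$ is continuous at
  $a$, so ties at $SE = a$ contribute zero either way.
* Seed discipline: each replication's data seed is a deterministic counter
  function of the base seed only, and estimators consume no randomness, so
  adding estimators never changes the simulated data and parallel and
  serial grid runs agree exactly.
* Harness accounting: all averages are over converged replications, with
  the convergence rate and its tier ($\ge$99%, 90–99%, <90%) attached to
  every aggregate; Type I error uses each estimator's own reference
  distribution (normal or *t* as fixed above).

## Worked example

```{r example, eval = FALSE}
csv <- system.file("extdata", "effects.csv", package = "biasbench")
cmd_estimate(csv)

cfg <- env_config("csgh", alpha1 = 0, sigma2_h = 0.056, n_target = 100)
res <- run_experiment(cfg, reps = 200, seed = 1,
                      estimators = c("RE", "TF", "WAAP", "PP"))
res$summary[, c("estimator", "bias_k", "mse_k", "coverage",
                "convergence_rate")]
```

## Known limitations

* The `csgh` selection/QRP parameter defaults are placeholders for values
  the source design never printed; exact-value claims are restricted to
  the no-selection, no-QRP cells.
* p-curve's loss is the plain KS distance on conditional p-values; other
  implementations use different transformations, which can shift estimates
  in small samples.
* Conditional p-values use the normal sampling approximation rather than
  the noncentral *t* on raw group sizes — the estimators only see
  (effect, SE) pairs. This is the main fidelity deviation for Cohen's *d*
  worlds.
* Alternative $\tau^2$ estimators (DerSimonian–Laird, Paule–Mandel),
  multilevel models, and the selection-model variants with a-priori fixed
  weights are out of scope.
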