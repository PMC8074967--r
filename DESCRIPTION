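Package: biasbench
Title: Simulation Benchmarking of Publication-Bias-Correcting Meta-Analysis
    Estimators
Version: 0.1.0
Authors@R: person("Sam", "Keller", email = "sam.keller@example.org",
    role = c("aut", "cre"))
Description: Generates synthetic meta-analytic samples under several published
    Monte Carlo designs (two-group Cohen's d and log odds ratio studies,
    univariate regressions with omitted-variable heterogeneity, panel studies,
    and studies distorted by questionable research practices), applies eleven
    publication-bias-correcting estimators (trim-and-fill, p-curve, p-uniform,
    random effects, three- and four-parameter step selection models, symmetric
    and asymmetric maximum-likelihood selection models, WAAP, PET-PEESE, and
    the endogenous-kink meta-regression), and scores them on bias, mean
    squared error, coverage, Type I error, and convergence, supporting an
    evidence-based choice of estimator for a given research situation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    parallel,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
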