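Package: probmet
Title: Bayesian Multi-Environment Trial Analysis and Probabilities of
    Superior Performance and Stability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits Bayesian hierarchical models to multi-environment trial
    (MET) phenotype data (entry-mean, randomized complete block and
    incomplete block designs, with optional breeding-region and year
    effects and heterogeneous residual variances), and post-processes the
    posterior draws into the full calculus of probabilities used for
    risk-aware cultivar recommendation: marginal, within-location and
    within-region probabilities of superior performance, probabilities of
    superior stability based on the variance of genotype-by-environment
    interaction effects, pairwise comparisons, and the joint probability
    of superior performance and stability. Includes variance-component
    summaries with highest-posterior-density intervals, posterior
    predictive goodness-of-fit checks (Bayesian P-values, WAIC with the
    variance-based penalty, split R-hat, effective sample size), and a
    synthetic MET data generator for calibration studies. MCMC is run
    with JAGS via rjags.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    coda,
    jsonlite,
    rjags,
    stats,
    utils
Suggests:
    lme4,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
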