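---
title: "Probabilistic genotype evaluation in multi-environment trials: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probabilistic genotype evaluation in multi-environment trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model family

probmet fits hierarchical Bayesian linear models to long-format MET tables.
The observation model is `y ~ N(E[y], sigma)`, and `E[y]` is assembled from
the design and the declared structure:

| term | present when |
|------|--------------|
| intercept `mu` | always |
| genotype `g_j`, location `l_k`, genotype-by-location `gl_jk` | always |
| region `r_m`, genotype-by-region `gr_jm` | `use_region` |
| year `t_q`, genotype-by-year `gt_jq` | `use_year` |
| replicate-within-location(-year) | `rcbd`, `ibd` |
| block-within-replicate | `ibd` |

Three designs times the region and year switches give the twelve variants.
Every effect family `x` is random with prior `N(0, S[x])` and hyperprior
`S[x] ~ Half-Cauchy(0, phi)`; the residual scale has
`sigma ~ Half-Cauchy(0, S[sigma])` with `S[sigma] ~ Half-Cauchy(0, phi)`.
The single global hyperparameter defaults to `phi = max(y) * 10`, a weakly
informative scale an order of magnitude above the data. Traits whose
maximum is not positive fall back to `max(|y|) * 10` (with a warning),
since a prior scale must be positive; an all-zero trait is rejected. The
only fixed-effect-like quantity is the intercept, with a vague
`N(mean(y), phi)` prior; no sum-to-zero constraints are imposed — the
hierarchical shrinkage priors provide the regularization that renders the
decomposition interpretable.

Three structural choices deserve comment:

* **Entry-mean identification.** With one adjusted mean per
  genotype-location cell, `gl_jk` and the residual both live at cell level
  and are separated only by their hierarchical priors. We keep both terms
  — the interaction draws are what the stability probabilities are made of,
  and the variance decomposition stays comparable across the twelve
  variants — and we accept that their individual posteriors are wide and
  mix slowly (see *Convergence* below). With replicates (RCBD/IBD) the two
  are cleanly identified. Entry-mean data must have exactly one record per
  genotype x location (x year) cell; duplicates are a hard error, because
  the entry-mean residual *is* the cell effect. Replicated designs allow
  them.
* **Year effects** enter symmetrically to regions: a main effect plus a
  genotype-by-year interaction, and replicates nest in location x year. No
  location-by-year term is fitted; with typically few years, a free
  location-year interaction would mostly trade off against the residual.
* **Heterogeneous residuals** (`res_het = TRUE`) give one `sigma_k` per
  location — never per region, even in region models — drawn from a common
  `Half-Cauchy(0, S[sigma])` with a single shared hyperscale. One
  hyperprior for K location scales borrows strength across locations; K
  independent hyperpriors would leave small locations' scales nearly
  unidentified.

Sampling is delegated to JAGS (rjags), run as `n_chains` independent chains
with half the iterations used as burn-in by default (adaptation counts
toward the burn-in), and one user seed fanned out deterministically to
per-chain RNG seeds, so a fit is reproducible bit for bit. The probability
calculus downstream only requires exchangeable posterior draws; it is
agnostic to the sampler. JAGS reports no divergence or tree-depth
information, so the diagnostics report marks those fields "not available".

## The probability calculus

All recommendation quantities derive from one primitive: within each
posterior draw `s`, form the selected set Omega as the top
`n_sel = max(1, round(intensity * J))` genotypes (half-up rounding; the
pool J is all genotypes marginally and the observed genotypes within an
environment). A genotype's probability of superior performance is the
fraction of draws in which it lands in Omega. Re-forming Omega inside
every draw is the crux: the indicator inherits the full posterior
uncertainty, not the point ranking.

* Conditional (within-location / within-region) values are
  `g_j + ge_jk` with the matching interaction; genotypes unobserved in an
  environment are reported as missing and do not compete there, so each
  environment's probabilities sum exactly to its own `n_sel`.
* Stability uses the per-draw *population* variance (divide by the number
  of observed environments) of the interaction effects across the
  genotype's observed environments — a posterior analogue of Shukla's
  stability variance. Small variance wins regardless of the selection
  direction. Genotypes seen in fewer than two environments have no defined
  stability and are excluded with a warning.
* Pairwise probabilities count strict per-draw wins in the selection
  direction, so `P(j, j') + P(j', j) = 1` for continuous draws; ties within
  a draw (measure-zero for continuous posteriors) break deterministically
  by genotype index.
* The joint probability multiplies marginal performance and stability,
  which the linear model's construction renders independent.
* Within-location values in region models use `g + gl` only; the
  genotype-by-region effect contributes to within-region tables. The
  alternative reading (adding the enclosing region's `gr` to
  within-location values) is available via
  `prob_sup(..., region_in_location = TRUE)` but is not the default, since
  the conditional definition pairs each environment with *its own*
  interaction term. The joint probability uses location-based stability by
  default; `joint_stability = "region"` switches to the region-based table.

Every one of these operations is checked against independent brute-force
loop implementations on hundreds of random draw sets in the test suite, and
the conservation identities (probabilities summing to `n_sel`, pairwise
antisymmetry, joint = product) are asserted exactly.

## Posterior summaries and diagnostics

* **HPD intervals** use the empirical shortest-window convention (gap
  `round(mass * S)` over the sorted draws, first-shortest tie-break),
  matching `coda::HPDinterval`; the test suite cross-checks against coda
  and against direct enumeration.
* The **variance table** reports the posterior *mean* of the squared scale
  draws. With heavy-tailed Half-Cauchy hyperpriors this mean can sit far
  above the HPD interval (region variances with few regions are the
  classic case); that is a property of the posterior, not a bug, and is why
  the SD and HPD columns matter. The *naive SE* is `SD / sqrt(S)` with no
  autocorrelation correction — labelled naive for exactly that reason.
* **MAP estimates** of genotype effects are the mode of a Gaussian kernel
  density over the draws, since a Gibbs backend exposes no per-draw joint
  log-posterior.
* **Bayesian P-values** use strict exceedance (`T(yrep) > T(y)`; ties count
  against), for the five statistics max, min, median, mean, SD. Values far
  from 0.01/0.99 indicate the model generates data like the observed.
* **WAIC** uses the variance-based penalty
  (`p = sum_i Var_s(loglik_is)`), with a log-sum-exp-stable lppd.
* **R-hat** is the classic split-chain potential scale reduction factor
  (each chain halved, no rank normalization), reported per parameter and
  as the mean over all scalar parameters. Half-chains need at least two
  draws; degenerate (constant) draws report missing rather than infinite.
* **ESS** is the classic Geyer initial-monotone-positive-sequence
  estimator with FFT autocovariances, combining chains through the
  between/within variance decomposition.

### Convergence in practice

In entry-mean models the weakly identified `gl`-versus-residual split makes
the interaction cells and the two scale parameters the slowest-mixing
quantities; the mean split R-hat over *all* parameters (genotype effects
mix fast and sit near 1) is therefore an aggressive summary. For final
analyses, chain lengths of tens of thousands of iterations are advisable,
as is inspecting the per-parameter table `diagnose(fit)$per_parameter`
rather than the mean alone.

## The synthetic-data generator

`simulate_met()` draws every effect family from `N(0, sqrt(variance))` and
assembles observations through the same linear predictors the models fit —
it is the model's own generative process, which is exactly what parameter
recovery and probability-calibration studies require. Default variance
components sit at the scale of the motivating soybean dataset (genotype
3.314, location 251.972, genotype-by-location 6.861, residual 11.179;
yields around a grand mean of 50), and `soy_like()` produces that
dataset's structure: 39 genotypes x 14 locations x 3 regions, entry-mean,
with ~5% of cells missing completely at random. Missingness never empties
a location below two genotypes nor a genotype below two locations, so all
probability tables stay defined. Heterogeneous residuals are simulated by
log-normal perturbation of the per-location SD (log-SD 0.25) around the
target. Structured missingness (a genotype absent from a whole region) is
available behind an option, off by default.

What the generator does *not* emulate — and hence what passing tests do
not certify about field data: spatial trends within trials, outliers and
heavy-tailed errors, correlated (e.g. pedigree-structured) genotype
effects, and non-random missingness driven by selection decisions between
seasons. The generated values are synthetic throughout; only the structure
and variance scale of the motivating trial are reproduced.

## Problem sizes and numerical choices

The test suite runs small fits (hundreds to a couple of thousand
iterations on trials of roughly 6-30 genotypes) chosen so the whole suite
completes in about a minute while leaving the stochastic checks
comfortable margins: variance-component recovery uses 20 replicates of a
30 x 10 entry-mean trial at 4 chains x 2000 iterations (each truth covered
by its 90% HPD in at least 80% of replicates), and the calibration study
separates the best genotype by five noise SDs, which drives its marginal
probability essentially to 1. The acceptance pipeline
(`scripts/acceptance.R`) fits the full 39 x 14 x 3 configuration at 4
chains x 6000 iterations, about half a minute of sampling, as a balance
between chain quality and a desk-scale run.

Degenerate inputs are handled by contract rather than silently: fewer than
two genotypes or locations, non-numeric or missing trait cells, a location
mapped to two regions, missing region labels when a region column is
declared, entry-mean duplicates, `n_warmup >= n_iter`, and empty candidate
pools all raise informative errors (or produce flagged missing values where
the quantity is genuinely undefined, as with stability on a single
environment).

## Known limitations

* No genomic relationship matrices, spatial field models, or multi-trait
  models; genotype effects are exchangeable.
* Year models use the minimal symmetric structure (no location-by-year
  term).
* The Gibbs backend reports no divergence/energy diagnostics; convergence
  assessment rests on R-hat, ESS and the posterior-predictive checks.
* Probabilities are Monte Carlo estimates; with S draws their standard
  error is about `sqrt(p(1-p)/S)`, so ranking genotypes whose
  probabilities differ by less than that is over-reading the output.
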