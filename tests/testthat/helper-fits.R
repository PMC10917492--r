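# Small fitted models shared across test files (fitting is the slow step,
# so each configuration is fitted once per test run and cached).

.fit_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fit_cache)) {
    assign(key, force(expr), envir = .fit_cache)
  }
  get(key, envir = .fit_cache)
}

# entry-mean + region fit on a small simulated trial with a few empty cells
small_region_fit <- function() {
  cached("region", {
    sim <- simulate_met(sim_config(J = 8, K = 4, M = 2, design = "entry-mean",
                                   missing_frac = 0.1, seed = 11))
    spec <- met_model_spec("entry-mean", use_region = TRUE,
                           n_iter = 1200, n_chains = 2, seed = 42)
    list(sim = sim, fit = fit_met_model(build_met_model(sim$met, spec)))
  })
}

# plain entry-mean fit (no region), homogeneous residuals
small_plain_fit <- function() {
  cached("plain", {
    sim <- simulate_met(sim_config(J = 6, K = 4, design = "entry-mean",
                                   seed = 21))
    spec <- met_model_spec("entry-mean", n_iter = 1000, n_chains = 2,
                           seed = 7)
    list(sim = sim, fit = fit_met_model(build_met_model(sim$met, spec)))
  })
}
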