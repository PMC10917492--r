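test_that("phi defaults to max(y) * 10, with a guarded fallback", {
  df <- data.frame(Gen = c("A", "B"), Loc = c("E1", "E2"), Y = c(30.5, 61.9))
  met <- met_data(df, gen = "Gen", loc = "Loc", trait = "Y")
  expect_equal(phi_default(met), 619)

  neg <- met_data(data.frame(Gen = c("A", "B"), Loc = c("E1", "E2"),
                             Y = c(-4, -1)), gen = "Gen", loc = "Loc",
                  trait = "Y")
  expect_warning(p <- phi_default(neg), "max\\(\\|y\\|\\)")
  expect_equal(p, 40)

  zero <- met_data(data.frame(Gen = c("A", "B"), Loc = c("E1", "E2"),
                              Y = c(0, 0)), gen = "Gen", loc = "Loc",
                   trait = "Y")
  expect_error(phi_default(zero), "zero")
})

test_that("the model grid enumerates twelve buildable variants", {
  sim <- simulate_met(sim_config(J = 5, K = 4, M = 2, Q = 2, design = "ibd",
                                 n_repl = 2, n_block = 2, seed = 13))
  grid <- expand.grid(design = c("entry-mean", "rcbd", "ibd"),
                      use_region = c(FALSE, TRUE),
                      use_year = c(FALSE, TRUE),
                      stringsAsFactors = FALSE)
  expect_equal(nrow(grid), 12)
  for (i in seq_len(nrow(grid))) {
    spec <- met_model_spec(grid$design[i], use_region = grid$use_region[i],
                           use_year = grid$use_year[i], n_iter = 100,
                           n_chains = 1)
    met <- if (grid$design[i] == "entry-mean") {
      # collapse plots to one mean per genotype x location x year cell
      recs <- aggregate(value ~ gen + loc + reg + year, sim$met$records, mean)
      met_data(recs, gen = "gen", loc = "loc", trait = "value", reg = "reg",
               year = "year")
    } else sim$met
    model <- build_met_model(met, spec)
    fam <- c("g", "l", "gl",
             if (grid$use_region[i]) c("r", "gr"),
             if (grid$use_year[i]) c("yr", "gt"),
             if (grid$design[i] != "entry-mean") "rp",
             if (grid$design[i] == "ibd") "bl")
    expect_setequal(model$families, fam)
    expect_match(model$code, "dt\\(0, pow\\(phi, -2\\), 1\\) T\\(0,\\)")
  }
})

test_that("the soy configuration declares exactly the published component set", {
  met <- soy_like(seed = 3)
  spec <- met_model_spec("entry-mean", use_region = TRUE, n_iter = 100,
                         n_chains = 1)
  model <- build_met_model(met, spec)
  expect_setequal(model$families, c("g", "l", "gl", "r", "gr"))
})

test_that("spec/data mismatches are configuration errors", {
  sim <- simulate_met(sim_config(J = 4, K = 3, seed = 1))
  expect_error(build_met_model(sim$met, met_model_spec("entry-mean",
                                                       use_region = TRUE)),
               "no region column")
  expect_error(build_met_model(sim$met, met_model_spec("entry-mean",
                                                       use_year = TRUE)),
               "no year column")
  expect_error(build_met_model(sim$met, met_model_spec("rcbd")), "replicate")
  expect_error(met_model_spec("entry-mean", n_iter = 100, n_warmup = 100),
               "post-warmup")
  # entry-mean rejects duplicated genotype x location cells
  dup <- rbind(sim$met$records, sim$met$records[1, ])
  met2 <- met_data(dup, gen = "gen", loc = "loc", trait = "value")
  expect_error(build_met_model(met2, met_model_spec("entry-mean")),
               "duplicates")
})

test_that("fitting returns aligned, positive, chain-indexed draws", {
  out <- small_region_fit()
  fit <- out$fit
  S <- fit$spec$n_chains * (fit$spec$n_iter - fit$spec$n_warmup)
  expect_equal(nrow(fit$draws$g), S)
  expect_equal(length(fit$chain), S)
  expect_equal(sort(unique(fit$chain)), 1:2)
  for (nm in names(fit$draws)) expect_equal(nrow(fit$draws[[nm]]), S)
  expect_equal(dim(fit$yrep), dim(fit$loglik))
  expect_equal(ncol(fit$yrep), nrow(fit$met$records))
  expect_true(all(fit$scales > 0))
  expect_true(all(fit$sigma > 0))
  # interaction draws exist exactly for observed genotype x location cells
  arr <- gl_array(fit, "gl")
  expect_equal(!is.na(arr[1, , ]), fit$met$incidence, ignore_attr = TRUE)
})

test_that("the same seed reproduces the fit bit-for-bit", {
  sim <- simulate_met(sim_config(J = 4, K = 3, seed = 2))
  spec <- met_model_spec("entry-mean", n_iter = 200, n_chains = 2, seed = 99)
  f1 <- fit_met_model(build_met_model(sim$met, spec))
  f2 <- fit_met_model(build_met_model(sim$met, spec))
  expect_identical(f1$draws$g, f2$draws$g)
  expect_identical(f1$yrep, f2$yrep)
})

test_that("with identical genotypes the genotypic scale concentrates near zero", {
  sim <- simulate_met(sim_config(J = 10, K = 6, var_g = 0, var_l = 25,
                                 var_gl = 0, var_e = 4, seed = 17))
  spec <- met_model_spec("entry-mean", n_iter = 1500, n_chains = 2, seed = 3)
  fit <- fit_met_model(build_met_model(sim$met, spec))
  upper <- hpd_interval(fit$scales[, "s_g"], 0.90)[["upper"]]
  expect_lt(upper, sd(sim$met$records$value))
})

test_that("posterior-mean genotype effects track frequentist BLUPs", {
  skip_if_not_installed("lme4")
  sim <- simulate_met(sim_config(J = 20, K = 8, var_g = 4, var_l = 25,
                                 var_gl = 2, var_e = 4, seed = 23))
  spec <- met_model_spec("entry-mean", n_iter = 2000, n_chains = 2, seed = 5)
  fit <- fit_met_model(build_met_model(sim$met, spec))
  lmm <- lme4::lmer(value ~ (1 | gen) + (1 | loc), data = sim$met$records)
  blup <- lme4::ranef(lmm)$gen
  post <- colMeans(fit$draws$g)[rownames(blup)]
  expect_gte(cor(post, blup[[1]], method = "spearman"), 0.95)
})
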