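#' Specify a Bayesian MET model variant
#'
#' The model family is a grid of twelve variants: three experimental designs
#' (`entry-mean`, `rcbd`, `ibd`) crossed with the presence/absence of
#' breeding-region effects and of year effects. Every declared effect family
#' x gets a Normal(0, S\[x\]) prior with a Half-Cauchy(0, phi) hyperprior on
#' its scale; the residual scale (one global sigma, or one per location when
#' `res_het = TRUE`) gets a Half-Cauchy(0, S\[sigma\]) prior with
#' S\[sigma\] ~ Half-Cauchy(0, phi). The global hyperparameter phi defaults
#' to `max(y) * 10` at build time.
#'
#' @param design `"entry-mean"` (one adjusted mean per genotype-location
#'   (-year) cell), `"rcbd"` (adds replicate-within-location effects) or
#'   `"ibd"` (additionally adds block-within-replicate effects).
#' @param use_region,use_year include region / year main effects and their
#'   genotype interactions.
#' @param res_het per-location residual scales instead of a single sigma.
#'   Residual heterogeneity is always across locations, never regions.
#' @param phi positive hyperprior scale; `NULL` = `max(y) * 10` at build.
#' @param n_iter total MCMC iterations per chain.
#' @param n_chains number of chains.
#' @param n_warmup burn-in iterations per chain; default `n_iter / 2`.
#' @param seed integer seed, fanned out deterministically to per-chain RNG
#'   seeds.
#' @return A `met_model_spec` list.
#' @export
met_model_spec <- function(design = c("entry-mean", "rcbd", "ibd"),
                           use_region = FALSE, use_year = FALSE,
                           res_het = FALSE, phi = NULL,
                           n_iter = 2000L, n_chains = 4L, n_warmup = NULL,
                           seed = 1L) {
  design <- match.arg(design)
  n_iter <- as.integer(n_iter)
  n_chains <- as.integer(n_chains)
  if (is.null(n_warmup)) n_warmup <- n_iter %/% 2L
  n_warmup <- as.integer(n_warmup)
  if (n_iter < 2 || n_chains < 1) stop("need n_iter >= 2, n_chains >= 1",
                                       call. = FALSE)
  if (n_warmup >= n_iter || n_warmup < 0) {
    stop("n_warmup must satisfy 0 <= n_warmup < n_iter ",
         "(zero post-warmup draws otherwise)", call. = FALSE)
  }
  if (!is.null(phi) && phi <= 0) stop("phi must be positive", call. = FALSE)
  structure(list(design = design, use_region = isTRUE(use_region),
                 use_year = isTRUE(use_year), res_het = isTRUE(res_het),
                 phi = phi, n_iter = n_iter, n_chains = n_chains,
                 n_warmup = n_warmup, seed = as.integer(seed)),
            class = "met_model_spec")
}

#' Default global hyperprior scale
#'
#' `phi = max(y) * 10`. For traits whose maximum is not positive (phi must
#' be a positive scale) the fallback is `max(|y|) * 10`, with a warning;
#' an all-zero trait is an error.
#'
#' @param met a [met_data] object.
#' @return a positive scalar.
#' @export
phi_default <- function(met) {
  stopifnot(inherits(met, "met_data"))
  y <- met$records$value
  if (length(y) == 0) stop("no trait values", call. = FALSE)
  m <- max(y)
  if (m > 0) return(m * 10)
  m <- max(abs(y))
  if (m == 0) stop("all trait values are zero; cannot set a prior scale",
                   call. = FALSE)
  warning("max(y) <= 0; using max(|y|) * 10 as the hyperprior scale phi")
  m * 10
}

# Observed-cell index for an interaction family: unique (row factor, col
# factor) combinations in first-appearance order, plus per-record cell id.
.cell_index <- function(f1, f2) {
  key <- paste(as.integer(f1), as.integer(f2), sep = "_")
  ukey <- unique(key)
  id <- match(key, ukey)
  parts <- do.call(rbind, strsplit(ukey, "_", fixed = TRUE))
  list(id = id, row = as.integer(parts[, 1]), col = as.integer(parts[, 2]),
       n = length(ukey))
}

#' Assemble a MET model definition
#'
#' Builds the JAGS model code, the data list and all index maps for one of
#' the twelve model variants. The genotype-by-location (and
#' genotype-by-region, genotype-by-year) parameters exist only for observed
#' cells; downstream code receives the cell maps and the incidence mask.
#'
#' @param met a [met_data] object.
#' @param spec a [met_model_spec()] consistent with `met` (`use_region`
#'   requires a region column, `use_year` a year column, `rcbd`/`ibd` a
#'   replicate column, `ibd` a block column).
#' @return A `met_model` list with elements `code` (JAGS model string),
#'   `data`, `index` (per-record and cell maps), `families` (effect family
#'   names), `spec`, `met`.
#' @export
build_met_model <- function(met, spec) {
  stopifnot(inherits(met, "met_data"), inherits(spec, "met_model_spec"))
  recs <- met$records
  if (spec$use_region && length(met$regions) == 0) {
    stop("spec requests region effects but the data has no region column",
         call. = FALSE)
  }
  if (spec$use_year && length(met$years) == 0) {
    stop("spec requests year effects but the data has no year column",
         call. = FALSE)
  }
  if (spec$design %in% c("rcbd", "ibd") && is.null(recs$repl)) {
    stop("design '", spec$design, "' requires a replicate column",
         call. = FALSE)
  }
  if (spec$design == "ibd" && is.null(recs$block)) {
    stop("design 'ibd' requires a block column", call. = FALSE)
  }
  if (spec$design == "entry-mean") {
    cell <- paste(recs$gen, recs$loc,
                  if (!is.null(recs$year)) recs$year else "")
    if (anyDuplicated(cell)) {
      stop("entry-mean design requires exactly one record per genotype x ",
           "location", if (!is.null(recs$year)) " x year",
           " cell; found duplicates", call. = FALSE)
    }
  }

  N <- nrow(recs)
  J <- length(met$genotypes)
  K <- length(met$locations)
  phi <- if (is.null(spec$phi)) phi_default(met) else spec$phi

  idx <- list(gen = as.integer(recs$gen), loc = as.integer(recs$loc))
  data <- list(y = recs$value, N = N, J = J, K = K,
               gen = idx$gen, loc = idx$loc,
               phi = phi, ybar = mean(recs$value))

  pred <- "mu + g[gen[i]] + l[loc[i]] + gl[glcell[i]]"
  gl <- .cell_index(recs$gen, recs$loc)
  idx$glcell <- gl
  data$glcell <- gl$id
  data$Cgl <- gl$n
  families <- c("g", "l", "gl")

  lines <- character(0)
  if (spec$use_region) {
    reg_of_rec <- factor(met$location_region[as.integer(recs$loc)],
                         levels = met$regions)
    gr <- .cell_index(recs$gen, reg_of_rec)
    idx$reg <- as.integer(reg_of_rec)
    idx$grcell <- gr
    data$reg <- idx$reg
    data$grcell <- gr$id
    data$M <- length(met$regions)
    data$Cgr <- gr$n
    pred <- paste0(pred, " + r[reg[i]] + gr[grcell[i]]")
    lines <- c(lines,
               "  for (m in 1:M) { r[m] ~ dnorm(0, pow(s_r, -2)) }",
               "  for (c in 1:Cgr) { gr[c] ~ dnorm(0, pow(s_gr, -2)) }")
    families <- c(families, "r", "gr")
  }
  if (spec$use_year) {
    gt <- .cell_index(recs$gen, recs$year)
    idx$year <- as.integer(recs$year)
    idx$gtcell <- gt
    data$year <- idx$year
    data$gtcell <- gt$id
    data$Q <- length(met$years)
    data$Cgt <- gt$n
    pred <- paste0(pred, " + yr[year[i]] + gt[gtcell[i]]")
    lines <- c(lines,
               "  for (q in 1:Q) { yr[q] ~ dnorm(0, pow(s_yr, -2)) }",
               "  for (c in 1:Cgt) { gt[c] ~ dnorm(0, pow(s_gt, -2)) }")
    families <- c(families, "yr", "gt")
  }
  if (spec$design %in% c("rcbd", "ibd")) {
    # replicates nested in location (x year)
    repkey <- interaction(recs$loc,
                          if (spec$use_year) recs$year else NULL,
                          recs$repl, drop = TRUE, lex.order = TRUE)
    idx$repid <- as.integer(repkey)
    data$repid <- idx$repid
    data$Rrep <- nlevels(repkey)
    pred <- paste0(pred, " + rp[repid[i]]")
    lines <- c(lines,
               "  for (c in 1:Rrep) { rp[c] ~ dnorm(0, pow(s_rp, -2)) }")
    families <- c(families, "rp")
  }
  if (spec$design == "ibd") {
    blkkey <- interaction(recs$loc,
                          if (spec$use_year) recs$year else NULL,
                          recs$repl, recs$block, drop = TRUE,
                          lex.order = TRUE)
    idx$blkid <- as.integer(blkkey)
    data$blkid <- idx$blkid
    data$Bblk <- nlevels(blkkey)
    pred <- paste0(pred, " + bl[blkid[i]]")
    lines <- c(lines,
               "  for (c in 1:Bblk) { bl[c] ~ dnorm(0, pow(s_bl, -2)) }")
    families <- c(families, "bl")
  }

  res_line <- if (spec$res_het) {
    paste0("    y[i] ~ dnorm(mu_y[i], pow(sigma[loc[i]], -2))\n")
  } else {
    "    y[i] ~ dnorm(mu_y[i], pow(sigma, -2))\n"
  }
  sigma_prior <- if (spec$res_het) {
    "  for (k in 1:K) { sigma[k] ~ dt(0, pow(s_sig, -2), 1) T(0,) }"
  } else {
    "  sigma ~ dt(0, pow(s_sig, -2), 1) T(0,)"
  }
  scale_priors <- vapply(
    paste0("s_", c(families, "sig")),
    function(s) sprintf("  %s ~ dt(0, pow(phi, -2), 1) T(0,)", s),
    character(1))

  code <- paste0(
    "model {\n",
    "  for (i in 1:N) {\n",
    "    mu_y[i] <- ", pred, "\n",
    res_line,
    "  }\n",
    "  for (j in 1:J) { g[j] ~ dnorm(0, pow(s_g, -2)) }\n",
    "  for (k in 1:K) { l[k] ~ dnorm(0, pow(s_l, -2)) }\n",
    "  for (c in 1:Cgl) { gl[c] ~ dnorm(0, pow(s_gl, -2)) }\n",
    paste(lines, collapse = "\n"), if (length(lines)) "\n",
    "  mu ~ dnorm(ybar, pow(phi, -2))\n",
    sigma_prior, "\n",
    paste(scale_priors, collapse = "\n"), "\n",
    "}\n")

  structure(list(code = code, data = data, index = idx,
                 families = families, phi = phi, spec = spec, met = met),
            class = "met_model")
}

# pull columns "name[1]".."name[n]" from a coda matrix, in index order
.pull <- function(mat, name, n) {
  if (n == 1 && name %in% colnames(mat)) {
    return(mat[, name, drop = FALSE])
  }
  mat[, paste0(name, "[", seq_len(n), "]"), drop = FALSE]
}

#' Fit a MET model by MCMC
#'
#' Runs the JAGS sampler (`n_chains` chains, `n_warmup` burn-in iterations —
#' adaptation counts towards the burn-in — and `n_iter - n_warmup` retained
#' iterations per chain), then assembles aligned posterior draw matrices for
#' every effect family and scale parameter, posterior-predictive replicates
#' of the data, and the pointwise log-likelihood.
#'
#' @param model a [build_met_model()] result.
#' @param quiet suppress JAGS progress output.
#' @return A `met_fit` object: list with
#' \describe{
#'   \item{draws}{named list of S x dim matrices (`mu`, `g`, `l`, `gl`, and
#'     `r`, `gr`, `yr`, `gt`, `rp`, `bl` when present). Interaction draws are
#'     stored per observed cell; see [gl_array()].}
#'   \item{scales}{S x n matrix of effect-family scale draws
#'     (`s_g`, `s_l`, ..., `s_sig`).}
#'   \item{sigma}{S x 1 residual-scale draws, or S x K when `res_het`.}
#'   \item{yrep, loglik}{S x n_records matrices.}
#'   \item{chain, iteration}{per-draw bookkeeping.}
#'   \item{sampler}{backend info; divergence/tree-depth/BFMI counts are
#'     `NA` ("not available") for the Gibbs backend.}
#' }
#' @export
fit_met_model <- function(model, quiet = TRUE) {
  stopifnot(inherits(model, "met_model"))
  spec <- model$spec
  n_keep <- spec$n_iter - spec$n_warmup
  if (n_keep <= 0) stop("zero post-warmup draws", call. = FALSE)

  inits <- lapply(seq_len(spec$n_chains), function(ch) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = (abs(spec$seed) * 1009L + ch * 31L) %% 2147483629L + 1L)
  })
  n_adapt <- min(1000L, spec$n_warmup)
  jm <- rjags::jags.model(textConnection(model$code), data = model$data,
                          inits = inits, n.chains = spec$n_chains,
                          n.adapt = n_adapt, quiet = quiet)
  extra_burn <- spec$n_warmup - n_adapt
  if (extra_burn > 0) update(jm, extra_burn, progress.bar = "none")

  fam <- model$families
  monitors <- c("mu", "g", "l", "gl",
                intersect(c("r", "gr", "yr", "gt", "rp", "bl"), fam),
                paste0("s_", c(fam, "sig")), "sigma")
  samp <- rjags::coda.samples(jm, monitors, n.iter = n_keep,
                              progress.bar = "none")
  mat <- as.matrix(samp)
  S <- nrow(mat)
  chain <- rep(seq_len(spec$n_chains), each = n_keep)
  iteration <- rep(seq_len(n_keep), times = spec$n_chains)

  met <- model$met
  J <- length(met$genotypes); K <- length(met$locations)
  d <- model$data
  draws <- list(mu = .pull(mat, "mu", 1),
                g = .pull(mat, "g", J),
                l = .pull(mat, "l", K),
                gl = .pull(mat, "gl", d$Cgl))
  colnames(draws$g) <- met$genotypes
  colnames(draws$l) <- met$locations
  if ("r" %in% fam) {
    draws$r <- .pull(mat, "r", d$M)
    draws$gr <- .pull(mat, "gr", d$Cgr)
    colnames(draws$r) <- met$regions
  }
  if ("yr" %in% fam) {
    draws$yr <- .pull(mat, "yr", d$Q)
    draws$gt <- .pull(mat, "gt", d$Cgt)
    colnames(draws$yr) <- met$years
  }
  if ("rp" %in% fam) draws$rp <- .pull(mat, "rp", d$Rrep)
  if ("bl" %in% fam) draws$bl <- .pull(mat, "bl", d$Bblk)

  scale_names <- paste0("s_", fam)
  scales <- mat[, scale_names, drop = FALSE]
  s_sig <- mat[, "s_sig", drop = FALSE]
  sigma <- if (spec$res_het) {
    sg <- .pull(mat, "sigma", K); colnames(sg) <- met$locations; sg
  } else .pull(mat, "sigma", 1)

  # linear predictor per draw per record, by indexing draw matrices with the
  # record maps; then posterior predictive replicates and pointwise loglik
  idx <- model$index
  linpred <- as.vector(draws$mu) +
    draws$g[, idx$gen, drop = FALSE] +
    draws$l[, idx$loc, drop = FALSE] +
    draws$gl[, idx$glcell$id, drop = FALSE]
  if ("r" %in% fam) {
    linpred <- linpred + draws$r[, idx$reg, drop = FALSE] +
      draws$gr[, idx$grcell$id, drop = FALSE]
  }
  if ("yr" %in% fam) {
    linpred <- linpred + draws$yr[, idx$year, drop = FALSE] +
      draws$gt[, idx$gtcell$id, drop = FALSE]
  }
  if ("rp" %in% fam) linpred <- linpred + draws$rp[, idx$repid, drop = FALSE]
  if ("bl" %in% fam) linpred <- linpred + draws$bl[, idx$blkid, drop = FALSE]

  sig_rec <- if (spec$res_het) sigma[, idx$loc, drop = FALSE] else
    matrix(sigma, S, length(d$y))
  ymat <- matrix(d$y, S, length(d$y), byrow = TRUE)
  loglik <- stats::dnorm(ymat, linpred, sig_rec, log = TRUE)
  set.seed((abs(spec$seed) * 2003L + 17L) %% 2147483629L)
  yrep <- linpred + stats::rnorm(length(linpred)) * sig_rec

  structure(list(draws = draws, scales = scales, s_sig = s_sig,
                 sigma = sigma, yrep = yrep, loglik = loglik,
                 chain = chain, iteration = iteration,
                 index = idx, families = fam, phi = model$phi,
                 spec = spec, met = met,
                 sampler = list(backend = "jags",
                                divergences = NA_integer_,
                                treedepth_hits = NA_integer_,
                                bfmi = NA_real_)),
            class = "met_fit")
}

#' @export
print.met_fit <- function(x, ...) {
  cat(sprintf("Bayesian MET fit (%s%s%s%s): %d draws (%d chains), %d records\n",
              x$spec$design,
              if (x$spec$use_region) " + region" else "",
              if (x$spec$use_year) " + year" else "",
              if (x$spec$res_het) ", heterogeneous residuals" else "",
              nrow(x$draws$g), x$spec$n_chains, ncol(x$yrep)))
  invisible(x)
}

#' Expand interaction draws to a draws x J x E array
#'
#' Interaction effects are sampled only for observed genotype-by-environment
#' cells; this expands them to a dense array with `NA` in never-observed
#' cells (the mask equals the genotype-by-location incidence for
#' `which = "gl"`).
#'
#' @param fit a [fit_met_model()] result.
#' @param which `"gl"` (locations), `"gr"` (regions) or `"gt"` (years).
#' @return numeric array S x J x E with dimnames.
#' @export
gl_array <- function(fit, which = c("gl", "gr", "gt")) {
  which <- match.arg(which)
  if (is.null(fit$draws[[which]])) {
    stop("effect family '", which, "' is not in this model", call. = FALSE)
  }
  env_labels <- switch(which, gl = fit$met$locations, gr = fit$met$regions,
                       gt = fit$met$years)
  cells <- switch(which, gl = fit$index$glcell, gr = fit$index$grcell,
                  gt = fit$index$gtcell)
  S <- nrow(fit$draws[[which]])
  J <- length(fit$met$genotypes)
  E <- length(env_labels)
  arr <- array(NA_real_, c(S, J, E),
               dimnames = list(NULL, fit$met$genotypes, env_labels))
  for (c in seq_len(cells$n)) {
    arr[, cells$row[c], cells$col[c]] <- fit$draws[[which]][, c]
  }
  arr
}
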