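#' Configuration for the synthetic MET generator
#'
#' Describes a simulated multi-environment trial drawn from the same
#' generative process the models fit: independent Normal effects for every
#' declared family, assembled through the design's linear predictor, with
#' Normal residuals (optionally with per-location residual scales).
#'
#' @param J,K number of genotypes and locations (both >= 2).
#' @param M number of breeding regions (0 = no regions). Regions partition
#'   the locations into contiguous groups of near-equal size.
#' @param Q number of years (0 = no years).
#' @param design `"entry-mean"`, `"rcbd"` or `"ibd"`.
#' @param res_het if `TRUE`, per-location residual SDs are drawn from a
#'   log-normal centred (in median) on `sqrt(var_e)` with log-SD
#'   `res_het_lsd`.
#' @param mu grand mean of the trait.
#' @param var_g,var_l,var_gl,var_r,var_gr,var_t,var_gt,var_e true variances
#'   of the genotype, location, genotype-by-location, region,
#'   genotype-by-region, year, genotype-by-year and residual families
#'   (all >= 0). Region/year variances are ignored when `M`/`Q` is 0.
#' @param var_rep,var_blk replicate-within-location and
#'   block-within-replicate variances (RCBD/IBD only).
#' @param n_repl,n_block replicates per location(-year) and blocks per
#'   replicate (IBD).
#' @param missing_frac fraction of genotype-by-location cells removed
#'   completely at random, in `[0, 0.5]`; no location is emptied below two
#'   genotypes.
#' @param drop_region_frac fraction of genotypes dropped from one whole
#'   region (structured missingness; 0 by default).
#' @param res_het_lsd log-scale SD of the per-location residual SDs.
#' @param seed integer seed; the same config and seed give a bit-identical
#'   dataset.
#' @return A `sim_config` list.
#' @export
sim_config <- function(J = 30, K = 10, M = 0, Q = 0,
                       design = c("entry-mean", "rcbd", "ibd"),
                       res_het = FALSE, mu = 50,
                       var_g = 3.314, var_l = 251.972, var_gl = 6.861,
                       var_r = 10, var_gr = 1.139, var_t = 5, var_gt = 1,
                       var_e = 11.179, var_rep = 2, var_blk = 1,
                       n_repl = 3, n_block = 2,
                       missing_frac = 0, drop_region_frac = 0,
                       res_het_lsd = 0.25, seed = 1L) {
  design <- match.arg(design)
  vars <- c(var_g = as.numeric(var_g)[1], var_l = as.numeric(var_l)[1],
            var_gl = as.numeric(var_gl)[1], var_r = as.numeric(var_r)[1],
            var_gr = as.numeric(var_gr)[1], var_t = as.numeric(var_t)[1],
            var_gt = as.numeric(var_gt)[1], var_e = as.numeric(var_e)[1],
            var_rep = as.numeric(var_rep)[1], var_blk = as.numeric(var_blk)[1])
  if (any(vars < 0)) stop("variance components must be >= 0", call. = FALSE)
  if (J < 2 || K < 2) stop("need J >= 2 and K >= 2", call. = FALSE)
  if (M > K) stop("more regions than locations", call. = FALSE)
  if (missing_frac < 0 || missing_frac > 0.5) {
    stop("missing_frac must be in [0, 0.5]", call. = FALSE)
  }
  structure(c(list(J = J, K = K, M = M, Q = Q, design = design,
                   res_het = res_het, mu = mu),
              as.list(vars),
              list(n_repl = n_repl, n_block = n_block,
                   missing_frac = missing_frac,
                   drop_region_frac = drop_region_frac,
                   res_het_lsd = res_het_lsd, seed = as.integer(seed))),
            class = "sim_config")
}

#' Simulate a MET dataset with known variance components
#'
#' Draws every effect family from Normal(0, sqrt(variance)), assembles
#' observations through the design's linear predictor, removes cells
#' completely at random when requested, and returns both the validated
#' dataset and the truth record (all drawn effects and the configured
#' variances) for recovery and calibration studies.
#'
#' @param config a [sim_config()].
#' @return list with `met` (a [met_data]) and `truth` (list of drawn effect
#'   vectors/matrices, per-location residual SDs if heterogeneous, and the
#'   configured variances).
#' @examples
#' sim <- simulate_met(sim_config(J = 5, K = 3, seed = 42))
#' summary(sim$met)
#' @export
simulate_met <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cf <- config
  set.seed(cf$seed)

  gen_lab <- sprintf("G%02d", seq_len(cf$J))
  loc_lab <- sprintf("E%d", seq_len(cf$K))
  reg_lab <- if (cf$M > 0) sprintf("R%d", seq_len(cf$M)) else character(0)
  yr_lab <- if (cf$Q > 0) sprintf("Y%d", seq_len(cf$Q)) else character(0)
  # contiguous near-equal partition of locations into regions
  loc_region <- if (cf$M > 0) {
    sort(rep_len(seq_len(cf$M), cf$K))
  } else NULL

  g <- stats::rnorm(cf$J, 0, sqrt(cf$var_g))
  l <- stats::rnorm(cf$K, 0, sqrt(cf$var_l))
  gl <- matrix(stats::rnorm(cf$J * cf$K, 0, sqrt(cf$var_gl)), cf$J, cf$K,
               dimnames = list(gen_lab, loc_lab))
  r <- gr <- tt <- gt <- NULL
  if (cf$M > 0) {
    r <- stats::rnorm(cf$M, 0, sqrt(cf$var_r))
    gr <- matrix(stats::rnorm(cf$J * cf$M, 0, sqrt(cf$var_gr)), cf$J, cf$M,
                 dimnames = list(gen_lab, reg_lab))
  }
  if (cf$Q > 0) {
    tt <- stats::rnorm(cf$Q, 0, sqrt(cf$var_t))
    gt <- matrix(stats::rnorm(cf$J * cf$Q, 0, sqrt(cf$var_gt)), cf$J, cf$Q,
                 dimnames = list(gen_lab, yr_lab))
  }

  sigma_k <- if (cf$res_het) {
    sqrt(cf$var_e) * exp(stats::rnorm(cf$K, 0, cf$res_het_lsd))
  } else rep(sqrt(cf$var_e), cf$K)

  # genotype x location incidence after missingness
  keep <- matrix(TRUE, cf$J, cf$K)
  if (cf$drop_region_frac > 0 && cf$M > 0) {
    dropped <- sample(cf$J, max(1, round(cf$drop_region_frac * cf$J)))
    keep[dropped, loc_region == 1] <- FALSE
  }
  if (cf$missing_frac > 0) {
    holes <- sample(cf$J * cf$K, round(cf$missing_frac * cf$J * cf$K))
    keep[holes] <- FALSE
  }
  for (k in seq_len(cf$K)) {  # never empty a location below 2 genotypes
    if (sum(keep[, k]) < 2) keep[sample(cf$J, 2), k] <- TRUE
  }
  for (j in seq_len(cf$J)) {  # keep every genotype in >= 2 locations
    if (sum(keep[j, ]) < 2) keep[j, sample(cf$K, 2)] <- TRUE
  }

  cells <- which(keep, arr.ind = TRUE)
  qseq <- if (cf$Q > 0) seq_len(cf$Q) else 0L
  rows <- list()
  for (q in qseq) {
    base <- data.frame(gen = cells[, 1], loc = cells[, 2])
    if (cf$Q > 0) base$year <- q
    if (cf$design == "entry-mean") {
      base$repl <- NA_integer_
      rows[[length(rows) + 1]] <- base
    } else {
      for (rep_i in seq_len(cf$n_repl)) {
        b <- base
        b$repl <- rep_i
        rows[[length(rows) + 1]] <- b
      }
    }
  }
  d <- do.call(rbind, rows)

  rep_eff <- blk_eff <- NULL
  if (cf$design %in% c("rcbd", "ibd")) {
    # replicate effects nested in location (x year)
    rep_key <- unique(d[, c("loc", if (cf$Q > 0) "year" else NULL, "repl"),
                        drop = FALSE])
    rep_key$id <- seq_len(nrow(rep_key))
    rep_eff <- stats::rnorm(nrow(rep_key), 0, sqrt(cf$var_rep))
    d <- merge(d, rep_key, sort = FALSE)
    if (cf$design == "ibd") {
      d$block <- ((d$gen - 1L) %% cf$n_block) + 1L
      blk_key <- unique(d[, c("id", "block")])
      blk_key$bid <- seq_len(nrow(blk_key))
      blk_eff <- stats::rnorm(nrow(blk_key), 0, sqrt(cf$var_blk))
      d <- merge(d, blk_key, sort = FALSE)
    }
  }

  ey <- cf$mu + g[d$gen] + l[d$loc] + gl[cbind(d$gen, d$loc)]
  if (cf$M > 0) {
    m_of <- loc_region[d$loc]
    ey <- ey + r[m_of] + gr[cbind(d$gen, m_of)]
  }
  if (cf$Q > 0) ey <- ey + tt[d$year] + gt[cbind(d$gen, d$year)]
  if (!is.null(rep_eff)) ey <- ey + rep_eff[d$id]
  if (!is.null(blk_eff)) ey <- ey + blk_eff[d$bid]
  d$value <- ey + stats::rnorm(nrow(d), 0, sigma_k[d$loc])

  out <- data.frame(Gen = gen_lab[d$gen], Loc = loc_lab[d$loc],
                    stringsAsFactors = FALSE)
  if (cf$M > 0) out$Reg <- reg_lab[loc_region[d$loc]]
  if (cf$Q > 0) out$Year <- yr_lab[d$year]
  if (cf$design %in% c("rcbd", "ibd")) out$Repl <- paste0("Rep", d$repl)
  if (cf$design == "ibd") out$Block <- paste0("B", d$block)
  out$Y <- d$value
  out <- out[order(d$loc, d$gen), , drop = FALSE]

  met <- met_data(out, gen = "Gen", loc = "Loc", trait = "Y",
                  reg = if (cf$M > 0) "Reg" else NULL,
                  year = if (cf$Q > 0) "Year" else NULL,
                  repl = if (cf$design %in% c("rcbd", "ibd")) "Repl" else NULL,
                  block = if (cf$design == "ibd") "Block" else NULL)

  truth <- list(mu = cf$mu, g = stats::setNames(g, gen_lab),
                l = stats::setNames(l, loc_lab), gl = gl,
                r = r, gr = gr, year = tt, gt = gt,
                sigma_k = stats::setNames(sigma_k, loc_lab),
                variances = c(var_g = cf$var_g, var_l = cf$var_l,
                              var_gl = cf$var_gl, var_r = cf$var_r,
                              var_gr = cf$var_gr, var_t = cf$var_t,
                              var_gt = cf$var_gt, var_e = cf$var_e),
                config = cf)
  list(met = met, truth = truth)
}

#' Simulate a soybean-trial-shaped MET dataset
#'
#' Entry-mean dataset with the structure of the USDA Northern Region Uniform
#' Soybean Tests subset commonly used to demonstrate this methodology: 39
#' genotypes, 14 locations nested in 3 breeding regions, one adjusted mean
#' per genotype-location cell, ~5% of cells missing. Variance components are
#' set to the scale reported for that trial (genotype 3.3, location 252,
#' genotype-by-location 6.9, region 10, genotype-by-region 1.1, residual
#' 11.2; yield in bushels/acre around a grand mean of 50). The values are
#' synthetic; only the structure and variance scale emulate the real trial.
#'
#' @param seed integer seed.
#' @param missing_frac fraction of empty genotype-by-location cells.
#' @return A [met_data] object.
#' @examples
#' met <- soy_like(seed = 7)
#' summary(met)
#' @export
soy_like <- function(seed = 1L, missing_frac = 0.05) {
  simulate_met(sim_config(J = 39, K = 14, M = 3, design = "entry-mean",
                          missing_frac = missing_frac, seed = seed))$met
}
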