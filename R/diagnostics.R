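#' Posterior-predictive Bayesian P-value
#'
#' Fraction of posterior-predictive draws in which the test statistic of the
#' replicated data is strictly higher than in the observed data:
#' `(1/S) * sum_s I(T(yrep_s) > T(y))`. Values near 0.5 indicate the model
#' generates data resembling the observations; values near 0 or 1 flag
#' misfit. Ties count as failures (strict inequality).
#'
#' @param stat one of `"max"`, `"min"`, `"median"`, `"mean"`, `"sd"`.
#' @param yrep S x n matrix of posterior-predictive replicates.
#' @param y observed vector of length n.
#' @return scalar in \[0, 1\].
#' @export
bayes_pvalue <- function(stat, yrep, y) {
  fns <- list(max = max, min = min, median = stats::median, mean = mean,
              sd = stats::sd)
  if (!stat %in% names(fns)) {
    stop("unknown statistic '", stat, "'; use one of ",
         paste(names(fns), collapse = ", "), call. = FALSE)
  }
  stopifnot(is.matrix(yrep), ncol(yrep) == length(y))
  f <- fns[[stat]]
  t_obs <- f(y)
  mean(apply(yrep, 1, f) > t_obs)
}

#' WAIC with the variance-based effective-parameter penalty
#'
#' From the S x n pointwise log-likelihood matrix:
#' `lppd = sum_i log( (1/S) sum_s exp(l_is) )` (computed via a stable
#' log-sum-exp), `p = sum_i Var_s(l_is)` (the effective number of
#' parameters), and `waic2 = -2 (lppd - p)`.
#'
#' @param loglik S x n matrix of pointwise log-likelihood draws.
#' @return list with `waic2`, `eff_n_params`, `lppd`.
#' @export
waic2 <- function(loglik) {
  stopifnot(is.matrix(loglik))
  if (any(!is.finite(loglik))) stop("non-finite log-likelihood values",
                                    call. = FALSE)
  S <- nrow(loglik)
  mx <- apply(loglik, 2, max)
  lppd <- sum(mx + log(colMeans(exp(sweep(loglik, 2, mx)))))
  p <- sum(apply(loglik, 2, stats::var))
  list(waic2 = -2 * (lppd - p), eff_n_params = p, lppd = lppd)
}

# autocovariance at lags 0..n-1 (1/n normalization, as stats::acf), via FFT
.acov_fft <- function(v) {
  n <- length(v)
  x <- v - mean(v)
  len <- 2^ceiling(log2(2 * n))
  f <- stats::fft(c(x, numeric(len - n)))
  Re(stats::fft(f * Conj(f), inverse = TRUE))[seq_len(n)] / (len * n)
}

# split each chain in half (dropping the middle draw of odd-length chains)
# and return a list of half-chain vectors
.split_chains <- function(x, chain) {
  out <- list()
  for (ch in unique(chain)) {
    v <- x[chain == ch]
    h <- length(v) %/% 2
    out[[length(out) + 1]] <- v[seq_len(h)]
    out[[length(out) + 1]] <- v[seq.int(length(v) - h + 1, length(v))]
  }
  out
}

#' Split potential scale reduction factor (R-hat)
#'
#' Each chain is split in half and the classic potential-scale-reduction
#' statistic is computed on the half-chains:
#' `R-hat = sqrt( ((n-1)/n * W + B/n) / W )`, with `W` the mean within-chain
#' variance and `B` the between-chain variance of the half-chain means.
#' Values near 1 indicate the chains sample a common distribution.
#' Degenerate draws (zero within-chain variance) give `NA`.
#'
#' @param x numeric vector of draws (all chains concatenated), or a matrix
#'   with one column per parameter.
#' @param chain integer chain id per draw.
#' @return scalar (or named vector for a matrix input); `NA` when undefined.
#' @export
split_rhat <- function(x, chain) {
  if (is.matrix(x)) {
    return(apply(x, 2, split_rhat, chain = chain))
  }
  halves <- .split_chains(x, chain)
  n <- min(lengths(halves))
  if (length(halves) < 2 || n < 2) return(NA_real_)
  halves <- lapply(halves, function(v) v[seq_len(n)])
  means <- vapply(halves, mean, numeric(1))
  W <- mean(vapply(halves, stats::var, numeric(1)))
  B <- n * stats::var(means)
  if (!is.finite(W) || W <= 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Effective sample size
#'
#' Classic autocorrelation-based estimator: per-lag autocovariances are
#' averaged across chains, converted to correlations against the
#' between-plus-within variance estimate, summed in adjacent pairs, and
#' truncated by Geyer's initial monotone positive sequence;
#' `ESS = S / (1 + 2 * sum(rho))`.
#'
#' @param x numeric vector of draws (all chains concatenated), or a matrix
#'   with one column per parameter.
#' @param chain integer chain id per draw.
#' @return scalar ESS (or named vector); `NA` for degenerate draws.
#' @export
effective_sample_size <- function(x, chain) {
  if (is.matrix(x)) {
    return(apply(x, 2, effective_sample_size, chain = chain))
  }
  chains <- split(x, chain)
  n <- min(lengths(chains))
  if (n < 4) return(NA_real_)
  chains <- lapply(chains, function(v) v[seq_len(n)])
  m <- length(chains)
  within <- vapply(chains, stats::var, numeric(1))
  W <- mean(within)
  if (!is.finite(W) || W <= 0) return(NA_real_)
  B_over_n <- if (m > 1) stats::var(vapply(chains, mean, numeric(1))) else 0
  var_plus <- (n - 1) / n * W + B_over_n

  acov <- vapply(chains, .acov_fft, numeric(n))
  mean_acov <- rowMeans(acov)  # lag 0 .. n-1
  rho <- 1 - (W - mean_acov) / var_plus  # rho[1] is lag 0

  # Geyer pairs Gamma_k = rho(2k) + rho(2k+1), k = 0, 1, ...
  max_pairs <- n %/% 2
  gam <- numeric(0)
  for (k in seq_len(max_pairs)) {
    i <- 2 * (k - 1) + 1
    if (i + 1 > length(rho)) break
    g2 <- rho[i] + rho[i + 1]
    if (g2 <= 0) break
    gam <- c(gam, g2)
  }
  if (length(gam) == 0) return(m * n)
  gam <- cummin(gam)  # initial monotone sequence
  tau <- max(-1 + 2 * sum(gam), 1 / (m * n))
  m * n / tau
}

# one wide matrix of every scalar parameter's draws, for R-hat / ESS tables
.param_matrix <- function(fit) {
  blocks <- list()
  for (nm in names(fit$draws)) {
    b <- fit$draws[[nm]]
    cn <- colnames(b)
    colnames(b) <- if (ncol(b) == 1 && nm == "mu") "mu" else
      paste0(nm, "[", if (is.null(cn)) seq_len(ncol(b)) else cn, "]")
    blocks[[nm]] <- b
  }
  sig <- fit$sigma
  colnames(sig) <- if (ncol(sig) == 1) "sigma" else
    paste0("sigma[", colnames(sig), "]")
  do.call(cbind, c(blocks, list(fit$scales, s_sig = fit$s_sig, sig)))
}

#' Goodness-of-fit diagnostics report
#'
#' Assembles the full posterior-predictive and convergence battery for a
#' fitted MET model: Bayesian P-values of five test statistics (maximum,
#' minimum, median, mean, SD), the WAIC with its effective number of
#' parameters, the mean split R-hat over all scalar parameters (with the
#' per-parameter table), effective sample sizes, and backend-reported
#' divergence/tree-depth/BFMI counts where the backend provides them
#' (`NA` = not available).
#'
#' @param fit a [fit_met_model()] result.
#' @return A `met_diagnostics` list; see [write_diagnostics_json()].
#' @export
diagnose <- function(fit) {
  stopifnot(inherits(fit, "met_fit"))
  y <- fit$met$records$value
  pvals <- vapply(c("max", "min", "median", "mean", "sd"),
                  bayes_pvalue, numeric(1), yrep = fit$yrep, y = y)
  w <- waic2(fit$loglik)
  pm <- .param_matrix(fit)
  rhat <- split_rhat(pm, fit$chain)
  ess <- effective_sample_size(pm, fit$chain)
  S <- length(fit$chain)
  structure(list(
    p_max = pvals[["max"]], p_min = pvals[["min"]],
    p_median = pvals[["median"]], p_mean = pvals[["mean"]],
    p_sd = pvals[["sd"]],
    waic2 = w$waic2, eff_n_params = w$eff_n_params, lppd = w$lppd,
    rhat_mean = mean(rhat, na.rm = TRUE),
    ess_mean = mean(ess, na.rm = TRUE),
    ess_ratio_mean = mean(ess, na.rm = TRUE) / S,
    n_draws = S,
    per_parameter = data.frame(parameter = colnames(pm), rhat = unname(rhat),
                               ess = unname(ess)),
    divergences = fit$sampler$divergences,
    treedepth_hits = fit$sampler$treedepth_hits,
    bfmi = fit$sampler$bfmi
  ), class = "met_diagnostics")
}

#' @export
print.met_diagnostics <- function(x, ...) {
  cat("Goodness-of-fit diagnostics\n")
  cat(sprintf("  Bayesian P-values: max %.3f, min %.3f, median %.3f, mean %.3f, sd %.3f\n",
              x$p_max, x$p_min, x$p_median, x$p_mean, x$p_sd))
  cat(sprintf("  WAIC2 %.2f (effective parameters %.1f)\n",
              x$waic2, x$eff_n_params))
  cat(sprintf("  mean split R-hat %.4f; mean ESS %.0f of %d draws\n",
              x$rhat_mean, x$ess_mean, x$n_draws))
  if (is.na(x$divergences)) {
    cat("  divergences / tree-depth / BFMI: not available from this backend\n")
  }
  invisible(x)
}

#' Write / read a diagnostics report as JSON
#'
#' @param report a [diagnose()] result.
#' @param path output path.
#' @return `path`, invisibly (writer); a `met_diagnostics` object (reader).
#' @export
write_diagnostics_json <- function(report, path) {
  stopifnot(inherits(report, "met_diagnostics"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       na = "null", dataframe = "columns")
  invisible(path)
}

#' @rdname write_diagnostics_json
#' @export
read_diagnostics_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$per_parameter <- as.data.frame(obj$per_parameter)
  for (nm in c("divergences", "treedepth_hits", "bfmi")) {
    if (is.null(obj[[nm]])) obj[[nm]] <- NA
  }
  structure(obj, class = "met_diagnostics")
}
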