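#' Highest posterior density interval
#'
#' Shortest interval over the sorted draws: with window gap
#' `m = round(mass * S)` (clamped to `[1, S - 1]`), the candidate intervals
#' are `[x_(i), x_(i+m)]` and the first (lowest) shortest one is returned.
#' At `mass` close to 1 the window spans all draws and the interval is the
#' sample range. This is the empirical-HPD convention of
#' `coda::HPDinterval()`.
#'
#' @param samples numeric vector of at least 10 posterior draws.
#' @param mass probability mass in (0, 1).
#' @return named vector `c(lower, upper)`.
#' @examples
#' hpd_interval(1:100, 0.90)  # (1, 91)
#' @export
hpd_interval <- function(samples, mass = 0.95) {
  if (length(samples) < 10) stop("need at least 10 samples", call. = FALSE)
  if (!is.numeric(mass) || mass <= 0 || mass >= 1) {
    stop("mass must be in (0, 1)", call. = FALSE)
  }
  x <- sort(samples)
  S <- length(x)
  m <- max(1L, min(S - 1L, round(mass * S)))
  widths <- x[(1 + m):S] - x[1:(S - m)]
  i <- which.min(widths)  # first shortest
  c(lower = x[i], upper = x[i + m])
}

.family_labels <- c(g = "Genotype (G)", l = "Location (L)", gl = "G×L",
                    r = "Region (R)", gr = "G×R", yr = "Year (Y)",
                    gt = "G×Y", rp = "Replicate", bl = "Block")

#' Variance-component summary table
#'
#' One row per effect family plus the residual: the posterior mean of the
#' squared scale draws ("Variance"), the posterior SD of the variance draws,
#' the naive Monte Carlo standard error (SD / sqrt(S), no autocorrelation
#' correction) and the HPD interval of the variance at the requested
#' probabilities.
#'
#' With heterogeneous residuals the "Residual" row summarizes the per-draw
#' average of the per-location variances; the per-location table is attached
#' as `attr(, "residual_by_location")`.
#'
#' @param fit a [fit_met_model()] result.
#' @param probs length-2 vector `(p_low, p_high)`; the HPD mass is
#'   `p_high - p_low` (e.g. `c(0.05, 0.95)` gives a 90% interval).
#' @return data.frame with columns `component`, `variance`, `sd`, `naive_se`,
#'   `hpd_lower`, `hpd_upper`.
#' @export
variance_table <- function(fit, probs = c(0.05, 0.95)) {
  stopifnot(inherits(fit, "met_fit"), length(probs) == 2)
  mass <- probs[2] - probs[1]
  if (mass <= 0 || mass >= 1) stop("probs must satisfy 0 < p2 - p1 < 1",
                                   call. = FALSE)
  one <- function(var_draws, label) {
    h <- hpd_interval(var_draws, mass)
    data.frame(component = label,
               variance = mean(var_draws),
               sd = stats::sd(var_draws),
               naive_se = stats::sd(var_draws) / sqrt(length(var_draws)),
               hpd_lower = h[["lower"]], hpd_upper = h[["upper"]])
  }
  rows <- lapply(fit$families, function(f) {
    one(fit$scales[, paste0("s_", f)]^2, .family_labels[[f]])
  })
  res_draws <- if (fit$spec$res_het) rowMeans(fit$sigma^2) else fit$sigma[, 1]^2
  rows[[length(rows) + 1]] <- one(res_draws, "Residual")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (fit$spec$res_het) {
    per_loc <- do.call(rbind, lapply(fit$met$locations, function(k) {
      one(fit$sigma[, k]^2, paste0("Residual (", k, ")"))
    }))
    rownames(per_loc) <- NULL
    attr(out, "residual_by_location") <- per_loc
  }
  out
}

# posterior mode of a draw vector via Gaussian kernel density
.kde_mode <- function(x) {
  if (stats::sd(x) == 0) return(x[1])
  d <- stats::density(x)
  d$x[which.max(d$y)]
}

#' Per-genotype posterior summary of the main effects
#'
#' Posterior mean, MAP estimate (highest-density draw value via Gaussian
#' kernel density, since the Gibbs backend exposes no per-draw
#' log-posterior) and two nested HPD intervals per genotype — the caterpillar
#' plot's numbers.
#'
#' @param fit a [fit_met_model()] result.
#' @param probs the two HPD interval masses, inner first (default 95% and
#'   97.5%).
#' @return data.frame with `genotype`, `map`, `mean`, `lo_inner`, `up_inner`,
#'   `lo_outer`, `up_outer`, sorted by posterior mean, decreasing.
#' @export
genotype_posterior <- function(fit, probs = c(0.95, 0.975)) {
  stopifnot(inherits(fit, "met_fit"), length(probs) == 2)
  probs <- sort(probs)
  g <- fit$draws$g
  rows <- lapply(colnames(g), function(j) {
    x <- g[, j]
    h1 <- hpd_interval(x, probs[1])
    h2 <- hpd_interval(x, probs[2])
    data.frame(genotype = j, map = .kde_mode(x), mean = mean(x),
               lo_inner = h1[["lower"]], up_inner = h1[["upper"]],
               lo_outer = h2[["lower"]], up_outer = h2[["upper"]])
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$mean, decreasing = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  out
}
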