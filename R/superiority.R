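#' Selection rule: intensity and direction
#'
#' The sole tuning knob of the probability calculus. The selected set Omega
#' is re-formed within every posterior draw: the top `n_sel` genotypes by
#' the draw's values (highest if `increase`, lowest otherwise), with
#' `n_sel = max(1, round_half_up(intensity * J))` computed per candidate
#' pool (all J genotypes marginally; the genotypes observed in environment k
#' conditionally).
#'
#' @param intensity selected fraction, in (0, 1].
#' @param increase `TRUE` to select for high trait values, `FALSE` for low.
#' @return A `selection_rule` list.
#' @export
selection_rule <- function(intensity = 0.2, increase = TRUE) {
  if (!is.numeric(intensity) || intensity <= 0 || intensity > 1) {
    stop("intensity must be in (0, 1]", call. = FALSE)
  }
  structure(list(intensity = intensity, increase = isTRUE(increase)),
            class = "selection_rule")
}

#' @rdname selection_rule
#' @param rule a `selection_rule`.
#' @param J candidate-pool size.
#' @export
n_sel <- function(rule, J) {
  stopifnot(inherits(rule, "selection_rule"), J >= 1)
  max(1L, as.integer(floor(rule$intensity * J + 0.5)))  # half-up rounding
}

# per-draw membership of the selected set: S x J logical matrix.
# ties within a draw break by column (genotype) index order.
.selected <- function(values, rule, nsel) {
  if (nsel >= ncol(values)) {
    return(matrix(TRUE, nrow(values), ncol(values)))
  }
  sgn <- if (rule$increase) -1 else 1
  t(apply(values, 1, function(v) {
    rank(sgn * v, ties.method = "first") <= nsel
  }))
}

#' Marginal probability of superior performance
#'
#' For each posterior draw the selected set Omega is the top `n_sel`
#' genotypes by genotypic main effect; a genotype's probability is the
#' fraction of draws in which it belongs to Omega.
#'
#' @param g S x J matrix of genotypic main-effect draws (columns named by
#'   genotype).
#' @param rule a [selection_rule()].
#' @return named numeric vector of probabilities (genotype order preserved);
#'   the probabilities sum to `n_sel(rule, J)` exactly.
#' @examples
#' g <- matrix(c(1, 3, 0, 1, 2, 2, 5, 1.5, 3, 1, 1, 2), nrow = 4)
#' marginal_superiority(g, selection_rule(1 / 3))
#' @export
marginal_superiority <- function(g, rule) {
  stopifnot(is.matrix(g), ncol(g) >= 2)
  sel <- .selected(g, rule, n_sel(rule, ncol(g)))
  stats::setNames(colMeans(sel), colnames(g))
}

#' Conditional probability of superior performance within environments
#'
#' Within each environment k the genotype's value is
#' `g_j + ge_jk` (main effect plus interaction). Only genotypes observed in
#' k compete; Omega_k holds the top `n_sel(J_k)` of the `J_k` observed
#' genotypes. Unobserved cells are `NA`; an environment with fewer than two
#' observed genotypes is skipped with a warning.
#'
#' @param g S x J matrix of genotypic main-effect draws.
#' @param ge S x J x E array of interaction draws, `NA` for unobserved
#'   cells (see [gl_array()]).
#' @param rule a [selection_rule()].
#' @return J x E matrix of probabilities with `NA` for unobserved cells.
#' @export
conditional_superiority <- function(g, ge, rule) {
  stopifnot(is.matrix(g), length(dim(ge)) == 3, ncol(g) == dim(ge)[2])
  J <- ncol(g); E <- dim(ge)[3]
  out <- matrix(NA_real_, J, E,
                dimnames = list(colnames(g), dimnames(ge)[[3]]))
  for (e in seq_len(E)) {
    obs <- which(!is.na(ge[1, , e]))
    if (length(obs) < 2) {
      warning("environment ", e, " has fewer than 2 observed genotypes; skipped")
      next
    }
    vals <- g[, obs, drop = FALSE] + ge[, obs, e]
    sel <- .selected(vals, rule, n_sel(rule, length(obs)))
    out[obs, e] <- colMeans(sel)
  }
  out
}

#' Pairwise probabilities of superior performance
#'
#' `P[j, j']` is the fraction of draws in which genotype j's value beats
#' genotype j' in the selection direction (strictly greater when
#' `increase`, strictly smaller otherwise). On tie-free draws
#' `P[j, j'] + P[j', j] = 1`; the diagonal is `NA`.
#'
#' @param values S x J matrix of per-draw genotype values (main effects for
#'   the across-environments version; `g + ge` within one environment).
#' @param rule a [selection_rule()].
#' @return J x J matrix.
#' @export
pairwise_superiority <- function(values, rule) {
  stopifnot(is.matrix(values))
  J <- ncol(values)
  out <- matrix(NA_real_, J, J, dimnames = list(colnames(values),
                                                colnames(values)))
  for (j in seq_len(J)) {
    for (jp in seq_len(J)) {
      if (j == jp) next
      out[j, jp] <- if (rule$increase) {
        mean(values[, j] > values[, jp])
      } else {
        mean(values[, j] < values[, jp])
      }
    }
  }
  out
}

# per-draw population variance of interaction effects across the observed
# environments of each genotype; NA column if < 2 observed environments
.ge_var_draws <- function(ge) {
  J <- dim(ge)[2]
  S <- dim(ge)[1]
  out <- matrix(NA_real_, S, J, dimnames = list(NULL, dimnames(ge)[[2]]))
  for (j in seq_len(J)) {
    obs <- which(!is.na(ge[1, j, ]))
    if (length(obs) < 2) next
    x <- ge[, j, obs, drop = FALSE]
    dim(x) <- c(S, length(obs))
    ctr <- x - rowMeans(x)
    out[, j] <- rowMeans(ctr * ctr)  # population variance (divide by E_j)
  }
  out
}

#' Probability of superior stability
#'
#' A stable genotype has a small variance of its genotype-by-environment
#' interaction effects (a posterior, per-draw analogue of Shukla's stability
#' variance). Per draw, the population variance of `ge_jk` across the
#' genotype's observed environments is computed and the `n_sel` genotypes
#' with the smallest variance are selected — regardless of the selection
#' direction, stability always favours small variance. Genotypes observed in
#' fewer than two environments are `NA` (with a warning) and do not compete.
#'
#' @param ge S x J x E interaction-draw array (`NA` = unobserved cell);
#'   location-based (`gl`) or region-based (`gr`) draws.
#' @param rule a [selection_rule()]; only the intensity is used.
#' @return named probability vector (NA for ineligible genotypes); the
#'   non-NA entries sum to `n_sel` of the eligible pool.
#' @export
stability_superiority <- function(ge, rule) {
  v <- .ge_var_draws(ge)
  elig <- which(!is.na(v[1, ]))
  if (length(elig) < ncol(v)) {
    warning(ncol(v) - length(elig),
            " genotype(s) observed in < 2 environments; stability not defined")
  }
  out <- stats::setNames(rep(NA_real_, ncol(v)), colnames(v))
  if (length(elig) < 2) return(out)
  asc <- selection_rule(rule$intensity, increase = FALSE)  # smallest variance
  sel <- .selected(v[, elig, drop = FALSE], asc,
                   n_sel(rule, length(elig)))
  out[elig] <- colMeans(sel)
  out
}

#' Pairwise probabilities of superior stability
#'
#' `P[j, j']` is the fraction of draws in which genotype j's interaction
#' variance is strictly smaller than genotype j''s.
#'
#' @inheritParams stability_superiority
#' @return J x J matrix (`NA` diagonal and rows/columns of ineligible
#'   genotypes).
#' @export
pairwise_stability <- function(ge) {
  v <- .ge_var_draws(ge)
  J <- ncol(v)
  out <- matrix(NA_real_, J, J, dimnames = list(colnames(v), colnames(v)))
  for (j in seq_len(J)) {
    if (is.na(v[1, j])) next
    for (jp in seq_len(J)) {
      if (j == jp || is.na(v[1, jp])) next
      out[j, jp] <- mean(v[, j] < v[, jp])
    }
  }
  out
}

#' Joint probability of superior performance and stability
#'
#' The genotypic main effects and the interaction variances are independent
#' by the linear model's construction, so the joint probability is the
#' elementwise product of the marginal-performance and stability
#' probabilities.
#'
#' @param marginal,stability named probability vectors over the same
#'   genotype set.
#' @return named probability vector.
#' @export
joint_probability <- function(marginal, stability) {
  if (is.null(names(marginal)) || is.null(names(stability)) ||
      !identical(sort(names(marginal)), sort(names(stability)))) {
    stop("marginal and stability tables cover different genotype sets",
         call. = FALSE)
  }
  marginal * stability[names(marginal)]
}

# sorted per-genotype data.frame for reporting
.prob_df <- function(p) {
  d <- data.frame(genotype = names(p), prob = unname(p))
  d <- d[order(-d$prob, d$genotype), , drop = FALSE]
  rownames(d) <- NULL
  d
}

#' Full probability-of-superiority pipeline
#'
#' Computes every probability table the methodology defines from a fitted
#' MET model: marginal and pairwise probabilities of superior performance
#' (genotypic main effects), conditional probabilities within locations and
#' (when modelled) within regions (`g + ge` with the matching interaction),
#' probabilities of superior stability across locations and across regions,
#' pairwise stability, and the joint probability of superior performance
#' and stability. Only the selection intensity and direction drive the
#' computation.
#'
#' Within-location values use `g + gl` only — the genotype-by-region effect
#' enters the within-region tables, not the within-location ones — unless
#' `region_in_location = TRUE`, which adds the location's region interaction
#' to the within-location values.
#'
#' @param fit a [fit_met_model()] result.
#' @param intensity,increase selection intensity and direction, see
#'   [selection_rule()].
#' @param joint_stability which stability table the joint probability uses:
#'   `"location"` (default) or `"region"`.
#' @param region_in_location see Details.
#' @return A `met_prob` list: `marginal`, `within_location`,
#'   `within_region`, `pairwise_marginal`, `pairwise_location` (list of
#'   per-location matrices), `pairwise_region`, `stability_location`,
#'   `stability_region`, `pairwise_stab_location`, `pairwise_stab_region`,
#'   `joint`, plus the sorted reporting tables `marginal_table` and
#'   `joint_table`, the `rule` and `n_sel`.
#' @export
prob_sup <- function(fit, intensity = 0.2, increase = TRUE,
                     joint_stability = c("location", "region"),
                     region_in_location = FALSE) {
  stopifnot(inherits(fit, "met_fit"))
  joint_stability <- match.arg(joint_stability)
  rule <- selection_rule(intensity, increase)
  g <- fit$draws$g
  J <- ncol(g)
  has_region <- !is.null(fit$draws$gr)
  if (joint_stability == "region" && !has_region) {
    stop("region-based joint probability requires a region model",
         call. = FALSE)
  }

  gl <- gl_array(fit, "gl")
  gl_cond <- gl
  if (region_in_location && has_region) {
    grr <- gl_array(fit, "gr")
    reg_of_loc <- match(fit$met$location_region, fit$met$regions)
    for (k in seq_len(dim(gl)[3])) {
      gl_cond[, , k] <- gl_cond[, , k] + grr[, , reg_of_loc[k]]
    }
  }

  marginal <- marginal_superiority(g, rule)
  within_location <- conditional_superiority(g, gl_cond, rule)
  pairwise_marginal <- pairwise_superiority(g, rule)
  pairwise_location <- lapply(seq_len(dim(gl)[3]), function(k) {
    obs <- which(!is.na(gl_cond[1, , k]))
    pairwise_superiority(g[, obs, drop = FALSE] + gl_cond[, obs, k], rule)
  })
  names(pairwise_location) <- fit$met$locations
  stability_location <- stability_superiority(gl, rule)
  pairwise_stab_location <- pairwise_stability(gl)

  within_region <- pairwise_region <- NULL
  stability_region <- pairwise_stab_region <- NULL
  if (has_region) {
    gr <- gl_array(fit, "gr")
    within_region <- conditional_superiority(g, gr, rule)
    pairwise_region <- lapply(seq_len(dim(gr)[3]), function(m) {
      obs <- which(!is.na(gr[1, , m]))
      pairwise_superiority(g[, obs, drop = FALSE] + gr[, obs, m], rule)
    })
    names(pairwise_region) <- fit$met$regions
    stability_region <- stability_superiority(gr, rule)
    pairwise_stab_region <- pairwise_stability(gr)
  }

  stab_for_joint <- if (joint_stability == "location") stability_location else
    stability_region
  joint <- marginal * stab_for_joint  # NA where stability undefined

  structure(list(
    marginal = marginal,
    within_location = within_location,
    within_region = within_region,
    pairwise_marginal = pairwise_marginal,
    pairwise_location = pairwise_location,
    pairwise_region = pairwise_region,
    stability_location = stability_location,
    stability_region = stability_region,
    pairwise_stab_location = pairwise_stab_location,
    pairwise_stab_region = pairwise_stab_region,
    joint = joint,
    marginal_table = .prob_df(marginal),
    joint_table = .prob_df(joint[!is.na(joint)]),
    rule = rule, n_sel = n_sel(rule, J),
    joint_stability = joint_stability
  ), class = "met_prob")
}

#' @export
print.met_prob <- function(x, ...) {
  cat(sprintf(
    "Probabilities of superior performance and stability (top %d of %d, %s)\n",
    x$n_sel, length(x$marginal),
    if (x$rule$increase) "increase" else "decrease"))
  top <- utils::head(x$marginal_table, 5)
  cat("  Highest marginal probabilities:\n")
  for (i in seq_len(nrow(top))) {
    cat(sprintf("    %-6s %.3f\n", top$genotype[i], top$prob[i]))
  }
  invisible(x)
}

#' Write probability tables to CSV files
#'
#' Writes every table of a [prob_sup()] result into a directory with a
#' fixed naming convention (`marginal.csv`, `within_location.csv`,
#' `stability_location.csv`, `pairwise_marginal.csv`,
#' `pairwise_location_<loc>.csv`, `joint.csv`, ...).
#'
#' @param tables a `met_prob` object.
#' @param dir output directory (created if missing).
#' @return the directory path, invisibly.
#' @export
write_prob_tables <- function(tables, dir) {
  stopifnot(inherits(tables, "met_prob"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wv <- function(v, file) {
    utils::write.csv(.prob_df(v[!is.na(v)]), file.path(dir, file),
                     row.names = FALSE)
  }
  wm <- function(m, file) {
    utils::write.csv(as.data.frame(m), file.path(dir, file))
  }
  wv(tables$marginal, "marginal.csv")
  wv(tables$stability_location, "stability_location.csv")
  wv(tables$joint, "joint.csv")
  wm(tables$within_location, "within_location.csv")
  wm(tables$pairwise_marginal, "pairwise_marginal.csv")
  wm(tables$pairwise_stab_location, "pairwise_stability_location.csv")
  for (k in names(tables$pairwise_location)) {
    wm(tables$pairwise_location[[k]], paste0("pairwise_location_", k, ".csv"))
  }
  if (!is.null(tables$within_region)) {
    wm(tables$within_region, "within_region.csv")
    wv(tables$stability_region, "stability_region.csv")
    wm(tables$pairwise_stab_region, "pairwise_stability_region.csv")
    for (m in names(tables$pairwise_region)) {
      wm(tables$pairwise_region[[m]], paste0("pairwise_region_", m, ".csv"))
    }
  }
  invisible(dir)
}
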