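# Independent brute-force oracles for the probability calculus and the
# diagnostics formulas: explicit loops over draws, no shared code with the
# package implementations.

oracle_nsel <- function(intensity, J) max(1, floor(intensity * J + 0.5))

# which genotypes are selected in one draw: sort values, take the top nsel
# (direction-aware), ties broken by original index via stable order()
oracle_selected_one <- function(v, nsel, increase) {
  ord <- order(v, decreasing = increase)
  sort(ord[seq_len(min(nsel, length(v)))])
}

oracle_marginal <- function(g, nsel, increase) {
  S <- nrow(g); J <- ncol(g)
  count <- numeric(J)
  for (s in seq_len(S)) {
    sel <- oracle_selected_one(g[s, ], nsel, increase)
    count[sel] <- count[sel] + 1
  }
  count / S
}

oracle_conditional <- function(g, ge, intensity, increase) {
  S <- dim(ge)[1]; J <- dim(ge)[2]; E <- dim(ge)[3]
  out <- matrix(NA_real_, J, E)
  for (e in seq_len(E)) {
    obs <- which(!is.na(ge[1, , e]))
    if (length(obs) < 2) next
    nsel <- oracle_nsel(intensity, length(obs))
    count <- numeric(length(obs))
    for (s in seq_len(S)) {
      vals <- g[s, obs] + ge[s, obs, e]
      sel <- oracle_selected_one(vals, nsel, increase)
      count[sel] <- count[sel] + 1
    }
    out[obs, e] <- count / S
  }
  out
}

oracle_pairwise <- function(values, increase) {
  S <- nrow(values); J <- ncol(values)
  out <- matrix(NA_real_, J, J)
  for (j in seq_len(J)) for (jp in seq_len(J)) {
    if (j == jp) next
    wins <- 0
    for (s in seq_len(S)) {
      wins <- wins + if (increase) values[s, j] > values[s, jp] else
        values[s, j] < values[s, jp]
    }
    out[j, jp] <- wins / S
  }
  out
}

oracle_popvar <- function(x) sum((x - mean(x))^2) / length(x)

oracle_ge_vars <- function(ge) {
  S <- dim(ge)[1]; J <- dim(ge)[2]
  v <- matrix(NA_real_, S, J)
  for (j in seq_len(J)) {
    obs <- which(!is.na(ge[1, j, ]))
    if (length(obs) < 2) next
    for (s in seq_len(S)) v[s, j] <- oracle_popvar(ge[s, j, obs])
  }
  v
}

oracle_stability <- function(ge, intensity) {
  v <- oracle_ge_vars(ge)
  J <- ncol(v)
  elig <- which(!is.na(v[1, ]))
  out <- rep(NA_real_, J)
  if (length(elig) < 2) return(out)
  nsel <- oracle_nsel(intensity, length(elig))
  count <- numeric(length(elig))
  for (s in seq_len(nrow(v))) {
    sel <- oracle_selected_one(v[s, elig], nsel, increase = FALSE)
    count[sel] <- count[sel] + 1
  }
  out[elig] <- count / nrow(v)
  out
}

oracle_pairwise_stability <- function(ge) {
  v <- oracle_ge_vars(ge)
  J <- ncol(v)
  out <- matrix(NA_real_, J, J)
  for (j in seq_len(J)) for (jp in seq_len(J)) {
    if (j == jp || is.na(v[1, j]) || is.na(v[1, jp])) next
    out[j, jp] <- mean(v[, j] < v[, jp])
  }
  out
}

# shortest window over sorted draws, enumerated directly
oracle_hpd <- function(x, mass) {
  x <- sort(x)
  S <- length(x)
  m <- max(1, min(S - 1, round(mass * S)))
  best <- c(x[1], x[1 + m])
  for (i in seq_len(S - m)) {
    if (x[i + m] - x[i] < best[2] - best[1]) best <- c(x[i], x[i + m])
  }
  best
}

# naive two-pass WAIC formula (no log-sum-exp tricks)
oracle_waic <- function(ll) {
  lppd <- 0
  for (i in seq_len(ncol(ll))) lppd <- lppd + log(mean(exp(ll[, i])))
  p <- 0
  for (i in seq_len(ncol(ll))) p <- p + var(ll[, i])
  list(waic2 = -2 * (lppd - p), eff_n_params = p, lppd = lppd)
}

# textbook split R-hat, written out longhand over half-chains
oracle_rhat <- function(chains_list) {
  halves <- list()
  for (v in chains_list) {
    h <- length(v) %/% 2
    halves <- c(halves, list(v[1:h]), list(v[(length(v) - h + 1):length(v)]))
  }
  n <- length(halves[[1]])
  m <- length(halves)
  means <- sapply(halves, mean)
  W <- mean(sapply(halves, var))
  B <- n * var(means)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# random interaction array with a masked (unobserved) cell pattern; every
# genotype keeps >= 2 observed environments
random_ge_array <- function(S, J, E, mask_frac = 0.2) {
  ge <- array(rnorm(S * J * E), c(S, J, E))
  if (mask_frac > 0 && E > 2) {
    for (j in seq_len(J)) {
      drop <- which(runif(E) < mask_frac)
      if (length(drop) > E - 2) drop <- drop[seq_len(E - 2)]
      ge[, j, drop] <- NA
    }
  }
  ge
}
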