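test_that("selected-set size uses half-up rounding per candidate pool", {
  rule <- selection_rule(0.2)
  expect_equal(n_sel(rule, 39), 8)   # 7.8 rounds up
  expect_equal(n_sel(rule, 10), 2)
  expect_equal(n_sel(rule, 12), 2)   # 2.4 rounds down
  expect_equal(n_sel(rule, 3), 1)    # floor of 1
  expect_equal(n_sel(selection_rule(0.25), 10), 3)  # 2.5 rounds half up
  expect_equal(n_sel(selection_rule(1), 7), 7)
  expect_error(selection_rule(0), "intensity")
  expect_error(selection_rule(1.2), "intensity")
})

test_that("marginal probabilities count per-draw membership in the selected set", {
  g <- rbind(c(1, 2, 3), c(3, 2, 1), c(0, 5, 1), c(1, 1.5, 2))
  colnames(g) <- c("a", "b", "c")
  p <- marginal_superiority(g, selection_rule(1 / 3))
  expect_equal(unname(p), c(0.25, 0.25, 0.50))

  # intensity 1: everyone is selected in every draw
  expect_equal(unname(marginal_superiority(g, selection_rule(1))), rep(1, 3))

  # deterministic ordering g1 > g2 > g3
  const <- matrix(rep(c(3, 2, 1), each = 10), 10, 3)
  expect_equal(unname(marginal_superiority(const, selection_rule(1 / 3))),
               c(1, 0, 0))
  # decrease direction flips the winner
  expect_equal(unname(marginal_superiority(const,
                                           selection_rule(1 / 3, FALSE))),
               c(0, 0, 1))
})

test_that("conditional probabilities reduce to marginal in a single environment", {
  set.seed(20)
  g <- matrix(rnorm(40 * 4), 40, 4)
  ge <- array(rnorm(40 * 4), c(40, 4, 1))
  rule <- selection_rule(0.25)
  expect_equal(unname(conditional_superiority(g, ge, rule)[, 1]),
               unname(marginal_superiority(g + ge[, , 1], rule)))
})

test_that("unobserved cells are NA and observed probabilities conserve n_sel", {
  set.seed(21)
  g <- matrix(rnorm(30 * 5), 30, 5)
  ge <- array(rnorm(30 * 5 * 3), c(30, 5, 3))
  ge[, 2, 1] <- NA  # genotype 2 never observed in environment 1
  ge[, 5, 1] <- NA
  rule <- selection_rule(0.4)
  p <- conditional_superiority(g, ge, rule)
  expect_true(all(is.na(p[c(2, 5), 1])))
  expect_equal(sum(p[, 1], na.rm = TRUE), n_sel(rule, 3))
  expect_equal(sum(p[, 2]), n_sel(rule, 5))

  # an environment with < 2 observed genotypes is skipped with a warning
  ge[, 2:5, 2] <- NA
  expect_warning(p2 <- conditional_superiority(g, ge, rule), "fewer than 2")
  expect_true(all(is.na(p2[, 2])))
})

test_that("crossover interaction flips the conditional winner across environments", {
  S <- 50
  g <- matrix(rep(c(0.5, 0.4, -1), each = S), S, 3)  # close mains, g1 first
  ge <- array(0, c(S, 3, 2))
  ge[, 1, 1] <- 2; ge[, 2, 1] <- -2   # env 1 favours genotype 1
  ge[, 1, 2] <- -2; ge[, 2, 2] <- 2   # env 2 favours genotype 2
  rule <- selection_rule(1 / 3)
  p <- conditional_superiority(g, ge, rule)
  expect_equal(p[, 1], c(1, 0, 0), ignore_attr = TRUE)
  expect_equal(p[, 2], c(0, 1, 0), ignore_attr = TRUE)
  expect_equal(unname(marginal_superiority(g, rule)), c(1, 0, 0))
})

test_that("pairwise performance probabilities count per-draw wins", {
  v <- cbind(a = c(1, 2, 3, 4), b = c(2, 1, 4, 3))
  rule <- selection_rule(0.5)
  p <- pairwise_superiority(v, rule)
  expect_equal(p["a", "b"], 0.5)
  expect_equal(p["b", "a"], 0.5)
  expect_true(is.na(p["a", "a"]))

  dom <- cbind(x = 2:5, y = 1:4)  # x always exceeds y
  expect_equal(pairwise_superiority(dom, rule)["x", "y"], 1)
  expect_equal(pairwise_superiority(dom, selection_rule(0.5, FALSE))["x", "y"],
               0)

  # antisymmetry on tie-free draws
  set.seed(22)
  r <- matrix(rnorm(200), 50, 4)
  pr <- pairwise_superiority(r, rule)
  expect_equal(pr + t(pr), matrix(1, 4, 4) + diag(NA_real_, 4),
               ignore_attr = TRUE)
})

test_that("stability favours small interaction variance, whatever the direction", {
  S <- 30
  ge <- array(rnorm(S * 3 * 4), c(S, 3, 4))
  ge[, 2, ] <- 0  # genotype 2 has zero interaction variance in every draw
  rule <- selection_rule(1 / 3)
  p <- stability_superiority(ge, rule)
  expect_equal(unname(p[2]), 1)
  expect_equal(p, stability_superiority(ge, selection_rule(1 / 3, FALSE)))

  # hand-built variance draws: g1 vars (1, 4), g2 vars (2, 3) -> (0.5, 0.5)
  # variance across 2 envs of (a, -a) is a^2, so use a = sqrt(var)
  mk <- function(v1, v2) {
    arr <- array(0, c(2, 2, 2))
    arr[1, 1, ] <- c(sqrt(v1[1]), -sqrt(v1[1]))
    arr[2, 1, ] <- c(sqrt(v1[2]), -sqrt(v1[2]))
    arr[1, 2, ] <- c(sqrt(v2[1]), -sqrt(v2[1]))
    arr[2, 2, ] <- c(sqrt(v2[2]), -sqrt(v2[2]))
    arr
  }
  p2 <- stability_superiority(mk(c(1, 4), c(2, 3)), selection_rule(0.5))
  expect_equal(unname(p2), c(0.5, 0.5))
})

test_that("genotypes observed in fewer than two environments are excluded", {
  set.seed(23)
  ge <- array(rnorm(20 * 4 * 3), c(20, 4, 3))
  ge[, 3, 2:3] <- NA  # genotype 3 observed in a single environment
  expect_warning(p <- stability_superiority(ge, selection_rule(0.5)),
                 "< 2 environments")
  expect_true(is.na(p[3]))
  expect_equal(sum(p, na.rm = TRUE), n_sel(selection_rule(0.5), 3))
})

test_that("pairwise stability compares interaction variances draw by draw", {
  S <- 40
  ge <- array(rnorm(S * 2 * 3), c(S, 2, 3))
  ge[, 1, ] <- 0
  p <- pairwise_stability(ge)
  expect_equal(p[1, 2], 1)
  expect_equal(p[2, 1], 0)

  set.seed(24)
  r <- array(rnorm(S * 4 * 3), c(S, 4, 3))
  pr <- pairwise_stability(r)
  expect_equal(pr + t(pr), matrix(1, 4, 4) + diag(NA_real_, 4),
               ignore_attr = TRUE)
})

test_that("joint probability is the product and an elementwise lower bound", {
  m <- c(G1 = 0.5, G2 = 0.4, G3 = 0)
  s <- c(G1 = 0.4, G2 = 0.5, G3 = 0.9)
  j <- joint_probability(m, s)
  expect_equal(unname(j), c(0.2, 0.2, 0))
  expect_true(all(j <= pmin(m, s)))
  expect_error(joint_probability(m, s[1:2]), "different genotype sets")
})

test_that("adding a constant to one genotype never lowers its probability", {
  set.seed(25)
  g <- matrix(rnorm(60 * 5), 60, 5)
  rule <- selection_rule(0.4)
  p0 <- marginal_superiority(g, rule)
  g2 <- g
  g2[, 3] <- g2[, 3] + 0.8
  p1 <- marginal_superiority(g2, rule)
  expect_gte(p1[3], p0[3])
})

test_that("negating the draws and flipping the direction leaves probabilities unchanged", {
  set.seed(26)
  g <- matrix(rnorm(50 * 4), 50, 4)
  up <- selection_rule(0.3, increase = TRUE)
  dn <- selection_rule(0.3, increase = FALSE)
  expect_equal(marginal_superiority(g, up), marginal_superiority(-g, dn))
  expect_equal(pairwise_superiority(g, up), pairwise_superiority(-g, dn))
  ge <- array(rnorm(50 * 4 * 3), c(50, 4, 3))
  expect_equal(conditional_superiority(g, ge, up),
               conditional_superiority(-g, -ge, dn))
})

test_that("the full pipeline satisfies its conservation and product identities", {
  out <- small_region_fit()
  fit <- out$fit
  tables <- prob_sup(fit, intensity = 0.25, increase = TRUE)
  J <- length(fit$met$genotypes)
  expect_equal(sum(tables$marginal), tables$n_sel)
  for (k in seq_along(fit$met$locations)) {
    obs <- sum(!is.na(tables$within_location[, k]))
    expect_equal(sum(tables$within_location[, k], na.rm = TRUE),
                 n_sel(tables$rule, obs))
  }
  for (m in seq_along(fit$met$regions)) {
    obs <- sum(!is.na(tables$within_region[, m]))
    expect_equal(sum(tables$within_region[, m], na.rm = TRUE),
                 n_sel(tables$rule, obs))
  }
  expect_equal(sum(tables$stability_location, na.rm = TRUE),
               n_sel(tables$rule, sum(!is.na(tables$stability_location))))
  expect_equal(tables$joint,
               tables$marginal * tables$stability_location)
  # reporting tables are sorted in decreasing probability order
  expect_false(is.unsorted(rev(tables$marginal_table$prob)))
  all_p <- c(tables$marginal, tables$within_location, tables$within_region,
             tables$stability_location, tables$stability_region,
             tables$pairwise_marginal, tables$joint)
  expect_true(all(all_p >= 0 & all_p <= 1, na.rm = TRUE))
})

test_that("region-based joint probability is available behind the flag", {
  out <- small_region_fit()
  tr <- prob_sup(out$fit, 0.25, joint_stability = "region")
  expect_equal(tr$joint, tr$marginal * tr$stability_region)
  plain <- small_plain_fit()
  expect_error(prob_sup(plain$fit, 0.25, joint_stability = "region"),
               "region model")
})

test_that("probability tables write to CSV with the documented layout", {
  out <- small_region_fit()
  tables <- prob_sup(out$fit, 0.2)
  dir <- file.path(tempdir(), "probtabs")
  write_prob_tables(tables, dir)
  files <- list.files(dir)
  expect_true(all(c("marginal.csv", "stability_location.csv", "joint.csv",
                    "within_location.csv", "within_region.csv",
                    "pairwise_marginal.csv") %in% files))
  marg <- read.csv(file.path(dir, "marginal.csv"))
  expect_equal(marg$prob, sort(unname(tables$marginal), decreasing = TRUE))
})
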