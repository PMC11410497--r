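test_that("Spearman: hand ranks, boundaries, and exact permutation oracle", {
  expect_equal(spearman_cor(1:6, (1:6)^2)$rho, 1)
  expect_equal(spearman_cor(1:6, rev(1:6))$rho, -1)
  expect_equal(spearman_cor(c(1, 2, 3, 4), c(2, 1, 4, 3))$rho, 0.6)
  expect_warning(out <- spearman_cor(rep(1, 5), 1:5), "zero variance")
  expect_true(is.na(out$rho))
  expect_error(spearman_cor(1:2, 1:2), "at least 3")

  # statistic equals midrank Pearson (ties included) to 1e-12, and the
  # t-approximate p tracks the exact permutation p on small n
  set.seed(31)
  for (trial in 1:6) {
    n <- sample(5:7, 1)
    x <- sample(n); y <- sample(n)
    if (trial > 3) y[1:2] <- y[2:1] * 0 + y[1]  # inject ties
    ex <- spearman_cor(x, y, method = "exact")
    ap <- spearman_cor(x, y)
    expect_equal(ex$rho, cor(rank(x), rank(y)), tolerance = 1e-12)
    expect_equal(ap$rho, ex$rho, tolerance = 1e-12)
    # permutation p at these n has granularity ~ n!; allow generous MC-style slack
    expect_lt(abs(ap$p - ex$p), 0.2)
  }
})

test_that("Welch from summaries: zero case, antisymmetry, textbook check", {
  eq <- welch_t(10, 2, 30, 10, 3, 40)
  expect_equal(eq$t, 0)
  expect_equal(eq$p, 1)
  a <- welch_t(39, 10.5, 52, 34, 10.0, 60)
  b <- welch_t(34, 10.0, 60, 39, 10.5, 52)
  expect_equal(a$t, -b$t)
  expect_equal(a$p, b$p)
  # against stats::t.test on raw samples
  set.seed(4)
  x <- rnorm(25, 1, 1); y <- rnorm(35, 0, 2.5)
  ref <- t.test(x, y)
  got <- welch_t(mean(x), sd(x), 25, mean(y), sd(y), 35)
  expect_equal(got$t, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(got$df, unname(ref$parameter), tolerance = 1e-10)
  expect_equal(got$p, ref$p.value, tolerance = 1e-10)
  expect_error(welch_t(1, 0, 10, 2, 1, 10), "standard deviations")
  expect_error(welch_t(1, 1, 1, 2, 1, 10), "n >= 2")
})

test_that("BH step-up: hand cases, monotonicity, permutation invariance", {
  expect_equal(bh_adjust(0.04), 0.04)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  p <- c(0.005, 0.011, 0.02, 0.04, 0.13)
  expect_equal(bh_adjust(p), p.adjust(p, "BH"))
  set.seed(9)
  for (trial in 1:5) {
    p <- runif(sample(3:12, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, p.adjust(p, "BH"))
    expect_true(all(adj >= p - 1e-12))
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
    perm <- sample(length(p))
    expect_equal(bh_adjust(p[perm]), adj[perm])
  }
  expect_error(bh_adjust(c(0.1, 1.2)), "0, 1")
})

test_that("comparison assembly wires families, BH scope and Welch together", {
  S_dr <- setNames(seq(3, 0, length.out = 8), sprintf("c%d", 1:8))
  S_fe <- S_dr + rnorm(8, 0, 0.2)
  beh <- data.frame(animal_id = rep(sprintf("c%d", 1:8), 2),
                    period = rep(c("hot", "normal"), each = 8),
                    mean_visits = runif(16, 2, 10),
                    mean_duration_s = runif(16, 100, 900),
                    mean_intake_kg = runif(16, 40, 120))
  blocks <- expand.grid(animal_id = sprintf("c%d", 1:8),
                        period = c("hot", "normal"), block = 0:5,
                        stringsAsFactors = FALSE)
  blocks$pct_visits <- runif(nrow(blocks), 0, 40)
  blocks$pct_duration <- runif(nrow(blocks), 0, 40)
  blocks$pct_intake <- runif(nrow(blocks), 0, 40)
  rd <- data.frame(date = as.Date("2020-07-01") + 0:19,
                   period = rep(c("hot", "normal"), each = 10),
                   n_events = c(rpois(10, 39), rpois(10, 34)))
  set.seed(2)
  comp <- assemble_comparisons(
    list(drinker = S_dr, feeder = S_fe, hot = S_dr, normal = S_dr),
    beh, blocks, rd)
  cc <- comp$correlations
  expect_setequal(unique(cc$family[startsWith(cc$family, "blocks_")]),
                  as.vector(outer(c("blocks_pct_visits_", "blocks_pct_duration_",
                                    "blocks_pct_intake_"),
                                  c("hot", "normal"), paste0)))
  # each block family holds exactly 6 tests, BH applied within it
  for (fam in unique(cc$family[startsWith(cc$family, "blocks_")])) {
    i <- cc$family == fam
    expect_equal(sum(i), 6L)
    expect_equal(cc$p_adj[i], bh_adjust(cc$p[i]))
  }
  # daily families unadjusted by default
  expect_equal(cc$p_adj[cc$family == "daily_hot"], cc$p[cc$family == "daily_hot"])
  expect_equal(cc$rho[cc$label == "feeder_vs_drinker"],
               spearman_cor(S_fe, S_dr)$rho)
  expect_s3_class(comp$welch, "data.frame")
  expect_equal(comp$welch$n_hot, 10)
  # disjoint animal sets must error
  expect_error(assemble_comparisons(
    list(drinker = S_dr, feeder = setNames(1:3, c("x", "y", "z")))),
    "no shared animals")
})
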