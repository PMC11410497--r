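test_that("expected winning probability: closed forms and complementarity", {
  expect_equal(expected_win_prob(1000, 1000), 0.5)
  expect_equal(expected_win_prob(1400, 1000, 400), 10 / 11)
  expect_equal(expected_win_prob(1000, 1400, 400), 1 / 11)
  r <- runif(20, 800, 1200)
  s <- runif(20, 800, 1200)
  expect_equal(expected_win_prob(r, s) + expected_win_prob(s, r), rep(1, 20))
  diffs <- seq(-800, 800, by = 50)
  expect_true(all(diff(expected_win_prob(1000 + diffs, 1000)) > 0))
  expect_error(expected_win_prob(1, 2, scale = 0), "scale")
})

test_that("single updates transfer k*(1-p) and conserve rating mass", {
  st <- elo_state(c("A", "B"), r0 = 1000, k = 100, scale = 400)
  st1 <- elo_update(st, "A", "B")
  expect_equal(unname(st1$ratings), c(1050, 950))
  # expected win from +scale edge: winner gains k/11
  st2 <- elo_state(c("W", "L"), r0 = 1000, k = 100)
  st2$ratings[] <- c(1400, 1000)
  up <- elo_update(st2, "W", "L")
  expect_equal(up$ratings[["W"]], 1400 + 100 / 11)
  # upset gains k*10/11
  down <- elo_update(st2, "L", "W")
  expect_equal(down$ratings[["L"]], 1000 + 1000 / 11)
  expect_equal(sum(down$ratings), sum(st2$ratings))
  expect_error(elo_update(st, "A", "A"), "actor == reactor")
})

test_that("sequence runs: entries at prior, two-step hand value, conservation", {
  ev0 <- data.frame(actor_id = character(0), reactor_id = character(0))
  expect_equal(unname(elo_run(ev0, roster = c("A", "B"))$ratings), c(1000, 1000))

  ev <- data.frame(actor_id = c("A", "A"), reactor_id = c("B", "B"))
  st <- elo_run(ev, r0 = 1000, k = 100, scale = 400)
  # hand-rolled: 1000 -> 1050; then p = 1/(1+10^-0.25), gain 100*(1-p)
  p2 <- 1 / (1 + 10^(-100 / 400))
  expect_equal(st$ratings[["A"]], 1050 + 100 * (1 - p2), tolerance = 1e-12)
  expect_equal(st$ratings[["A"]], 1085.99, tolerance = 1e-4)
  expect_equal(sum(st$ratings), 2000)

  # newcomers start at r0 while incumbents keep accumulated ratings
  ev2 <- rbind(ev, data.frame(actor_id = "C", reactor_id = "B"))
  st2 <- elo_run(ev2)
  expect_equal(sum(st2$ratings), 3000)  # conservation incl. entry mass
  expect_error(elo_run(data.frame(actor_id = c("A", "B"),
                                  reactor_id = c("B", "A"),
                                  time = base_ts + c(20, 10))),
               "sorted")
})

test_that("conservation holds over long random sequences (property)", {
  for (seed in 1:4) {
    ev <- random_events(n = 200, n_cows = 10, seed = seed)
    st <- elo_run(ev, r0 = 1000)
    expect_equal(sum(st$ratings), 1000 * length(st$ratings), tolerance = 1e-9)
  }
})

test_that("summed winning probabilities: closed forms, totals, brute force", {
  st <- elo_state(c("a", "b", "c", "d"))
  expect_equal(unname(summed_winning_prob(st)), rep(1.5, 4))

  st2 <- elo_state(c("hi", "lo"))
  st2$ratings[] <- c(1100, 900)
  S <- summed_winning_prob(st2)
  expect_equal(unname(S), c(0.7597, 0.2403), tolerance = 1e-4)

  for (seed in 1:3) {
    n <- 50
    st3 <- elo_state(sprintf("c%02d", 1:n))
    set.seed(seed)
    st3$ratings[] <- runif(n, 700, 1300)
    S3 <- summed_winning_prob(st3)
    expect_equal(S3, oracle_S(st3$ratings, 400), tolerance = 1e-9)
    expect_equal(sum(S3), n * (n - 1) / 2, tolerance = 1e-9)
  }
  expect_error(summed_winning_prob(elo_state("only")), "at least 2")
})

test_that("steepness: ladder, egalitarian, OLS value, bounds", {
  expect_equal(steepness(c(2, 1, 0)), 1)
  expect_equal(steepness(rep(3.5, 8)), 0)
  expect_equal(steepness(c(1.9, 1.0, 0.1)), 0.9)
  expect_error(steepness(1), "at least 2")
  # clipped to [0, 1] even for super-despotic synthetic scores
  expect_equal(steepness(c(10, 5, 0)), 1)
  for (seed in 1:10) {
    set.seed(seed)
    s <- steepness(runif(sample(2:40, 1), 0, 39))
    expect_gte(s, 0); expect_lte(s, 1)
  }
})

test_that("resampling summaries: determinism, dyad symmetry and separation", {
  one_sided <- data.frame(actor_id = rep("A", 20), reactor_id = rep("B", 20),
                          time = base_ts + 1:20 * 60)
  s1 <- elo_summary(one_sided, n_rep = 100, seed = 5)
  s2 <- elo_summary(one_sided, n_rep = 100, seed = 5)
  expect_identical(s1$animals, s2$animals)
  expect_identical(s1$steepness, s2$steepness)
  A <- s1$animals[s1$animals$animal_id == "A", ]
  B <- s1$animals[s1$animals$animal_id == "B", ]
  expect_gt(A$S_mean, B$S_mean)
  expect_lt(A$S_sd, 0.05)  # order permutations cannot change a 20-0 dyad much
  expect_equal(A$rank, 1L)

  # balanced dyad: A and B each win 10; mean S gap below MC noise bound
  bal <- data.frame(actor_id = rep(c("A", "B"), 10),
                    reactor_id = rep(c("B", "A"), 10),
                    time = base_ts + 1:20 * 60)
  n_rep <- 400
  sb <- elo_summary(bal, n_rep = n_rep, seed = 7)
  gap <- abs(diff(sb$animals$S_mean))
  bound <- 3 * max(sb$animals$S_sd) / sqrt(n_rep)
  expect_lt(gap, max(bound, 0.05))

  sboot <- elo_summary(bal, n_rep = 50, mode = "bootstrap", seed = 1)
  expect_s3_class(sboot, "dominance_summary")
  expect_error(elo_summary(bal, n_rep = 1), "n_rep")
})
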