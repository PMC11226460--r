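test_that("pcp and cpcp follow their definitions", {
  p <- paired_sequence(c(0, 1, 2, 0), c(0, 2, 2, 1))
  expect_equal(pcp(p), 0.5)
  expect_equal(cpcp(p), c(1, 0.5, 2 / 3, 0.5))
  same <- paired_sequence(c(0, 1, 2), c(0, 1, 2))
  expect_equal(pcp(same), 1)
  expect_true(all(cpcp(same) == 1))
  disjoint <- paired_sequence(rep(0, 5), rep(1, 5))
  expect_equal(pcp(disjoint), 0)
  # CPCP at n equals the overall PCP
  pr <- simulate_pair(kicker_model(3), 100, seed = 1)
  expect_equal(cpcp(pr)[pr$n], pcp(pr))
  expect_equal(pcp(pr, 11:20), mean(pr$x[11:20] == pr$y[11:20]))
  expect_error(pcp(p, integer(0)), "empty")
})

test_that("sliding windows reproduce the session geometry", {
  w <- sliding_windows(1000)
  expect_identical(nrow(w), 6L)
  expect_identical(w$start, as.integer(c(1, 151, 301, 451, 601, 751)))
  expect_identical(w$end[6L], 1000L)
  expect_identical(nrow(sliding_windows(250)), 1L)
  w2 <- sliding_windows(400)
  expect_identical(nrow(w2), 2L)
  expect_identical(w2$end, c(250L, 400L))
  expect_error(sliding_windows(100), "smaller")
})

test_that("normalization and logit transform behave at the boundaries", {
  expect_equal(normalize_and_logit(0.4, 0.8), 0)        # ratio 0.5 -> 0
  # at the theoretical ceiling the ratio clips to 1 - eps
  expect_equal(normalize_and_logit(0.8, 0.8), qlogis(1 - 1e-3))
  expect_equal(normalize_and_logit(0.9, 0.8), qlogis(1 - 1e-3))
  # monotone in the score
  z <- normalize_and_logit(seq(0.1, 0.7, by = 0.1), 0.8)
  expect_true(all(diff(z) > 0))
  expect_error(normalize_and_logit(0.5, 0), "max_score")
})

test_that("slope-based exclusion flags deteriorating participants", {
  up <- exclude_by_slope(c(0, 0.1, 0.2, 0.3, 0.4, 0.5))
  expect_true(up$keep)
  expect_equal(up$slope, 0.1, tolerance = 1e-12)
  down <- exclude_by_slope(c(0.5, 0.4, 0.3, 0.2, 0.1, 0))
  expect_false(down$keep)
  flat <- exclude_by_slope(rep(0.3, 6))
  expect_true(flat$keep)                     # zero slope is not negative
  expect_equal(flat$slope, 0, tolerance = 1e-12)
  expect_error(exclude_by_slope(0.1), "two windows")
})

test_that("the simulated benchmark matches the analytic scores", {
  m3 <- kicker_model(3)
  b <- build_benchmark(m3, n_sequences = 2000, length = 250, seed = 17)
  se <- stats::sd(b$matching) / sqrt(b$n_sequences)
  expect_lt(abs(mean(b$matching) - matching_score(m3)), 3 * se)
  se2 <- stats::sd(b$maximizing) / sqrt(b$n_sequences)
  expect_lt(abs(mean(b$maximizing) - maximizing_score(m3)), 3 * se2)
  # maximizing density sits to the right of the matching density
  expect_gt(mean(b$maximizing), mean(b$matching))
  # densities integrate to ~1 on the evaluation grid
  int_m <- sum(b$dens_matching$y) * diff(b$dens_matching$x[1:2])
  expect_lt(abs(int_m - 1), 1e-3)
  int_x <- sum(b$dens_maximizing$y) * diff(b$dens_maximizing$x[1:2])
  expect_lt(abs(int_x - 1), 1e-3)
  # cutoff sits below the matching median; deterministic given the seed
  expect_lt(b$cutoff, stats::median(b$matching))
  b2 <- build_benchmark(m3, n_sequences = 2000, length = 250, seed = 17)
  expect_identical(b$matching, b2$matching)
  expect_identical(b$cutoff, b2$cutoff)
})

test_that("classification partitions scores into exactly one label", {
  b <- build_benchmark(kicker_model(3), n_sequences = 2000, length = 250,
                       seed = 19)
  grid <- seq(0, 1, by = 0.01)
  labels <- classify_strategy(grid, b)
  expect_false(anyNA(labels))
  expect_identical(levels(labels), c("suboptimal", "matching", "maximizing"))
  # anchor points
  expect_identical(as.character(classify_strategy(0, b)), "suboptimal")
  expect_identical(as.character(classify_strategy(mean(b$maximizing), b)),
                   "maximizing")
  expect_identical(as.character(classify_strategy(mean(b$matching), b)),
                   "matching")
  # simulated matching agents are rarely called suboptimal
  m3 <- kicker_model(3)
  set.seed(29)
  scores <- replicate(200, {
    x <- simulate_chain(m3, 250)
    mean(respond(m3, x, kind = "matching") == x)
  })
  lab <- classify_strategy(scores, b)
  expect_gte(mean(lab != "suboptimal"), 0.8)
})

test_that("maximizing agents outscore uniform agents on windows", {
  set.seed(37)
  for (mdl in list(kicker_model(1), kicker_model(3))) {
    d <- numeric(10)
    for (r in 1:10) {
      x <- simulate_chain(mdl, 250)
      d[r] <- mean(respond(mdl, x, kind = "maximizing") == x) -
        mean(respond(mdl, x, kind = "uniform") == x)
    }
    expect_gt(mean(d), 0)
  }
})
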