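test_that("count tables match hand enumeration", {
  p <- paired_sequence(c(0, 1, 2, 0, 1), c(1, 2, 0, 1, 2))
  ct <- count_tables(p, L = 1)
  expect_identical(ct$N_xy["0", "2"], 2L)
  expect_identical(ct$N_xy["1", "0"], 1L)
  expect_identical(ct$N_xy["2", "1"], 1L)
  expect_identical(sum(ct$N_xy[c("0", "1", "2"), ]), 4L)
  expect_identical(unname(ct$N_x[match("0", rownames(ct$N_xy))]), 2L)
  # root row collects every response
  expect_identical(unname(ct$N_x[match("", rownames(ct$N_xy))]), 5L)
  # constant sequences
  pc <- paired_sequence(rep(0, 10), rep(1, 10))
  expect_identical(count_tables(pc, 1)$N_xy["0", "1"], 9L)
  # denominator identity N^X(u) = sum_a N^XY(u, a) holds by construction
  pr <- simulate_pair(kicker_model(3), 400, seed = 2)
  ct2 <- count_tables(pr, 3)
  expect_true(all(ct2$N_x == rowSums(ct2$N_xy)))
})

test_that("qhat, df and node log-likelihood follow their definitions", {
  p <- paired_sequence(c(0, 1, 2, 0, 1), c(1, 2, 0, 1, 2))
  ct <- count_tables(p, L = 1)
  expect_equal(qhat(ct, "0", "2"), 1)
  expect_equal(sum(qhat(ct, "1")), 1)
  expect_error(qhat(ct, "00"), "undefined context")
  expect_identical(df_node(ct, "0"), 0L)     # only response 2 observed
  expect_identical(df_node(ct, ""), 2L)      # all three responses observed
  expect_identical(df_tree(ct, context_tree(c("0", "1", "2"))), 0L)
  # deterministic context: perfect fit, log-likelihood 0
  expect_equal(node_loglik(ct, "0"), 0)
  # counts (1,1) over two symbols: 2 log(1/2)
  p2 <- paired_sequence(c(0, 0, 0), c(1, 2, 1))
  ct2 <- count_tables(p2, L = 1)
  expect_equal(node_loglik(ct2, "0"), 2 * log(0.5))
  # likelihood additivity: tree log-likelihood = sum over contexts
  pr <- simulate_pair(kicker_model(3), 500, seed = 4)
  ct3 <- count_tables(pr, 2)
  tr <- admissible_tree(pr$x, 2)
  ll_tree <- sum(vapply(tr$contexts, node_loglik, numeric(1), counts = ct3))
  # recompute from per-trial plug-in probabilities as an independent check
  n <- pr$n
  ll_direct <- 0
  for (t in 1:(n - 1L)) {
    w <- context_of(tr, pr$x[1:t])
    if (is.na(w)) next                       # past still shorter than any leaf
    ll_direct <- ll_direct + log(qhat(ct3, w, pr$y[t + 1L]))
  }
  expect_equal(ll_tree, ll_direct, tolerance = 1e-8)
})

test_that("bic_prune collapses to the root under a huge penalty", {
  pr <- simulate_pair(kicker_model(3), 300, kind = "matching", seed = 5)
  expect_identical(bic_prune(pr, L = 4, c = 1e6)$contexts, "")
  # c = 0 keeps the likelihood-maximal admissible tree (all depth-L leaves)
  t0 <- bic_prune(pr, L = 2, c = 0)
  expect_true(all(nchar(t0$contexts) >= 1L))
})

test_that("bic_prune equals the exhaustive oracle on small instances", {
  set.seed(6)
  for (r in 1:40) {
    mdl <- kicker_model(sample(1:4, 1))
    pr <- simulate_pair(mdl, sample(100:400, 1),
                        kind = sample(c("matching", "uniform", "maximizing"),
                                      1))
    for (cc in c(0, 0.1, 0.5, 1, 5)) {
      a <- bic_prune(pr, 2, cc)
      b <- exhaustive_bic(pr, 2, cc)
      expect_true(tree_equal(a, b),
                  label = sprintf("prune == oracle (c = %g)", cc))
    }
  }
  expect_error(exhaustive_bic(simulate_pair(kicker_model(3), 100, seed = 1),
                              L = 3, c = 1), "too large")
})

test_that("larger penalties never yield larger models", {
  pr <- simulate_pair(kicker_model(3), 800, kind = "matching", seed = 8)
  ct <- count_tables(pr, 4)
  grid <- c(0.05, 0.1, 0.3, 0.5, 1, 2, 4)
  dfs <- vapply(grid, function(cc) {
    df_tree(ct, bic_prune(ct, L = 4, c = cc))
  }, integer(1))
  expect_true(all(diff(dfs) <= 0L))
})

test_that("penalty tuning recovers the generating tree and the null", {
  # matching data from model 3: tuned fit recovers tau3
  pr <- simulate_pair(kicker_model(3), 1000, kind = "matching", seed = 12)
  f <- fit_driven_tree(pr, L = 4)
  expect_true(tree_equal(f$tree, tau3()))
  expect_equal(unname(f$q["21", ]), c(0.25, 0.75, 0), tolerance = 0.12)
  # a response independent of the stimulus: root-only tree
  pru <- simulate_pair(kicker_model(3), 1000, kind = "uniform", seed = 12)
  expect_identical(fit_driven_tree(pru, L = 4)$tree$contexts, "")
  # risk trace has one value per grid point and the fit is deterministic
  sel <- select_penalty(pr, L = 4)
  expect_identical(nrow(sel$trace), 40L)
  expect_identical(sel$c, select_penalty(pr, L = 4)$c)
})

test_that("a windowed fit runs end-to-end quickly", {
  pr <- simulate_pair(kicker_model(3), 250, kind = "matching", seed = 3)
  elapsed <- system.time(f <- fit_driven_tree(pr, L = 4))[["elapsed"]]
  expect_s3_class(f$tree, "context_tree")
  expect_lt(elapsed, 10)
})
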