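test_that("markov embedding has the right states and structure", {
  emb <- markov_embedding(kicker_model(3))
  # forward-reachability: 8 recurrent length-2 pasts ("22" never occurs)
  expect_setequal(emb$states,
                  c("00", "10", "20", "01", "11", "21", "02", "12"))
  expect_equal(unname(rowSums(emb$M)), rep(1, 8), tolerance = 1e-10)
  expect_equal(as.vector(emb$mu %*% emb$M), emb$mu, tolerance = 1e-8)
  # overlap constraint: transitions only shift the window by one symbol
  for (i in seq_along(emb$states)) {
    for (j in seq_along(emb$states)) {
      if (emb$M[i, j] > 0) {
        expect_identical(substr(emb$states[j], 1, 1),
                         substr(emb$states[i], 2, 2))
      }
    }
  }
  # a third of the stationary mass sits on pasts ending in 2
  ends2 <- substr(emb$states, 2, 2) == "2"
  expect_equal(sum(emb$mu[ends2]), 1 / 3, tolerance = 1e-8)
  # deterministic cycle embeds as a permutation matrix
  Mc <- markov_embedding(cycle_model())$M
  expect_true(all(Mc %in% c(0, 1)) && all(rowSums(Mc) == 1) &&
                all(colSums(Mc) == 1))
})

test_that("stationary_distribution solves mu M = mu", {
  M2 <- rbind(c(0, 1), c(1, 0))
  expect_equal(stationary_distribution(M2), c(0.5, 0.5))
  Mu <- matrix(1 / 3, 3, 3)
  expect_equal(stationary_distribution(Mu), rep(1 / 3, 3))
  expect_error(stationary_distribution(diag(2)), "reducible")
  expect_error(stationary_distribution(rbind(c(0.5, 0.6), c(0.5, 0.5))),
               "stochastic")
})

test_that("entropy rates reproduce the reference values", {
  # the 211-block model: exact value 2 H2(0.25) / 3
  h2 <- function(p) -p * log2(p) - (1 - p) * log2(1 - p)
  expect_equal(entropy_rate(kicker_model(3)), 2 * h2(0.25) / 3,
               tolerance = 1e-10)
  expect_equal(round(entropy_rate(kicker_model(3)), 2), 0.54)
  expect_equal(round(entropy_rate(kicker_model(1)), 2), 0.65)
  expect_equal(round(entropy_rate(kicker_model(2)), 2), 0.81)
  # iid uniform and deterministic extremes
  expect_equal(entropy_rate(iid_model()), log2(3), tolerance = 1e-10)
  expect_equal(entropy_rate(cycle_model()), 0, tolerance = 1e-12)
})

test_that("entropy rate is invariant under relabeling and embedding order", {
  set.seed(21)
  for (r in 1:10) {
    mdl <- random_model(L = 2)
    h <- entropy_rate(mdl)
    # relabel symbols 0<->2 jointly in contexts and distributions
    relabel <- c("0" = "2", "1" = "1", "2" = "0")
    swap2 <- function(w) paste(relabel[strsplit(w, "")[[1]]], collapse = "")
    ctx2 <- vapply(mdl$tree$contexts, swap2, character(1))
    probs2 <- mdl$probs[, c(3, 2, 1), drop = FALSE]
    rownames(probs2) <- ctx2
    mdl2 <- context_tree_model(context_tree(ctx2), probs2)
    expect_equal(entropy_rate(mdl2), h, tolerance = 1e-9)
    # embedding at one order deeper gives the same rate
    expect_equal(entropy_rate(markov_embedding(mdl, L = mdl$tree$height + 1L)),
                 h, tolerance = 1e-9)
  }
})

test_that("matching and maximizing scores evaluate the known cases", {
  m <- iid_model(c(0.25, 0.75, 0))
  expect_equal(matching_score(m), 0.25^2 + 0.75^2)
  expect_equal(maximizing_score(m), 0.75)
  expect_equal(matching_score(cycle_model()), 1)
  expect_equal(maximizing_score(cycle_model()), 1)
  expect_equal(maximizing_score(iid_model()), 1 / 3, tolerance = 1e-12)
  # model 3: deterministic contexts carry 1/3 of the mass
  expect_equal(matching_score(kicker_model(3)), 1 / 3 + 2 / 3 * 0.625,
               tolerance = 1e-9)
  expect_equal(maximizing_score(kicker_model(3)), 1 / 3 + 2 / 3 * 0.75,
               tolerance = 1e-9)
})

test_that("matching_score <= maximizing_score on random models", {
  set.seed(31)
  for (r in 1:100) {
    mdl <- random_model(L = 2)
    expect_lte(matching_score(mdl), maximizing_score(mdl) + 1e-12)
  }
})

test_that("long-run context frequencies agree with the stationary law", {
  m3 <- kicker_model(3)
  emb <- markov_embedding(m3)
  x <- simulate_chain(m3, 30000, seed = 23)
  n <- length(x)
  pasts <- paste0(x[1:(n - 1L)], x[2:n])
  freq <- table(factor(pasts, levels = emb$states)) / (n - 1L)
  for (s in seq_along(emb$states)) {
    sigma <- sqrt(emb$mu[s] * (1 - emb$mu[s]) / (n - 1L))
    # 3 sigma with a small dependence allowance (adjacent pasts overlap)
    expect_lt(abs(freq[[s]] - emb$mu[s]), 3 * sigma + 0.005)
  }
})
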