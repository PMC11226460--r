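test_that("simulate_chain is deterministic given a seed", {
  m <- kicker_model(3)
  a <- simulate_chain(m, 200, seed = 42)
  b <- simulate_chain(m, 200, seed = 42)
  expect_identical(a, b)
  expect_false(identical(a, simulate_chain(m, 200, seed = 43)))
  # seeded calls do not perturb the session RNG stream
  set.seed(1); r1 <- runif(1)
  set.seed(1); invisible(simulate_chain(m, 50, seed = 5)); r2 <- runif(1)
  expect_identical(r1, r2)
})

test_that("a deterministic cycle model produces the cycle", {
  x <- simulate_chain(cycle_model(), 9, seed = 1, burn_in = 100)
  # whatever the phase, consecutive symbols follow 0->1->2->0
  codes <- as.integer(x)
  expect_true(all(diff(codes) %in% c(1L, -2L)))
  ip <- attr(x, "init_past")
  expect_length(ip, 1L)
  expect_identical(context_of(cycle_model()$tree, ip), ip)
})

test_that("model-3 chains reproduce the stochastic slot probability", {
  m3 <- kicker_model(3)
  x <- simulate_chain(m3, 30000, seed = 7)
  # after a 2 the next symbol is 0 with probability 0.25
  after2 <- x[which(x[-length(x)] == "2") + 1L]
  phat <- mean(after2 == "0")
  sigma <- sqrt(0.25 * 0.75 / length(after2))
  expect_lt(abs(phat - 0.25), 3 * sigma)
  # stationary frequency of symbol 2 is 1/3 (one slot in each 211 block)
  expect_lt(abs(mean(x == "2") - 1 / 3), 0.01)
})

test_that("agents implement their strategy definitions", {
  m3 <- kicker_model(3)
  x <- simulate_chain(m3, 500, seed = 3)
  # maximizing after a past ending 2,1: argmax of (0.25, 0.75, 0) is 1
  y <- respond(m3, x, kind = "maximizing")
  n <- length(x)
  at21 <- which(x[1:(n - 2L)] == "2" & x[2:(n - 1L)] == "1") + 1L
  expect_true(all(y[at21 + 1L] == "1"))
  # constant agent answers the fixed symbol everywhere
  expect_identical(respond(m3, x, kind = "constant", symbol = "2"),
                   rep("2", length(x)))
  # uniform agent hits each symbol about equally often
  yu <- respond(m3, x, kind = "uniform", seed = 8)
  expect_true(max(abs(table(factor(yu, c("0", "1", "2"))) / 500 - 1 / 3))
              < 0.07)
  expect_error(respond(m3, x, kind = "constant"), "symbol")
})

test_that("maximizing responses follow the conditional mode everywhere", {
  m3 <- kicker_model(3)
  x <- simulate_chain(m3, 2000, seed = 11)
  y <- respond(m3, x, kind = "maximizing")
  lut_mode <- apply(m3$probs, 1L, which.max)
  ip <- attr(x, "init_past")
  for (t in seq(1L, 2000L, by = 97L)) {
    past <- c(ip, x[seq_len(t - 1L)])
    w <- context_of(m3$tree, past)
    expect_identical(y[t], m3$tree$alphabet[lut_mode[[match(w,
      rownames(m3$probs))]]])
  }
})

test_that("matching responses reproduce the context distributions", {
  m3 <- kicker_model(3)
  x <- simulate_chain(m3, 30000, seed = 13)
  y <- respond(m3, x, kind = "matching", seed = 14)
  # responses following a past ending in "21" sample (0.25, 0.75, 0)
  n <- length(x)
  at <- which(x[1:(n - 2L)] == "2" & x[2:(n - 1L)] == "1") + 1L
  resp <- y[at + 1L]
  phat <- mean(resp == "0")
  sigma <- sqrt(0.25 * 0.75 / length(resp))
  expect_lt(abs(phat - 0.25), 3 * sigma)
  expect_equal(mean(resp == "2"), 0)
  # matching responses and a fresh chain share per-context distributions
  x2 <- simulate_chain(m3, 30000, seed = 15)
  p_resp <- mean(y == "2")
  p_chain <- mean(x2 == "2")
  expect_lt(abs(p_resp - p_chain), 0.01)
})

test_that("respond falls back to uniform draws without an initial past", {
  m <- cycle_model()
  x <- as.character(c(0, 1, 2, 0, 1, 2))
  attr(x, "init_past") <- NULL
  set.seed(2)
  first <- replicate(300, respond(m, x)[1L])
  tab <- table(factor(first, c("0", "1", "2"))) / 300
  expect_true(max(abs(tab - 1 / 3)) < 0.09)
  # with a declared past the first response is determined by the cycle
  expect_identical(respond(m, x, kind = "maximizing", init_past = "2")[1L],
                   "0")
})
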