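# Performance scoring and strategy classification: proportion of correct
# predictions, sliding windows, normalization/logit, slope-based exclusion,
# and the simulated kernel-density benchmark of matching vs maximizing.

#' Proportion of correct predictions
#'
#' The fraction of trials in `trials` where the response equals the
#' stimulus symbol; with the default `trials = NULL` the whole sequence is
#' scored.
#'
#' @param pair A [paired_sequence()].
#' @param trials Integer vector of trial indices (non-empty subset of
#'   1..n), or `NULL` for all trials.
#' @return A proportion in \[0, 1\].
#' @export
pcp <- function(pair, trials = NULL) {
  stopifnot(inherits(pair, "paired_sequence"))
  trials <- trials %||% seq_len(pair$n)
  if (length(trials) == 0L) stop("empty trial set", call. = FALSE)
  if (any(trials < 1L | trials > pair$n)) {
    stop("trial indices out of range", call. = FALSE)
  }
  mean(pair$x[trials] == pair$y[trials])
}

#' Cumulative proportion of correct predictions
#'
#' `cpcp(pair)[t]` is the proportion of correct predictions over trials
#' 1..t — the running performance curve.
#'
#' @inheritParams pcp
#' @return Numeric vector of length n.
#' @export
cpcp <- function(pair) {
  stopifnot(inherits(pair, "paired_sequence"))
  cumsum(pair$x == pair$y) / seq_len(pair$n)
}

#' Sliding trial windows
#'
#' Maximal list of windows `[1 + k*step, length + k*step]` fitting in `n`
#' trials. With the defaults (length 250, step 150) a 1000-trial session
#' yields six windows, the last one covering trials 751–1000.
#'
#' @param n Number of trials.
#' @param length Window length, default 250.
#' @param step Step between window starts, default 150.
#' @return Data frame with columns `window`, `start`, `end`.
#' @examples
#' sliding_windows(1000)
#' @export
sliding_windows <- function(n, length = 250L, step = 150L) {
  if (n < length) stop("n is smaller than one window", call. = FALSE)
  starts <- as.integer(seq(1L, n - length + 1L, by = step))
  data.frame(window = seq_along(starts), start = starts,
             end = starts + as.integer(length) - 1L)
}

#' Normalized, logit-transformed score
#'
#' Divides a proportion of correct predictions by the theoretical
#' maximizing score of the stimulus model (so performance is comparable
#' across models), clips the ratio to `[eps, 1 - eps]`, and applies the
#' logit. Clipping absorbs lucky windows whose raw score exceeds the
#' theoretical ceiling.
#'
#' @param pcp Proportion(s) of correct predictions.
#' @param max_score Theoretical maximizing score, in (0, 1].
#' @param eps Clipping margin, default 1e-3.
#' @return Logit-scale score(s).
#' @export
normalize_and_logit <- function(pcp, max_score, eps = 1e-3) {
  if (max_score <= 0 || max_score > 1) {
    stop("max_score must be in (0, 1]", call. = FALSE)
  }
  r <- pmin(pmax(pcp / max_score, eps), 1 - eps)
  stats::qlogis(r)
}

#' Participant exclusion by learning slope
#'
#' Fits an ordinary least-squares line to a participant's logit scores as
#' a function of window index and flags participants with a negative slope
#' for exclusion (a proxy for non-compliance: performance should not
#' deteriorate across a session).
#'
#' @param z Numeric vector of logit scores, one per window (>= 2 windows).
#' @param windows Window indices; defaults to `seq_along(z)`.
#' @return List with `keep` (logical; `TRUE` when slope >= 0), `slope`,
#'   `intercept`.
#' @export
exclude_by_slope <- function(z, windows = seq_along(z)) {
  if (length(z) < 2L) stop("need at least two windows", call. = FALSE)
  fit <- stats::lm.fit(cbind(1, windows), z)
  slope <- unname(fit$coefficients[2L])
  list(keep = slope >= 0, slope = slope,
       intercept = unname(fit$coefficients[1L]))
}

#' Simulated strategy benchmark for a stimulus model
#'
#' Builds the reference distributions against which a participant's
#' proportion of correct predictions is classified: `n_sequences` stimulus
#' chains of `length` trials are simulated from the model, a fully
#' informed matching and a fully informed maximizing responder answer each
#' chain, and Gaussian kernel density estimates (Silverman bandwidth) are
#' formed from the two samples of per-sequence scores. The suboptimal
#' cutoff is the `q_cutoff` quantile of the matching sample — the
#' anticipated lower bound of performance for a responder who has at least
#' learned the model.
#'
#' @param model A [context_tree_model()].
#' @param n_sequences Number of simulated sequences, default 10000.
#' @param length Trials per sequence, default 250 (one analysis window).
#' @param seed Optional integer seed.
#' @param q_cutoff Quantile of the matching sample used as the suboptimal
#'   cutoff, default 0.005.
#' @return An object of class `strategy_benchmark`: list with `matching`
#'   and `maximizing` (score samples), `dens_matching`, `dens_maximizing`
#'   (`stats::density` objects on a common grid), `cutoff`, `model_name`,
#'   `n_sequences`, `length`.
#' @export
build_benchmark <- function(model, n_sequences = 10000L, length = 250L,
                            seed = NULL, q_cutoff = 0.005) {
  stopifnot(inherits(model, "context_tree_model"))
  with_seed(seed, {
    alpha <- model$tree$alphabet
    m <- base::length(alpha)
    sim <- simulate_chains_coded(model, n_sequences, length)
    h <- model$tree$height
    lut <- context_lookup(model$tree)
    # contexts per position for every chain (the responder sees init past)
    ctx <- matrix(1L, n_sequences, length)
    if (h > 0L) {
      z <- cbind(sim$init, sim$x)
      mpow <- m^(0:(h - 1L))
      for (t in seq_len(length)) {
        acc <- numeric(n_sequences)
        for (j in 0:(h - 1L)) {
          acc <- acc + (z[, t + h - 1L - j] - 1L) * mpow[j + 1L]
        }
        ctx[, t] <- lut[as.integer(acc + 1L)]
      }
    }
    cp <- t(apply(model$probs, 1L, cumsum)); cp[, m] <- 1
    u <- matrix(stats::runif(n_sequences * length), n_sequences, length)
    mode_of <- apply(model$probs, 1L, which.max)
    match_hits <- matrix(0L, n_sequences, length)
    maxim_hits <- matrix(0L, n_sequences, length)
    for (t in seq_len(length)) {
      y_match <- 1L + as.integer(rowSums(u[, t] > cp[ctx[, t], ,
                                                     drop = FALSE]))
      match_hits[, t] <- y_match == sim$x[, t]
      maxim_hits[, t] <- mode_of[ctx[, t]] == sim$x[, t]
    }
    pcp_match <- rowMeans(match_hits)
    pcp_maxim <- rowMeans(maxim_hits)
    grid <- c(-0.1, 1.1)
    structure(
      list(matching = pcp_match, maximizing = pcp_maxim,
           dens_matching = stats::density(pcp_match, from = grid[1L],
                                          to = grid[2L], n = 1024L),
           dens_maximizing = stats::density(pcp_maxim, from = grid[1L],
                                            to = grid[2L], n = 1024L),
           cutoff = unname(stats::quantile(pcp_match, q_cutoff)),
           model_name = attr(model, "name") %||% "custom",
           fingerprint = model_fingerprint(model),
           n_sequences = n_sequences, length = length),
      class = "strategy_benchmark"
    )
  })
}

#' @export
print.strategy_benchmark <- function(x, ...) {
  cat("Strategy benchmark for ", x$model_name, " (",
      x$n_sequences, " x ", x$length, " trials)\n", sep = "")
  cat(sprintf("  matching   mean %.3f\n", mean(x$matching)))
  cat(sprintf("  maximizing mean %.3f\n", mean(x$maximizing)))
  cat(sprintf("  suboptimal cutoff %.3f\n", x$cutoff))
  invisible(x)
}

#' Classify a score against a strategy benchmark
#'
#' A proportion of correct predictions below the benchmark's suboptimal
#' cutoff is labelled `suboptimal`; otherwise the label is the strategy
#' whose kernel density is higher at the observed score, with ties (and
#' scores outside both density supports) going to `matching`, the more
#' conservative label.
#'
#' @param pcp Numeric vector of scores.
#' @param benchmark A [build_benchmark()] object.
#' @return Factor with levels `suboptimal`, `matching`, `maximizing`.
#' @export
classify_strategy <- function(pcp, benchmark) {
  stopifnot(inherits(benchmark, "strategy_benchmark"))
  d_match <- stats::approx(benchmark$dens_matching$x,
                           benchmark$dens_matching$y, xout = pcp,
                           yleft = 0, yright = 0)$y
  d_maxim <- stats::approx(benchmark$dens_maximizing$x,
                           benchmark$dens_maximizing$y, xout = pcp,
                           yleft = 0, yright = 0)$y
  label <- ifelse(pcp < benchmark$cutoff, "suboptimal",
                  ifelse(d_maxim > d_match, "maximizing", "matching"))
  factor(label, levels = c("suboptimal", "matching", "maximizing"))
}
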