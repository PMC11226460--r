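# Markov embedding, stationary distribution, entropy rate and the
# theoretical matching / maximizing scores of a context tree model.

#' First-order Markov embedding of a context tree model
#'
#' Rewrites the variable-length chain as a first-order Markov chain on the
#' state space of length-`L` pasts with positive stationary probability
#' (`L` defaults to the tree height; root-only models use `L = 1`). The
#' transition matrix moves from a past to the past obtained by appending
#' the next symbol, drawn from the distribution of the context of the
#' current past. States that are merely transient (reachable only from
#' special starting pasts) carry no stationary mass and are excluded.
#'
#' @param model A [context_tree_model()].
#' @param L Embedding order; must be at least the tree height (and >= 1).
#' @return An object of class `markov_embedding`: list with `states`
#'   (character, oldest-first strings), `M` (row-stochastic transition
#'   matrix), `mu` (stationary distribution), `L`, and `context` (the
#'   context of each state).
#' @examples
#' emb <- markov_embedding(kicker_model(3))
#' emb$states
#' @export
markov_embedding <- function(model, L = NULL) {
  stopifnot(inherits(model, "context_tree_model"))
  check_complete(model)
  tree <- model$tree
  m <- length(tree$alphabet)
  h <- tree$height
  L <- as.integer(L %||% max(h, 1L))
  if (L < max(h, 1L)) {
    stop("embedding order L must be at least the tree height (min 1)",
         call. = FALSE)
  }
  states_all <- all_strings(tree$alphabet, L)
  lut <- context_lookup(tree, L)
  n_s <- length(states_all)
  M <- matrix(0, n_s, n_s, dimnames = list(states_all, states_all))
  mpow <- m^(L - 1L)
  for (i in seq_len(n_s)) {
    ci <- lut[i]
    if (is.na(ci)) next                # pasts without context cannot recur
    p <- model$probs[ci, ]
    for (a in seq_len(m)) {
      if (p[a] == 0) next
      j <- ((i - 1L) %% mpow) * m + (a - 1L) + 1L
      M[i, j] <- M[i, j] + p[a]
    }
  }
  # recurrent support: states inside closed communicating classes
  reach <- (M > 0) | diag(TRUE, n_s)
  for (k in seq_len(ceiling(log2(n_s)) + 1L)) {
    reach <- (reach %*% reach) > 0
  }
  closed <- vapply(seq_len(n_s), function(i) {
    to <- which(reach[i, ])
    all(reach[to, i])                  # everything i reaches, reaches back
  }, logical(1))
  closed <- closed & !is.na(lut) & rowSums(M) > 0
  if (!any(closed)) stop("model has no recurrent state", call. = FALSE)
  # distinct closed classes -> no unique stationary distribution
  rep_state <- which(closed)[1L]
  if (!all(reach[rep_state, closed])) {
    classes <- unique(apply(reach[closed, closed, drop = FALSE], 1L,
                            paste, collapse = ""))
    stop("reducible chain: ", length(classes),
         " closed communicating classes; stationary distribution not unique",
         call. = FALSE)
  }
  keep <- which(closed)
  M <- M[keep, keep, drop = FALSE]
  M <- M / rowSums(M)
  mu <- stationary_distribution(M)
  structure(
    list(states = states_all[keep], M = M, mu = mu, L = L,
         context = tree$contexts[lut[keep]], model = model),
    class = "markov_embedding"
  )
}

#' @export
print.markov_embedding <- function(x, ...) {
  cat("Markov embedding: ", length(x$states), " states of length ", x$L,
      "\n", sep = "")
  print(round(stats::setNames(x$mu, x$states), 4))
  invisible(x)
}

#' Stationary distribution of a row-stochastic matrix
#'
#' The normalized non-negative left eigenvector of `M` for eigenvalue 1,
#' i.e. the solution of \eqn{\mu M = \mu}, \eqn{\sum_i \mu_i = 1}. Uses the
#' eigendecomposition of \eqn{M^T} with a linear-solve fallback; errors if
#' the eigenvalue 1 is not simple (reducible chain).
#'
#' @param M Row-stochastic square matrix.
#' @param tol Numerical tolerance (default 1e-10).
#' @return Numeric vector `mu` with `mu >= 0`, `sum(mu) == 1`.
#' @export
stationary_distribution <- function(M, tol = 1e-10) {
  M <- as.matrix(M)
  if (nrow(M) != ncol(M)) stop("M must be square", call. = FALSE)
  if (any(abs(rowSums(M) - 1) > 1e-8)) {
    stop("M is not row-stochastic", call. = FALSE)
  }
  if (nrow(M) == 1L) return(1)
  ev <- eigen(t(M))
  near1 <- which(abs(ev$values - 1) < 1e-6)
  if (length(near1) > 1L) {
    stop("eigenvalue 1 is not simple: the chain is reducible",
         call. = FALSE)
  }
  v <- Re(ev$vectors[, near1[1L]])
  mu <- v / sum(v)
  if (any(mu < -1e-6)) {
    # fall back to solving (M^T - I) mu = 0 with the normalization row
    A <- rbind(t(M) - diag(nrow(M)), rep(1, nrow(M)))
    b <- c(rep(0, nrow(M)), 1)
    mu <- as.vector(qr.solve(A, b))
  }
  mu[abs(mu) < tol] <- 0
  mu <- mu / sum(mu)
  if (max(abs(as.vector(mu %*% M) - mu)) > 1e-8) {
    stop("failed to compute a stationary distribution", call. = FALSE)
  }
  mu
}

#' Entropy rate of a context tree model (bits per symbol)
#'
#' Computed on the Markov embedding as
#' \eqn{H = \sum_i \mu_i ( -\sum_j M_{ij} \log_2 M_{ij} )}: the stationary
#' average of the conditional entropy of the next symbol given the current
#' state. Always between 0 and \eqn{\log_2 |A|}.
#'
#' @param model A [context_tree_model()] or a `markov_embedding`.
#' @return Entropy rate in bits per symbol.
#' @examples
#' entropy_rate(kicker_model(3))   # ~0.5409
#' @export
entropy_rate <- function(model) {
  emb <- if (inherits(model, "markov_embedding")) model
         else markov_embedding(model)
  h_rows <- apply(emb$M, 1L, function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  })
  sum(emb$mu * h_rows)
}

# Stationary probability of each context: weight of the states mapping to it.
context_weights <- function(emb) {
  tapply(emb$mu, emb$context, sum)
}

#' Theoretical matching score
#'
#' The stationary probability that an independent draw from the conditional
#' distribution of the current context equals the next chain symbol — the
#' expected proportion of correct predictions of a fully informed responder
#' playing the matching strategy:
#' \eqn{\sum_w \mu(w) \sum_a p(a|w)^2}.
#'
#' @param model A [context_tree_model()] or `markov_embedding`.
#' @return A probability.
#' @export
matching_score <- function(model) {
  emb <- if (inherits(model, "markov_embedding")) model
         else markov_embedding(model)
  probs <- emb$model$probs
  rows <- match(emb$context, rownames(probs))
  sum(emb$mu * rowSums(probs[rows, , drop = FALSE]^2))
}

#' Theoretical maximizing score
#'
#' Expected proportion of correct predictions of a fully informed responder
#' who always answers the conditional mode:
#' \eqn{\sum_w \mu(w) \max_a p(a|w)}. Never smaller than
#' [matching_score()].
#'
#' @inheritParams matching_score
#' @return A probability.
#' @export
maximizing_score <- function(model) {
  emb <- if (inherits(model, "markov_embedding")) model
         else markov_embedding(model)
  probs <- emb$model$probs
  rows <- match(emb$context, rownames(probs))
  sum(emb$mu * apply(probs[rows, , drop = FALSE], 1L, max))
}
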