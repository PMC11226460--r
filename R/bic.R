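# BIC context-tree estimation for driven response sequences: the recursive
# bottom-up pruning and an exhaustive-search oracle for small instances.
#
# The estimator maximizes  log L_(tau, qhat) - c * df(tau) * log(n)  over
# all admissible trees of height <= L built on pasts observed in the
# stimulus sequence. All node values are held in the log domain (the
# penalized likelihoods n^{-c df(w)} L_w underflow long before n = 1000).

# Per-node penalized score, log domain, for all observed pasts.
node_scores <- function(counts, c_pen) {
  N_xy <- counts$N_xy
  N_x <- counts$N_x
  keep <- N_x >= 1L
  nm <- rownames(N_xy)[keep]
  nxy <- N_xy[keep, , drop = FALSE]
  nx <- N_x[keep]
  ll <- rowSums(ifelse(nxy > 0L, nxy * log(nxy / nx), 0))
  df <- rowSums(nxy >= 1L) - 1L
  # names carry a "." sentinel so the root context "" stays indexable
  key <- paste0(".", nm)
  list(node = nm, loglik = stats::setNames(ll, key),
       df = stats::setNames(df, key),
       score = stats::setNames(ll - c_pen * df * log(counts$n), key))
}

# Core recursion shared by bic_prune() and select_penalty(): computes the
# log-domain values V_w and indicators chi_w bottom-up and extracts the
# optimizing tree. Ties (children product equal to the node value) prune,
# matching the strict inequality in the indicator definition.
prune_from_scores <- function(scores, counts, return_state = FALSE) {
  alphabet <- counts$alphabet
  keep <- nchar(scores$node) <= counts$L
  nodes <- scores$node[keep]
  len <- nchar(nodes)
  vlog <- scores$score[paste0(".", nodes)]
  chi <- stats::setNames(rep(FALSE, length(nodes)), paste0(".", nodes))
  for (w in nodes[order(len, decreasing = TRUE)]) {
    if (nchar(w) == counts$L) next                   # leaves: chi = 0
    kids <- paste0(".", alphabet, w)
    kids <- kids[kids %in% names(vlog)]
    if (length(kids) == 0L) next                     # boundary leaf
    s_kids <- sum(vlog[kids])
    if (s_kids > scores$score[[paste0(".", w)]]) {
      chi[[paste0(".", w)]] <- TRUE
      vlog[[paste0(".", w)]] <- s_kids
    }
  }
  # a node is a context iff its indicator is 0 and every proper suffix on
  # the path to the root has indicator 1
  contexts <- character(0)
  stack <- ""
  while (length(stack) > 0L) {
    w <- stack[[1L]]; stack <- stack[-1L]
    if (!chi[[paste0(".", w)]]) {
      contexts <- c(contexts, w)
    } else {
      kids <- paste0(alphabet, w)
      stack <- c(stack, kids[kids %in% nodes])
    }
  }
  tree <- context_tree(contexts, alphabet)
  if (return_state) {
    k <- paste0(".", nodes)
    attr(tree, "prune_state") <- data.frame(
      node = nodes, V = unname(vlog[k]), chi = unname(chi[k]),
      df = unname(scores$df[k]), loglik = unname(scores$loglik[k]),
      stringsAsFactors = FALSE)
  }
  tree
}

#' BIC context-tree estimate by recursive pruning
#'
#' Estimates the context tree driving the response sequence: among all
#' admissible trees of height at most `L` built on observed stimulus
#' pasts, finds the maximizer of the penalized log-likelihood
#' \eqn{\log L_{(\tau,\hat q)} - c \, df(\tau) \log n} by the bottom-up
#' indicator recursion. Each node carries the log-domain value
#' \eqn{V_w = \max\{ -c\, df(w)\log n + \log L_w,\ \sum_b V_{bw} \}} and an
#' indicator that records whether splitting beat keeping the node; the
#' estimated contexts are the nodes with indicator 0 whose ancestors all
#' have indicator 1. Ties resolve to pruning (the smaller tree).
#'
#' @param pair A [paired_sequence()], or a precomputed [count_tables()].
#' @param L Maximal height of candidate trees.
#' @param c Penalty constant (>= 0). Large values force small trees.
#' @param return_state If `TRUE`, attach the per-node values, indicators,
#'   degrees of freedom and log-likelihoods as attribute `"prune_state"`.
#' @return A [context_tree()].
#' @examples
#' pr <- simulate_pair(kicker_model(3), 1000, kind = "matching", seed = 1)
#' bic_prune(pr, L = 4, c = 0.5)
#' @export
bic_prune <- function(pair, L, c, return_state = FALSE) {
  if (c < 0) stop("penalty constant c must be >= 0", call. = FALSE)
  counts <- if (inherits(pair, "count_tables")) pair
            else count_tables(pair, L)
  if (counts$L < L) stop("count tables were built with a smaller L",
                         call. = FALSE)
  counts$L <- L
  prune_from_scores(node_scores(counts, c), counts, return_state)
}

# Enumerate every admissible subtree rooted at `w` (depth budget `depth`),
# returning for each the leaf set and the score accumulated with the same
# nested summation order as the pruning recursion (so that oracle and
# recursion agree bit-for-bit, ties included).
enumerate_subtrees <- function(w, depth, scores, alphabet) {
  out <- list(list(leaves = w, score = scores$score[[paste0(".", w)]]))
  if (depth == 0L) return(out)
  kids <- paste0(alphabet, w)
  kids <- kids[kids %in% scores$node]
  if (length(kids) == 0L) return(out)
  per_kid <- lapply(kids, enumerate_subtrees, depth = depth - 1L,
                    scores = scores, alphabet = alphabet)
  combos <- list(list(leaves = character(0), score = 0))
  for (k in per_kid) {
    combos <- unlist(lapply(combos, function(acc) {
      lapply(k, function(sub) {
        list(leaves = c(acc$leaves, sub$leaves),
             score = acc$score + sub$score)
      })
    }), recursive = FALSE)
  }
  c(out, combos)
}

#' Exhaustive-search oracle for the BIC estimator
#'
#' Enumerates every admissible context tree of height at most `L` on the
#' observed stimulus pasts, scores each by
#' \eqn{\log L_{(\tau,\hat q)} - c\, df(\tau)\log n}, and returns the
#' argmax (ties to the smaller tree). Only feasible for tiny search spaces
#' (`L <= 2`, alphabet size <= 3); it exists as an independent correctness
#' check of [bic_prune()].
#'
#' @inheritParams bic_prune
#' @return A [context_tree()], with the number of trees searched in
#'   attribute `"n_searched"`.
#' @export
exhaustive_bic <- function(pair, L, c) {
  counts <- if (inherits(pair, "count_tables")) pair
            else count_tables(pair, L)
  if (L > 2L || length(counts$alphabet) > 3L) {
    stop("search space too large: exhaustive_bic requires L <= 2 and ",
         "|A| <= 3", call. = FALSE)
  }
  counts$L <- L
  scores <- node_scores(counts, c)
  trees <- enumerate_subtrees("", L, scores, counts$alphabet)
  best <- NULL
  for (tr in trees) {   # leaf options enumerate first: ties keep smaller
    if (is.null(best) || tr$score > best$score) best <- tr
  }
  out <- context_tree(best$leaves, counts$alphabet)
  attr(out, "n_searched") <- length(trees)
  out
}
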