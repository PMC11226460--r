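# Sufficient statistics for driven response sequences: the count tables
# N^XY(u, a) (past u in the stimulus followed by response a) and
# N^X(u) = sum_a N^XY(u, a), for all observed pasts u up to length L.

#' Count tables for a paired stimulus/response sequence
#'
#' For every string `u` of length 0..`L` occurring as a past in the
#' stimulus sequence, counts how often it is followed by each response
#' symbol: `N_xy[u, a]` sums over trials `t = l(u) .. n-1` the events
#' \{stimulus window ending at t equals u, response at t+1 equals a\}.
#' Trials before `t = l(u)` contribute to no count; the empty past `""`
#' collects all `n` responses.
#'
#' @param pair A [paired_sequence()].
#' @param L Maximal past length (>= 1, and < n).
#' @return An object of class `count_tables`: list with `N_xy` (integer
#'   matrix, rows = observed pasts of length 0..L in canonical order,
#'   columns = alphabet), `N_x` (row sums), `n`, `L`, `alphabet`.
#' @examples
#' p <- paired_sequence(c(0, 1, 2, 0, 1), c(1, 2, 0, 1, 2))
#' count_tables(p, L = 1)$N_xy
#' @export
count_tables <- function(pair, L) {
  stopifnot(inherits(pair, "paired_sequence"))
  L <- as.integer(L)
  if (L < 1L) stop("L must be >= 1", call. = FALSE)
  n <- pair$n
  alphabet <- pair$alphabet
  x <- pair$x; y <- pair$y
  blocks <- list()
  # l = 0: the root past precedes every response
  root <- matrix(tabulate(match(y, alphabet), length(alphabet)), 1L,
                 dimnames = list("", alphabet))
  blocks[[1L]] <- root
  for (len in seq_len(min(L, n - 1L))) {
    t_end <- len:(n - 1L)
    win <- rep("", length(t_end))
    for (j in 1:len) win <- paste0(win, x[t_end - len + j])
    tab <- table(factor(win), factor(y[t_end + 1L], levels = alphabet))
    mat <- matrix(as.integer(tab), nrow(tab), ncol(tab),
                  dimnames = dimnames(tab))
    mat <- mat[order_contexts(rownames(mat), alphabet), , drop = FALSE]
    blocks[[len + 1L]] <- mat
  }
  N_xy <- do.call(rbind, blocks)
  N_x <- rowSums(N_xy)
  storage.mode(N_x) <- "integer"
  structure(
    list(N_xy = N_xy, N_x = N_x, n = n, L = L, alphabet = alphabet),
    class = "count_tables"
  )
}

#' @export
print.count_tables <- function(x, ...) {
  cat("Count tables: n =", x$n, ", L =", x$L, ",",
      nrow(x$N_xy), "observed pasts\n")
  invisible(x)
}

.require_past <- function(counts, u) {
  i <- match(u, rownames(counts$N_xy))
  if (is.na(i) || counts$N_x[i] == 0L) {
    stop("undefined context: \"", if (u == "") "<root>" else u,
         "\" has no occurrences as a past", call. = FALSE)
  }
  i
}

#' Plug-in transition probability estimate
#'
#' \eqn{\hat q(a | u) = N^{XY}(u, a) / N^X(u)}: the maximum-likelihood
#' estimate of the probability of response `a` after stimulus past `u`.
#'
#' @param counts A [count_tables()] object.
#' @param u Past string.
#' @param a Optional response symbol; if omitted the full distribution over
#'   the alphabet is returned.
#' @export
qhat <- function(counts, u, a = NULL) {
  i <- .require_past(counts, u)
  q <- counts$N_xy[i, ] / counts$N_x[i]
  if (is.null(a)) q else unname(q[as.character(a)])
}

#' Degrees of freedom of a past / of a tree
#'
#' `df_node(counts, u)` is the number of response symbols observed at least
#' once after `u`, minus one; `df_tree` sums it over the contexts of a
#' tree. This is the dimension counting used in the BIC penalty.
#'
#' @inheritParams qhat
#' @export
df_node <- function(counts, u) {
  i <- match(u, rownames(counts$N_xy))
  if (is.na(i)) return(0L)
  as.integer(sum(counts$N_xy[i, ] >= 1L) - 1L)
}

#' @rdname df_node
#' @param tree A [context_tree()].
#' @export
df_tree <- function(counts, tree) {
  sum(vapply(tree$contexts, df_node, integer(1), counts = counts))
}

#' Node log-likelihood
#'
#' \eqn{\sum_a N^{XY}(u,a) \log \hat q(a|u)} with the convention
#' \eqn{0 \log 0 = 0}; the log-likelihood contribution of treating `u` as
#' a context. Summed over the contexts of a tree it gives the maximized
#' log-likelihood of that tree (the likelihood factorizes over contexts).
#'
#' @inheritParams qhat
#' @export
node_loglik <- function(counts, u) {
  i <- .require_past(counts, u)
  nxy <- counts$N_xy[i, ]
  pos <- nxy > 0L
  sum(nxy[pos] * log(nxy[pos] / counts$N_x[i]))
}
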