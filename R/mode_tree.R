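#' Mode (consensus) context tree of a collection of trees
#'
#' Summarizes a set of estimated context trees by majority-rule consensus:
#' starting from the root, a node `w` is kept as a context when at least
#' as many input trees have `w` as a context as have some *deeper* context
#' inside `w`'s branch; otherwise the node is split and the rule recurses
#' into its supported children. Ties resolve toward the context (the
#' smaller, shallower tree), and branches never identified by any tree are
#' dropped. The leaves of the result are the strings identified as
#' contexts most often across the collection; per-node vote proportions
#' are returned alongside, which is what tree-consensus shading plots
#' display.
#'
#' @param trees Non-empty list of [context_tree()] objects over a common
#'   alphabet.
#' @param L Maximal height of the mode tree; defaults to the largest input
#'   height.
#' @return An object of class `mode_tree`: list with `tree` (the mode
#'   [context_tree()]), `votes` (data frame of every string that received
#'   at least one vote or is a mode-tree context: `node`, `n_votes`,
#'   `proportion`, `in_mode_tree`) and `n_trees`.
#' @examples
#' t3 <- kicker_model(3)$tree
#' mode_context_tree(list(t3, t3, context_tree("")))$tree
#' @export
mode_context_tree <- function(trees, L = NULL) {
  if (!is.list(trees) || length(trees) == 0L) {
    stop("`trees` must be a non-empty list of context trees", call. = FALSE)
  }
  stopifnot(all(vapply(trees, inherits, logical(1), "context_tree")))
  alphabet <- trees[[1L]]$alphabet
  if (!all(vapply(trees, function(t) identical(t$alphabet, alphabet),
                  logical(1)))) {
    stop("all trees must share the same alphabet", call. = FALSE)
  }
  L <- as.integer(L %||% max(vapply(trees, function(t) t$height,
                                    numeric(1))))
  all_contexts <- lapply(trees, function(t) t$contexts)
  votes <- table(unlist(all_contexts))
  count_of <- function(w) {
    v <- votes[w]
    if (is.na(v) || w == "") sum(vapply(all_contexts, function(ctx)
      w %in% ctx, logical(1))) else as.integer(v)
  }
  # number of trees holding a context strictly deeper than w on w's branch
  splitters_of <- function(w) {
    sum(vapply(all_contexts, function(ctx) {
      any(ctx != w & nchar(ctx) > nchar(w) &
            substring(ctx, nchar(ctx) - nchar(w) + 1L) == w)
    }, logical(1)))
  }
  build <- function(w, depth) {
    n_leaf <- count_of(w)
    if (depth == 0L || splitters_of(w) <= n_leaf) return(w)
    kids <- paste0(alphabet, w)
    supported <- kids[vapply(kids, function(k) {
      count_of(k) > 0L || splitters_of(k) > 0L
    }, logical(1))]
    if (length(supported) == 0L) return(w)
    unlist(lapply(supported, build, depth = depth - 1L))
  }
  tree <- context_tree(build("", L), alphabet)
  all_nodes <- union(names(votes), tree$contexts)
  all_nodes <- all_nodes[order_contexts(all_nodes, alphabet)]
  n_votes <- vapply(all_nodes, count_of, integer(1))
  structure(
    list(tree = tree,
         votes = data.frame(node = ifelse(all_nodes == "", "<root>",
                                          all_nodes),
                            n_votes = n_votes,
                            proportion = n_votes / length(trees),
                            in_mode_tree = all_nodes %in% tree$contexts,
                            row.names = NULL, stringsAsFactors = FALSE),
         n_trees = length(trees)),
    class = "mode_tree"
  )
}

#' @export
print.mode_tree <- function(x, ...) {
  cat("Mode context tree of", x$n_trees, "trees:", format(x$tree), "\n")
  print(x$votes[x$votes$in_mode_tree, c("node", "n_votes", "proportion")],
        row.names = FALSE)
  invisible(x)
}
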