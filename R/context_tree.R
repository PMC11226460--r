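#' Context trees over a finite alphabet
#'
#' A context tree is a suffix-free set of context strings over a finite
#' ordered alphabet. Context strings are written oldest-first, with the most
#' recent symbol *last*: the context `"21"` matches any past whose previous
#' symbol is `1` preceded by `2`. The empty string `""` is the root context
#' (an order-0 model). Suffix-freeness guarantees that any sufficiently long
#' past matches at most one context, so the tree can be drawn as a rooted
#' \eqn{|A|}-ary tree whose leaves are the contexts.
#'
#' @param contexts Character vector of context strings (oldest-first). Use
#'   `""` alone for the root-only tree.
#' @param alphabet Character vector of symbols; the order defines the
#'   tie-breaking order used throughout the package. Default `c("0","1","2")`.
#' @return An object of class `context_tree` with elements `contexts`
#'   (canonically ordered), `alphabet` and `height`.
#' @examples
#' tau3 <- context_tree(c("2", "00", "10", "20", "01", "11", "21"))
#' context_of(tau3, c("0", "2", "1"))
#' @export
context_tree <- function(contexts, alphabet = c("0", "1", "2")) {
  alphabet <- as.character(alphabet)
  if (length(alphabet) < 2L || anyDuplicated(alphabet)) {
    stop("alphabet must contain at least two distinct symbols", call. = FALSE)
  }
  if (any(nchar(alphabet) != 1L)) {
    stop("alphabet symbols must be single characters", call. = FALSE)
  }
  contexts <- unique(as.character(contexts))
  if (length(contexts) == 0L) {
    stop("a context tree needs at least one context (use \"\" for the root)",
         call. = FALSE)
  }
  # validate symbols
  for (w in contexts) {
    if (nchar(w) > 0L) symbol_codes(strsplit(w, "")[[1]], alphabet)
  }
  # suffix-freeness
  if (length(contexts) > 1L) {
    if ("" %in% contexts) {
      stop("the root context cannot coexist with other contexts",
           call. = FALSE)
    }
    for (u in contexts) {
      for (w in contexts) {
        if (u != w && is_proper_suffix(u, w)) {
          stop("contexts are not suffix-free: \"", u,
               "\" is a suffix of \"", w, "\"", call. = FALSE)
        }
      }
    }
  }
  contexts <- contexts[order_contexts(contexts, alphabet)]
  structure(
    list(contexts = contexts, alphabet = alphabet,
         height = max(nchar(contexts))),
    class = "context_tree"
  )
}

#' @export
print.context_tree <- function(x, ...) {
  cat("Context tree over {", paste(x$alphabet, collapse = ","),
      "}, height ", x$height, "\n", sep = "")
  cat("  contexts:",
      if (identical(x$contexts, "")) "(root only)"
      else paste(x$contexts, collapse = " "), "\n")
  invisible(x)
}

#' @export
format.context_tree <- function(x, ...) {
  paste0("{", paste(ifelse(x$contexts == "", "<root>", x$contexts),
                    collapse = ","), "}")
}

#' Test two context trees for equality
#'
#' Trees are equal when they share the alphabet and the same context set
#' (order-independent).
#' @param a,b `context_tree` objects.
#' @export
tree_equal <- function(a, b) {
  identical(a$alphabet, b$alphabet) && setequal(a$contexts, b$contexts)
}

#' Context associated to a past
#'
#' Returns the unique context of `tree` that is a suffix of `past`, or `NA`
#' if no suffix of the past (including the full past) is a context. The root
#' context `""` matches every past, including the empty one.
#'
#' @param tree A [context_tree()].
#' @param past Character vector of symbols, oldest first (most recent last).
#' @return The matching context string, or `NA_character_` if absent.
#' @export
context_of <- function(tree, past) {
  stopifnot(inherits(tree, "context_tree"))
  past <- as.character(past)
  if (length(past) > 0L) symbol_codes(past, tree$alphabet)
  if ("" %in% tree$contexts) return("")
  if (length(past) == 0L) return(NA_character_)
  s <- paste(past, collapse = "")
  l <- nchar(s)
  cand <- substring(s, pmax(1L, l - (1:min(l, tree$height)) + 1L), l)
  hit <- cand[cand %in% tree$contexts]
  if (length(hit) == 0L) return(NA_character_)
  hit[[1L]]
}

# Lookup table: index of the context (row in tree$contexts) for every
# length-h past, encoded by past_index(); NA where no context matches.
context_lookup <- function(tree, h = tree$height) {
  m <- length(tree$alphabet)
  pasts <- all_strings(tree$alphabet, h)
  vapply(pasts, function(s) {
    w <- context_of(tree, strsplit(s, "")[[1]])
    if (is.na(w)) NA_integer_ else match(w, tree$contexts)
  }, integer(1), USE.NAMES = FALSE)
}

#' Admissible context tree of a stimulus sequence
#'
#' Builds the candidate tree of maximal height `L` whose contexts are the
#' observed strings: every string of length `L` that occurs as a past in
#' `x` (at least `min_count` times) is a leaf, together with shorter
#' observed strings that admit no observed extension (a boundary effect at
#' the start of the sequence). This is the tree that seeds the BIC pruning
#' recursion.
#'
#' @param x Character vector, the stimulus sequence.
#' @param L Maximal height (\eqn{\ge 1}).
#' @param alphabet Alphabet; defaults to `c("0","1","2")`.
#' @param min_count Minimal number of occurrences (as a past, i.e. ending
#'   before the final position) for a string to count as observed.
#' @return A [context_tree()].
#' @export
admissible_tree <- function(x, L, alphabet = c("0", "1", "2"),
                            min_count = 1L) {
  x <- as.character(x)
  n <- length(x)
  if (n == 0L) stop("empty sequence", call. = FALSE)
  if (L < 1L) stop("L must be >= 1", call. = FALSE)
  if (n <= L) stop("sequence length must exceed L", call. = FALSE)
  symbol_codes(x, alphabet)
  observed <- character(0)
  for (len in 1:L) {
    t_end <- len:(n - 1L)
    win <- rep("", length(t_end))
    for (j in 1:len) win <- paste0(win, x[t_end - len + j])
    tab <- table(win)
    observed <- c(observed, names(tab)[tab >= min_count])
  }
  has_ext <- vapply(observed, function(w) {
    any(paste0(alphabet, w) %in% observed)
  }, logical(1))
  leaves <- observed[nchar(observed) == L | !has_ext]
  context_tree(leaves, alphabet)
}
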