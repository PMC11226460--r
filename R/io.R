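# Structured-text serialization: trees and models as JSON, paired
# sequences as TSV. Round trips are exact and order-independent.

#' Read and write context trees and models
#'
#' Trees and models are stored as JSON with fields `alphabet`, `contexts`
#' and (for models) `probs`, a map from context string to the probability
#' vector in alphabet order. Reading validates the alphabet, rejects
#' duplicate contexts and suffix-free violations, and reproduces the
#' original object exactly regardless of the order of contexts in the
#' file.
#'
#' @param tree A [context_tree()].
#' @param path File path.
#' @return `read_tree()` returns a [context_tree()]; `read_model()` a
#'   [context_tree_model()]; the writers return `path` invisibly.
#' @export
write_tree <- function(tree, path) {
  stopifnot(inherits(tree, "context_tree"))
  jsonlite::write_json(
    list(alphabet = tree$alphabet, contexts = tree$contexts),
    path, auto_unbox = FALSE, pretty = TRUE
  )
  invisible(path)
}

.parse_tree_fields <- function(obj, path) {
  if (is.null(obj$alphabet) || is.null(obj$contexts)) {
    stop("malformed tree file ", path,
         ": fields `alphabet` and `contexts` are required", call. = FALSE)
  }
  contexts <- as.character(unlist(obj$contexts))
  if (length(contexts) == 0L) contexts <- ""
  dup <- contexts[duplicated(contexts)]
  if (length(dup) > 0L) {
    stop("malformed tree file ", path, ": duplicate context \"",
         dup[[1L]], "\"", call. = FALSE)
  }
  context_tree(contexts, as.character(unlist(obj$alphabet)))
}

#' @rdname write_tree
#' @export
read_tree <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  .parse_tree_fields(obj, path)
}

#' @rdname write_tree
#' @param model A [context_tree_model()].
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "context_tree_model"))
  probs <- lapply(seq_len(nrow(model$probs)),
                  function(i) unname(model$probs[i, ]))
  names(probs) <- rownames(model$probs)
  jsonlite::write_json(
    list(alphabet = model$tree$alphabet,
         contexts = model$tree$contexts,
         probs = probs,
         name = attr(model, "name"),
         verified = attr(model, "verified")),
    path, auto_unbox = FALSE, pretty = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}

#' @rdname write_tree
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  tree <- .parse_tree_fields(obj, path)
  if (is.null(obj$probs)) {
    stop("malformed model file ", path, ": field `probs` is required",
         call. = FALSE)
  }
  probs <- do.call(rbind, lapply(obj$probs, function(p) unlist(p)))
  rownames(probs) <- names(obj$probs)
  context_tree_model(
    tree, probs,
    name = if (length(obj$name) > 0L) unlist(obj$name) else NULL,
    verified = if (length(obj$verified) > 0L) unlist(obj$verified) else TRUE
  )
}

#' Read and write paired stimulus/response sequences
#'
#' The interchange format is a tab-separated table with a header and the
#' columns `trial` (1-based), `kicker` (stimulus) and `goalkeeper`
#' (response). Writing then reading reproduces the sequences exactly.
#'
#' @param pair A [paired_sequence()].
#' @param path File path.
#' @export
write_pairs <- function(pair, path) {
  stopifnot(inherits(pair, "paired_sequence"))
  utils::write.table(
    data.frame(trial = seq_len(pair$n), kicker = pair$x,
               goalkeeper = pair$y),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_pairs
#' @param alphabet Alphabet for validation, default `c("0","1","2")`.
#' @export
read_pairs <- function(path, alphabet = c("0", "1", "2")) {
  tab <- utils::read.delim(path, colClasses = "character")
  need <- c("trial", "kicker", "goalkeeper")
  missing <- setdiff(need, names(tab))
  if (length(missing) > 0L) {
    stop("malformed pairs file ", path, ": missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!identical(as.integer(tab$trial), seq_len(nrow(tab)))) {
    stop("malformed pairs file ", path,
         ": `trial` must run 1..n in order", call. = FALSE)
  }
  paired_sequence(tab$kicker, tab$goalkeeper, alphabet,
                  meta = list(source = path))
}
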