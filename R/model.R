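#' Context tree models (variable-length Markov chains)
#'
#' A context tree model pairs a [context_tree()] with one transition
#' distribution over the alphabet per context. Together they define a
#' stationary stochastic chain with memory of variable length: each new
#' symbol is drawn from the distribution attached to the context of the
#' current past.
#'
#' @param tree A [context_tree()].
#' @param probs Numeric matrix with one row per context (rownames must be
#'   the context strings) and one column per symbol (in alphabet order), or
#'   a named list of numeric vectors. Rows must be non-negative and sum to
#'   1 (tolerance 1e-12).
#' @param name Optional model label carried through outputs.
#' @param verified Logical; `FALSE` marks a model whose probabilities are a
#'   best-effort reconstruction rather than an exactly specified object.
#' @return An object of class `context_tree_model`.
#' @examples
#' m <- context_tree_model(
#'   context_tree(c("0", "1", "2")),
#'   rbind("0" = c(0, 1, 0), "1" = c(0, 0, 1), "2" = c(1, 0, 0))
#' )
#' simulate_chain(m, 9, seed = 1)
#' @export
context_tree_model <- function(tree, probs, name = NULL, verified = TRUE) {
  stopifnot(inherits(tree, "context_tree"))
  m <- length(tree$alphabet)
  if (is.list(probs)) {
    probs <- do.call(rbind, probs[names(probs)])
  }
  probs <- as.matrix(probs)
  if (is.null(rownames(probs))) {
    if (nrow(probs) == length(tree$contexts)) {
      rownames(probs) <- tree$contexts
    } else {
      stop("probs must have context rownames", call. = FALSE)
    }
  }
  missing <- setdiff(tree$contexts, rownames(probs))
  if (length(missing) > 0L) {
    stop("no distribution for context(s): ",
         paste(ifelse(missing == "", "<root>", missing), collapse = ", "),
         call. = FALSE)
  }
  probs <- probs[match(tree$contexts, rownames(probs)), , drop = FALSE]
  rownames(probs) <- tree$contexts
  if (ncol(probs) != m) {
    stop("probs must have one column per alphabet symbol", call. = FALSE)
  }
  colnames(probs) <- tree$alphabet
  if (any(probs < 0)) stop("negative transition probability", call. = FALSE)
  bad <- abs(rowSums(probs) - 1) > 1e-12
  if (any(bad)) {
    stop("distribution for context(s) ",
         paste(ifelse(rownames(probs)[bad] == "", "<root>",
                      rownames(probs)[bad]), collapse = ", "),
         " does not sum to 1", call. = FALSE)
  }
  structure(
    list(tree = tree, probs = probs),
    name = name, verified = verified,
    class = "context_tree_model"
  )
}

#' @export
print.context_tree_model <- function(x, digits = 3, ...) {
  nm <- attr(x, "name")
  cat("Context tree model", if (!is.null(nm)) paste0(" \"", nm, "\""),
      " over {", paste(x$tree$alphabet, collapse = ","), "}\n", sep = "")
  if (isFALSE(attr(x, "verified"))) {
    cat("  [unverified reconstruction]\n")
  }
  tab <- round(x$probs, digits)
  rownames(tab) <- ifelse(rownames(tab) == "", "<root>", rownames(tab))
  print(tab)
  invisible(x)
}

#' Check that a model assigns a context to every reachable past
#'
#' A model is complete when every past of length `height` built from the
#' alphabet has a context. Incomplete models can strand the simulator on an
#' orphan past.
#'
#' @param model A [context_tree_model()].
#' @return `TRUE` invisibly, or an error naming an orphan past.
#' @export
check_complete <- function(model) {
  tree <- model$tree
  if (tree$height == 0L) return(invisible(TRUE))
  lut <- context_lookup(tree)
  if (anyNA(lut)) {
    orphan <- all_strings(tree$alphabet, tree$height)[which(is.na(lut))[1L]]
    stop("incomplete model: no context for past \"", orphan, "\"",
         call. = FALSE)
  }
  invisible(TRUE)
}

# A short, stable fingerprint of a model (alphabet, contexts, probabilities
# at 1e-12 resolution), so results can record exactly which model produced
# them without serialising it in full.
#' Fingerprint of a context tree model
#' @param model A [context_tree_model()].
#' @return A character scalar.
#' @export
model_fingerprint <- function(model) {
  payload <- paste(
    paste(model$tree$alphabet, collapse = ","),
    paste(model$tree$contexts, collapse = ","),
    paste(sprintf("%.12g", t(model$probs)), collapse = ","),
    sep = "|"
  )
  # 32-bit FNV-1a over the payload bytes: cheap, dependency-free
  h <- 2166136261
  for (b in as.integer(charToRaw(payload))) {
    h <- bitwXor(as.integer(h %% 2^31), b) * 16777619
    h <- h %% 2^31
  }
  sprintf("%s-%08x", attr(model, "name") %||% "model", as.integer(h))
}
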