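# Simulation of stimulus chains and responder agents.

# Vectorised simulation of `nseq` independent chains of length `len`.
# Returns integer code matrices: $x (nseq x len) and $init (nseq x h), the
# h symbols immediately preceding column 1 of $x. Each chain starts from a
# uniform random past of length h and runs `burn_in` warm-up steps that are
# discarded, so the returned block is approximately stationary.
simulate_chains_coded <- function(model, nseq, len, burn_in = 100L) {
  check_complete(model)
  tree <- model$tree
  m <- length(tree$alphabet)
  h <- tree$height
  lut <- context_lookup(tree)          # past index -> context row
  cp <- t(apply(model$probs, 1L, cumsum))
  cp[, m] <- 1                          # guard against rounding
  if (h == 0L) {
    u <- matrix(stats::runif(nseq * len), nseq, len)
    x <- matrix(0L, nseq, len)
    for (t in seq_len(len)) {
      x[, t] <- 1L + as.integer(rowSums(u[, t] > matrix(cp, nseq, m,
                                                        byrow = TRUE)))
    }
    return(list(x = x, init = matrix(integer(0), nseq, 0L)))
  }
  total <- burn_in + len
  # rolling past index per chain; start from uniform pasts
  past <- matrix(sample.int(m, nseq * h, replace = TRUE), nseq, h)
  idx <- apply(past, 1L, past_index, m = m)
  keep <- matrix(0L, nseq, len)
  init <- matrix(0L, nseq, h)
  mpow <- m^(h - 1L)
  for (t in seq_len(total)) {
    ctx <- lut[idx]
    if (anyNA(ctx)) {
      orphan <- all_strings(tree$alphabet, h)[idx[which(is.na(ctx))[1L]]]
      stop("incomplete model: no context for past \"", orphan, "\"",
           call. = FALSE)
    }
    u <- stats::runif(nseq)
    a <- 1L + as.integer(rowSums(u > cp[ctx, , drop = FALSE]))
    if (t > burn_in) {
      keep[, t - burn_in] <- a
    }
    if (t > burn_in - h && t <= burn_in) {
      init[, t - burn_in + h] <- a
    }
    idx <- ((idx - 1L) %% mpow) * m + (a - 1L) + 1L
  }
  if (burn_in < h) {
    # not enough warm-up to fill the initial past: take the uniform start
    fill <- h - burn_in
    init[, seq_len(fill)] <- past[, burn_in + seq_len(fill), drop = FALSE]
  }
  list(x = keep, init = init)
}

#' Simulate a stimulus sequence from a context tree model
#'
#' Draws `n` symbols from the variable-length Markov chain defined by
#' `model`. The chain is started from a uniformly drawn past of length
#' equal to the tree height and run for `burn_in` warm-up steps that are
#' discarded, so the returned stretch is approximately stationary. The
#' symbols of the past immediately preceding the first returned symbol are
#' attached as attribute `"init_past"`, which lets a fully informed
#' responder condition on a well-defined context from the first trial.
#'
#' @param model A [context_tree_model()].
#' @param n Number of symbols to return.
#' @param seed Optional integer seed (same seed, same sequence).
#' @param burn_in Warm-up length, default 100.
#' @return Character vector of length `n` with attribute `init_past`.
#' @examples
#' x <- simulate_chain(kicker_model(3), 12, seed = 7)
#' @export
simulate_chain <- function(model, n, seed = NULL, burn_in = 100L) {
  stopifnot(inherits(model, "context_tree_model"), n >= 1L)
  sim <- with_seed(seed, simulate_chains_coded(model, 1L, n, burn_in))
  out <- model$tree$alphabet[sim$x[1L, ]]
  attr(out, "init_past") <- model$tree$alphabet[sim$init[1L, ]]
  out
}

#' Responder agents: matching, maximizing, uniform, constant
#'
#' Generates a response sequence for a stimulus sequence `x`, where the
#' response at trial t is a prediction of `x[t]` made from the stimulus
#' past `x[1..t-1]` only (plus `init_past`, if the responder observed the
#' chain before trial 1):
#' \describe{
#'   \item{matching}{samples from the model's conditional distribution at
#'     the current context — the strategy that emulates the generator.}
#'   \item{maximizing}{always answers the conditional mode; ties broken
#'     toward the smallest symbol in alphabet order.}
#'   \item{uniform}{guesses uniformly, ignoring the past.}
#'   \item{constant}{always answers `symbol`.}
#' }
#' Trials whose past has no defined context (only possible when
#' `init_past` is missing or too short) are answered uniformly at random.
#'
#' @param model A [context_tree_model()] (the model *known to the agent*).
#' @param x Stimulus sequence (character).
#' @param kind Agent kind, see above.
#' @param symbol Fixed response for the constant agent.
#' @param init_past Symbols preceding `x[1]`; defaults to the
#'   `"init_past"` attribute of `x` when present.
#' @param seed Optional integer seed.
#' @return Character vector of responses, same length as `x`.
#' @examples
#' x <- simulate_chain(kicker_model(3), 20, seed = 1)
#' respond(kicker_model(3), x, kind = "maximizing")
#' @export
respond <- function(model, x,
                    kind = c("matching", "maximizing", "uniform", "constant"),
                    symbol = NULL, init_past = attr(x, "init_past"),
                    seed = NULL) {
  kind <- match.arg(kind)
  stopifnot(inherits(model, "context_tree_model"))
  tree <- model$tree
  alphabet <- tree$alphabet
  m <- length(alphabet)
  n <- length(x)
  xc <- symbol_codes(x, alphabet)
  if (kind == "constant") {
    if (is.null(symbol)) stop("constant agent needs `symbol`", call. = FALSE)
    symbol_codes(symbol, alphabet)
    return(rep(as.character(symbol), n))
  }
  with_seed(seed, {
    if (kind == "uniform") {
      return(alphabet[sample.int(m, n, replace = TRUE)])
    }
    h <- tree$height
    lut <- context_lookup(tree)
    ip <- if (is.null(init_past)) integer(0) else
      symbol_codes(init_past, alphabet)
    if (length(ip) > h) ip <- ip[(length(ip) - h + 1L):length(ip)]
    # context row per trial; NA where undefined
    ctx <- rep(NA_integer_, n)
    n_head <- min(n, max(0L, h - length(ip)))
    if (h == 0L) {
      ctx[] <- 1L
    } else {
      if (n > n_head) {
        z <- c(ip, xc)                  # length >= n - n_head + h
        tt <- (n_head + 1L):n
        acc <- numeric(length(tt))
        off <- length(ip) - h           # 0 when init past is full
        for (j in 0:(h - 1L)) acc <- acc + (z[tt + h - 1L - j + off] - 1L) * m^j
        ctx[tt] <- lut[as.integer(acc + 1L)]
      }
      for (t in seq_len(n_head)) {      # short pasts at the very start
        past <- c(alphabet[ip], x[seq_len(t - 1L)])
        w <- context_of(tree, past)
        ctx[t] <- if (is.na(w)) NA_integer_ else match(w, tree$contexts)
      }
    }
    y <- integer(n)
    und <- is.na(ctx)
    if (any(und)) y[und] <- sample.int(m, sum(und), replace = TRUE)
    def <- which(!und)
    if (length(def) > 0L) {
      if (kind == "maximizing") {
        mode_of <- apply(model$probs, 1L, which.max)  # first max = smallest
        y[def] <- mode_of[ctx[def]]
      } else {                                        # matching
        cp <- t(apply(model$probs, 1L, cumsum)); cp[, m] <- 1
        u <- stats::runif(length(def))
        y[def] <- 1L + as.integer(rowSums(u > cp[ctx[def], , drop = FALSE]))
      }
    }
    alphabet[y]
  })
}

#' Paired stimulus/response sequences
#'
#' The universal sample container: aligned stimulus (`x`) and response
#' (`y`) sequences of equal length over a shared alphabet, with free-form
#' metadata (model id, agent, seed, ...).
#'
#' @param x,y Character vectors of equal length.
#' @param alphabet Alphabet, default `c("0","1","2")`.
#' @param meta Named list of metadata.
#' @return An object of class `paired_sequence` with elements `x`, `y`,
#'   `n`, `alphabet`, `meta`.
#' @export
paired_sequence <- function(x, y, alphabet = c("0", "1", "2"),
                            meta = list()) {
  x <- as.character(x); y <- as.character(y)
  if (length(x) != length(y)) {
    stop("stimulus and response sequences must have equal length",
         call. = FALSE)
  }
  symbol_codes(x, alphabet); symbol_codes(y, alphabet)
  structure(list(x = x, y = y, n = length(x),
                 alphabet = as.character(alphabet), meta = meta),
            class = "paired_sequence")
}

#' @export
print.paired_sequence <- function(x, ...) {
  cat("Paired sequence, n =", x$n, "trials\n")
  k <- min(x$n, 15L)
  cat("  stimulus:", paste(x$x[seq_len(k)], collapse = " "),
      if (x$n > k) "...", "\n")
  cat("  response:", paste(x$y[seq_len(k)], collapse = " "),
      if (x$n > k) "...", "\n")
  if (length(x$meta) > 0L) {
    cat("  meta:", paste(names(x$meta),
                         vapply(x$meta, function(v) paste(format(v),
                                                         collapse = ","),
                                character(1)),
                         sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Simulate a full stimulus/response pair
#'
#' Convenience wrapper: simulates a stimulus chain from `model` and a
#' response sequence from the given agent, returning a [paired_sequence()]
#' with reproducibility metadata.
#'
#' @inheritParams respond
#' @param n Number of trials.
#' @param seed Integer seed governing both the chain and the agent.
#' @param burn_in Chain warm-up, see [simulate_chain()].
#' @export
simulate_pair <- function(model, n, kind = "matching", symbol = NULL,
                          seed = NULL, burn_in = 100L) {
  with_seed(seed, {
    x <- simulate_chain(model, n, seed = NULL, burn_in = burn_in)
    y <- respond(model, x, kind = kind, symbol = symbol)
    paired_sequence(x, y, model$tree$alphabet,
                    meta = list(model = attr(model, "name") %||% "custom",
                                fingerprint = model_fingerprint(model),
                                agent = kind, seed = seed %||% NA))
  })
}
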