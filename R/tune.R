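# Penalty tuning by one-step-ahead prediction risk, and the end-to-end fit.

# Suffix strings of x ending at each position t in `t_end`, for lengths
# 0..L: a list with element l+1 holding the length-l suffixes (l = 0 is "").
position_suffixes <- function(x, t_end, L) {
  out <- vector("list", L + 1L)
  out[[1L]] <- rep("", length(t_end))
  for (len in seq_len(L)) {
    win <- rep("", length(t_end))
    for (j in 1:len) win <- paste0(win, x[t_end - len + j])
    out[[len + 1L]] <- win
  }
  out
}

# Context (string) of each position given a fitted tree, longest match
# first; NA where no leaf covers the past (possible only for pasts unseen
# in the data the tree was fitted on).
position_contexts <- function(suffixes, tree) {
  npos <- length(suffixes[[1L]])
  ctx <- rep(NA_character_, npos)
  for (len in sort(unique(nchar(tree$contexts)), decreasing = TRUE)) {
    leaves <- tree$contexts[nchar(tree$contexts) == len]
    cand <- suffixes[[len + 1L]]
    hit <- is.na(ctx) & cand %in% leaves
    ctx[hit] <- cand[hit]
  }
  ctx
}

# Per-position one-step-ahead Brier scores of the plug-in predictor qhat
# on positions t_end (predicting y[t_end + 1]), backing off to the longest
# past with positive training count when the context itself is unseen.
brier_errors <- function(counts, tree, suffixes, y_next) {
  ctx <- position_contexts(suffixes, tree)
  rows <- match(ctx, rownames(counts$N_xy))
  # back off unseen or uncovered contexts toward shorter suffixes
  bad <- which(is.na(rows) | counts$N_x[ifelse(is.na(rows), 1L, rows)] == 0L)
  if (length(bad) > 0L) {
    for (i in bad) {
      for (len in rev(seq_len(counts$L + 1L)) - 1L) {
        r <- match(suffixes[[len + 1L]][i], rownames(counts$N_xy))
        if (!is.na(r) && counts$N_x[r] > 0L) { rows[i] <- r; break }
      }
    }
  }
  q <- counts$N_xy[rows, , drop = FALSE] / counts$N_x[rows]
  a <- match(y_next, counts$alphabet)
  q_true <- q[cbind(seq_along(a), a)]
  1 - 2 * q_true + rowSums(q^2)
}

#' Choose the BIC penalty constant by prediction-error risk
#'
#' Fits the BIC tree for every penalty value on a grid and scores each by
#' an estimate of the final prediction error — the one-step-ahead risk of
#' its plug-in predictor; the risk-minimizing penalty is returned (ties
#' toward the largest penalty, i.e. the smaller tree).
#'
#' Two risk estimates are available:
#' \describe{
#'   \item{`"cv"` (default)}{a 2-fold chronological cross-validation: the
#'     tree and its probabilities are refitted on each half of the
#'     sequence and the Brier score of the one-step-ahead predictor is
#'     evaluated on the other half (unseen contexts back off to the
#'     longest past observed in the training half). This estimate is
#'     unbiased for out-of-sample risk and reliably separates over- from
#'     underfitted trees.}
#'   \item{`"fpe"`}{the in-sample one-step-ahead Brier score multiplied by
#'     the classical final-prediction-error correction
#'     \eqn{(N + df)/(N - df)}. Cheaper, but the correction is too weak to
#'     offset the in-sample optimism of large trees, so it tends to select
#'     small penalties; kept as a diagnostic.}
#' }
#'
#' With `one_se = TRUE` (the default) the returned penalty is the largest
#' one whose risk lies within one standard error of the minimum — the
#' usual parsimony rule for noisy risk curves. Refinements that split a
#' context into children with (near-)identical response distributions
#' leave the prediction risk essentially unchanged, so the raw minimizer
#' is decided by noise; the one-SE rule resolves such flat stretches
#' toward the smaller tree.
#'
#' @param pair A [paired_sequence()].
#' @param L Maximal candidate-tree height.
#' @param c_grid Penalty grid; default 40 log-spaced points in
#'   \[0.05, 4\].
#' @param risk `"cv"` (default) or `"fpe"`.
#' @param one_se Apply the one-standard-error rule (default `TRUE`).
#' @return An object of class `penalty_selection`: list with `c` (the
#'   chosen constant), `risk` (method used) and `trace` (data frame with
#'   one row per grid point: `c`, `risk`, `se`, `df`, `n_contexts`).
#' @export
select_penalty <- function(pair, L,
                           c_grid = exp(seq(log(0.05), log(4),
                                            length.out = 40L)),
                           risk = c("cv", "fpe"), one_se = TRUE) {
  risk <- match.arg(risk)
  stopifnot(inherits(pair, "paired_sequence"))
  counts <- count_tables(pair, L)
  n <- pair$n
  t_end <- L:(n - 1L)
  sufs <- position_suffixes(pair$x, t_end, L)
  y_next <- pair$y[t_end + 1L]
  if (risk == "cv") {
    h <- n %/% 2L
    folds <- list(
      list(train = 1:h, test_end = h:(n - 1L)),
      list(train = (h + 1L):n, test_end = L:(h - 1L))
    )
    fold_data <- lapply(folds, function(f) {
      sub <- paired_sequence(pair$x[f$train], pair$y[f$train],
                             pair$alphabet)
      list(counts = count_tables(sub, L),
           sufs = position_suffixes(pair$x, f$test_end, L),
           y_next = pair$y[f$test_end + 1L])
    })
  }
  risks <- ses <- numeric(length(c_grid))
  dfs <- integer(length(c_grid))
  sizes <- integer(length(c_grid))
  for (i in seq_along(c_grid)) {
    tree <- prune_from_scores(node_scores(counts, c_grid[i]), counts)
    dfs[i] <- df_tree(counts, tree)
    sizes[i] <- length(tree$contexts)
    if (risk == "fpe") {
      errs <- brier_errors(counts, tree, sufs, y_next)
      N <- length(y_next)
      fac <- if (dfs[i] >= N) Inf else (N + dfs[i]) / (N - dfs[i])
      risks[i] <- mean(errs) * fac
      ses[i] <- stats::sd(errs) / sqrt(N)
    } else {
      errs <- unlist(lapply(fold_data, function(fd) {
        tr <- prune_from_scores(node_scores(fd$counts, c_grid[i]),
                                fd$counts)
        brier_errors(fd$counts, tr, fd$sufs, fd$y_next)
      }))
      risks[i] <- mean(errs)
      ses[i] <- stats::sd(errs) / sqrt(length(errs))
    }
  }
  if (all(!is.finite(risks))) {
    warning("all penalty fits degenerate; falling back to c = 0.5")
    best <- which.min(abs(c_grid - 0.5))
  } else if (one_se) {
    i_min <- which.min(risks)
    best <- max(which(risks <= risks[i_min] + ses[i_min]))
  } else {
    best <- max(which(risks <= min(risks) + 1e-12))   # ties: largest c
  }
  structure(
    list(c = c_grid[best], risk = risk,
         trace = data.frame(c = c_grid, risk = risks, se = ses, df = dfs,
                            n_contexts = sizes)),
    class = "penalty_selection"
  )
}

#' @export
print.penalty_selection <- function(x, ...) {
  cat("Penalty selection (", x$risk, " risk): c = ",
      signif(x$c, 4), "\n", sep = "")
  invisible(x)
}

#' Fit a context tree model to a driven response sequence
#'
#' The full estimation pipeline: tune the BIC penalty constant (unless a
#' fixed `c` is given), prune the admissible tree of the stimulus sequence,
#' and attach the plug-in transition probabilities of each estimated
#' context. This is the per-participant, per-window model-selection step.
#'
#' @inheritParams select_penalty
#' @param c Either `"auto"` (tune by `risk`) or a fixed non-negative
#'   penalty constant.
#' @param L Maximal candidate-tree height; default 4.
#' @return An object of class `driven_fit`: list with `tree`
#'   (a [context_tree()]), `q` (matrix of plug-in probabilities, one row
#'   per context), `c`, `penalty` (the `penalty_selection` trace, or
#'   `NULL` when `c` was fixed), `L`, `n` and `meta` (copied from the
#'   pair, plus the risk method used).
#' @examples
#' pr <- simulate_pair(kicker_model(3), 1000, kind = "matching", seed = 1)
#' fit_driven_tree(pr, L = 4)
#' @export
fit_driven_tree <- function(pair, L = 4L, c = "auto",
                            c_grid = exp(seq(log(0.05), log(4),
                                             length.out = 40L)),
                            risk = c("cv", "fpe"), one_se = TRUE) {
  risk <- match.arg(risk)
  stopifnot(inherits(pair, "paired_sequence"))
  sel <- NULL
  if (identical(c, "auto")) {
    sel <- select_penalty(pair, L, c_grid, risk, one_se)
    c <- sel$c
  }
  counts <- count_tables(pair, L)
  tree <- prune_from_scores(node_scores(counts, c), counts)
  q <- t(vapply(tree$contexts, function(u) qhat(counts, u),
                numeric(length(pair$alphabet))))
  rownames(q) <- tree$contexts
  structure(
    list(tree = tree, q = q, c = c, penalty = sel, L = L, n = pair$n,
         meta = c(pair$meta, list(risk = if (is.null(sel)) "fixed-c"
                                         else risk))),
    class = "driven_fit"
  )
}

#' @export
print.driven_fit <- function(x, digits = 3, ...) {
  cat("Driven context-tree fit (L = ", x$L, ", c = ", signif(x$c, 4),
      ")\n", sep = "")
  cat("  contexts:", format(x$tree), "\n")
  tab <- round(x$q, digits)
  rownames(tab) <- ifelse(rownames(tab) == "", "<root>", rownames(tab))
  print(tab)
  invisible(x)
}
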