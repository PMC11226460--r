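# Fixtures built in code: random trees/models and small reference models.

# Random complete context tree grown by recursive splitting from the root.
random_tree <- function(L = 3L, alphabet = c("0", "1", "2"),
                        p_split = 0.6) {
  grow <- function(w, depth) {
    if (depth == 0L || stats::runif(1) > p_split) return(w)
    unlist(lapply(paste0(alphabet, w), grow, depth = depth - 1L))
  }
  context_tree(grow("", L), alphabet)
}

# Random complete, ergodic model: all transition probabilities positive.
random_model <- function(L = 2L, alphabet = c("0", "1", "2"),
                         p_split = 0.6, floor = 0.05) {
  tree <- random_tree(L, alphabet, p_split)
  m <- length(alphabet)
  probs <- matrix(stats::rexp(length(tree$contexts) * m) + floor, ncol = m)
  probs <- probs / rowSums(probs)
  rownames(probs) <- tree$contexts
  context_tree_model(tree, probs)
}

# Deterministic 3-cycle 0 -> 1 -> 2 -> 0.
cycle_model <- function() {
  context_tree_model(
    context_tree(c("0", "1", "2")),
    rbind("0" = c(0, 1, 0), "1" = c(0, 0, 1), "2" = c(1, 0, 0)),
    name = "cycle"
  )
}

# Order-0 (iid) model with the given distribution.
iid_model <- function(p = c(1, 1, 1) / 3) {
  context_tree_model(context_tree(""),
                     matrix(p, nrow = 1, dimnames = list("", NULL)),
                     name = "iid")
}

tau3 <- function() kicker_model(3)$tree
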