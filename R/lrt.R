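# Likelihood-ratio test: does the response depend on the responder's own
# past beyond the stimulus past?

#' Likelihood-ratio test of conditional independence from own past
#'
#' Tests, for a paired stimulus/response sequence, the null hypothesis
#' that the response at each trial is conditionally independent of the
#' responder's own previous `k` responses given the previous `k_prime`
#' stimulus symbols, against the alternative that both pasts matter. Both
#' hypotheses are fitted by maximum likelihood (stratified multinomial
#' plug-ins) and compared by
#' \deqn{-2\log R = -2\Big[\sum_{w_x,a} N(w_x,a)\log\hat q(a|w_x)
#'   - \sum_{w_x,w_y,a} N(w_x,w_y,a)\log\hat q(a|w_x,w_y)\Big],}
#' which under the null is asymptotically chi-squared. The nominal degrees
#' of freedom are \eqn{(|A|-1)|A|^{k'}(|A|^k - 1)}, the difference in
#' dimension between the two full parameter spaces. When the data contain
#' structural zeros (responses or pasts that never occur — routine for
#' responders locked to a low-entropy model), the nominal count overstates
#' the dimension and makes the test arbitrarily conservative, so by
#' default the degrees of freedom are counted from the observed support:
#' \eqn{\sum_{w_x,w_y}(k_{w_x,w_y}-1) - \sum_{w_x}(k_{w_x}-1)} with
#' \eqn{k} the number of response symbols observed in the stratum. Both
#' counts are reported.
#'
#' @param pair A [paired_sequence()].
#' @param k Length of the own-response past, default 1.
#' @param k_prime Length of the stimulus past, default 1.
#' @param df_method `"observed"` (default) or `"nominal"`: which degrees
#'   of freedom to use for the p-value.
#' @return An object of class `lrt_result`: list with `statistic`, `df`,
#'   `p_value`, `df_nominal`, `df_observed`, `loglik_h0`, `loglik_h1`,
#'   `k`, `k_prime`, `n_used`, `empty_strata_fraction`, and `counts`
#'   (the stratified tables).
#' @examples
#' pr <- simulate_pair(kicker_model(3), 1000, kind = "matching", seed = 1)
#' lrt_independence(pr)
#' @export
lrt_independence <- function(pair, k = 1L, k_prime = 1L,
                             df_method = c("observed", "nominal")) {
  df_method <- match.arg(df_method)
  stopifnot(inherits(pair, "paired_sequence"))
  k <- as.integer(k); kp <- as.integer(k_prime)
  if (k < 1L || kp < 1L) stop("k and k_prime must be >= 1", call. = FALSE)
  n <- pair$n
  m <- length(pair$alphabet)
  start <- max(k, kp) + 1L
  if (n < start + m) stop("insufficient data for the requested pasts",
                          call. = FALSE)
  idx <- start:n
  wx <- rep("", length(idx))
  for (j in 1:kp) wx <- paste0(wx, pair$x[idx - kp + j - 1L])
  wy <- rep("", length(idx))
  for (j in 1:k) wy <- paste0(wy, pair$y[idx - k + j - 1L])
  a <- pair$y[idx]
  tab0 <- table(wx, a)
  tab1 <- table(paste(wx, wy, sep = "|"), a)
  ll_of <- function(tab) {
    nx <- rowSums(tab)
    pos <- tab > 0L
    sum(tab[pos] * log((tab / nx)[pos]))
  }
  ll0 <- ll_of(tab0)
  ll1 <- ll_of(tab1)
  stat <- max(-2 * (ll0 - ll1), 0)
  df_nominal <- as.integer((m - 1L) * m^kp * (m^k - 1L))
  df_of <- function(tab) sum(pmax(rowSums(tab > 0L) - 1L, 0L))
  df_observed <- as.integer(df_of(tab1) - df_of(tab0))
  df_observed <- max(df_observed, 0L)
  df_use <- if (df_method == "observed") df_observed else df_nominal
  p <- if (df_use > 0L) {
    stats::pchisq(stat, df_use, lower.tail = FALSE)
  } else if (stat < 1e-8) 1 else NA_real_
  n_strata_full <- m^kp * m^k
  empty_frac <- 1 - nrow(tab1) / n_strata_full
  structure(
    list(statistic = stat, df = df_use, p_value = p,
         df_nominal = df_nominal, df_observed = df_observed,
         df_method = df_method,
         loglik_h0 = ll0, loglik_h1 = ll1,
         k = k, k_prime = kp, n_used = length(idx),
         empty_strata_fraction = empty_frac,
         counts = list(N_wx_a = tab0, N_wx_wy_a = tab1)),
    class = "lrt_result"
  )
}

#' @export
print.lrt_result <- function(x, ...) {
  cat("Likelihood-ratio test: response vs own past ",
      "(k = ", x$k, ", k' = ", x$k_prime, ")\n", sep = "")
  cat(sprintf("  -2 log R = %.3f, df = %d (%s; nominal %d), p = %.4g\n",
              x$statistic, x$df, x$df_method, x$df_nominal, x$p_value))
  if (x$empty_strata_fraction > 0.1) {
    cat(sprintf("  note: %.0f%% of (stimulus, response)-past strata are empty\n",
                100 * x$empty_strata_fraction))
  }
  invisible(x)
}

#' Type-I error calibration of the independence test
#'
#' Monte-Carlo check of the chi-squared reference: simulates paired
#' sequences whose responses depend on the stimulus only (so the null
#' hypothesis holds by construction), runs the test on each, and reports
#' the rejection rate at level `alpha`.
#'
#' @param model A [context_tree_model()].
#' @param kind Responder kind (an agent whose response ignores its own
#'   past; default `"matching"`).
#' @param n Trials per simulated sequence.
#' @param reps Number of replicates.
#' @param alpha Significance level, default 0.05.
#' @param k,k_prime Past lengths passed to [lrt_independence()].
#' @param seed Optional integer seed.
#' @param df_method Passed to [lrt_independence()].
#' @return List with `rate`, `reps`, `alpha` and the vector of
#'   `p_values`.
#' @export
lrt_type1_calibration <- function(model, kind = "matching", n = 1000L,
                                  reps = 500L, alpha = 0.05,
                                  k = 1L, k_prime = 1L, seed = NULL,
                                  df_method = "observed") {
  with_seed(seed, {
    p_values <- vapply(seq_len(reps), function(r) {
      x <- simulate_chain(model, n)
      y <- respond(model, x, kind = kind)
      lrt_independence(paired_sequence(x, y, model$tree$alphabet),
                       k = k, k_prime = k_prime,
                       df_method = df_method)$p_value
    }, numeric(1))
    list(rate = mean(p_values < alpha), reps = reps, alpha = alpha,
         p_values = p_values)
  })
}
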