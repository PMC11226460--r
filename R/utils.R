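# Internal helpers shared across modules.

# Evaluate `code` with a private RNG state. If `seed` is NULL the global
# stream is used (and advanced); otherwise the caller's .Random.seed is
# restored afterwards so seeded calls never perturb the session stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer or NULL", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

# Map symbols (character) to integer codes 1..m; error on foreign symbols.
symbol_codes <- function(x, alphabet) {
  codes <- match(as.character(x), alphabet)
  if (anyNA(codes)) {
    bad <- unique(as.character(x)[is.na(codes)])
    stop("symbol(s) not in alphabet: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  codes
}

# All strings of length `len` over `alphabet`, oldest-first digit order,
# enumerated so that string index matches past_index() below.
all_strings <- function(alphabet, len) {
  if (len == 0L) return("")
  m <- length(alphabet)
  idx <- 0:(m^len - 1L)
  out <- rep("", length(idx))
  for (j in seq_len(len) - 1L) {
    # digit j is the j-th most recent symbol: rightmost char first, prepend
    digit <- (idx %/% m^j) %% m
    out <- paste0(alphabet[digit + 1L], out)
  }
  out
}

# Index (1-based) of a past of length H given integer codes, most recent
# symbol = lowest digit. `codes` is oldest-first.
past_index <- function(codes, m) {
  h <- length(codes)
  if (h == 0L) return(1L)
  sum((rev(codes) - 1L) * m^(0:(h - 1L))) + 1L
}

# Vectorised past indices for positions 1..n of a coded sequence `z`
# (length n + h, the first h entries being the initial past). Row t gives
# the index of the length-h past preceding position t.
rolling_past_index <- function(z, n, h, m) {
  if (h == 0L) return(rep(1L, n))
  idx <- rep(1L, n)
  acc <- numeric(n)
  for (j in 0:(h - 1L)) {
    # j-th most recent symbol before position t is z[t + h - 1 - j]
    acc <- acc + (z[(1:n) + h - 1L - j] - 1L) * m^j
  }
  as.integer(acc + 1L)
}

# All suffixes of a string, longest first, excluding the empty string.
suffixes_of <- function(w) {
  l <- nchar(w)
  if (l == 0L) return(character(0))
  substring(w, 1:l, l)
}

is_proper_suffix <- function(u, w) {
  lu <- nchar(u); lw <- nchar(w)
  lu < lw && substring(w, lw - lu + 1L, lw) == u
}

# Canonical ordering of context strings: by length, then lexicographic in
# alphabet order (mapped through symbol codes so alphabets need not sort
# alphabetically).
order_contexts <- function(contexts, alphabet) {
  key <- vapply(contexts, function(w) {
    if (nchar(w) == 0L) return("")
    paste(sprintf("%02d", symbol_codes(strsplit(w, "")[[1]], alphabet)),
          collapse = "")
  }, character(1))
  order(nchar(contexts), key)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
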