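# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Naive O(n * o) window-scan transition counter: builds each state string by
# pasting the lagged symbols and tallies into a named matrix.
naive_count_oracle <- function(x, symbols, o, gap = NULL) {
  n <- length(x)
  h <- if (is.null(gap)) o else gap
  k <- if (is.null(gap)) o else o + 1L
  tuples <- expand.grid(rep(list(symbols), k), stringsAsFactors = FALSE)
  # lexical order: first tuple position most significant
  ord <- do.call(order, tuples[, seq_len(k), drop = FALSE])
  states <- apply(tuples[ord, , drop = FALSE], 1L, paste, collapse = "")
  mat <- matrix(0L, length(states), length(symbols),
                dimnames = list(states, symbols))
  if (n > h) {
    for (t in (h + 1L):n) {
      s <- if (is.null(gap)) {
        paste(x[(t - o):(t - 1L)], collapse = "")
      } else {
        paste(c(x[t - gap], x[(t - o):(t - 1L)]), collapse = "")
      }
      mat[s, x[t]] <- mat[s, x[t]] + 1L
    }
  }
  mat
}

# Minimum expected codeword length over all monotone integer length vectors
# satisfying the Kraft inequality (exhaustive search; m <= 6).
min_expected_codelength <- function(p) {
  p <- sort(p[p > 0], decreasing = TRUE)
  m <- length(p)
  if (m == 1L) return(1)
  best <- Inf
  gen <- function(lens) {
    i <- length(lens) + 1L
    if (i > m) {
      if (sum(2^-lens) <= 1 + 1e-12) best <<- min(best, sum(p * lens))
      return(invisible())
    }
    lo <- if (i == 1L) 1L else lens[i - 1L]
    for (l in lo:m) gen(c(lens, l))
  }
  gen(integer(0))
  best
}

# Expected codeword length of a codebook under a named weight vector.
codebook_expected_length <- function(book, weights) {
  w <- weights[book$symbols]
  sum(w * book$lengths) / sum(w)
}

# Shannon entropy (base 2) of a probability vector.
entropy2 <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

# A random probability vector over m symbols.
random_prob <- function(m) {
  g <- rgamma(m, shape = 1)
  g / sum(g)
}

# A small random count table shaped like a pmm_counts object.
random_count_table <- function(seed, m = 2L, o = 2L, n = 600L) {
  set.seed(seed)
  ab <- alphabet(if (m == 2L) c("0", "1") else letters[seq_len(m)])
  x <- sample(as.character(ab), n, replace = TRUE,
              prob = random_prob(m))
  suppressWarnings(count_transitions(x, ab, model_spec(o)))
}
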