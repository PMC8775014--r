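#' Count state-to-symbol transitions in a sample
#'
#' For a sample `x` of length `n` and an order-`o` model, `N(s, a)` is the
#' number of positions `t` with `o < t <= n` whose preceding `o`-tuple is
#' `s` and whose symbol is `a`. With a gap `G` the window additionally
#' includes the symbol at lag `G` and `t` ranges over `G < t <= n`.
#' Counting never wraps around and stays within the single sequence given.
#'
#' @param x Sequence: character vector of symbols, or a single string.
#' @param alphabet A [alphabet()].
#' @param spec A [model_spec()] (or a plain order).
#' @return An object of class `pmm_counts`: a list with the count matrix
#'   (`states x symbols`), marginals, sample length `n`, and the state
#'   space.
#' @examples
#' ct <- count_transitions("caabacba", alphabet(c("a", "b", "c")), 1)
#' ct$counts
#' @export
count_transitions <- function(x, alphabet, spec) {
  alphabet <- as_alphabet(alphabet)
  spec <- as_spec(spec)
  x <- as_symbols(x)
  n <- length(x)
  h <- history_length(spec)
  if (n <= h) {
    stop(sprintf("sample too short: need length > %d, got %d", h, n),
         call. = FALSE)
  }
  m <- length(alphabet)
  o <- spec$order
  if (o >= floor(log(n, base = max(m, 2L))) - 1) {
    warning(sprintf(
      "order %d is large for a sample of length %d over %d symbols; the recommended bound is o < floor(log_|A|(n)) - 1",
      o, n, m), call. = FALSE)
  }
  xi <- symbol_indices(x, alphabet)
  states <- enumerate_states(alphabet, spec)
  k <- state_tuple_length(spec)
  lags <- if (is.null(spec$gap)) o:1 else c(spec$gap, o:1)
  tt <- (h + 1L):n
  id <- rep(1, length(tt))
  for (j in seq_len(k)) {
    id <- id + (xi[tt - lags[j]] - 1) * m^(k - j)
  }
  cell <- (id - 1) * m + xi[tt]
  tab <- tabulate(cell, nbins = length(states) * m)
  counts <- matrix(tab, nrow = length(states), ncol = m, byrow = TRUE,
                   dimnames = list(as.character(states), as.character(alphabet)))
  structure(
    list(counts = counts, marginals = rowSums(counts), n = n,
         alphabet = alphabet, spec = spec, states = as.character(states)),
    class = "pmm_counts"
  )
}

#' @export
print.pmm_counts <- function(x, ...) {
  cat(sprintf("Transition counts: n = %d, order = %d%s, %d states x %d symbols (%d observed states)\n",
              x$n, x$spec$order,
              if (is.null(x$spec$gap)) "" else sprintf(", gap = %d", x$spec$gap),
              nrow(x$counts), ncol(x$counts), sum(x$marginals > 0)))
  print(x$counts, ...)
  invisible(x)
}

#' Construct a partition of a state space
#'
#' A partition groups states into disjoint, covering parts. Parts are
#' renumbered by first appearance when scanning states in lexical order,
#' the canonical numbering used for serialisation.
#'
#' @param index_of Integer vector of part labels, one per state, in lexical
#'   state order (labels are arbitrary; they are renumbered). May be named
#'   by state.
#' @param states Character vector of states in lexical order.
#' @return An object of class `pmm_partition` with elements `index_of`
#'   (named integer vector), `parts` (list of character vectors), and
#'   `n_parts`.
#' @examples
#' st <- enumerate_states(alphabet(c("0", "1")), 3)
#' partition(c(1, 2, 2, 1, 1, 2, 3, 1), st)
#' @export
partition <- function(index_of, states) {
  states <- as.character(states)
  index_of <- as.integer(index_of)
  if (length(index_of) != length(states)) {
    stop("`index_of` must assign a part to every state", call. = FALSE)
  }
  if (anyNA(index_of)) stop("part labels must not be NA", call. = FALSE)
  # renumber by first appearance in lexical scan order
  first <- unique(index_of)
  idx <- match(index_of, first)
  names(idx) <- states
  parts <- split(states, idx)
  parts <- parts[order(as.integer(names(parts)))]
  names(parts) <- NULL
  structure(
    list(index_of = idx, parts = parts, n_parts = length(parts)),
    class = "pmm_partition"
  )
}

singleton_partition <- function(states) {
  partition(seq_along(states), states)
}

#' @export
print.pmm_partition <- function(x, ...) {
  cat(sprintf("Partition of %d states into %d parts\n",
              length(x$index_of), x$n_parts))
  for (i in seq_along(x$parts)) {
    cat(sprintf("  L%d: {%s}\n", i, paste(x$parts[[i]], collapse = ", ")))
  }
  invisible(x)
}

#' Aggregate state-level transition counts to part level
#'
#' `N(L, a) = sum over s in L of N(s, a)`; aggregation preserves the column
#' totals of the state-level table.
#'
#' @param counts A `pmm_counts` object or a plain count matrix with states
#'   as rows.
#' @param partition A [partition()] over the same state space.
#' @return Count matrix with one row per part (`L1`, `L2`, ...).
#' @export
aggregate_counts <- function(counts, partition) {
  mat <- if (inherits(counts, "pmm_counts")) counts$counts else counts
  if (nrow(mat) != length(partition$index_of) ||
      !identical(rownames(mat), names(partition$index_of))) {
    stop("partition does not match the count table's state space",
         call. = FALSE)
  }
  grp <- factor(partition$index_of, levels = seq_len(partition$n_parts))
  agg <- rowsum(mat, grp)
  rownames(agg) <- paste0("L", seq_len(partition$n_parts))
  agg
}

#' Conditional transition probabilities from counts
#'
#' Each row of the returned matrix is `N(., a) / N(.)`, the maximum
#' likelihood estimate of the conditional law of the next symbol given the
#' state (or part). Rows with zero marginal count are left as `NA` and
#' flagged in the `unobserved` attribute rather than estimated.
#'
#' @param counts A `pmm_counts` object or a count matrix (states or parts
#'   as rows).
#' @return Row-stochastic matrix of the same shape, with attribute
#'   `unobserved` listing zero-marginal rows.
#' @export
transition_probs <- function(counts) {
  mat <- if (inherits(counts, "pmm_counts")) counts$counts else counts
  marg <- rowSums(mat)
  if (all(marg == 0)) stop("count table has no data", call. = FALSE)
  probs <- mat / marg
  probs[marg == 0, ] <- NA_real_
  attr(probs, "unobserved") <- rownames(mat)[marg == 0]
  probs
}

#' Conditional distribution of a block of symbols given a state
#'
#' The probability of a `b`-symbol block following state `s` is the product
#' of one-step transition probabilities, each conditioned on the `o`-tuple
#' preceding the corresponding in-block position (sliding through the
#' concatenation of `s` and the block). Blocks are enumerated in lexical
#' order. Only contiguous (gap-free) models admit `b > 1`.
#'
#' @param probs Row-stochastic state-level probability matrix, rows named
#'   by states in lexical order (as from [transition_probs()]).
#' @param state State string whose block law is required.
#' @param b Block size (`>= 1`).
#' @param alphabet A [alphabet()].
#' @param order Model order `o` matching `probs`.
#' @param missing How to treat a state reachable within the block whose row
#'   is not estimated (`NA`): `"error"` raises; `"zero"` assigns zero mass
#'   to continuations through it, which is what the codec uses — a block
#'   that actually occurs in the sample never passes through an unobserved
#'   intermediate state, so encoder and decoder still agree on every
#'   realizable block.
#' @return Named numeric vector of length `|A|^b`, summing to one (up to
#'   the mass removed under `missing = "zero"`).
#' @examples
#' ab <- alphabet(c("a", "b", "c"))
#' p <- example_conditional_chain()$probs
#' block_transition_probs(p, "a", 2, ab, 1)[["aa"]]
#' @export
block_transition_probs <- function(probs, state, b, alphabet, order,
                                   missing = c("error", "zero")) {
  missing <- match.arg(missing)
  alphabet <- as_alphabet(alphabet)
  b <- as.integer(b)
  if (is.na(b) || b < 1L) stop("`b` must be an integer >= 1", call. = FALSE)
  m <- length(alphabet)
  o <- as.integer(order)
  if (nrow(probs) != m^o) {
    stop("`probs` must have one row per contiguous order-`o` state",
         call. = FALSE)
  }
  sid <- match(state, rownames(probs))
  if (is.na(sid)) stop("unknown state: ", state, call. = FALSE)
  p <- 1
  ctx <- sid
  for (i in seq_len(b)) {
    rows <- probs[ctx, , drop = FALSE]
    if (anyNA(rows)) {
      na_row <- is.na(rows[, 1L])
      if (missing == "error" && any(na_row & p > 0)) {
        bad <- rownames(probs)[ctx[which(na_row & p > 0)[1L]]]
        stop(sprintf(
          "state '%s' reachable within the block has no estimated row", bad),
          call. = FALSE)
      }
      rows[na_row, ] <- 0
    }
    p <- as.vector(t(rows * p))
    ctx <- as.vector(t(outer(((ctx - 1L) %% m^(o - 1)) * m, seq_len(m), "+")))
  }
  blocks <- ""
  for (i in seq_len(b)) {
    blocks <- as.vector(t(outer(blocks, unclass(alphabet), paste0)))
  }
  names(p) <- blocks
  p
}
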