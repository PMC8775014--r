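# x * log(x / total) with the 0 * log 0 = 0 convention, rowwise.
row_loglik <- function(mat) {
  tot <- rowSums(mat)
  ll <- mat * log(mat / tot)
  ll[mat == 0] <- 0
  out <- rowSums(ll)
  out[tot == 0] <- 0
  out
}

#' Log pseudo-likelihood of a partition
#'
#' `sum over parts L and symbols a of N(L, a) * ln(N(L, a) / N(L))`, the
#' log of the pseudo maximum likelihood given the partition, restricted to
#' parts with positive counts (`0 * ln 0 = 0`).
#'
#' @param part_counts Count matrix at part (or state) level.
#' @return Nonpositive scalar.
#' @export
log_pseudo_likelihood <- function(part_counts) {
  mat <- if (inherits(part_counts, "pmm_counts")) part_counts$counts else part_counts
  sum(row_loglik(mat))
}

#' BIC of a partition for a sample
#'
#' `BIC = ln ML(L, x) - (|A| - 1) |L| / 2 * ln(n)`, where `ln ML` is the
#' log pseudo-likelihood of the partition and `|L|` counts the parts with
#' positive counts (empty parts contribute no parameters).
#'
#' @param counts A `pmm_counts` object (state-level counts).
#' @param partition A [partition()]; defaults to singleton states.
#' @param n Sample length; defaults to the count table's.
#' @return List of class `pmm_bic` with `log_pseudo_likelihood`, `penalty`,
#'   and `bic`.
#' @export
bic_value <- function(counts, partition = NULL, n = NULL) {
  if (is.null(n)) n <- counts$n
  if (n <= 1) stop("`n` must exceed 1", call. = FALSE)
  m <- length(counts$alphabet)
  agg <- if (is.null(partition)) counts$counts else aggregate_counts(counts, partition)
  npart <- sum(rowSums(agg) > 0)
  ll <- log_pseudo_likelihood(agg)
  pen <- (m - 1) * npart / 2 * log(n)
  structure(list(log_pseudo_likelihood = ll, penalty = pen, bic = ll - pen),
            class = "pmm_bic")
}

#' @export
print.pmm_bic <- function(x, ...) {
  cat(sprintf("BIC = %.4f (log pseudo-likelihood %.4f, penalty %.4f)\n",
              x$bic, x$log_pseudo_likelihood, x$penalty))
  invisible(x)
}

#' Estimate the partition of the state space by BIC agglomeration
#'
#' Greedy agglomerative maximisation of the BIC: starting from singleton
#' parts over the observed states, repeatedly merge the pair of parts whose
#' merge yields the largest strictly positive BIC gain, and stop when no
#' merge improves the BIC. Ties are broken towards the pair with the
#' smallest part indices. If the single-part partition scores higher than
#' the greedy result it is returned instead, so the returned BIC is at
#' least `max(BIC(singletons), BIC(one part))`.
#'
#' Unobserved states (zero marginal count) take no role in the estimation;
#' for serialisation they are attached to the estimated part with index 1,
#' and the result is renumbered by first appearance in lexical order. The
#' `observed` attribute records which states carried data.
#'
#' @param counts A `pmm_counts` object.
#' @return A [partition()] over the full state space, with attributes
#'   `observed` and `bic` (the achieved `pmm_bic`).
#' @export
estimate_partition <- function(counts) {
  mat <- counts$counts
  n <- counts$n
  m <- ncol(mat)
  obs <- which(rowSums(mat) > 0)
  if (length(obs) == 0L) stop("no observed states", call. = FALSE)
  pen_gain <- (m - 1) / 2 * log(n) # penalty saved by removing one part
  rows <- mat[obs, , drop = FALSE]
  K <- nrow(rows)
  group <- seq_len(K) # part id per observed state
  if (K > 1L) {
    ll <- row_loglik(rows)
    # gain[i, j] (i < j): BIC change from merging parts i and j
    gain <- matrix(-Inf, K, K)
    for (i in seq_len(K - 1L)) {
      js <- (i + 1L):K
      merged <- rows[js, , drop = FALSE] +
        matrix(rows[i, ], length(js), m, byrow = TRUE)
      gain[i, js] <- row_loglik(merged) - ll[i] - ll[js] + pen_gain
    }
    alive <- rep(TRUE, K)
    repeat {
      best <- max(gain)
      if (best <= 0) break
      hits <- which(gain == best, arr.ind = TRUE)
      hit <- hits[order(hits[, 1L], hits[, 2L])[1L], ]
      i <- hit[[1L]]; j <- hit[[2L]]
      rows[i, ] <- rows[i, ] + rows[j, ]
      ll[i] <- row_loglik(rows[i, , drop = FALSE])
      alive[j] <- FALSE
      group[group == j] <- i
      gain[j, ] <- -Inf
      gain[, j] <- -Inf
      others <- which(alive)
      others <- others[others != i]
      if (length(others)) {
        merged <- rows[others, , drop = FALSE] +
          matrix(rows[i, ], length(others), m, byrow = TRUE)
        g <- row_loglik(merged) - ll[i] - ll[others] + pen_gain
        lo <- pmin(others, i)
        hi <- pmax(others, i)
        gain[cbind(lo, hi)] <- g
      }
      if (sum(alive) == 1L) break
    }
  }
  # fall back to the one-part partition if it scores higher
  idx_obs <- match(group, unique(group))
  cand <- rep(1L, length(counts$states))
  cand[obs] <- idx_obs
  part <- partition(cand, counts$states)
  one <- partition(rep(1L, length(counts$states)), counts$states)
  b_part <- bic_value(counts, part)
  b_one <- bic_value(counts, one)
  if (b_one$bic > b_part$bic) {
    part <- one
    b_part <- b_one
  }
  attr(part, "observed") <- counts$states[obs]
  attr(part, "bic") <- b_part
  part
}

#' Exhaustive BIC maximisation over all set partitions
#'
#' Brute-force oracle for small state spaces: enumerates every partition of
#' the observed states (via restricted growth strings) and returns the one
#' with maximal BIC. Intended for validating [estimate_partition()] on
#' state spaces of up to about five observed states.
#'
#' @param counts A `pmm_counts` object with few observed states.
#' @return A [partition()] over the full state space with attribute `bic`.
#' @export
exhaustive_partition_search <- function(counts) {
  obs <- which(rowSums(counts$counts) > 0)
  K <- length(obs)
  if (K > 9L) stop("exhaustive search is limited to 9 observed states",
                   call. = FALSE)
  best <- NULL
  best_bic <- -Inf
  assign_rec <- function(labels, k) {
    if (length(labels) == K) {
      cand <- rep(1L, length(counts$states))
      cand[obs] <- labels
      part <- partition(cand, counts$states)
      b <- bic_value(counts, part)
      if (b$bic > best_bic) {
        best_bic <<- b$bic
        best <<- part
        attr(best, "bic") <<- b
      }
      return(invisible())
    }
    for (lab in seq_len(k + 1L)) {
      assign_rec(c(labels, lab), max(k, lab))
    }
  }
  assign_rec(integer(0), 0L)
  attr(best, "observed") <- counts$states[obs]
  best
}

#' Plug-in entropy estimate from a fitted partition
#'
#' Estimates the per-symbol entropy of the process in base `D` as
#' `-ln ML(L, x) / (n ln D)`, which is algebraically identical to the
#' weighted plug-in form `sum over L of (N(L)/n) * H_L` built from the
#' empirical conditional laws of the parts.
#'
#' @param counts A `pmm_counts` object.
#' @param partition A [partition()] (typically from
#'   [estimate_partition()]).
#' @param D Code alphabet size (base of the entropy), `>= 2`.
#' @param denominator `"n"` divides by the sample length as in the
#'   estimator's definition; `"transitions"` divides by the number of
#'   counted transitions (`n - o`, or `n - G` with a gap).
#' @return Object of class `pmm_entropy`: list with `value`, `D`, and
#'   `source`.
#' @export
entropy_plugin <- function(counts, partition, D = 2,
                           denominator = c("n", "transitions")) {
  if (D < 2) stop("`D` must be at least 2", call. = FALSE)
  denominator <- match.arg(denominator)
  agg <- aggregate_counts(counts, partition)
  denom <- if (denominator == "n") counts$n else sum(agg)
  value <- -log_pseudo_likelihood(agg) / (denom * log(D))
  structure(list(value = value, D = D, source = "plug-in"),
            class = "pmm_entropy")
}

#' Entropy of a known partition Markov model
#'
#' For a stationary order-`o` chain whose states are partitioned into parts
#' with shared conditional laws, the entropy rate in base `D` is
#' `-sum over L of P(L) sum over a of P(a|L) log_D P(a|L)`.
#'
#' @param pmm A [pmm()] with part weights.
#' @param D Base of the entropy.
#' @return Object of class `pmm_entropy`.
#' @export
entropy_closed_form <- function(pmm, D = 2) {
  if (D < 2) stop("`D` must be at least 2", call. = FALSE)
  w <- pmm$part_weights
  if (is.null(w)) {
    stop("the model carries no part weights", call. = FALSE)
  }
  if (abs(sum(w) - 1) > 1e-8) {
    stop("part weights must sum to 1", call. = FALSE)
  }
  p <- pmm$cond_probs
  h <- p * log(p, base = D)
  h[p == 0] <- 0
  value <- -sum(w * rowSums(h))
  structure(list(value = value, D = D, source = "closed-form"),
            class = "pmm_entropy")
}

#' @export
print.pmm_entropy <- function(x, ...) {
  cat(sprintf("Entropy estimate (%s): %.6f (base %g, per symbol)\n",
              x$source, x$value, x$D))
  invisible(x)
}

#' Estimated minimum expected codeword length per symbol
#'
#' The plug-in entropy of the fitted model is also the estimate of the
#' minimum expected codeword length per symbol attainable by an optimal
#' block code, which the realised per-symbol rate of the block codec
#' approaches from above as the block size grows.
#'
#' @inheritParams entropy_plugin
#' @return Numeric scalar (code symbols per source symbol).
#' @export
min_codeword_rate <- function(counts, partition, D = 2,
                              denominator = c("n", "transitions")) {
  entropy_plugin(counts, partition, D, denominator)$value
}
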