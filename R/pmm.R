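#' Construct a partition Markov model
#'
#' A partition Markov model (PMM) is an order-`o` Markov chain whose states
#' are grouped into parts sharing one conditional law each: the parameters
#' are one probability row per part instead of one per state. A minimal PMM
#' has pairwise distinct part rows.
#'
#' @param alphabet A [alphabet()].
#' @param spec A [model_spec()] (or plain order).
#' @param partition A [partition()] over the state space of `spec`.
#' @param cond_probs Matrix of conditional probabilities, one row per part
#'   (rows sum to 1), columns in alphabet order.
#' @param part_weights Optional vector `P(L)` per part (sums to 1). Needed
#'   for the closed-form entropy; estimated models carry `N(L)/(n - o)`.
#' @return Object of class `pmm`.
#' @export
pmm <- function(alphabet, spec, partition, cond_probs, part_weights = NULL) {
  alphabet <- as_alphabet(alphabet)
  spec <- as_spec(spec)
  states <- enumerate_states(alphabet, spec)
  if (length(partition$index_of) != length(states)) {
    stop("partition does not cover the state space", call. = FALSE)
  }
  if (nrow(cond_probs) != partition$n_parts ||
      ncol(cond_probs) != length(alphabet)) {
    stop("`cond_probs` must be |L| x |A|", call. = FALSE)
  }
  if (any(abs(rowSums(cond_probs) - 1) > 1e-12)) {
    stop("conditional probability rows must sum to 1", call. = FALSE)
  }
  if (!is.null(part_weights)) {
    if (length(part_weights) != partition$n_parts) {
      stop("need one weight per part", call. = FALSE)
    }
    if (abs(sum(part_weights) - 1) > 1e-12) {
      stop("part weights must sum to 1", call. = FALSE)
    }
  }
  rownames(cond_probs) <- paste0("L", seq_len(partition$n_parts))
  colnames(cond_probs) <- unclass(alphabet)
  structure(
    list(alphabet = alphabet, spec = spec, states = as.character(states),
         partition = partition, cond_probs = cond_probs,
         part_weights = part_weights),
    class = "pmm"
  )
}

# Expand part-level probability rows to a full state-level matrix.
state_probs <- function(pmm_or_fit) {
  x <- pmm_or_fit
  probs <- x$cond_probs[x$partition$index_of, , drop = FALSE]
  rownames(probs) <- x$states
  probs
}

#' @export
print.pmm <- function(x, ...) {
  cat(sprintf("Partition Markov model: |A| = %d, order = %d%s, %d states in %d parts\n",
              length(x$alphabet), x$spec$order,
              if (is.null(x$spec$gap)) "" else sprintf(", gap = %d", x$spec$gap),
              length(x$states), x$partition$n_parts))
  print(round(x$cond_probs, 4))
  invisible(x)
}

#' Fit a partition Markov model to a sequence
#'
#' Counts transitions, estimates the partition of the state space by BIC
#' agglomeration, and returns the fitted model together with its BIC,
#' plug-in entropy, and estimated minimum expected codeword length per
#' symbol.
#'
#' @param x Sequence (character vector of symbols or single string).
#' @param alphabet A [alphabet()].
#' @param order Memory order `o`.
#' @param gap Optional gap lag `G > o`.
#' @param D Base for the entropy estimate (2 for bits).
#' @return Object of class `pmm_fit`: the fitted `pmm` plus `counts`,
#'   `bic`, `entropy`, and `min_rate`.
#' @examples
#' set.seed(1)
#' ab <- alphabet(c("0", "1"))
#' x <- sample(c("0", "1"), 2000, replace = TRUE)
#' fit <- fit_pmm(x, ab, order = 2)
#' glance(fit)
#' @export
fit_pmm <- function(x, alphabet, order, gap = NULL, D = 2) {
  alphabet <- as_alphabet(alphabet)
  spec <- model_spec(order = order, gap = gap)
  counts <- count_transitions(x, alphabet, spec)
  part <- estimate_partition(counts)
  agg <- aggregate_counts(counts, part)
  marg <- rowSums(agg)
  probs <- agg / ifelse(marg > 0, marg, 1)
  # empty parts cannot arise: every part holds at least one observed state
  # except possibly part 1 when all its states are unobserved, which the
  # estimator's renumbering prevents.
  weights <- marg / sum(marg)
  model <- pmm(alphabet, spec, part, probs, part_weights = weights)
  ent <- entropy_plugin(counts, part, D = D)
  structure(
    c(unclass(model),
      list(counts = counts, bic = attr(part, "bic"), entropy = ent,
           min_rate = ent$value)),
    class = c("pmm_fit", "pmm")
  )
}

#' @export
print.pmm_fit <- function(x, ...) {
  NextMethod()
  cat(sprintf("n = %d, BIC = %.2f, entropy (base %g) = %.4f per symbol\n",
              x$counts$n, x$bic$bic, x$entropy$D, x$entropy$value))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted partition Markov model
#'
#' One row per (part, symbol) with the estimated conditional probability,
#' the part-level count, and the part's member states.
#'
#' @param x A `pmm_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.pmm_fit <- function(x, ...) {
  agg <- aggregate_counts(x$counts, x$partition)
  k <- x$partition$n_parts
  m <- length(x$alphabet)
  tibble::tibble(
    part = rep(seq_len(k), each = m),
    symbol = rep(as.character(x$alphabet), times = k),
    count = as.vector(t(agg)),
    prob = as.vector(t(x$cond_probs)),
    states = rep(vapply(x$partition$parts, paste, "", collapse = ","), each = m)
  )
}

#' One-line model summary of a fitted PMM
#'
#' @param x A `pmm_fit`.
#' @param ... Unused.
#' @return A one-row tibble with sample size, order, state and part counts,
#'   log pseudo-likelihood, BIC, entropy, and the estimated minimum
#'   codeword rate.
#' @export
glance.pmm_fit <- function(x, ...) {
  tibble::tibble(
    n = x$counts$n,
    order = x$spec$order,
    gap = if (is.null(x$spec$gap)) NA_integer_ else x$spec$gap,
    n_states = length(x$states),
    n_parts = x$partition$n_parts,
    log_pseudo_likelihood = x$bic$log_pseudo_likelihood,
    bic = x$bic$bic,
    entropy = x$entropy$value,
    min_codeword_rate = x$min_rate
  )
}

#' Plot the conditional laws of a fitted PMM
#'
#' Tile map of the estimated `P(a | L)` by part and symbol.
#'
#' @param object A `pmm_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pmm_fit <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$symbol,
                                  y = factor(.data$part),
                                  fill = .data$prob)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$prob)),
                       colour = "white") +
    ggplot2::labs(x = "next symbol", y = "part",
                  fill = "P(a | L)",
                  title = "Conditional transition laws by part") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
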