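#' Huffman codelengths for a weight vector
#'
#' Runs the binary Huffman merge on the positive-weight symbols and returns
#' the codelength sequence in canonical order: symbols sorted by ascending
#' codelength, ties broken by descending weight and then by the symbols'
#' lexical order (their position in the input, which must be lexical).
#' Because Huffman lengths are nonincreasing in weight, this is the usual
#' "nonincreasing probability" ordering whenever weights are exact; sorting
#' on the length first keeps the ordering stable when analytically equal
#' weights differ by floating-point noise. Ties in the two-minimum
#' selection are broken towards the group whose lexically smallest member
#' comes first, which makes the construction deterministic.
#'
#' A single positive-weight symbol is assigned length 1 (its codeword will
#' be `"0"`). Zero-weight symbols receive no codeword; callers reconstruct
#' the same support from transmitted frequencies, so encoder and decoder
#' codebooks agree.
#'
#' @param weights Named nonnegative numeric vector in lexical symbol order
#'   (probabilities or raw counts; only ratios matter).
#' @return An object of class `pmm_codelengths`: list with `symbols`
#'   (canonical order) and `lengths` (nondecreasing integers).
#' @examples
#' huffman_codelengths(c(a = 1, b = 4, c = 3, d = 2, e = 1) / 11)
#' @export
huffman_codelengths <- function(weights) {
  if (is.null(names(weights))) {
    names(weights) <- as.character(seq_along(weights))
  }
  w0 <- weights
  keep <- which(weights > 0)
  if (length(keep) == 0L) {
    stop("all weights are zero: nothing to code", call. = FALSE)
  }
  syms <- names(weights)[keep]
  w <- as.numeric(weights[keep])
  m <- length(w)
  len <- integer(m)
  if (m == 1L) {
    len <- 1L
  } else {
    # groups: weight, lexical rank of smallest member, member indices
    gw <- w
    grank <- seq_len(m)
    members <- as.list(seq_len(m))
    active <- rep(TRUE, m + m - 1L) # room for merged groups
    gw <- c(gw, rep(NA_real_, m - 1L))
    grank <- c(grank, rep(NA_integer_, m - 1L))
    members <- c(members, vector("list", m - 1L))
    nxt <- m + 1L
    n_active <- m
    while (n_active > 1L) {
      act <- which(active[seq_len(nxt - 1L)])
      ww <- gw[act]
      i1 <- act[order(ww, grank[act])[1:2]]
      I <- i1[1L]; J <- i1[2L]
      mem <- c(members[[I]], members[[J]])
      len[mem] <- len[mem] + 1L
      active[c(I, J)] <- FALSE
      gw[nxt] <- gw[I] + gw[J]
      grank[nxt] <- min(grank[I], grank[J])
      members[[nxt]] <- mem
      active[nxt] <- TRUE
      nxt <- nxt + 1L
      n_active <- n_active - 1L
    }
  }
  ord <- order(len, -w, seq_len(m))
  structure(
    list(symbols = syms[ord], lengths = len[ord]),
    class = "pmm_codelengths"
  )
}

#' @export
print.pmm_codelengths <- function(x, ...) {
  cat("Canonical codelengths:\n")
  print(stats::setNames(x$lengths, x$symbols))
  invisible(x)
}

kraft_sum <- function(lengths, D = 2) sum(D^(-lengths))

#' Canonical Huffman codebook from a codelength sequence
#'
#' The first codeword is `l_1` zeros; each subsequent codeword is the
#' previous one plus one in binary, shifted left (zero-padded on the right)
#' when the codelength increases. The result is prefix-free whenever the
#' lengths are nondecreasing and satisfy the Kraft inequality.
#'
#' @param codelengths A `pmm_codelengths` object, or a character vector of
#'   symbols (then `lengths` must be given).
#' @param lengths Integer codelengths, nondecreasing, when `codelengths` is
#'   a plain symbol vector.
#' @return An object of class `pmm_codebook`: list with `symbols`,
#'   `lengths`, and `codewords` (named character vector of bit strings).
#' @examples
#' canonical_codebook(c("b", "c", "d", "a", "e"), c(1, 2, 3, 4, 4))
#' @export
canonical_codebook <- function(codelengths, lengths = NULL) {
  if (inherits(codelengths, "pmm_codelengths")) {
    symbols <- codelengths$symbols
    lengths <- codelengths$lengths
  } else {
    symbols <- as.character(codelengths)
  }
  lengths <- as.integer(lengths)
  if (length(symbols) != length(lengths) || length(symbols) == 0L) {
    stop("need one codelength per symbol", call. = FALSE)
  }
  if (is.unsorted(lengths)) {
    stop("codelengths must be nondecreasing in canonical symbol order",
         call. = FALSE)
  }
  if (any(lengths < 1L) || any(lengths > 53L)) {
    stop("codelengths must lie in [1, 53]", call. = FALSE)
  }
  if (kraft_sum(lengths) > 1 + 1e-12) {
    stop("codelengths violate the Kraft inequality", call. = FALSE)
  }
  m <- length(symbols)
  cw <- character(m)
  code <- 0
  cw[1L] <- strrep("0", lengths[1L])
  if (m > 1L) {
    for (i in 2L:m) {
      code <- (code + 1) * 2^(lengths[i] - lengths[i - 1L])
      cw[i] <- int_to_bitstr(code, lengths[i])
    }
  }
  names(cw) <- symbols
  structure(
    list(symbols = symbols, lengths = stats::setNames(lengths, symbols),
         codewords = cw, canonical = TRUE),
    class = "pmm_codebook"
  )
}

#' @export
print.pmm_codebook <- function(x, ...) {
  cat("Canonical Huffman codebook:\n")
  print(x$codewords)
  invisible(x)
}

#' Conditional canonical Huffman codebooks per context
#'
#' Builds one canonical codebook per conditioning context (state or part)
#' from a row-stochastic probability matrix or a count table. For block
#' size `b > 1` the codebook covers the `b`-symbol blocks with positive
#' conditional probability, computed by [block_transition_probs()] from the
#' state-level rows.
#'
#' @param probs Row-stochastic matrix: rows are contexts in lexical (or
#'   part-index) order; `NA` rows are skipped. For `b > 1` the rows must be
#'   at state level.
#' @param b Block size.
#' @param alphabet A [alphabet()] (required for `b > 1`).
#' @param order Model order (required for `b > 1`).
#' @return Named list of `pmm_codebook`s, one per context with an estimated
#'   row; attributes `b` and `granularity`.
#' @examples
#' p <- example_conditional_chain()$probs
#' conditional_codebooks(p)[["a"]]$codewords
#' @export
conditional_codebooks <- function(probs, b = 1L, alphabet = NULL,
                                  order = NULL) {
  b <- as.integer(b)
  ctxs <- rownames(probs)
  if (is.null(ctxs) || nrow(probs) == 0L) {
    stop("`probs` must have at least one named context row", call. = FALSE)
  }
  ok <- !is.na(probs[, 1L])
  if (!any(ok)) stop("no context has an estimated row", call. = FALSE)
  books <- vector("list", nrow(probs))
  names(books) <- ctxs
  for (i in which(ok)) {
    row <- if (b == 1L) {
      stats::setNames(probs[i, ], colnames(probs))
    } else {
      block_transition_probs(probs, ctxs[i], b, alphabet, order,
                             missing = "zero")
    }
    books[[i]] <- canonical_codebook(huffman_codelengths(row))
  }
  structure(books[ok], b = b,
            granularity = attr(probs, "granularity", exact = TRUE) %||% "by States")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Codelength-description bit field
#'
#' Describes a canonical codebook by its first codelength followed by the
#' per-symbol increments, which is all a receiver needs to rebuild the
#' codewords. In `"paper"` mode every increment (including the first
#' length, read as an increment from zero) is a single bit, so the field is
#' exactly one bit per symbol; an increment of 2 or more cannot be
#' represented and raises an error. `"escape"` mode encodes each increment
#' `k` in unary (`k` ones then a zero), which is self-delimiting for any
#' codebook at the price of a longer field.
#'
#' @param codelengths A `pmm_codelengths`, `pmm_codebook`, or plain integer
#'   vector of nondecreasing lengths.
#' @param mode `"paper"` or `"escape"`.
#' @return Bit string (characters `0`/`1`).
#' @examples
#' codelength_description(c(1, 2, 2)) # "110"
#' @export
codelength_description <- function(codelengths, mode = c("paper", "escape")) {
  mode <- match.arg(mode)
  lengths <- if (inherits(codelengths, c("pmm_codelengths", "pmm_codebook"))) {
    as.integer(codelengths$lengths)
  } else {
    as.integer(codelengths)
  }
  inc <- diff(c(0L, lengths))
  if (any(inc < 0L)) {
    stop("codelengths must be nondecreasing", call. = FALSE)
  }
  if (mode == "paper") {
    if (any(inc > 1L)) {
      stop("codelength increment exceeds 1; use mode = \"escape\"",
           call. = FALSE)
    }
    paste(inc, collapse = "")
  } else {
    paste(vapply(inc, function(k) paste0(strrep("1", k), "0"), ""),
          collapse = "")
  }
}

# Inverse of codelength_description. Returns lengths and bits consumed.
parse_codelength_description <- function(bits, n_symbols,
                                         mode = c("paper", "escape")) {
  mode <- match.arg(mode)
  if (mode == "paper") {
    used <- n_symbols
    inc <- as.integer(strsplit(substr(bits, 1L, used), "", fixed = TRUE)[[1L]])
  } else {
    inc <- integer(n_symbols)
    pos <- 1L
    for (i in seq_len(n_symbols)) {
      k <- 0L
      while (substr(bits, pos, pos) == "1") {
        k <- k + 1L
        pos <- pos + 1L
      }
      pos <- pos + 1L # the terminating zero
      inc[i] <- k
    }
    used <- pos - 1L
  }
  list(lengths = cumsum(inc), used = used)
}

# Expected codeword length under the weights that built a codebook.
expected_length <- function(codebook, probs) {
  p <- probs[codebook$symbols]
  sum(p * codebook$lengths) / sum(p)
}

# TRUE when no codeword is a prefix of another.
is_prefix_free <- function(codewords) {
  cw <- sort(as.character(codewords))
  if (anyDuplicated(cw)) return(FALSE)
  if (length(cw) < 2L) return(TRUE)
  pre <- cw[-length(cw)]
  nxt <- cw[-1L]
  !any(substr(nxt, 1L, nchar(pre)) == pre)
}
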