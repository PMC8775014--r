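#' Order field of the model header
#'
#' The order `o` is transmitted in binary at the fixed width
#' `floor(log2(log_|A|(n) - 1)) + 1`, which suffices for any order obeying
#' the recommended bound `o < floor(log_|A|(n)) - 1`. Gapped models instead
#' reserve 4 bits for `o` and 8 bits for `G` (see
#' [assemble_container()]).
#'
#' @param o Model order.
#' @param n Sample length.
#' @param alphabet_size `|A|`.
#' @param allow_widen When the order violates the admissibility bound and
#'   does not fit the computed width, widen the field to
#'   `floor(log2(o)) + 1` bits with a warning instead of erroring. Only
#'   meaningful for accounting (a receiver could not infer the widened
#'   width), so self-contained containers never widen.
#' @return A bit field (list with `name`, `bits`, `width`).
#' @examples
#' order_field(3, 393, 2)$bits # "011"
#' @export
order_field <- function(o, n, alphabet_size, allow_widen = FALSE) {
  inner <- log(n, base = alphabet_size) - 1
  if (inner < 1) {
    stop("sample too short to size the order field", call. = FALSE)
  }
  width <- as.integer(floor(log2(inner)) + 1)
  if (o > 2^width - 1) {
    if (!allow_widen) {
      stop(sprintf(
        "order %d does not fit the %d-bit order field; the model order should satisfy o < floor(log_|A|(n)) - 1",
        o, width), call. = FALSE)
    }
    width <- as.integer(floor(log2(o)) + 1)
    warning(sprintf(
      "order %d exceeds the admissible bound for n = %d; order field widened to %d bits",
      o, n, width), call. = FALSE)
  }
  bit_field("order", int_to_bitstr(o, width))
}

#' Partition index field: the coded state-to-part map
#'
#' Scanning states in lexical order yields a list of part indices. A
#' canonical Huffman code is built on the index frequencies `|L_i| / |S|`
#' and the index list is replaced by the corresponding codewords. The
#' accompanying codelength-description field lets the receiver rebuild the
#' index codebook.
#'
#' @param partition A [partition()].
#' @param desc_mode Codelength-description mode, `"paper"` or `"escape"`
#'   (see [codelength_description()]).
#' @return List with `indices` (integer per state), `codebook`
#'   (`pmm_codebook` over the index symbols), `index_field` and
#'   `desc_field` (bit fields).
#' @export
partition_index_field <- function(partition, desc_mode = "paper") {
  idx <- partition$index_of
  if (length(idx) == 0L) stop("empty partition", call. = FALSE)
  sizes <- lengths(partition$parts)
  weights <- stats::setNames(sizes / sum(sizes),
                             as.character(seq_along(sizes)))
  book <- canonical_codebook(huffman_codelengths(weights))
  bits <- paste(book$codewords[as.character(idx)], collapse = "")
  list(
    indices = unname(idx),
    codebook = book,
    index_field = bit_field("partition_index", bits),
    desc_field = bit_field("codelength_desc",
                           codelength_description(book, mode = desc_mode))
  )
}

#' Fixed-width frequency field
#'
#' Concatenates the binary representation of every transition count, each
#' at the common width `floor(log2(n)) + 1`, scanning contexts in row order
#' (states in lexical order, or parts by index) and symbols in alphabet
#' order within each context.
#'
#' @param counts Count matrix (state- or part-level rows).
#' @param n Sample length.
#' @return A bit field.
#' @export
frequency_field <- function(counts, n) {
  mat <- if (inherits(counts, "pmm_counts")) counts$counts else counts
  if (any(mat > n)) stop("a count exceeds the sample length", call. = FALSE)
  w <- frequency_width(n)
  words <- vapply(as.vector(t(mat)), int_to_bitstr, "", width = w)
  bit_field("frequencies", paste(words, collapse = ""))
}

#' Fixed-width coding of the leading symbols
#'
#' The first symbols of the message (the `o` symbols before transition
#' coding can start, or the first `G` symbols of a gapped model) are coded
#' by their 1-based lexical position in the alphabet, each at width
#' `floor(log2(|A|)) + 1`.
#'
#' @param symbols Character vector of leading symbols.
#' @param alphabet A [alphabet()].
#' @return A bit field.
#' @examples
#' initial_symbols_field("c", alphabet(c("a", "b", "c")))$bits # "11"
#' @export
initial_symbols_field <- function(symbols, alphabet) {
  alphabet <- as_alphabet(alphabet)
  symbols <- as_symbols(symbols)
  idx <- symbol_indices(symbols, alphabet)
  w <- as.integer(floor(log2(length(alphabet))) + 1)
  bit_field("initial_symbols",
            paste(vapply(idx, int_to_bitstr, "", width = w), collapse = ""))
}

# State ids (1-based, lexical) at positions (h+1):n of the symbol-index
# vector xi; identical arithmetic to count_transitions.
context_ids <- function(xi, m, spec) {
  o <- spec$order
  h <- history_length(spec)
  k <- state_tuple_length(spec)
  lags <- if (is.null(spec$gap)) o:1 else c(spec$gap, o:1)
  n <- length(xi)
  tt <- (h + 1L):n
  id <- rep(1, length(tt))
  for (j in seq_len(k)) {
    id <- id + (xi[tt - lags[j]] - 1) * m^(k - j)
  }
  id
}

#' Encode a sequence with conditional canonical Huffman codebooks
#'
#' The leading symbols are coded by lexical position; the remaining symbols
#' are coded in consecutive `b`-symbol blocks, each with the block codebook
#' of the state preceding the block; a trailing remainder of fewer than `b`
#' symbols is coded symbol-by-symbol with the `b = 1` codebooks.
#'
#' @param x Sequence (character vector or single string).
#' @param probs State-level row-stochastic matrix the codebooks derive from
#'   (state rows for by-states coding, part rows expanded to states for
#'   by-parts coding).
#' @param alphabet A [alphabet()].
#' @param spec A [model_spec()]; `spec$block_size` sets `b`. Gapped models
#'   support `b = 1` only.
#' @return List with bit fields `initial` and `data` and their
#'   concatenation `bits`.
#' @examples
#' ex <- example_conditional_chain()
#' enc <- encode_data(ex$message, ex$probs, ex$alphabet, model_spec(1))
#' enc$bits # "111011101001110"
#' @export
encode_data <- function(x, probs, alphabet, spec) {
  alphabet <- as_alphabet(alphabet)
  spec <- as_spec(spec)
  b <- spec$block_size
  if (!is.null(spec$gap) && b > 1L) {
    stop("gapped models support block size 1 only", call. = FALSE)
  }
  x <- as_symbols(x)
  n <- length(x)
  m <- length(alphabet)
  h <- history_length(spec)
  if (n < h) stop("sequence shorter than the model history", call. = FALSE)
  init <- initial_symbols_field(x[seq_len(h)], alphabet)
  if (n == h) {
    return(list(initial = init, data = bit_field("data", ""),
                bits = init$bits))
  }
  xi <- symbol_indices(x, alphabet)
  ids <- context_ids(xi, m, spec)
  states <- rownames(probs)
  books1 <- conditional_codebooks(probs, b = 1L)
  nb <- (n - h) %/% b
  r <- (n - h) %% b
  pieces <- character(nb + r)
  if (b > 1L && nb > 0L) {
    booksb <- conditional_codebooks(probs, b = b, alphabet = alphabet,
                                    order = spec$order)
    xstr <- paste(x, collapse = "")
    starts <- h + (seq_len(nb) - 1L) * b + 1L
    ctx <- states[ids[starts - h]]
    blocks <- substring(xstr, starts, starts + b - 1L)
    for (k in seq_len(nb)) {
      pieces[k] <- booksb[[ctx[k]]]$codewords[[blocks[k]]]
    }
  } else if (nb > 0L) {
    starts <- h + seq_len(nb)
    ctx <- states[ids[starts - h]]
    for (k in seq_len(nb)) {
      pieces[k] <- books1[[ctx[k]]]$codewords[[x[starts[k]]]]
    }
  }
  if (r > 0L) {
    for (j in seq_len(r)) {
      t <- h + nb * b + j
      pieces[nb + j] <- books1[[states[ids[t - h]]]]$codewords[[x[t]]]
    }
  }
  data <- bit_field("data", paste(pieces, collapse = ""))
  list(initial = init, data = data, bits = paste0(init$bits, data$bits))
}

# Build per-context codeword -> emitted-string lookup environments.
decode_tables <- function(books) {
  lapply(books, function(bk) {
    e <- new.env(parent = emptyenv(), size = length(bk$codewords))
    for (i in seq_along(bk$codewords)) {
      assign(bk$codewords[[i]], bk$symbols[[i]], envir = e)
    }
    e
  })
}

#' Decode a conditionally Huffman-coded bit string
#'
#' Exact inverse of [encode_data()]: reads the leading symbols from their
#' fixed-width lexical positions, then decodes `b`-blocks (and the
#' remainder symbol-by-symbol) with the codebooks derived from `probs`.
#' Decoding is streaming: the prefix property resolves each codeword as
#' soon as its last bit arrives.
#'
#' @param bits Bit string produced by [encode_data()] (`initial` plus
#'   `data`).
#' @param n Length of the original sequence.
#' @inheritParams encode_data
#' @return Character vector of symbols, length `n`.
#' @export
decode_data <- function(bits, n, probs, alphabet, spec) {
  alphabet <- as_alphabet(alphabet)
  spec <- as_spec(spec)
  b <- spec$block_size
  m <- length(alphabet)
  h <- history_length(spec)
  w0 <- as.integer(floor(log2(m)) + 1)
  bv <- strsplit(bits, "", fixed = TRUE)[[1L]]
  pos <- 1L
  take <- function(k) {
    if (pos + k - 1L > length(bv)) {
      stop("bit stream exhausted mid-field", call. = FALSE)
    }
    out <- paste(bv[pos:(pos + k - 1L)], collapse = "")
    pos <<- pos + k
    out
  }
  x <- character(n)
  for (i in seq_len(h)) {
    p <- bitstr_to_int(take(w0))
    if (p < 1 || p > m) stop("invalid initial-symbol position", call. = FALSE)
    x[i] <- alphabet[p]
  }
  if (n > h) {
    books1 <- conditional_codebooks(probs, b = 1L)
    tab1 <- decode_tables(books1)
    nb <- (n - h) %/% b
    r <- (n - h) %% b
    tabb <- if (b > 1L && nb > 0L) {
      decode_tables(conditional_codebooks(probs, b = b, alphabet = alphabet,
                                          order = spec$order))
    }
    states <- rownames(probs)
    xi <- integer(n)
    xi[seq_len(h)] <- match(x[seq_len(h)], alphabet)
    o <- spec$order
    k <- state_tuple_length(spec)
    lags <- if (is.null(spec$gap)) o:1 else c(spec$gap, o:1)
    state_at <- function(t) {
      id <- 1
      for (j in seq_len(k)) id <- id + (xi[t - lags[j]] - 1) * m^(k - j)
      states[id]
    }
    read_code <- function(tab) {
      cur <- ""
      repeat {
        if (pos > length(bv)) {
          stop("bit stream exhausted mid-codeword", call. = FALSE)
        }
        cur <- paste0(cur, bv[pos])
        pos <<- pos + 1L
        hit <- get0(cur, envir = tab, inherits = FALSE)
        if (!is.null(hit)) return(hit)
      }
    }
    t <- h + 1L
    for (blk in seq_len(nb)) {
      ctx <- state_at(t)
      if (b > 1L) {
        block <- read_code(tabb[[ctx]])
        sy <- strsplit(block, "", fixed = TRUE)[[1L]]
        x[t:(t + b - 1L)] <- sy
        xi[t:(t + b - 1L)] <- match(sy, alphabet)
        t <- t + b
      } else {
        sym <- read_code(tab1[[ctx]])
        x[t] <- sym
        xi[t] <- match(sym, alphabet)
        t <- t + 1L
      }
    }
    for (j in seq_len(r)) {
      ctx <- state_at(t)
      sym <- read_code(tab1[[ctx]])
      x[t] <- sym
      xi[t] <- match(sym, alphabet)
      t <- t + 1L
    }
  }
  if (pos <= length(bv)) {
    stop("trailing bits after the decoded sequence", call. = FALSE)
  }
  x
}
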