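#' Declare a finite ordered alphabet
#'
#' The alphabet fixes both the symbol set and the symbol order used
#' everywhere else in the package: state enumeration, count-table columns,
#' codebook tie-breaking, and the fixed-width binary representation of
#' initial symbols all refer to the position of a symbol in this vector.
#'
#' @param symbols Character vector of distinct single-character symbols.
#'   The order given is the lexical order used by the package; it need not
#'   be the native character-set order.
#' @return A character vector of class `pmm_alphabet`.
#' @examples
#' dna <- alphabet(c("a", "c", "g", "t"))
#' binary <- alphabet(c("0", "1"))
#' @export
alphabet <- function(symbols) {
  symbols <- as.character(symbols)
  if (length(symbols) < 1L) {
    stop("an alphabet needs at least one symbol", call. = FALSE)
  }
  if (anyDuplicated(symbols)) {
    stop("alphabet symbols must be distinct", call. = FALSE)
  }
  if (any(nchar(symbols) != 1L)) {
    stop("alphabet symbols must be single characters", call. = FALSE)
  }
  structure(symbols, class = "pmm_alphabet")
}

as_alphabet <- function(x) {
  if (inherits(x, "pmm_alphabet")) x else alphabet(x)
}

#' Model specification: memory order, optional gap, block size
#'
#' An order-`o` Markov state is the contiguous `o`-tuple of symbols at lags
#' `o, ..., 1`. The gapped variant additionally conditions on the single
#' symbol at lag `G > o` (an interstice), so a state becomes the
#' `(o + 1)`-tuple (lag-`G` symbol, contiguous `o`-tuple). `block_size`
#' controls how many symbols are coded per codeword when compressing data.
#'
#' @param order Integer memory `o >= 1`.
#' @param gap Optional integer lag `G > order` for the gapped state variant.
#' @param block_size Integer `b >= 1`, symbols per coded block.
#' @return An object of class `pmm_spec`.
#' @examples
#' model_spec(order = 3)
#' model_spec(order = 3, gap = 9) # the gapped DNA model shape
#' @export
model_spec <- function(order, gap = NULL, block_size = 1L) {
  order <- as.integer(order)
  if (is.na(order) || order < 1L) {
    stop("`order` must be an integer >= 1", call. = FALSE)
  }
  if (!is.null(gap)) {
    gap <- as.integer(gap)
    if (is.na(gap) || gap <= order) {
      stop("`gap` must be an integer strictly larger than `order`",
           call. = FALSE)
    }
  }
  block_size <- as.integer(block_size)
  if (is.na(block_size) || block_size < 1L) {
    stop("`block_size` must be an integer >= 1", call. = FALSE)
  }
  structure(
    list(order = order, gap = gap, block_size = block_size),
    class = "pmm_spec"
  )
}

as_spec <- function(x) {
  if (inherits(x, "pmm_spec")) return(x)
  if (is.numeric(x) && length(x) == 1L) return(model_spec(order = x))
  stop("expected a `pmm_spec` or a plain order", call. = FALSE)
}

# tuple length of a state under a spec
state_tuple_length <- function(spec) {
  spec$order + if (is.null(spec$gap)) 0L else 1L
}

# number of leading symbols not covered by transition counting
history_length <- function(spec) {
  if (is.null(spec$gap)) spec$order else spec$gap
}

#' Enumerate the state space in lexical order
#'
#' States are all tuples over the alphabet of length `order` (contiguous
#' model) or `order + 1` (gapped model, lag-`G` symbol first). They are
#' returned as collapsed strings in lexical order under the alphabet's
#' symbol order, the order in which every other operation scans states.
#'
#' @param alphabet A [alphabet()] (or plain character vector of symbols).
#' @param spec A [model_spec()] (or a plain order).
#' @return Character vector of state strings, with attributes `alphabet`
#'   and `spec`.
#' @examples
#' enumerate_states(alphabet(c("0", "1")), model_spec(3))
#' @export
enumerate_states <- function(alphabet, spec) {
  alphabet <- as_alphabet(alphabet)
  spec <- as_spec(spec)
  k <- state_tuple_length(spec)
  states <- ""
  for (i in seq_len(k)) {
    states <- as.vector(t(outer(states, unclass(alphabet), paste0)))
  }
  structure(states, alphabet = alphabet, spec = spec)
}

# Symbol indices (1-based alphabet positions) of a sequence, with a
# position-naming error for foreign symbols.
symbol_indices <- function(x, alphabet) {
  idx <- match(x, alphabet)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1L]
    stop(sprintf("symbol '%s' at position %d is not in the alphabet",
                 x[bad], bad), call. = FALSE)
  }
  idx
}

# Split a single string into a symbol vector; pass vectors through.
as_symbols <- function(x) {
  if (is.character(x) && length(x) == 1L && nchar(x) > 1L) {
    strsplit(x, "", fixed = TRUE)[[1L]]
  } else {
    as.character(x)
  }
}
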