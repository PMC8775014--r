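# Bit-string helpers. Bit strings are plain character vectors of '0'/'1',
# most significant bit first, never padded beyond the stated width.

# Nonnegative integer (double-safe up to 2^53) to fixed-width bit string.
int_to_bitstr <- function(v, width) {
  v <- as.numeric(v)
  if (is.na(v) || v < 0) stop("value must be a nonnegative integer", call. = FALSE)
  if (v >= 2^width) {
    stop(sprintf("value %s does not fit in %d bits", format(v), width),
         call. = FALSE)
  }
  out <- character(width)
  for (i in width:1) {
    out[i] <- if (v %% 2 >= 1) "1" else "0"
    v <- v %/% 2
  }
  paste(out, collapse = "")
}

bitstr_to_int <- function(bits) {
  digs <- as.integer(strsplit(bits, "", fixed = TRUE)[[1L]])
  sum(digs * 2^((length(digs) - 1L):0))
}

#' Fixed width of a transmitted frequency
#'
#' Every transition count in a length-`n` sample is at most `n`, so all
#' frequencies are transmitted at the common fixed width
#' `floor(log2(n)) + 1` bits.
#'
#' @param n Sample length (`>= 1`).
#' @return Integer bit width.
#' @examples
#' frequency_width(393) # 9
#' @export
frequency_width <- function(n) {
  if (any(n < 1)) stop("`n` must be >= 1", call. = FALSE)
  as.integer(floor(log2(n)) + 1)
}

# A named bit field with its width.
bit_field <- function(name, bits) {
  list(name = name, bits = bits, width = nchar(bits))
}
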