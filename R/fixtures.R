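# Built-in worked examples. These small objects back the documentation
# examples and the test suite, so every pinned check runs offline.

#' Worked example: an order-1 chain over {a, b, c} with its message
#'
#' A three-symbol, memory-1 chain with known transition probabilities and
#' the 8-symbol message used throughout the documentation. Encoding the
#' message with the conditional canonical Huffman codebooks of the chain
#' yields the 15-bit string `111011101001110`.
#'
#' @return List with `alphabet`, `probs` (row-stochastic 3 x 3 matrix),
#'   `message` (single string), and `codes` (the per-state canonical
#'   codewords).
#' @export
example_conditional_chain <- function() {
  ab <- alphabet(c("a", "b", "c"))
  probs <- matrix(c(1 / 6, 2 / 6, 3 / 6,
                    1 / 3, 1 / 3, 1 / 3,
                    2 / 7, 1 / 7, 4 / 7),
                  nrow = 3, byrow = TRUE,
                  dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  codes <- list(
    a = c(a = "11", b = "10", c = "0"),
    b = c(a = "10", b = "11", c = "0"),
    c = c(a = "10", b = "11", c = "0")
  )
  list(alphabet = ab, probs = probs, message = "caabacba", codes = codes)
}

#' Worked example: a 3-part partition of the binary order-3 state space
#'
#' An order-3 binary chain whose eight states fall into three parts, with
#' the state-level transition counts of a length-393 sample. Serialising
#' this model by states costs 147 bits (3 for the order plus 144 for the 16
#' state-level counts at 9 bits each); by parts it costs 69 bits (3 + 12
#' for the coded part-index list + 54 for the 6 part-level counts).
#'
#' @return List with `alphabet`, `order`, `n`, `partition`, and `counts`
#'   (a `pmm_counts` object carrying the printed count table).
#' @export
example_partition_model <- function() {
  ab <- alphabet(c("0", "1"))
  spec <- model_spec(3)
  states <- enumerate_states(ab, spec)
  part <- partition(c(1, 2, 2, 1, 1, 2, 3, 1), states)
  mat <- matrix(c(30, 20,
                  24, 25,
                  26, 25,
                  31, 20,
                  29, 20,
                  25, 25,
                  10, 30,
                  30, 20),
                nrow = 8, byrow = TRUE,
                dimnames = list(as.character(states), c("0", "1")))
  counts <- structure(
    list(counts = mat, marginals = rowSums(mat), n = 393L,
         alphabet = ab, spec = spec, states = as.character(states)),
    class = "pmm_counts"
  )
  list(alphabet = ab, order = 3L, n = 393L, partition = part,
       counts = counts)
}
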