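# The 144-bit state-level frequency field of the worked n = 393 example:
# sixteen counts, each at 9 = floor(log2 393) + 1 bits, states in lexical
# order and symbols 0 then 1 within each state.
eq16_field <- paste0(
  "000011110", "000010100", "000011000", "000011001",
  "000011010", "000011001", "000011111", "000010100",
  "000011101", "000010100", "000011001", "000011001",
  "000001010", "000011110", "000011110", "000010100")
eq17_field <- "001111000001010000001001011001001011000001010000011110"

test_that("frequency widths follow floor(log2 n) + 1", {
  expect_identical(frequency_width(393), 9L)
  expect_identical(frequency_width(1), 1L)
  expect_identical(frequency_width(29903), 15L)
  expect_error(frequency_width(0), ">= 1")
})

test_that("the order field uses the width the header protocol mandates", {
  f <- order_field(3, 393, 2)
  expect_identical(f$bits, "011")
  expect_identical(f$width, 3L)
  f1 <- order_field(1, 4, 2)
  expect_identical(f1$bits, "1")
  # o = 3 for a DNA-sized sample still fits the computed width
  f3 <- order_field(3, 29903, 4)
  expect_identical(strtoi(f3$bits, base = 2), 3L)
  expect_error(order_field(4, 1000, 4), "does not fit")
  expect_warning(w <- order_field(4, 1000, 4, allow_widen = TRUE), "widened")
  expect_identical(w$bits, "100")
})

test_that("the partition index field reproduces the printed 12-bit string", {
  em <- example_partition_model()
  pif <- partition_index_field(em$partition)
  expect_identical(pif$indices, c(1L, 2L, 2L, 1L, 1L, 2L, 3L, 1L))
  expect_identical(unname(pif$codebook$codewords), c("0", "10", "11"))
  expect_identical(pif$index_field$bits, "010100010110")
  expect_identical(pif$index_field$width, 12L)
  expect_identical(pif$desc_field$bits, "110")
  expect_identical(pif$desc_field$width, 3L)

  # one-part partition over 4 states: one codeword "0" per state
  st <- enumerate_states(alphabet(c("0", "1")), 2)
  one <- partition_index_field(partition(rep(1, 4), st))
  expect_identical(one$index_field$bits, "0000")
})

test_that("frequency fields concatenate fixed-width words in scan order", {
  em <- example_partition_model()
  fs <- frequency_field(em$counts, 393)
  expect_identical(fs$bits, eq16_field)
  expect_identical(fs$width, 144L)
  agg <- aggregate_counts(em$counts, em$partition)
  fp <- frequency_field(agg, 393)
  expect_identical(fp$bits, eq17_field)
  expect_identical(fp$width, 54L)
  # zero counts become all-zero words
  z <- frequency_field(matrix(c(0, 3), 1), 5)
  expect_identical(z$bits, "000011")
  expect_error(frequency_field(matrix(10, 1, 1), 5), "exceeds")
})

test_that("initial symbols are coded by lexical position at fixed width", {
  abc <- alphabet(c("a", "b", "c"))
  expect_identical(initial_symbols_field("c", abc)$bits, "11")
  expect_identical(initial_symbols_field("a", abc)$bits, "01")
  dna <- alphabet(c("a", "c", "g", "t"))
  expect_identical(initial_symbols_field("t", dna)$bits, "100")
  expect_identical(initial_symbols_field(c("c", "a"), dna)$bits, "010001")
  expect_error(initial_symbols_field("x", abc), "not in the alphabet")
})

test_that("the worked message encodes to the printed 15 bits and decodes back", {
  ex <- example_conditional_chain()
  enc <- encode_data(ex$message, ex$probs, ex$alphabet, model_spec(1))
  expect_identical(enc$bits, "111011101001110")
  expect_identical(enc$initial$bits, "11")
  expect_identical(enc$data$width, 13L)
  dec <- decode_data(enc$bits, 8, ex$probs, ex$alphabet, model_spec(1))
  expect_identical(paste(dec, collapse = ""), ex$message)

  # constant sequence: degenerate codebooks emit one bit per symbol
  ab <- alphabet(c("a", "b"))
  xc <- rep("a", 40)
  ctc <- count_transitions(xc, ab, 1)
  pc <- transition_probs(ctc)
  encc <- encode_data(xc, pc, ab, model_spec(1))
  expect_identical(encc$data$width, 39L)
  expect_identical(encc$data$bits, strrep("0", 39))

  # truncation errors rather than silent misdecoding
  expect_error(decode_data(substr(enc$bits, 1, 10), 8, ex$probs,
                           ex$alphabet, model_spec(1)), "exhausted")
  expect_error(decode_data(paste0(enc$bits, "01"), 8, ex$probs,
                           ex$alphabet, model_spec(1)), "[Tt]railing")
})

test_that("the worked model serialises to 147 bits by states and 69 by parts", {
  em <- example_partition_model()
  cs <- assemble_container(em$counts, mode = "states", accounting = "paper")
  expect_identical(cs$model_bits, 147L)
  cp <- assemble_container(em$counts, mode = "parts", accounting = "paper",
                           partition = em$partition)
  expect_identical(cp$model_bits, 69L)
  # field-level tallies: 12-bit index list + 3-bit codelength description
  bp <- bit_accounting(cp)
  w <- setNames(bp$fields$width, bp$fields$name)
  expect_identical(w[["partition_index"]], 12L)
  expect_identical(w[["codelength_desc"]], 3L)
  expect_identical(w[["partition_index"]] + w[["codelength_desc"]], 15L)
  expect_identical(w[["frequencies"]], 54L)
  expect_identical(w[["order"]], 3L)
  # transmitted frequency counts: 16 by states, 6 by parts
  expect_equal(bit_accounting(cs)$n_frequencies, 16)
  expect_equal(bp$n_frequencies, 6)
})

test_that("self-contained containers round-trip across alphabets, orders, and blocks", {
  set.seed(404)
  for (m in c(2, 3, 4)) {
    ab <- alphabet(letters[seq_len(m)])
    for (o in c(1, 2, 3)) {
      sc <- scenario_spec(m, o, min(2L, m^o), sample_sizes = 1, seed = m * 10 + o)
      mod <- random_pmm(sc)
      x <- sample_sequence(mod, 350, seed = o)
      for (b in c(1, 2, 4)) {
        for (mode in c("states", "parts")) {
          counts <- suppressWarnings(
            count_transitions(x, mod$alphabet, model_spec(o, block_size = b)))
          cont <- assemble_container(counts, x = x, mode = mode,
                                     accounting = "self_contained", b = b,
                                     desc_mode = "escape")
          parsed <- parse_container(container_bits(cont), mod$alphabet)
          expect_identical(parsed$sequence, x,
                           label = sprintf("m=%d o=%d b=%d %s", m, o, b, mode))
        }
      }
    }
  }
})

test_that("gapped models encode and decode losslessly at block size 1", {
  ab <- alphabet(c("0", "1"))
  st <- enumerate_states(ab, model_spec(1, gap = 4))
  mod <- pmm(ab, model_spec(1, gap = 4), partition(c(1, 2, 2, 1), st),
             matrix(c(0.85, 0.15, 0.3, 0.7), 2, byrow = TRUE))
  x <- sample_sequence(mod, 500, seed = 12)
  cont <- compress_sequence(x, ab, order = 1, gap = 4, mode = "parts")
  y <- decompress_sequence(container_bits(cont), ab)
  expect_identical(as.character(y), x)
  expect_error(compress_sequence(x, ab, order = 1, gap = 4, mode = "parts",
                                 b = 2), NA)
  # b is forced to 1 under a gap by compress_sequence; direct assembly errors
  counts <- count_transitions(x, ab, model_spec(1, gap = 4))
  expect_error(assemble_container(counts, x = x, mode = "states",
                                  accounting = "self_contained", b = 2),
               "block size 1")
})

test_that("pmz files round-trip and corruption is detected, not misdecoded", {
  set.seed(7)
  ab <- alphabet(c("a", "c", "g", "t"))
  sc <- scenario_spec(4, 2, 3, sample_sizes = 1, seed = 21, separation = 0.2)
  mod <- random_pmm(sc)
  x <- sample_sequence(mod, 600, seed = 3)
  tmp <- tempfile(fileext = ".pmz")
  cont <- compress_sequence(x, ab, order = 2, mode = "parts", b = 4,
                            path = tmp)
  y <- decompress_sequence(tmp, ab)
  expect_identical(as.character(y), x)
  expect_identical(attr(y, "model")$mode, "by Parts")
  # Rc matches its definition
  expect_equal(cont$compression_ratio,
               600 * 2 / cont$total_bits, tolerance = 1e-12)

  # corrupt one frequency word to all ones: its value must exceed n
  bits <- container_bits(cont)
  f <- cont$fields$frequencies
  start <- sum(vapply(cont$fields, `[[`, 0L, "width")[
    seq_len(which(names(cont$fields) == "frequencies") - 1L)])
  w <- frequency_width(600)
  corrupted <- paste0(substr(bits, 1, start),
                      strrep("1", w),
                      substr(bits, start + w + 1, nchar(bits)))
  expect_error(parse_container(corrupted, ab), "exceeds n")

  expect_error(suppressWarnings(read_pmz(tempfile())))
})

test_that("malformed headers raise parse errors", {
  ab <- alphabet(c("0", "1"))
  expect_error(parse_container("0101", ab), "truncated")
  tmp <- tempfile(fileext = ".pmz")
  writeBin(charToRaw("NOTPMZ"), tmp)
  expect_error(read_pmz(tmp), "not a .pmz file")
})
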