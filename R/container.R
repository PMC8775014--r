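#' Assemble a compressed container
#'
#' Serialises a fitted model (and optionally the sequence itself) into an
#' ordered list of bit fields with exact per-field accounting.
#'
#' Two accounting conventions are supported. `"paper"` reproduces the
#' classical tallies: the by-states model description is the order field
#' followed by the state-level frequency field; the by-parts description is
#' order, coded partition-index list, and part-level frequency field, with
#' the codelength-description field carried alongside but not counted in
#' the model total. `"self_contained"` additionally prepends everything a
#' receiver needs that the classical tallies leave implicit — a 3-bit flag
#' field, the sample length `n` (32 bits), the block size `b` (8 bits), and
#' for by-parts models the part count (width `floor(log2 |S|) + 1`) — and
#' always includes the codelength description, so the container decodes
#' with no side information beyond the alphabet. Gapped models always
#' transmit `o` in 4 bits and `G` in 8 bits.
#'
#' @param model A `pmm_fit` (from [fit_pmm()]) or `pmm_counts` object.
#' @param x The sequence to encode, or `NULL` for a model-only container
#'   (`"paper"` accounting only).
#' @param mode `"states"` (full chain: one frequency row per state) or
#'   `"parts"` (PMM: partition plus one row per part).
#' @param accounting `"paper"` or `"self_contained"`.
#' @param b Block size for data coding (gapped models require 1).
#' @param partition Partition to use in `"parts"` mode when `model` is a
#'   bare count table; defaults to the fit's partition or, failing that, to
#'   [estimate_partition()].
#' @param desc_mode Codelength-description mode; `"paper"` or `"escape"`.
#' @return Object of class `pmm_container`.
#' @export
assemble_container <- function(model, x = NULL,
                               mode = c("parts", "states"),
                               accounting = c("self_contained", "paper"),
                               b = 1L, partition = NULL,
                               desc_mode = c("paper", "escape")) {
  mode <- match.arg(mode)
  accounting <- match.arg(accounting)
  desc_mode <- match.arg(desc_mode)
  b <- as.integer(b)
  if (inherits(model, "pmm_fit")) {
    counts <- model$counts
    if (is.null(partition)) partition <- model$partition
  } else if (inherits(model, "pmm_counts")) {
    counts <- model
  } else {
    stop("`model` must be a pmm_fit or pmm_counts object", call. = FALSE)
  }
  alphabet <- counts$alphabet
  spec <- counts$spec
  spec$block_size <- b
  if (!is.null(spec$gap) && b > 1L) {
    stop("gapped models support block size 1 only", call. = FALSE)
  }
  n <- counts$n
  m <- length(alphabet)
  if (accounting == "self_contained" && is.null(x)) {
    stop("a self-contained container needs the sequence itself",
         call. = FALSE)
  }
  fields <- list()
  add <- function(f) fields[[f$name]] <<- f
  if (accounting == "self_contained") {
    flags <- paste0(if (mode == "parts") "1" else "0",
                    if (is.null(spec$gap)) "0" else "1",
                    if (desc_mode == "escape") "1" else "0")
    add(bit_field("flags", flags))
    add(bit_field("length_n", int_to_bitstr(n, 32L)))
    add(bit_field("block_size", int_to_bitstr(b, 8L)))
  }
  if (is.null(spec$gap)) {
    add(order_field(spec$order, n, m,
                    allow_widen = accounting == "paper"))
  } else {
    add(bit_field("order", int_to_bitstr(spec$order, 4L)))
    add(bit_field("gap", int_to_bitstr(spec$gap, 8L)))
  }
  if (mode == "parts") {
    if (is.null(partition)) partition <- estimate_partition(counts)
    if (accounting == "self_contained") {
      wS <- as.integer(floor(log2(length(counts$states))) + 1)
      add(bit_field("part_count",
                    int_to_bitstr(partition$n_parts, wS)))
    }
    pif <- partition_index_field(partition, desc_mode = desc_mode)
    add(pif$desc_field)
    add(pif$index_field)
    freq_mat <- aggregate_counts(counts, partition)
    marg <- rowSums(freq_mat)
    probs <- (freq_mat / ifelse(marg > 0, marg, 1))[partition$index_of, ,
                                                    drop = FALSE]
    probs[(marg == 0)[partition$index_of], ] <- NA
    rownames(probs) <- counts$states
  } else {
    partition <- NULL
    freq_mat <- counts$counts
    probs <- transition_probs(counts)
  }
  add(frequency_field(freq_mat, n))
  data_bits <- 0L
  if (!is.null(x)) {
    enc <- encode_data(x, probs, alphabet, spec)
    add(enc$initial)
    add(enc$data)
    data_bits <- enc$initial$width + enc$data$width
  }
  widths <- vapply(fields, `[[`, 0L, "width")
  total <- sum(widths)
  model_names <- setdiff(names(fields), c("initial_symbols", "data"))
  if (accounting == "paper") {
    model_names <- setdiff(model_names, "codelength_desc")
  }
  model_bits <- sum(widths[model_names])
  uncompressed <- n * (floor(log2(max(m - 1, 1))) + 1)
  structure(
    list(mode = if (mode == "parts") "by Parts" else "by States",
         accounting = accounting, b = b, alphabet = alphabet, spec = spec,
         n = n, partition = partition, fields = fields,
         model_bits = model_bits, data_bits = data_bits,
         total_bits = sum(widths[model_names]) + data_bits,
         all_field_bits = total,
         uncompressed_bits = if (is.null(x)) NA_real_ else uncompressed,
         compression_ratio = if (is.null(x)) NA_real_ else
           uncompressed / (sum(widths[model_names]) + data_bits)),
    class = "pmm_container"
  )
}

#' @export
print.pmm_container <- function(x, ...) {
  cat(sprintf("Compressed container (%s, %s accounting, b = %d)\n",
              x$mode, x$accounting, x$b))
  for (f in x$fields) {
    preview <- if (f$width > 64L) paste0(substr(f$bits, 1, 64), "...") else f$bits
    cat(sprintf("  %-16s %6d bits  %s\n", f$name, f$width, preview))
  }
  cat(sprintf("  model %d bits, data %d bits, total %d bits",
              x$model_bits, x$data_bits, x$total_bits))
  if (!is.na(x$compression_ratio)) {
    cat(sprintf(", Rc = %.4f", x$compression_ratio))
  }
  cat("\n")
  invisible(x)
}

#' Per-field bit accounting of a container
#'
#' @param container A `pmm_container`.
#' @return List with `model_bits`, `data_bits`, `total_bits`,
#'   `compression_ratio`, `n_frequencies` (number of transmitted counts),
#'   and a tibble `fields` of per-field widths.
#' @export
bit_accounting <- function(container) {
  w <- frequency_width(container$n)
  list(
    model_bits = container$model_bits,
    data_bits = container$data_bits,
    total_bits = container$total_bits,
    compression_ratio = container$compression_ratio,
    n_frequencies = container$fields$frequencies$width / w,
    fields = tibble::tibble(
      name = vapply(container$fields, `[[`, "", "name"),
      width = vapply(container$fields, `[[`, 0L, "width")
    )
  )
}

#' Parse a self-contained container back into model and sequence
#'
#' Full inverse of [assemble_container()] with `"self_contained"`
#' accounting: rebuilds the header, the partition (for by-parts
#' containers), the transition frequencies, and the codebooks — which match
#' the encoder's bit-for-bit because both sides derive them from the same
#' transmitted counts — and decodes the data stream.
#'
#' @param bits Bit string of a self-contained container.
#' @param alphabet The [alphabet()] (the one piece of shared side
#'   information).
#' @return List with `sequence` (character vector), `spec`, `mode`,
#'   `partition` (or `NULL`), and the reconstructed count matrix `counts`.
#' @export
parse_container <- function(bits, alphabet) {
  alphabet <- as_alphabet(alphabet)
  m <- length(alphabet)
  pos <- 1L
  nb <- nchar(bits)
  take <- function(k) {
    if (pos + k - 1L > nb) stop("malformed container: header truncated",
                                call. = FALSE)
    out <- substr(bits, pos, pos + k - 1L)
    pos <<- pos + k
    out
  }
  flags <- take(3L)
  mode <- if (substr(flags, 1L, 1L) == "1") "parts" else "states"
  gapped <- substr(flags, 2L, 2L) == "1"
  desc_mode <- if (substr(flags, 3L, 3L) == "1") "escape" else "paper"
  n <- bitstr_to_int(take(32L))
  b <- bitstr_to_int(take(8L))
  if (n < 1 || b < 1) stop("malformed container header", call. = FALSE)
  if (gapped) {
    o <- bitstr_to_int(take(4L))
    G <- bitstr_to_int(take(8L))
    spec <- model_spec(order = o, gap = G, block_size = b)
  } else {
    inner <- log(n, base = m) - 1
    wo <- as.integer(floor(log2(inner)) + 1)
    o <- bitstr_to_int(take(wo))
    spec <- model_spec(order = o, block_size = b)
  }
  states <- enumerate_states(alphabet, spec)
  S <- length(states)
  w <- frequency_width(n)
  partition_obj <- NULL
  if (mode == "parts") {
    wS <- as.integer(floor(log2(S)) + 1)
    K <- bitstr_to_int(take(wS))
    if (K < 1 || K > S) stop("malformed part count", call. = FALSE)
    desc <- parse_codelength_description(substr(bits, pos, nb), K, desc_mode)
    pos <- pos + desc$used
    if (kraft_sum(desc$lengths) > 1 + 1e-12) {
      stop("reconstructed index codelengths violate the Kraft inequality",
           call. = FALSE)
    }
    idx_book <- canonical_codebook(as.character(seq_len(K)), desc$lengths)
    tab <- decode_tables(list(idx_book))[[1L]]
    ranks <- integer(S)
    cur <- ""
    for (i in seq_len(S)) {
      cur <- ""
      repeat {
        if (pos > nb) stop("malformed partition index field", call. = FALSE)
        cur <- paste0(cur, substr(bits, pos, pos))
        pos <- pos + 1L
        hit <- get0(cur, envir = tab, inherits = FALSE)
        if (!is.null(hit)) {
          ranks[i] <- as.integer(hit)
          break
        }
      }
    }
    partition_obj <- partition(ranks, states)
    if (partition_obj$n_parts != K) {
      stop("partition index field uses fewer parts than declared",
           call. = FALSE)
    }
    n_rows <- K
  } else {
    n_rows <- S
  }
  freq_bits <- take(n_rows * m * w)
  vals <- vapply(seq_len(n_rows * m), function(i) {
    bitstr_to_int(substr(freq_bits, (i - 1L) * w + 1L, i * w))
  }, 0)
  if (any(vals > n)) stop("corrupted frequency word: count exceeds n",
                          call. = FALSE)
  freq_mat <- matrix(vals, nrow = n_rows, ncol = m, byrow = TRUE)
  colnames(freq_mat) <- unclass(alphabet)
  if (mode == "parts") {
    rownames(freq_mat) <- paste0("L", seq_len(n_rows))
    marg <- rowSums(freq_mat)
    probs <- (freq_mat / ifelse(marg > 0, marg, 1))[partition_obj$index_of, ,
                                                    drop = FALSE]
    empty <- (marg == 0)[partition_obj$index_of]
    probs[empty, ] <- NA
    rownames(probs) <- states
  } else {
    rownames(freq_mat) <- states
    probs <- transition_probs(freq_mat)
  }
  rest <- substr(bits, pos, nb)
  sequence <- decode_data(rest, n, probs, alphabet, spec)
  list(sequence = sequence, spec = spec,
       mode = if (mode == "parts") "by Parts" else "by States",
       partition = partition_obj, counts = freq_mat)
}

#' Concatenated bit payload of a container
#'
#' The container's fields joined in layout order as one `0`/`1` string —
#' the text-dump form of the bitstream, directly comparable with printed
#' field strings.
#'
#' @param container A `pmm_container`.
#' @return Bit string.
#' @export
container_bits <- function(container) {
  paste(vapply(container$fields, `[[`, "", "bits"), collapse = "")
}

bits_to_raw <- function(bits) {
  v <- as.integer(strsplit(bits, "", fixed = TRUE)[[1L]])
  pad <- (8L - length(v) %% 8L) %% 8L
  v <- c(v, integer(pad))
  mat <- matrix(v, nrow = 8L)
  list(raw = as.raw(colSums(mat * 2L^(7:0))), pad = pad)
}

raw_to_bits <- function(r, pad) {
  if (length(r) == 0L) return("")
  bits <- matrix(0L, nrow = 8L, ncol = length(r))
  v <- as.integer(r)
  for (i in 8:1) {
    bits[i, ] <- v %% 2L
    v <- v %/% 2L
  }
  s <- paste(bits, collapse = "")
  substr(s, 1L, nchar(s) - pad)
}

#' Write a container to a .pmz file
#'
#' Layout: magic bytes `PMZ1`, one version byte, one flag byte whose low 3
#' bits give the number of zero pad bits appended to reach a byte boundary,
#' then the container's bit fields packed most-significant-bit first.
#'
#' @param container A `pmm_container` (self-contained accounting if the
#'   file is to be decompressed without side information).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pmz <- function(container, path) {
  bits <- container_bits(container)
  packed <- bits_to_raw(bits)
  flag <- as.raw(packed$pad)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("PMZ1"), as.raw(1L), flag, packed$raw), con)
  invisible(path)
}

#' Read the bit payload of a .pmz file
#'
#' @param path Path to a file written by [write_pmz()].
#' @return Bit string (characters `0`/`1`).
#' @export
read_pmz <- function(path) {
  r <- readBin(path, "raw", n = file.size(path))
  if (length(r) < 6L || !identical(r[1:4], charToRaw("PMZ1"))) {
    stop("not a .pmz file", call. = FALSE)
  }
  pad <- as.integer(r[6L]) %% 8L
  raw_to_bits(r[-(1:6)], pad)
}

#' Compress a sequence end to end
#'
#' Fits the model (a PMM in `"parts"` mode, the full chain in `"states"`
#' mode), assembles a self-contained container, and optionally writes it to
#' a `.pmz` file.
#'
#' @param x Sequence (character vector or single string).
#' @param alphabet A [alphabet()].
#' @param order Model order.
#' @param gap Optional gap lag.
#' @param mode `"parts"` or `"states"`.
#' @param b Block size (gapped models require 1).
#' @param path Optional output path for the `.pmz` file.
#' @return The `pmm_container`, invisibly when `path` is given.
#' @export
compress_sequence <- function(x, alphabet, order, gap = NULL,
                              mode = c("parts", "states"), b = 4L,
                              path = NULL) {
  mode <- match.arg(mode)
  alphabet <- as_alphabet(alphabet)
  x <- as_symbols(x)
  if (!is.null(gap)) b <- 1L
  counts <- count_transitions(x, alphabet, model_spec(order, gap = gap))
  part <- if (mode == "parts") estimate_partition(counts) else NULL
  cont <- assemble_container(counts, x = x, mode = mode,
                             accounting = "self_contained", b = b,
                             partition = part, desc_mode = "escape")
  if (!is.null(path)) {
    write_pmz(cont, path)
    return(invisible(cont))
  }
  cont
}

#' Decompress a .pmz file or bit string
#'
#' @param x Path to a `.pmz` file, or a bit string from
#'   [container_bits()].
#' @param alphabet The [alphabet()] the sequence was compressed with.
#' @return Character vector: the original sequence. The parsed model is
#'   attached as attribute `model`.
#' @export
decompress_sequence <- function(x, alphabet) {
  bits <- if (file.exists(x)) read_pmz(x) else x
  parsed <- parse_container(bits, alphabet)
  structure(parsed$sequence,
            model = parsed[c("spec", "mode", "partition", "counts")])
}
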