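#' Read sequences from a FASTA file
#'
#' Records are lower-cased and checked against the alphabet. Policy
#' `"strict"` errors at the first foreign character (naming record and
#' position), `"skip"` drops foreign characters with a logged count, and
#' `"keep"` extends the alphabet with whatever it finds.
#'
#' @param path FASTA file (single- or multi-record; wrapped lines fine).
#' @param alphabet Target [alphabet()]; defaults to the DNA bases.
#' @param policy `"strict"`, `"skip"`, or `"keep"`.
#' @return Named list of symbol vectors (names are record identifiers),
#'   with attribute `alphabet` (the possibly extended alphabet) and, under
#'   `"skip"`, attribute `dropped` (foreign symbols removed per record).
#' @export
read_fasta <- function(path, alphabet = NULL,
                       policy = c("strict", "skip", "keep")) {
  policy <- match.arg(policy)
  if (is.null(alphabet)) alphabet <- alphabet(c("a", "c", "g", "t"))
  alphabet <- as_alphabet(alphabet)
  recs <- seqinr::read.fasta(path, seqtype = "AA", as.string = FALSE,
                             set.attributes = FALSE)
  recs <- lapply(recs, function(s) tolower(as.character(s)))
  if (length(recs) == 0L) stop("empty FASTA file", call. = FALSE)
  dropped <- integer(length(recs))
  names(dropped) <- names(recs)
  out <- vector("list", length(recs))
  names(out) <- names(recs)
  for (i in seq_along(recs)) {
    x <- as.character(recs[[i]])
    foreign <- !(x %in% alphabet)
    if (any(foreign)) {
      if (policy == "strict") {
        stop(sprintf(
          "record '%s': symbol '%s' at position %d is not in the alphabet",
          names(recs)[i], x[which(foreign)[1L]], which(foreign)[1L]),
          call. = FALSE)
      }
      if (policy == "skip") {
        dropped[i] <- sum(foreign)
        x <- x[!foreign]
      } else {
        alphabet <- alphabet(sort(union(unclass(alphabet), unique(x))))
      }
    }
    if (length(x) == 0L) {
      stop(sprintf("record '%s' is empty after filtering", names(recs)[i]),
           call. = FALSE)
    }
    out[[i]] <- x
  }
  attr(out, "alphabet") <- alphabet
  if (policy == "skip") attr(out, "dropped") <- dropped
  out
}

#' Write sequences to a FASTA file
#'
#' @param records Named list of symbol vectors (as from [read_fasta()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  seqinr::write.fasta(sequences = records,
                      names = names(records) %||%
                        paste0("seq", seq_along(records)),
                      file.out = path, nbchar = 60)
  invisible(path)
}
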