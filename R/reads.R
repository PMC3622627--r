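# Read sets and the read-side BWT index.
#
# Reads are indexed exactly as given (no reverse complementing or
# canonicalization): the reference index carries both strands, so every
# matching orientation is already covered on the reference side.

#' Construct a read set
#'
#' @param sequences Character vector of read sequences over A, C, G, T, N,
#'   all the same length.
#' @param ids Optional read identifiers (defaults to `read_1..n`; made
#'   unique if duplicated).
#' @return An object of class `read_set` with fields `ids`, `sequences`,
#'   `read_length`.
#' @export
read_set <- function(sequences, ids = NULL) {
  if (length(sequences) == 0L) stop("empty read set")
  if (is.null(ids)) ids <- sprintf("read_%d", seq_along(sequences))
  ids <- make.unique(as.character(ids), sep = "/")
  lens <- unique(nchar(sequences))
  if (length(lens) != 1L)
    stop("reads have non-uniform lengths (", paste(sort(lens), collapse = ", "),
         "); load with pad_to_uniform = TRUE to N-pad")
  sequences <- as.character(sequences)
  names(sequences) <- ids
  check_alphabet(sequences)
  structure(list(ids = ids, sequences = unname(sequences),
                 read_length = lens),
            class = "read_set")
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("Read set: %d read(s) of length %d\n",
              length(x$sequences), x$read_length))
  invisible(x)
}

#' Load sequencing reads from FASTQ or FASTA
#'
#' Format is detected from the first byte (`@` = FASTQ, `>` = FASTA).
#' Qualities are ignored; bases are uppercased and degenerate IUPAC codes
#' other than N become N. With `pad_to_uniform`, shorter reads are
#' right-padded with N to the maximum read length; otherwise non-uniform
#' lengths are an error.
#'
#' @param path Path to a FASTQ or FASTA file.
#' @param pad_to_uniform Pad shorter reads with trailing N?
#' @return A [read_set()].
#' @export
load_reads <- function(path, pad_to_uniform = FALSE) {
  first <- readChar(path, 1L, useBytes = TRUE)
  if (length(first) == 0L) stop("empty file: ", path)
  fmt <- if (first == "@") "fastq" else "fasta"
  x <- Biostrings::readDNAStringSet(path, format = fmt)
  if (length(x) == 0L) stop("empty file: ", path)
  seqs <- toupper(as.character(x))
  if (any(grepl("[^ACGTN]", seqs))) seqs <- gsub("[^ACGTN]", "N", seqs)
  if (pad_to_uniform) {
    lens <- nchar(seqs)
    width <- max(lens)
    short <- lens < width
    seqs[short] <- paste0(seqs[short], strrep("N", width - lens[short]))
  }
  read_set(seqs, ids = sub("\\s.*$", "", names(x)))
}

#' Write a read set to FASTQ
#'
#' Constant placeholder qualities (`I`) are written; the classifier never
#' uses them.
#'
#' @param reads A `read_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(inherits(reads, "read_set"))
  con <- file(path, "wb")
  qual <- strrep("I", reads$read_length)
  writeLines(paste0("@", reads$ids, "\n", reads$sequences, "\n+\n", qual),
             con, sep = "\n")
  close(con)
  invisible(path)
}

#' Build the generalized BWT index of a read set
#'
#' For any k-mer Q, the size of Q's interval in this index equals the total
#' number of occurrences of Q across all reads.
#'
#' @param reads A `read_set`.
#' @return A `gbwt` object over the reads.
#' @export
build_read_index <- function(reads) {
  stopifnot(inherits(reads, "read_set"))
  seqs <- reads$sequences
  names(seqs) <- reads$ids
  build_gsa_bwt(seqs)
}
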