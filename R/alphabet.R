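# DNA alphabet and integer symbol codes.
#
# Symbol order is fixed as $-terminators < A < C < G < N < T; codes are
# 0 = terminator, 1 = A, 2 = C, 3 = G, 4 = N, 5 = T.  N is a literal
# symbol: a query N matches only an N in the text.

DNA_ALPHABET <- c("A", "C", "G", "N", "T")

.code_lut <- local({
  lut <- rep(NA_integer_, 256L)
  lut[utf8ToInt("A")] <- 1L
  lut[utf8ToInt("C")] <- 2L
  lut[utf8ToInt("G")] <- 3L
  lut[utf8ToInt("N")] <- 4L
  lut[utf8ToInt("T")] <- 5L
  lut
})

.bwt_lut <- local({
  lut <- .code_lut
  lut[utf8ToInt("$")] <- 0L
  lut
})

# Encode an uppercase DNA string to integer codes; NA marks a bad symbol.
encode_seq <- function(s) .code_lut[utf8ToInt(s)]

decode_codes <- function(codes) {
  intToUtf8(c(36L, 65L, 67L, 71L, 78L, 84L)[codes + 1L])
}

# Symbol-per-element character view of a code vector.
codes_to_symbols <- function(codes) {
  c("$", DNA_ALPHABET)[codes + 1L]
}

check_alphabet <- function(seqs) {
  for (j in seq_along(seqs)) {
    codes <- encode_seq(seqs[[j]])
    bad <- which(is.na(codes))
    if (length(bad) > 0L) {
      stop(sprintf("invalid symbol '%s' in sequence '%s' at position %d",
                   substr(seqs[[j]], bad[1L], bad[1L]),
                   names(seqs)[j], bad[1L]), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Reverse complement of DNA sequences
#'
#' Complements A<->T, C<->G, leaves N as N, and reverses. Vectorized over a
#' character vector of sequences.
#'
#' @param x Character vector of DNA sequences over A, C, G, T, N.
#' @return Character vector of the same length.
#' @export
#' @examples
#' reverse_complement("AAC")  # "GTT"
reverse_complement <- function(x) {
  if (length(x) == 0L) return(character(0))
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  names(out) <- names(x)
  out
}
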