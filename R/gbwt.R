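# Generalized BWT / generalized suffix array over a sequence collection.
#
# A "gbwt" object holds, for a collection of m sequences each conceptually
# terminated by a distinct sentinel $_1 < ... < $_m (all below the regular
# alphabet), the BWT symbol codes plus the generalized suffix array: A[i] is
# the 0-based offset of the i-th smallest suffix within its member, C[i] the
# 0-based member index.  Q-intervals are 0-based closed [b, e]; the empty
# interval is encoded as e = b - 1.

#' Build the generalized BWT and suffix array of a sequence collection
#'
#' Suffixes of all members (each followed by its own distinct terminator) are
#' sorted under the symbol order `$_1 < ... < $_m < A < C < G < N < T`, with
#' terminators ordered by member index. `bwt[i]` is the symbol preceding the
#' i-th smallest suffix; the terminator of member j precedes member j's
#' full-sequence suffix.
#'
#' @param seqs Named character vector of non-empty sequences over
#'   A, C, G, T, N (uppercase), or a [Biostrings::DNAStringSet]. Names must
#'   be unique; member order is preserved and significant.
#' @return An object of class `gbwt` with elements `bwt` (integer symbol
#'   codes, 0 = terminator), `A`, `C` (integer vectors of length
#'   `sum(nchar(seqs)) + length(seqs)`), `member_count`, `ids`,
#'   `seq_lengths`, and internal rank structures.
#' @seealso [gbwt_symbols()], [invert_bwt()], [backward_search()]
#' @export
#' @examples
#' x <- build_gsa_bwt(c(s1 = "AC", s2 = "GT"))
#' gbwt_symbols(x)   # "C" "T" "$" "A" "$" "G"
#' x$C               # 0 1 0 0 1 1
build_gsa_bwt <- function(seqs) {
  if (methods::is(seqs, "DNAStringSet")) {
    nm <- names(seqs)
    seqs <- as.character(seqs)
    names(seqs) <- nm
  }
  if (length(seqs) == 0L) stop("empty collection")
  if (is.null(names(seqs)) || anyNA(names(seqs)) || any(names(seqs) == ""))
    stop("every member must have an identifier")
  if (anyDuplicated(names(seqs)))
    stop("duplicate member identifiers: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  lens <- nchar(seqs)
  if (any(lens == 0L)) stop("empty sequence for member '",
                            names(seqs)[which(lens == 0L)[1L]], "'")
  check_alphabet(seqs)
  codes <- encode_seq(paste(seqs, collapse = ""))
  res <- cpp_build_gsa(codes, as.integer(lens))
  structure(
    list(bwt = res$bwt, A = res$A, C = res$C,
         occ = res$occ, cumF = res$cumF,
         member_count = length(seqs),
         ids = names(seqs),
         seq_lengths = as.integer(unname(lens))),
    class = "gbwt")
}

#' @export
print.gbwt <- function(x, ...) {
  cat(sprintf("Generalized BWT: %d member(s), %d bp, index length %d\n",
              x$member_count, sum(x$seq_lengths), length(x$bwt)))
  invisible(x)
}

#' BWT as a character vector of symbols
#'
#' Terminators are all rendered as `"$"`; position i's terminator belongs to
#' member `x$C[i]` (0-based).
#'
#' @param x A `gbwt` object.
#' @return Character vector of single symbols, one per BWT position.
#' @export
gbwt_symbols <- function(x) codes_to_symbols(x$bwt)

#' Invert a generalized BWT back to its member sequences
#'
#' @param x A `gbwt` object.
#' @return Named character vector of the member sequences (terminators
#'   stripped) in original member order.
#' @export
#' @examples
#' invert_bwt(build_gsa_bwt(c(s1 = "AC", s2 = "GT")))
invert_bwt <- function(x) {
  stopifnot(inherits(x, "gbwt"))
  if (sum(x$bwt == 0L) != x$member_count)
    stop(sprintf("malformed BWT: %d terminator(s) for %d member(s)",
                 sum(x$bwt == 0L), x$member_count))
  out <- cpp_invert(x$bwt, x$C, x$member_count)
  names(out) <- x$ids
  out
}

#' Q-interval constructor
#'
#' A Q-interval is the 0-based closed range `[b, e]` of index positions whose
#' suffixes start with a query Q; the empty interval has `e = b - 1`.
#'
#' @param b,e Integer interval bounds.
#' @return An object of class `q_interval`.
#' @export
q_interval <- function(b, e) {
  b <- as.integer(b); e <- as.integer(e)
  stopifnot(length(b) == 1L, length(e) == 1L, !is.na(b), !is.na(e))
  if (e < b - 1L) { b <- 0L; e <- -1L }  # canonical empty form
  structure(list(b = b, e = e), class = "q_interval")
}

#' @export
print.q_interval <- function(x, ...) {
  if (x$e < x$b) cat("Q-interval: empty\n")
  else cat(sprintf("Q-interval: [%d, %d], size %d\n", x$b, x$e, x$e - x$b + 1L))
  invisible(x)
}

#' Size of a Q-interval
#' @param x A `q_interval`.
#' @return Integer number of occurrences represented (0 if empty).
#' @export
interval_size <- function(x) max(0L, x$e - x$b + 1L)

#' Backward search for a query string
#'
#' Finds the Q-interval of `q` by successive left extensions from its last
#' symbol. The interval size equals the total number of (overlapping)
#' occurrences of `q` across all members; occurrences never span member
#' boundaries. `N` matches only a literal `N`.
#'
#' @param x A `gbwt` object.
#' @param q Non-empty query string over A, C, G, T, N.
#' @return A `q_interval` (empty if `q` is absent).
#' @export
#' @examples
#' x <- build_gsa_bwt(c(s1 = "AC", s2 = "GT"))
#' backward_search(x, "A")   # [2, 2]
backward_search <- function(x, q) {
  stopifnot(inherits(x, "gbwt"))
  if (!is.character(q) || length(q) != 1L || is.na(q) || nchar(q) == 0L)
    stop("query must be a single non-empty string")
  codes <- encode_seq(q)
  if (anyNA(codes))
    stop(sprintf("invalid symbol '%s' in query at position %d",
                 substr(q, which(is.na(codes))[1L], which(is.na(codes))[1L]),
                 which(is.na(codes))[1L]))
  n <- length(codes)
  c0 <- codes[n]
  b <- x$cumF[c0 + 1L]
  e <- x$cumF[c0 + 2L] - 1L
  if (n > 1L) {
    for (i in (n - 1L):1L) {
      if (e < b) break
      be <- cpp_extend(x$bwt, x$occ, x$cumF, b, e, codes[i])
      b <- be[1L]; e <- be[2L]
    }
  }
  q_interval(b, e)
}

#' Extend a Q-interval on the left by one symbol
#'
#' Maps the interval of Q to the interval of `cQ`, equivalent to
#' `backward_search(x, paste0(c, Q))`. An empty input yields an empty output.
#'
#' @param x A `gbwt` object.
#' @param interval A valid `q_interval` of `x`.
#' @param c Single symbol, one of A, C, G, T, N.
#' @return A `q_interval`.
#' @export
extend_interval_left <- function(x, interval, c) {
  stopifnot(inherits(x, "gbwt"), inherits(interval, "q_interval"))
  code <- .code_lut[utf8ToInt(c)]
  if (length(code) != 1L || is.na(code))
    stop("extension symbol must be one of A, C, G, T, N")
  if (interval$e < interval$b) return(q_interval(0L, -1L))
  be <- cpp_extend(x$bwt, x$occ, x$cumF, interval$b, interval$e, code)
  q_interval(be[1L], be[2L])
}

#' Members and offsets covered by a Q-interval
#'
#' Returns the generalized-suffix-array slice `(C[i], A[i])` for i in
#' `[b, e]`: which member each occurrence lies in and at which 0-based
#' offset.
#'
#' @param x A `gbwt` object.
#' @param interval A `q_interval` within bounds.
#' @return A data frame with integer columns `member` and `offset` (empty for
#'   an empty interval).
#' @export
interval_members <- function(x, interval) {
  stopifnot(inherits(x, "gbwt"), inherits(interval, "q_interval"))
  if (interval$e < interval$b)
    return(data.frame(member = integer(0), offset = integer(0)))
  if (interval$b < 0L || interval$e >= length(x$bwt))
    stop("interval out of bounds")
  idx <- (interval$b):(interval$e) + 1L
  data.frame(member = x$C[idx], offset = x$A[idx])
}

GBWT_FORMAT_VERSION <- 1L

#' Save / load a generalized BWT index
#'
#' On-disk layout (versioned, plain text): `header.json` with format name,
#' version, member ids and lengths; `bwt.txt` holding the BWT one symbol per
#' byte with terminators rendered as `$` (member identity of each terminator
#' is recoverable from the `C` column); `sa.tsv` with tab-separated columns
#' `A` and `C`. Saving is deterministic: the same index always produces
#' byte-identical files.
#'
#' @param x A `gbwt` object.
#' @param path Directory to write to / read from (created if needed).
#' @return `save_gbwt` returns `path` invisibly; `load_gbwt` returns a
#'   `gbwt` object structurally equal to the one saved.
#' @export
save_gbwt <- function(x, path) {
  stopifnot(inherits(x, "gbwt"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  header <- list(format = "kmertax-gbwt", version = GBWT_FORMAT_VERSION,
                 member_count = x$member_count, ids = x$ids,
                 seq_lengths = x$seq_lengths)
  jsonlite::write_json(header, file.path(path, "header.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  con <- file(file.path(path, "bwt.txt"), "wb")
  writeLines(decode_codes(x$bwt), con, sep = "\n")
  close(con)
  con <- file(file.path(path, "sa.tsv"), "wb")
  writeLines(c("A\tC", paste(x$A, x$C, sep = "\t")), con, sep = "\n")
  close(con)
  invisible(path)
}

#' @rdname save_gbwt
#' @export
load_gbwt <- function(path) {
  hpath <- file.path(path, "header.json")
  if (!file.exists(hpath)) stop("not a gbwt index directory: ", path)
  header <- jsonlite::read_json(hpath, simplifyVector = TRUE)
  if (!identical(header$format, "kmertax-gbwt"))
    stop("unrecognized index format")
  if (!identical(as.integer(header$version), GBWT_FORMAT_VERSION))
    stop(sprintf("index format version %s not supported (expected %d)",
                 header$version, GBWT_FORMAT_VERSION))
  for (f in c("bwt.txt", "sa.tsv"))
    if (!file.exists(file.path(path, f)))
      stop("corrupt index: missing ", f)
  bwt_txt <- readLines(file.path(path, "bwt.txt"), n = 1L)
  bwt <- .bwt_lut[utf8ToInt(bwt_txt)]
  if (anyNA(bwt)) stop("corrupt index: invalid symbol in bwt.txt")
  sa <- read.delim(file.path(path, "sa.tsv"), colClasses = "integer")
  m <- as.integer(header$member_count)
  L <- sum(header$seq_lengths) + m
  if (length(bwt) != L || nrow(sa) != L)
    stop("corrupt index: component lengths disagree with header")
  if (sum(bwt == 0L) != m)
    stop("corrupt index: terminator count does not match member count")
  aux <- cpp_index_aux(bwt)
  structure(
    list(bwt = bwt, A = sa$A, C = sa$C, occ = aux$occ, cumF = aux$cumF,
         member_count = m, ids = as.character(header$ids),
         seq_lengths = as.integer(header$seq_lengths)),
    class = "gbwt")
}
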