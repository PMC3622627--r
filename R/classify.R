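# The classifier: synchronized traversal of the reference and read indexes,
# per-k-mer taxonomic assignment at the deepest agreeing rank, per-genome
# copy-number filtering, and read occurrence counting.

#' Enumerate all k-mers shared between reads and reference
#'
#' Performs the staged synchronized traversal: starting from single-symbol
#' intervals, each stage makes one sequential pass over both BWT strings and
#' extends every interval pair alive in both indexes on the left. Every
#' k-mer present in both indexes is emitted exactly once, in lexicographic
#' order, with its Q-interval in each index. k-mers never span sequence
#' boundaries.
#'
#' @param ref A `ref_index`.
#' @param read_index A `gbwt` built by [build_read_index()].
#' @param k k-mer length, `1 <= k <=` read length.
#' @return Data frame with columns `kmer`, `ref_b`, `ref_e`, `read_b`,
#'   `read_e` (0-based closed interval bounds), sorted by `kmer`.
#' @export
enumerate_shared_kmers <- function(ref, read_index, k) {
  stopifnot(inherits(ref, "ref_index"), inherits(read_index, "gbwt"))
  check_k(k, read_index)
  res <- cpp_traverse(ref$gbwt$bwt, ref$gbwt$cumF,
                      read_index$bwt, read_index$cumF,
                      as.integer(k),
                      ref_gpos(ref), ref$text,
                      FALSE,
                      ref$gbwt$C, ref$genome_of_member,
                      lineage_matrix(ref))
  data.frame(kmer = res$kmer, ref_b = res$ref_b, ref_e = res$ref_e,
             read_b = res$read_b, read_e = res$read_e)
}

check_k <- function(k, read_index) {
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 1L ||
      k > max(read_index$seq_lengths))
    stop("k must be between 1 and the read length (",
         max(read_index$seq_lengths), ")")
  invisible(TRUE)
}

# Global text position of the suffix at each SA rank (for k-mer extraction).
ref_gpos <- function(ref) {
  ref$member_starts[ref$gbwt$C + 1L] + ref$gbwt$A
}

lineage_matrix <- function(ref) {
  ref$taxonomy$lineages[match(ref$genome_ids,
                              rownames(ref$taxonomy$lineages)), ,
                        drop = FALSE]
}

#' Classify a reference Q-interval at the deepest agreeing rank
#'
#' The interval is assigned the deepest rank l at which every genome with an
#' occurrence in the interval carries the same lineage value at ranks
#' 0..l; the taxon is the shared value at l. If the genomes disagree even at
#' superkingdom, the result is unclassified (`NA`).
#'
#' @param ref A `ref_index`.
#' @param interval A non-empty `q_interval` in the reference index.
#' @return List with `taxon` (integer id or `NA`), `level` (0 = superkingdom
#'   .. 7 = strain, or `NA`), and `level_name`.
#' @export
classify_interval <- function(ref, interval) {
  stopifnot(inherits(ref, "ref_index"))
  if (interval$e < interval$b) stop("cannot classify an empty interval")
  mem <- interval_members(ref$gbwt, interval)
  gs <- unique(ref$genome_of_member[mem$member + 1L])
  lin <- lineage_matrix(ref)[gs + 1L, , drop = FALSE]
  lvl <- NA_integer_
  for (l in seq_len(8L)) {
    if (length(unique(lin[, l])) == 1L) lvl <- l - 1L else break
  }
  if (is.na(lvl))
    return(list(taxon = NA_integer_, level = NA_integer_,
                level_name = NA_character_))
  list(taxon = unname(lin[1L, lvl + 1L]), level = lvl,
       level_name = TAX_LEVELS[lvl + 1L])
}

#' Per-genome occurrence counts of a reference Q-interval
#'
#' Counts interval members per genome, pooling each genome's forward and
#' reverse-complement members. Counts always sum to the interval size.
#'
#' @param ref A `ref_index`.
#' @param interval A non-empty `q_interval` in the reference index.
#' @return Named integer vector (names = genome ids) of occurrence counts.
#' @export
genome_occurrence_counts <- function(ref, interval) {
  stopifnot(inherits(ref, "ref_index"))
  if (interval$e < interval$b) stop("cannot count an empty interval")
  mem <- interval_members(ref$gbwt, interval)
  gs <- ref$genome_of_member[mem$member + 1L]
  tab <- table(factor(ref$genome_ids[gs + 1L], levels = ref$genome_ids))
  out <- as.integer(tab)
  names(out) <- names(tab)
  out[out > 0L]
}

#' Classify every k-mer shared between a read set and the reference
#'
#' For each shared k-mer: k-mers occurring more than once in any single
#' genome (forward and reverse-complement strands pooled) are discarded by
#' the copy-number filter; k-mers whose reference genomes disagree at every
#' rank are unclassified and dropped; the rest are assigned the deepest rank
#' on which all occurring genomes agree, together with their read occurrence
#' count. Note that a self-reverse-complementary k-mer occurring at a single
#' site still counts twice (once per strand member) and is therefore
#' filtered.
#'
#' @param ref A `ref_index`.
#' @param read_index A `gbwt` built by [build_read_index()].
#' @param k k-mer length, `1 <= k <=` read length.
#' @param verbose Log a run summary via [message()]?
#' @return An object of class `kmer_classifications`: a data frame with
#'   columns `kmer`, `taxon_id`, `taxon_name`, `level` (0-based rank depth),
#'   `level_name`, `read_count`, `ref_count`, sorted by `kmer`, with a
#'   traversal summary in `attr(, "summary")` and `k` in `attr(, "k")`.
#' @export
classify_dataset <- function(ref, read_index, k, verbose = FALSE) {
  stopifnot(inherits(ref, "ref_index"), inherits(read_index, "gbwt"))
  check_k(k, read_index)
  res <- cpp_traverse(ref$gbwt$bwt, ref$gbwt$cumF,
                      read_index$bwt, read_index$cumF,
                      as.integer(k),
                      ref_gpos(ref), ref$text,
                      TRUE,
                      ref$gbwt$C, ref$genome_of_member,
                      lineage_matrix(ref))
  out <- data.frame(kmer = res$kmer,
                    taxon_id = res$taxon,
                    taxon_name = unname(ref$taxonomy$names[res$taxon]),
                    level = res$level,
                    level_name = TAX_LEVELS[res$level + 1L],
                    read_count = res$read_count,
                    ref_count = res$ref_count)
  smry <- list(shared = res$n_shared,
               copy_filtered = res$n_copy_filtered,
               unclassified = res$n_unclassified,
               classified = nrow(out),
               total_read_occurrences = res$total_read_occurrences)
  if (verbose)
    message(sprintf(
      "classified %d of %d shared %d-mers (%d copy-filtered, %d unclassified)",
      nrow(out), as.integer(smry$shared), as.integer(k),
      as.integer(smry$copy_filtered), as.integer(smry$unclassified)))
  structure(out, k = as.integer(k), summary = smry,
            class = c("kmer_classifications", "data.frame"))
}

#' @export
print.kmer_classifications <- function(x, n = 6L, ...) {
  s <- attr(x, "summary")
  cat(sprintf(
    "k-mer classifications (k = %d): %d classified / %d shared (%d copy-filtered, %d unclassified)\n",
    attr(x, "k"), as.integer(s$classified), as.integer(s$shared),
    as.integer(s$copy_filtered), as.integer(s$unclassified)))
  if (nrow(x) > 0L) print.data.frame(head(as.data.frame(x), n))
  if (nrow(x) > n) cat("...", nrow(x) - n, "more row(s)\n")
  invisible(x)
}

#' @export
summary.kmer_classifications <- function(object, ...) {
  s <- attr(object, "summary")
  lvl <- table(factor(object$level_name, levels = TAX_LEVELS))
  structure(list(k = attr(object, "k"), counts = s, by_level = lvl),
            class = "summary.kmer_classifications")
}

#' @export
print.summary.kmer_classifications <- function(x, ...) {
  cat(sprintf("k = %d\nshared k-mers: %d\ncopy-filtered: %d\nunclassified: %d\nclassified: %d\n",
              x$k, as.integer(x$counts$shared),
              as.integer(x$counts$copy_filtered),
              as.integer(x$counts$unclassified),
              as.integer(x$counts$classified)))
  cat("classified by rank:\n")
  print(x$by_level)
  invisible(x)
}

#' Write / read a classification table as TSV
#'
#' Columns: `kmer`, `taxon_id`, `taxon_name`, `level_name`, `read_count`,
#' `ref_count`.
#'
#' @param x A `kmer_classifications` object.
#' @param path File path.
#' @return `write_classifications` returns `path` invisibly;
#'   `read_classifications` returns a data frame (the traversal summary is
#'   not persisted).
#' @export
write_classifications <- function(x, path) {
  df <- as.data.frame(x)[, c("kmer", "taxon_id", "taxon_name", "level_name",
                             "read_count", "ref_count")]
  s <- attr(x, "summary")
  hdr <- if (!is.null(s))
    sprintf("# shared=%d copy_filtered=%d unclassified=%d total_read_occurrences=%d",
            as.integer(s$shared), as.integer(s$copy_filtered),
            as.integer(s$unclassified), as.integer(s$total_read_occurrences))
  con <- file(path, "wb")
  writeLines(c(hdr, paste(colnames(df), collapse = "\t"),
               do.call(paste, c(unname(as.list(df)), sep = "\t"))), con)
  close(con)
  invisible(path)
}

#' @rdname write_classifications
#' @export
read_classifications <- function(path) {
  first <- readLines(path, n = 1L)
  df <- read.delim(path, header = TRUE, quote = "", comment.char = "#",
                   colClasses = c("character", "integer", "character",
                                  "character", "integer", "integer"))
  df$level <- match(df$level_name, TAX_LEVELS) - 1L
  if (startsWith(first, "#")) {
    kv <- regmatches(first, gregexpr("[a-z_]+=[0-9]+", first))[[1L]]
    s <- as.list(as.numeric(sub(".*=", "", kv)))
    names(s) <- sub("=.*", "", kv)
    s$classified <- nrow(df)
    attr(df, "summary") <- s
  }
  df
}

#' Assign whole reads by the LCA of their classified k-mers
#'
#' A secondary, non-canonical convenience: the primary unit of
#' classification is the k-mer. Each read is assigned the lowest common
#' ancestor of the taxa of its classified k-mers (reads whose k-mers were
#' all filtered or unshared stay unassigned).
#'
#' @param ref A `ref_index`.
#' @param reads A `read_set`.
#' @param k k-mer length.
#' @param classifications Optional precomputed [classify_dataset()] result
#'   for the same `ref`, reads and `k`.
#' @return Data frame with columns `read_id`, `taxon_id`, `taxon_name`,
#'   `level_name`, `n_kmers` (classified k-mer occurrences in the read).
#' @export
classify_reads <- function(ref, reads, k, classifications = NULL) {
  stopifnot(inherits(ref, "ref_index"), inherits(reads, "read_set"))
  if (is.null(classifications)) {
    idx <- build_read_index(reads)
    classifications <- classify_dataset(ref, idx, k)
  }
  cls <- as.data.frame(classifications)
  taxon_of <- cls$taxon_id
  names(taxon_of) <- cls$kmer
  rep_row <- rep_row_of_taxon(ref$taxonomy)
  lin <- ref$taxonomy$lineages
  level_of <- ref$taxonomy$level_of
  n <- length(reads$sequences)
  out_tax <- rep(NA_integer_, n)
  out_n <- integer(n)
  L <- reads$read_length
  for (i in seq_len(n)) {
    if (L < k) break
    kmers <- substring(reads$sequences[i], 1:(L - k + 1L), k:L)
    hit <- taxon_of[kmers]
    hit <- hit[!is.na(hit)]
    if (length(hit) == 0L) next
    out_n[i] <- length(hit)
    taxa <- unique(hit)
    # LCA over lineage prefixes of the hit taxa
    depth <- min(level_of[taxa])
    prefixes <- lin[rep_row[taxa], seq_len(depth + 1L), drop = FALSE]
    agree <- NA_integer_
    for (l in seq_len(depth + 1L)) {
      if (length(unique(prefixes[, l])) == 1L) agree <- l - 1L else break
    }
    if (!is.na(agree)) out_tax[i] <- prefixes[1L, agree + 1L]
  }
  data.frame(read_id = reads$ids,
             taxon_id = out_tax,
             taxon_name = ifelse(is.na(out_tax), NA_character_,
                                 ref$taxonomy$names[out_tax]),
             level_name = ifelse(is.na(out_tax), NA_character_,
                                 TAX_LEVELS[level_of[out_tax] + 1L]),
             n_kmers = out_n)
}
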