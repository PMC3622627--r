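# Taxonomic profiles: aggregation of k-mer read counts to a rank,
# genome-length normalization (sequence abundance -> cell abundance),
# percent fractions, and Euclidean profile comparison.

#' Aggregate classified k-mer read counts to one rank
#'
#' Every k-mer classified at rank `level` or deeper contributes its read
#' count to its lineage's ancestor taxon at `level`; k-mers classified at a
#' shallower rank contribute nothing.
#'
#' @param classifications A `kmer_classifications` object or compatible data
#'   frame (columns `taxon_id`, `level`, `read_count`).
#' @param taxonomy A `taxonomy_table`.
#' @param level Rank name (one of [tax_levels()]) or 0-based depth.
#' @return Named numeric vector of raw read counts, names = taxon ids at
#'   `level`.
#' @export
aggregate_by_level <- function(classifications, taxonomy, level) {
  stopifnot(inherits(taxonomy, "taxonomy_table"))
  l <- resolve_level(level)
  cls <- as.data.frame(classifications)
  if (nrow(cls) == 0L) return(numeric(0))
  if (anyNA(cls$taxon_id) || any(cls$taxon_id < 1L) ||
      any(cls$taxon_id > length(taxonomy$names)))
    stop("unknown taxon id in classifications")
  keep <- cls$level >= l
  if (!any(keep)) return(numeric(0))
  rep_row <- rep_row_of_taxon(taxonomy)
  anc <- taxonomy$lineages[rep_row[cls$taxon_id[keep]], l + 1L]
  counts <- tapply(cls$read_count[keep], anc, sum)
  out <- as.numeric(counts)
  names(out) <- names(counts)
  out
}

resolve_level <- function(level) {
  if (is.character(level)) {
    l <- match(level, TAX_LEVELS) - 1L
    if (is.na(l)) stop("unknown rank '", level, "'; expected one of ",
                       paste(TAX_LEVELS, collapse = ", "))
  } else {
    l <- as.integer(level)
    if (is.na(l) || l < 0L || l > 7L) stop("rank depth must be in 0..7")
  }
  l
}

#' Normalize taxon counts by mean genome length
#'
#' `normalized(t) = raw_count(t) / mean(length of every reference genome
#' whose lineage contains t)` — the mean is over all database genomes under
#' the taxon, not only detected ones, so the divisor is sample-independent.
#'
#' @param counts Named numeric vector from [aggregate_by_level()] (names =
#'   taxon ids).
#' @param taxonomy A `taxonomy_table`.
#' @param genome_lengths Named numeric vector of genome lengths (names =
#'   sequence ids of the taxonomy).
#' @return Named numeric vector of length-normalized values.
#' @export
normalize_by_genome_length <- function(counts, taxonomy, genome_lengths) {
  stopifnot(inherits(taxonomy, "taxonomy_table"))
  if (length(counts) == 0L) return(numeric(0))
  ids <- as.integer(names(counts))
  lens <- genome_lengths[rownames(taxonomy$lineages)]
  if (anyNA(lens)) stop("genome_lengths missing for some taxonomy genomes")
  out <- vapply(seq_along(ids), function(i) {
    t <- ids[i]
    lv <- taxonomy$level_of[t]
    under <- taxonomy$lineages[, lv + 1L] == t
    if (!any(under)) stop("taxon ", t, " has no genomes in the reference")
    counts[i] / mean(lens[under])
  }, numeric(1L))
  names(out) <- names(counts)
  out
}

#' Convert normalized values to percent fractions
#'
#' @param normalized Named non-negative numeric vector with at least one
#'   positive entry.
#' @return Named numeric vector summing to 100.
#' @export
to_fractions <- function(normalized) {
  if (length(normalized) == 0L || sum(normalized) <= 0)
    stop("cannot compute fractions of an all-zero profile")
  100 * normalized / sum(normalized)
}

#' Build a taxonomic profile at one rank
#'
#' Runs [aggregate_by_level()], [normalize_by_genome_length()] and
#' [to_fractions()] over a classification table. With
#' `include_unclassified`, the read-count mass of shared k-mers that did not
#' contribute at this rank (copy-filtered, unclassified, or classified at a
#' shallower rank) is carried as an explicit `unclassified` entry,
#' normalized by the mean length of all reference genomes, and competes for
#' the percent fractions.
#'
#' @param classifications A `kmer_classifications` object (from
#'   [classify_dataset()]; the traversal summary is required when
#'   `include_unclassified = TRUE`).
#' @param ref A `ref_index`.
#' @param level Rank name or 0-based depth.
#' @param include_unclassified Carry non-contributing read mass as an
#'   `unclassified` bucket?
#' @return An object of class `taxonomic_profile`: a data frame with columns
#'   `taxon_id`, `taxon`, `raw_count`, `normalized`, `fraction` (percent),
#'   with the rank name in `attr(, "level")`.
#' @export
taxonomic_profile <- function(classifications, ref, level,
                              include_unclassified = FALSE) {
  stopifnot(inherits(ref, "ref_index"))
  l <- resolve_level(level)
  counts <- aggregate_by_level(classifications, ref$taxonomy, l)
  if (length(counts) == 0L)
    stop("no k-mer was classified at rank ", TAX_LEVELS[l + 1L], " or deeper")
  normalized <- normalize_by_genome_length(counts, ref$taxonomy,
                                           ref$genome_lengths)
  ids <- as.integer(names(counts))
  taxa <- unname(ref$taxonomy$names[ids])
  raw <- as.numeric(counts)
  norm <- as.numeric(normalized)
  if (include_unclassified) {
    s <- attr(classifications, "summary")
    if (is.null(s))
      stop("include_unclassified requires a classify_dataset() result")
    rest <- s$total_read_occurrences - sum(raw)
    ids <- c(ids, NA_integer_)
    taxa <- c(taxa, "unclassified")
    raw <- c(raw, rest)
    norm <- c(norm, rest / mean(ref$genome_lengths))
  }
  new_profile(ids, taxa, raw, norm, TAX_LEVELS[l + 1L])
}

new_profile <- function(taxon_id, taxon, raw_count, normalized, level_name) {
  frac <- as.numeric(to_fractions(pmax(normalized, 0)))
  structure(
    data.frame(taxon_id = taxon_id, taxon = taxon, raw_count = raw_count,
               normalized = normalized, fraction = frac),
    level = level_name,
    class = c("taxonomic_profile", "data.frame"))
}

#' Assemble a taxonomic profile from known fractions
#'
#' Used for ground-truth profiles and for profiles read back from files.
#'
#' @param taxa Character vector of taxon names at the rank.
#' @param fractions Percent fractions (rescaled to sum to 100).
#' @param level Rank name or 0-based depth.
#' @return A `taxonomic_profile` (with `NA` raw counts).
#' @export
profile_from_fractions <- function(taxa, fractions, level) {
  l <- resolve_level(level)
  new_profile(rep(NA_integer_, length(taxa)), taxa,
              rep(NA_real_, length(taxa)), as.numeric(fractions),
              TAX_LEVELS[l + 1L])
}

#' @export
print.taxonomic_profile <- function(x, ...) {
  cat(sprintf("Taxonomic profile at rank %s (%d taxa)\n",
              attr(x, "level"), nrow(x)))
  df <- as.data.frame(x)
  df <- df[order(-df$fraction), ]
  df$fraction <- sprintf("%.2f%%", df$fraction)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' Euclidean distance between two taxonomic profiles
#'
#' Computed on percent fractions over the union of taxa (missing taxa count
#' as 0), including any explicit `unclassified` entries. Both profiles must
#' be at the same rank.
#'
#' @param p,q `taxonomic_profile` objects at the same rank.
#' @return Non-negative scalar; 0 iff the profiles are equal.
#' @export
#' @examples
#' p <- profile_from_fractions("X", 100, "species")
#' q <- profile_from_fractions("Y", 100, "species")
#' euclidean_distance(p, q)  # sqrt(20000) = 141.42...
euclidean_distance <- function(p, q) {
  stopifnot(inherits(p, "taxonomic_profile"), inherits(q, "taxonomic_profile"))
  if (!identical(attr(p, "level"), attr(q, "level")))
    stop("profiles are at different ranks (", attr(p, "level"), " vs ",
         attr(q, "level"), ")")
  taxa <- union(p$taxon, q$taxon)
  fp <- p$fraction[match(taxa, p$taxon)]
  fq <- q$fraction[match(taxa, q$taxon)]
  fp[is.na(fp)] <- 0
  fq[is.na(fq)] <- 0
  sqrt(sum((fp - fq)^2))
}

#' Write / read a taxonomic profile as TSV
#'
#' Columns: `level`, `taxon_id`, `taxon_name`, `raw_count`, `normalized`,
#' `fraction_percent`.
#'
#' @param x A `taxonomic_profile`.
#' @param path File path.
#' @return `write_profile` returns `path` invisibly; `read_profile` returns
#'   a `taxonomic_profile`.
#' @export
write_profile <- function(x, path) {
  stopifnot(inherits(x, "taxonomic_profile"))
  df <- data.frame(level = attr(x, "level"), taxon_id = x$taxon_id,
                   taxon_name = x$taxon, raw_count = x$raw_count,
                   normalized = sprintf("%.10g", x$normalized),
                   fraction_percent = sprintf("%.10g", x$fraction))
  con <- file(path, "wb")
  writeLines(c(paste(colnames(df), collapse = "\t"),
               do.call(paste, c(unname(as.list(df)), sep = "\t"))), con)
  close(con)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  df <- read.delim(path, header = TRUE, quote = "", comment.char = "")
  lvl <- unique(df$level)
  if (length(lvl) != 1L) stop("profile file mixes ranks")
  new_profile(df$taxon_id, df$taxon_name, df$raw_count,
              as.numeric(df$normalized), lvl)
}
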