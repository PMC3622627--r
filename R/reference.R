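# Taxonomy-annotated reference index: generalized BWT/GSA over genomes and
# their reverse complements, plus the taxonomy table, genome lengths, and a
# member -> genome mapping.  Members are interleaved so that member 2j is a
# forward record and member 2j+1 its reverse complement.

#' Read genome sequences from FASTA files
#'
#' Multi-record, wrapped-line, case-insensitive FASTA. Record names are the
#' first whitespace-delimited token of each header. Degenerate IUPAC codes
#' other than N are converted to N with a warning. Records sharing a name
#' are kept (they are treated as contigs of one genome by
#' [build_reference_index()]).
#'
#' @param paths Character vector of FASTA file paths.
#' @return Named character vector of uppercase sequences over A, C, G, T, N.
#' @export
read_genomes <- function(paths) {
  recs <- lapply(paths, function(p) {
    x <- Biostrings::readDNAStringSet(p)
    out <- toupper(as.character(x))
    names(out) <- sub("\\s.*$", "", names(x))
    out
  })
  seqs <- unlist(recs)
  n_amb <- sum(vapply(seqs, function(s) {
    nchar(gsub("[ACGTN]", "", s))
  }, numeric(1L)))
  if (n_amb > 0) {
    warning(sprintf("converted %d degenerate IUPAC base(s) to N", n_amb))
    seqs <- vapply(seqs, function(s) gsub("[^ACGTN]", "N", s), character(1L))
  }
  seqs
}

#' Write sequences to a FASTA file
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path,
                              width = width)
  invisible(path)
}

#' Build the taxonomy-annotated reference index
#'
#' Each (non-excluded) genome record contributes two index members: its
#' forward sequence and its reverse complement, both mapped to the same
#' genome. Records sharing a sequence id are contigs of one genome: each
#' becomes its own member pair and genome length is the sum over records.
#'
#' @param genomes Named character vector of genome records (names are
#'   sequence ids matching the taxonomy).
#' @param taxonomy A `taxonomy_table` with a lineage for every genome id.
#' @param exclude Character vector of record ids to drop before indexing
#'   (e.g. plasmids).
#' @return An object of class `ref_index`.
#' @export
build_reference_index <- function(genomes, taxonomy, exclude = character()) {
  stopifnot(inherits(taxonomy, "taxonomy_table"))
  if (length(exclude) > 0L) genomes <- genomes[!(names(genomes) %in% exclude)]
  if (length(genomes) == 0L) stop("no genomes left after exclusion")
  known <- rownames(taxonomy$lineages)
  missing <- setdiff(unique(names(genomes)), known)
  if (length(missing) > 0L)
    stop("genome without lineage: ", paste(missing, collapse = ", "))
  genome_ids <- unique(names(genomes))
  genome_idx <- match(names(genomes), genome_ids) - 1L  # per record, 0-based
  rc <- reverse_complement(genomes)
  n_rec <- length(genomes)
  members <- character(2L * n_rec)
  members[2L * seq_len(n_rec) - 1L] <- genomes
  members[2L * seq_len(n_rec)] <- rc
  strand <- rep(c("+", "-"), n_rec)
  member_ids <- sprintf("%s|%d|%s", rep(names(genomes), each = 2L),
                        rep(seq_len(n_rec), each = 2L), c("fwd", "rc"))
  names(members) <- member_ids
  gbwt <- build_gsa_bwt(members)
  genome_lengths <- vapply(split(nchar(genomes), names(genomes)), sum,
                           numeric(1L))[genome_ids]
  # concatenated text codes (terminator = 0 between members) and per-member
  # start offsets: used to extract k-mer strings during traversal
  lens <- nchar(members)
  member_starts <- c(0L, cumsum(as.integer(lens) + 1L))[seq_len(2L * n_rec)]
  text <- integer(sum(lens) + 2L * n_rec)
  pos <- member_starts + 1L
  codes <- encode_seq(paste(members, collapse = ""))
  off <- 0L
  for (j in seq_len(2L * n_rec)) {
    text[pos[j]:(pos[j] + lens[j] - 1L)] <- codes[(off + 1L):(off + lens[j])]
    off <- off + lens[j]
  }
  structure(
    list(gbwt = gbwt,
         genome_of_member = rep(genome_idx, each = 2L),
         genome_ids = genome_ids,
         genome_lengths = genome_lengths,
         taxonomy = taxonomy,
         members = members,
         member_strand = strand,
         text = text,
         member_starts = member_starts),
    class = "ref_index")
}

#' @export
print.ref_index <- function(x, ...) {
  cat(sprintf(paste0("Reference index: %d genome(s) (%d record pair(s), both",
                     " strands), %.3g Mbp indexed\n"),
              length(x$genome_ids), length(x$members) / 2L,
              sum(nchar(x$members)) / 1e6))
  invisible(x)
}

REF_FORMAT_VERSION <- 1L

#' Save / load a reference index
#'
#' Directory layout (versioned): `header.json`, the forward records as
#' `records.fasta`, the taxonomy as `taxonomy.tsv`, and the generalized BWT
#' under `gbwt/` (see [save_gbwt()]). Loading rebuilds the reverse
#' complements and rank structures; saves are byte-identical for equal
#' indexes.
#'
#' @param x A `ref_index`.
#' @param path Directory path.
#' @return `save_index` returns `path` invisibly; `load_index` returns a
#'   `ref_index` structurally equal to the saved one.
#' @export
save_index <- function(x, path) {
  stopifnot(inherits(x, "ref_index"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  n_rec <- length(x$members) / 2L
  fwd <- x$members[2L * seq_len(n_rec) - 1L]
  record_ids <- sub("\\|\\d+\\|fwd$", "", names(fwd))
  names(fwd) <- sprintf("record_%d %s", seq_len(n_rec), record_ids)
  header <- list(format = "kmertax-ref", version = REF_FORMAT_VERSION,
                 n_records = n_rec, record_ids = unname(record_ids),
                 genome_ids = x$genome_ids)
  jsonlite::write_json(header, file.path(path, "header.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_fasta(fwd, file.path(path, "records.fasta"))
  write_taxonomy(x$taxonomy, file.path(path, "taxonomy.tsv"))
  save_gbwt(x$gbwt, file.path(path, "gbwt"))
  invisible(path)
}

#' @rdname save_index
#' @export
load_index <- function(path) {
  hpath <- file.path(path, "header.json")
  if (!file.exists(hpath)) stop("not a reference index directory: ", path)
  header <- jsonlite::read_json(hpath, simplifyVector = TRUE)
  if (!identical(header$format, "kmertax-ref"))
    stop("unrecognized index format")
  if (!identical(as.integer(header$version), REF_FORMAT_VERSION))
    stop(sprintf("index format version %s not supported (expected %d)",
                 header$version, REF_FORMAT_VERSION))
  fwd <- read_genomes(file.path(path, "records.fasta"))
  names(fwd) <- as.character(header$record_ids)
  taxonomy <- load_taxonomy(file.path(path, "taxonomy.tsv"))
  x <- build_reference_index(fwd, taxonomy)
  stored <- load_gbwt(file.path(path, "gbwt"))
  if (!identical(stored$bwt, x$gbwt$bwt) ||
      !identical(stored$A, x$gbwt$A) || !identical(stored$C, x$gbwt$C))
    stop("corrupt index: stored BWT disagrees with records")
  if (!identical(as.character(header$genome_ids), x$genome_ids))
    stop("corrupt index: genome ids disagree with records")
  x
}
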