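# Eight-level taxonomy table.
#
# Lineages are rows of integer taxon identifiers at the fixed ranks
# superkingdom..strain.  Names are interned to integer ids in first-seen
# order (scanning rows top to bottom, ranks left to right), and the same id
# never appears at two different ranks.

#' Construct a taxonomy table from a data frame
#'
#' @param df Data frame whose first column is `sequence_id` and whose next
#'   eight columns are lineage names at the ranks superkingdom, phylum,
#'   class, order, family, genus, species, strain.
#' @return An object of class `taxonomy_table`: `lineages` (integer matrix,
#'   one row per genome, rownames = sequence ids), `names` (character vector
#'   mapping taxon id to name), `level_of` (integer vector, 0-based rank of
#'   each taxon id), `levels` (the eight rank names).
#' @details Interning is deterministic: identical inputs yield identical
#'   tables. Lineages must form a tree (a taxon may not appear under two
#'   different parents) and strain names must be unique per genome.
#' @export
as_taxonomy <- function(df) {
  if (ncol(df) < 9L)
    stop("expected 8 levels: need columns sequence_id + ",
         paste(TAX_LEVELS, collapse = ", "))
  ids <- as.character(df[[1L]])
  if (anyNA(ids) || any(ids == ""))
    stop("row ", which(is.na(ids) | ids == "")[1L], ": missing sequence_id")
  dup <- which(duplicated(ids))
  if (length(dup) > 0L)
    stop("row ", dup[1L], ": duplicate sequence_id '", ids[dup[1L]], "'")
  nm <- as.matrix(df[, 2:9, drop = FALSE])
  mode(nm) <- "character"
  bad <- which(apply(nm, 1L, function(r) anyNA(r) | any(r == "")))
  if (length(bad) > 0L)
    stop("row ", bad[1L], ": expected 8 levels (superkingdom..strain)")
  m <- nrow(nm)
  # intern (level, name) pairs in row-major first-seen order
  flat <- paste(rep(1:8, m), as.vector(t(nm)), sep = "\r")
  uniq <- unique(flat)
  id_of <- match(flat, uniq)
  lineages <- matrix(id_of, ncol = 8L, byrow = TRUE,
                     dimnames = list(ids, TAX_LEVELS))
  parts <- strsplit(uniq, "\r", fixed = TRUE)
  tax_names <- vapply(parts, `[`, character(1L), 2L)
  level_of <- as.integer(vapply(parts, `[`, character(1L), 1L)) - 1L
  # tree consistency: every non-root taxon has a single parent
  for (l in 2:8) {
    par <- tapply(lineages[, l - 1L], lineages[, l], function(v) length(unique(v)))
    if (any(par > 1L)) {
      t_bad <- as.integer(names(par)[which(par > 1L)[1L]])
      stop(sprintf("inconsistent lineage: %s '%s' appears under two different %s",
                   TAX_LEVELS[l], tax_names[t_bad], TAX_LEVELS[l - 1L]))
    }
  }
  if (anyDuplicated(lineages[, 8L]))
    stop("strain '", tax_names[lineages[, 8L][duplicated(lineages[, 8L])][1L]],
         "' assigned to more than one genome")
  structure(list(lineages = lineages, names = tax_names,
                 level_of = level_of, levels = TAX_LEVELS),
            class = "taxonomy_table")
}

#' Load a taxonomy table from a TSV file
#'
#' The file must have a header row and columns `sequence_id` followed by the
#' eight rank names (superkingdom..strain); loading the same file twice
#' yields identical tables.
#'
#' @param path Path to a tab-separated file.
#' @return A `taxonomy_table`; see [as_taxonomy()].
#' @export
load_taxonomy <- function(path) {
  df <- read.delim(path, header = TRUE, colClasses = "character",
                   check.names = FALSE, quote = "", comment.char = "")
  if (nrow(df) == 0L) stop("empty taxonomy file: ", path)
  as_taxonomy(df)
}

#' Write a taxonomy table to TSV
#'
#' Inverse of [load_taxonomy()]: writes sequence ids plus the eight lineage
#' name columns.
#'
#' @param x A `taxonomy_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_taxonomy <- function(x, path) {
  stopifnot(inherits(x, "taxonomy_table"))
  df <- as.data.frame(matrix(x$names[x$lineages], ncol = 8L,
                             dimnames = list(NULL, TAX_LEVELS)))
  df <- cbind(sequence_id = rownames(x$lineages), df)
  con <- file(path, "wb")
  writeLines(c(paste(colnames(df), collapse = "\t"),
               do.call(paste, c(unname(as.list(df)), sep = "\t"))), con)
  close(con)
  invisible(path)
}

#' @export
print.taxonomy_table <- function(x, ...) {
  cat(sprintf("Taxonomy table: %d genome(s), %d distinct taxa over 8 ranks\n",
              nrow(x$lineages), length(x$names)))
  invisible(x)
}

#' Human-readable name of taxon ids
#' @param taxonomy A `taxonomy_table`.
#' @param id Integer taxon id(s).
#' @return Character vector of names.
#' @export
taxon_name <- function(taxonomy, id) taxonomy$names[id]

# First lineage row containing each taxon id (taxonomy is a tree, so any
# row containing the taxon carries the same ancestry above it).
rep_row_of_taxon <- function(taxonomy) {
  n <- length(taxonomy$names)
  rep_row <- integer(n)
  lin <- taxonomy$lineages
  for (l in 8:1) {
    first <- !duplicated(lin[, l])
    rep_row[lin[first, l]] <- which(first)
  }
  rep_row
}
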