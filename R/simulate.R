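# Synthetic metagenome communities: phylogenetically structured reference
# genomes with known lineages, shotgun reads at specified cell abundances
# with substitution errors, ground-truth profiles, and the species-masking
# experiment.
#
# Genomes are generated top-down along the taxonomy tree: one random
# ancestor sequence per distinct taxon at each rank, children derived from
# their parent by point substitutions at a per-rank divergence rate.  Taxa
# in different superkingdoms therefore share no sequence beyond chance,
# while same-genus species remain detectably similar.

DEFAULT_DIVERGENCE <- c(phylum = 0.25, class = 0.18, order = 0.12,
                        family = 0.08, genus = 0.05, species = 0.02,
                        strain = 0.005)

#' Specify a synthetic community
#'
#' @param taxa Data frame with the eight rank-name columns (superkingdom ..
#'   strain; one row per organism/genome), plus `genome_length` (bp) and
#'   `cell_fraction` (summing to 1).
#' @param read_length Uniform read length in bp.
#' @param n_reads Number of reads to simulate.
#' @param error_rate Per-base substitution error rate in `[0, 1)`.
#' @param seed Integer seed; all generator randomness flows from it.
#' @param divergence Named positive vector of per-rank substitution rates
#'   (phylum..strain) applied when deriving a child taxon's sequence from
#'   its parent; must be non-increasing with depth of the split... i.e.
#'   shallower splits diverge at least as much as deeper ones.
#' @return An object of class `community_spec`.
#' @export
community_spec <- function(taxa, read_length = 80L, n_reads = 100000L,
                           error_rate = 0.01, seed = 1L,
                           divergence = DEFAULT_DIVERGENCE) {
  need <- c(TAX_LEVELS, "genome_length", "cell_fraction")
  miss <- setdiff(need, colnames(taxa))
  if (length(miss) > 0L)
    stop("taxa is missing column(s): ", paste(miss, collapse = ", "))
  if (abs(sum(taxa$cell_fraction) - 1) > 1e-8)
    stop("cell fractions must sum to 1")
  if (any(taxa$cell_fraction <= 0)) stop("cell fractions must be positive")
  if (any(taxa$genome_length < read_length))
    stop("every genome must be at least one read long")
  if (!identical(names(divergence), names(DEFAULT_DIVERGENCE)))
    stop("divergence must be named ", paste(names(DEFAULT_DIVERGENCE),
                                            collapse = ", "))
  if (any(divergence <= 0) || is.unsorted(rev(divergence)))
    stop("divergence rates must be positive and non-increasing with depth")
  if (error_rate < 0 || error_rate >= 1) stop("error_rate must be in [0, 1)")
  if (anyDuplicated(taxa$strain)) stop("strain names must be unique")
  structure(list(taxa = taxa, read_length = as.integer(read_length),
                 n_reads = as.integer(n_reads), error_rate = error_rate,
                 seed = as.integer(seed), divergence = divergence),
            class = "community_spec")
}

#' @export
print.community_spec <- function(x, ...) {
  cat(sprintf(paste0("Community spec: %d organism(s), %d reads of %d bp, ",
                     "error rate %.3g, seed %d\n"),
              nrow(x$taxa), x$n_reads, x$read_length, x$error_rate, x$seed))
  invisible(x)
}

#' An even community of distinct species
#'
#' The default community mirrors a benchmark design of fifteen bacterial
#' organisms at equal cell abundance, each its own genus/species/strain,
#' grouped into a consistent hierarchy (3 phyla of 5 organisms, orders of at
#' most 3), with genome lengths spanning a 10-fold range so that
#' genome-length normalization matters.
#'
#' @param n_species Number of organisms.
#' @param genome_lengths Genome lengths in bp (recycled/defaulted to an even
#'   spread over `20000..200000`).
#' @param ... Passed to [community_spec()] (`read_length`, `n_reads`,
#'   `error_rate`, `seed`, ...).
#' @return A `community_spec` with equal cell fractions `1/n_species`.
#' @export
even_community <- function(n_species = 15L,
                           genome_lengths = round(seq(20000, 200000,
                                                      length.out = n_species)),
                           ...) {
  i <- seq_len(n_species)
  phy <- (i - 1L) %/% 5L + 1L
  within <- (i - 1L) %% 5L
  ord <- paste0("p", phy, "_o", within %/% 3L + 1L)
  taxa <- data.frame(
    superkingdom = "superkingdom_1",
    phylum = paste0("phylum_", phy),
    class = paste0("class_", phy),
    order = paste0("order_", ord),
    family = paste0("family_", ord),
    genus = paste0("genus_", i),
    species = paste0("species_", i),
    strain = paste0("strain_", i),
    genome_length = rep_len(genome_lengths, n_species),
    cell_fraction = rep(1 / n_species, n_species))
  community_spec(taxa, ...)
}

# integer-coded random sequence / substitution helpers (codes 0..3 = ACGT)
random_codes <- function(len) sample.int(4L, len, replace = TRUE) - 1L

mutate_codes <- function(codes, rate) {
  n_mut <- rbinom(1L, length(codes), rate)
  if (n_mut == 0L) return(codes)
  pos <- sample.int(length(codes), n_mut)
  codes[pos] <- (codes[pos] + sample.int(3L, n_mut, replace = TRUE)) %% 4L
  codes
}

codes_to_string <- function(codes) {
  intToUtf8(c(65L, 67L, 71L, 84L)[codes + 1L])
}

#' Generate the reference genomes and taxonomy of a community
#'
#' One ancestor sequence is drawn per distinct taxon at each rank
#' (independent random sequences per superkingdom), each child derived from
#' its parent by substitutions at the per-rank divergence rate; every
#' genome is the prefix of its strain sequence at its specified length.
#' Deterministic under the spec seed.
#'
#' @param spec A `community_spec`.
#' @return List with `genomes` (named character vector, names = strain
#'   names used as sequence ids) and `taxonomy` (a `taxonomy_table`).
#' @export
simulate_reference_set <- function(spec) {
  stopifnot(inherits(spec, "community_spec"))
  taxa <- spec$taxa
  tax_df <- cbind(data.frame(sequence_id = taxa$strain),
                  taxa[, TAX_LEVELS])
  taxonomy <- as_taxonomy(tax_df)  # validates lineage consistency
  genomes <- with_seed(spec$seed, {
    node_seq <- new.env(parent = emptyenv())
    # path key of each row at each rank
    paths <- vapply(seq_len(8L), function(l) {
      apply(taxa[, TAX_LEVELS[seq_len(l)], drop = FALSE], 1L, paste,
            collapse = "|")
    }, character(nrow(taxa)))
    paths <- matrix(paths, nrow = nrow(taxa))
    # required ancestor length: max genome length below the node
    for (l in seq_len(8L)) {
      for (key in unique(paths[, l])) {
        rows <- which(paths[, l] == key)
        len <- max(taxa$genome_length[rows])
        s <- if (l == 1L) {
          random_codes(len)
        } else {
          parent <- get(paths[rows[1L], l - 1L], envir = node_seq)
          mutate_codes(parent[seq_len(len)], spec$divergence[[l - 1L]])
        }
        assign(key, s, envir = node_seq)
      }
    }
    out <- vapply(seq_len(nrow(taxa)), function(i) {
      codes_to_string(get(paths[i, 8L],
                          envir = node_seq)[seq_len(taxa$genome_length[i])])
    }, character(1L))
    names(out) <- taxa$strain
    out
  })
  list(genomes = genomes, taxonomy = taxonomy)
}

#' Simulate shotgun reads from a community
#'
#' Each read's source genome is drawn with probability proportional to
#' `cell_fraction * genome_length` (cell-abundance semantics: a cell
#' contributes DNA in proportion to its genome size), its start position
#' uniformly, its strand uniformly, and substitution errors are applied per
#' base at `error_rate`. Deterministic under the spec seed.
#'
#' @param genomes Named character vector from [simulate_reference_set()]
#'   (possibly modified, e.g. masked or duplicated variants).
#' @param spec The `community_spec`.
#' @return A [read_set()] with extra fields `source` (true source genome id
#'   per read), `strand`, and `start` (1-based forward-strand position).
#' @export
simulate_reads <- function(genomes, spec) {
  stopifnot(inherits(spec, "community_spec"))
  taxa <- spec$taxa
  if (!all(taxa$strain %in% names(genomes)))
    stop("genomes missing for some community members")
  genomes <- genomes[taxa$strain]
  lens <- nchar(genomes)
  rl <- spec$read_length
  if (any(lens < rl)) stop("genome shorter than the read length")
  with_seed(spec$seed + 1L, {
    w <- taxa$cell_fraction * lens
    src <- sample.int(nrow(taxa), spec$n_reads, replace = TRUE, prob = w)
    start <- integer(spec$n_reads)
    seqs <- character(spec$n_reads)
    for (j in seq_len(nrow(taxa))) {
      idx <- which(src == j)
      if (length(idx) == 0L) next
      st <- sample.int(lens[j] - rl + 1L, length(idx), replace = TRUE)
      start[idx] <- st
      seqs[idx] <- substring(genomes[j], st, st + rl - 1L)
    }
    strand <- ifelse(runif(spec$n_reads) < 0.5, "+", "-")
    rev_idx <- which(strand == "-")
    if (length(rev_idx) > 0L)
      seqs[rev_idx] <- reverse_complement(seqs[rev_idx])
    if (spec$error_rate > 0) {
      n_err <- rbinom(spec$n_reads, rl, spec$error_rate)
      hit <- which(n_err > 0L)
      for (i in hit) {
        chars <- strsplit(seqs[i], "", fixed = TRUE)[[1L]]
        pos <- sample.int(rl, n_err[i])
        old <- match(chars[pos], c("A", "C", "G", "T")) - 1L
        old[is.na(old)] <- sample.int(4L, sum(is.na(old)), replace = TRUE) - 1L
        chars[pos] <- c("A", "C", "G", "T")[
          ((old + sample.int(3L, n_err[i], replace = TRUE)) %% 4L) + 1L]
        seqs[i] <- paste(chars, collapse = "")
      }
    }
    rs <- read_set(seqs)
    rs$source <- taxa$strain[src]
    rs$strand <- strand
    rs$start <- start
    rs
  })
}

#' Ground-truth profile of a community at one rank
#'
#' Cell fractions aggregated to the requested rank, on the percent scale.
#'
#' @param spec A `community_spec`.
#' @param level Rank name or 0-based depth.
#' @return A `taxonomic_profile` (taxon names only; `NA` raw counts).
#' @export
true_profile <- function(spec, level) {
  stopifnot(inherits(spec, "community_spec"))
  l <- resolve_level(level)
  fr <- tapply(spec$taxa$cell_fraction, spec$taxa[[TAX_LEVELS[l + 1L]]], sum)
  profile_from_fractions(names(fr), 100 * as.numeric(fr), l)
}

#' Remove all reference genomes of given species
#'
#' Emulates classifying reads from organisms absent from the database:
#' every genome whose lineage contains one of the masked species is dropped
#' from the reference set (reads are not changed).
#'
#' @param genomes Named character vector of genomes (names = sequence ids).
#' @param taxonomy A `taxonomy_table` covering the genomes.
#' @param species Character vector of species names to mask.
#' @return List with the filtered `genomes` and `taxonomy`.
#' @export
mask_species <- function(genomes, taxonomy, species) {
  stopifnot(inherits(taxonomy, "taxonomy_table"))
  sp_names <- taxonomy$names[taxonomy$lineages[, "species"]]
  unknown <- setdiff(species, sp_names)
  if (length(unknown) > 0L)
    stop("unknown species: ", paste(unknown, collapse = ", "))
  drop_ids <- rownames(taxonomy$lineages)[sp_names %in% species]
  keep <- !(names(genomes) %in% drop_ids)
  if (!any(keep)) stop("masking would remove every reference genome")
  kept_ids <- setdiff(rownames(taxonomy$lineages), drop_ids)
  df <- data.frame(sequence_id = kept_ids,
                   matrix(taxonomy$names[taxonomy$lineages[kept_ids, ,
                                                           drop = FALSE]],
                          ncol = 8L, dimnames = list(NULL, TAX_LEVELS)))
  list(genomes = genomes[keep], taxonomy = as_taxonomy(df))
}
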