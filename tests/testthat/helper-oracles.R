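# Independent brute-force oracles used to pin down expected values.
# Everything here works by suffix enumeration, substring scanning and hash
# tables -- never through the package's index machinery.

# Distinct terminators rendered as "!<member number>" sort below "A" and in
# member order under byte-wise (radix) string ordering.
oracle_suffix_table <- function(seqs) {
  m <- length(seqs)
  rows <- do.call(rbind, lapply(seq_len(m), function(j) {
    s <- seqs[[j]]
    n <- nchar(s)
    term <- sprintf("!%09d", j)
    off <- 0:n
    data.frame(member = j - 1L, offset = off,
               suffix = paste0(substring(s, off + 1L, n), term),
               prev = ifelse(off == 0L, "$", substring(s, off, off)))
  }))
  rows[order(rows$suffix, method = "radix"), , drop = FALSE]
}

# overlapping occurrence count of q across all members
oracle_count <- function(seqs, q) {
  k <- nchar(q)
  sum(vapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(0L)
    sum(substring(s, 1:(n - k + 1L), k:n) == q)
  }, integer(1L)))
}

oracle_kmers <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  unique(substring(s, 1:(n - k + 1L), k:n))
}

oracle_rc <- function(s) {
  vapply(s, function(x) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "", fixed = TRUE)[[1L]]),
          collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

random_collection <- function(n_members, min_len = 1L, max_len = 200L,
                              p_n = 0.02) {
  lens <- sample(min_len:max_len, n_members, replace = TRUE)
  seqs <- vapply(lens, function(l) {
    paste(sample(c("A", "C", "G", "T", "N"), l, replace = TRUE,
                 prob = c(rep((1 - p_n) / 4, 4L), p_n)), collapse = "")
  }, character(1L))
  names(seqs) <- paste0("m", seq_along(seqs))
  seqs
}

# Hash-table reimplementation of the whole classifier: per-genome k-mer
# counts with strands pooled, once-per-genome filter, explicit lineage LCA.
# tax_df holds lineage NAMES (sequence_id + 8 rank columns), matching the
# genomes by name.
oracle_classify <- function(genomes, tax_df, reads, k) {
  counts_tab <- function(s) {
    n <- nchar(s)
    if (n < k) return(table(character(0)))
    table(substring(s, 1:(n - k + 1L), k:n))
  }
  per_genome <- lapply(genomes, function(g) {
    t1 <- counts_tab(g)
    t2 <- counts_tab(oracle_rc(g))
    all <- union(names(t1), names(t2))
    v1 <- as.integer(t1[all]); v1[is.na(v1)] <- 0L
    v2 <- as.integer(t2[all]); v2[is.na(v2)] <- 0L
    out <- v1 + v2
    names(out) <- all
    out
  })
  read_tab <- counts_tab(paste0(reads, collapse = "!"))  # "!" blocks joins
  read_tab <- read_tab[!grepl("!", names(read_tab), fixed = TRUE)]
  ref_kmers <- unique(unlist(lapply(per_genome, names)))
  shared <- sort(intersect(ref_kmers, names(read_tab)), method = "radix")
  lin <- as.matrix(tax_df[match(names(genomes), tax_df$sequence_id),
                          2:9, drop = FALSE])
  rows <- lapply(shared, function(q) {
    counts <- vapply(per_genome, function(t) {
      v <- t[q]
      if (is.na(v)) 0L else as.integer(v)
    }, integer(1L))
    present <- which(counts > 0L)
    if (any(counts[present] > 1L)) return(NULL)  # copy-number filter
    sub <- lin[present, , drop = FALSE]
    lvl <- NA_integer_
    for (l in 1:8) {
      if (nrow(unique(sub[, 1:l, drop = FALSE])) == 1L) lvl <- l - 1L
      else break
    }
    if (is.na(lvl)) return(NULL)  # unclassified
    data.frame(kmer = q, taxon_name = unname(sub[1L, lvl + 1L]), level = lvl,
               read_count = as.integer(read_tab[q]),
               ref_count = as.integer(sum(counts)))
  })
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (length(rows) == 0L)
    return(data.frame(kmer = character(0), taxon_name = character(0),
                      level = integer(0), read_count = integer(0),
                      ref_count = integer(0)))
  do.call(rbind, rows)
}

# small related community used by several classifier tests
small_community <- function(n_species = 3L, genome_length = 1500L,
                            n_reads = 150L, error_rate = 0.01, seed = 1L,
                            read_length = 60L) {
  even_community(n_species,
                 genome_lengths = rep(genome_length, n_species),
                 read_length = read_length, n_reads = n_reads,
                 error_rate = error_rate, seed = seed)
}
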