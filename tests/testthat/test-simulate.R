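# Synthetic community generator: divergence structure, abundance semantics,
# error model, determinism, masking.

test_that("generation is deterministic under the spec seed", {
  spec <- small_community(seed = 42L)
  a <- simulate_reference_set(spec)
  b <- simulate_reference_set(spec)
  expect_identical(a, b)
  ra <- simulate_reads(a$genomes, spec)
  rb <- simulate_reads(b$genomes, spec)
  expect_identical(ra, rb)
})

test_that("sibling strains diverge at about twice the strain rate", {
  taxa <- data.frame(
    superkingdom = "B", phylum = "P", class = "C", order = "O",
    family = "F", genus = "G", species = "S",
    strain = c("T1", "T2"),
    genome_length = 20000L, cell_fraction = 0.5)
  div <- c(phylum = 0.25, class = 0.18, order = 0.12, family = 0.08,
           genus = 0.05, species = 0.02, strain = 0.01)
  spec <- community_spec(taxa, seed = 2L, divergence = div)
  g <- simulate_reference_set(spec)$genomes
  a <- strsplit(g[["T1"]], "")[[1L]]
  b <- strsplit(g[["T2"]], "")[[1L]]
  identity <- mean(a == b)
  # two independent draws at rate 0.01 from the species ancestor
  expect_gt(identity, 0.975)
  expect_lt(identity, 0.99)
})

test_that("different superkingdoms share essentially no 20-mers", {
  taxa <- data.frame(
    superkingdom = c("B", "A"), phylum = c("P1", "P2"),
    class = c("C1", "C2"), order = c("O1", "O2"), family = c("F1", "F2"),
    genus = c("G1", "G2"), species = c("S1", "S2"), strain = c("T1", "T2"),
    genome_length = 30000L, cell_fraction = 0.5)
  spec <- community_spec(taxa, seed = 3L)
  g <- simulate_reference_set(spec)$genomes
  shared <- intersect(oracle_kmers(g[[1L]], 20L), oracle_kmers(g[[2L]], 20L))
  expect_lte(length(shared), 1L)
})

test_that("read counts follow cell abundance times genome length", {
  taxa <- data.frame(
    superkingdom = "B", phylum = c("P1", "P2"), class = c("C1", "C2"),
    order = c("O1", "O2"), family = c("F1", "F2"), genus = c("G1", "G2"),
    species = c("S1", "S2"), strain = c("T1", "T2"),
    genome_length = c(10000L, 40000L), cell_fraction = 0.5)
  spec <- community_spec(taxa, n_reads = 20000L, seed = 4L)
  rs <- simulate_reference_set(spec)
  reads <- simulate_reads(rs$genomes, spec)
  n2 <- sum(reads$source == "T2")
  n1 <- sum(reads$source == "T1")
  # p = 4/5 for the long genome; 5 sigma binomial band around 1:4
  expect_gt(n2 / n1, 3.5)
  expect_lt(n2 / n1, 4.6)
})

test_that("the substitution error model has the right rate and support", {
  spec <- small_community(n_species = 2L, genome_length = 5000L,
                          n_reads = 400L, error_rate = 0, seed = 6L,
                          read_length = 80L)
  rs <- simulate_reference_set(spec)
  reads <- simulate_reads(rs$genomes, spec)
  for (i in sample(length(reads$sequences), 50L)) {
    src <- rs$genomes[[reads$source[i]]]
    frag <- substr(src, reads$start[i], reads$start[i] + 79L)
    if (reads$strand[i] == "-") frag <- oracle_rc(frag)
    expect_identical(reads$sequences[i], frag)
  }
  # with errors: mean mismatches per 80 bp read ~= 80 * rate
  spec2 <- small_community(n_species = 2L, genome_length = 5000L,
                           n_reads = 4000L, error_rate = 0.02, seed = 6L,
                           read_length = 80L)
  reads2 <- simulate_reads(rs$genomes, spec2)
  mm <- vapply(seq_along(reads2$sequences), function(i) {
    src <- rs$genomes[[reads2$source[i]]]
    frag <- substr(src, reads2$start[i], reads2$start[i] + 79L)
    if (reads2$strand[i] == "-") frag <- oracle_rc(frag)
    sum(strsplit(reads2$sequences[i], "")[[1L]] != strsplit(frag, "")[[1L]])
  }, numeric(1L))
  expect_gt(mean(mm), 1.45)
  expect_lt(mean(mm), 1.75)
})

test_that("true profiles aggregate cell fractions on the percent scale", {
  spec <- even_community(15L, n_reads = 100L)
  tp <- true_profile(spec, "species")
  expect_equal(nrow(tp), 15L)
  expect_equal(tp$fraction, rep(100 / 15, 15L))
  expect_equal(sum(tp$fraction), 100)
  # two species of one genus at 10% each -> genus at 20%
  taxa <- data.frame(
    superkingdom = "B", phylum = "P", class = "C", order = "O", family = "F",
    genus = c("G1", "G1", "G2"), species = c("S1", "S2", "S3"),
    strain = c("T1", "T2", "T3"),
    genome_length = 10000L, cell_fraction = c(0.1, 0.1, 0.8))
  gp <- true_profile(community_spec(taxa), "genus")
  expect_equal(unname(gp$fraction[gp$taxon == "G1"]), 20)
})

test_that("species masking removes exactly the masked genomes", {
  taxa <- data.frame(
    superkingdom = "B", phylum = "P", class = "C", order = "O", family = "F",
    genus = c("G1", "G1", "G2"), species = c("S1", "S2", "S3"),
    strain = c("T1", "T2", "T3"),
    genome_length = 3000L, cell_fraction = c(0.4, 0.3, 0.3))
  spec <- community_spec(taxa, n_reads = 300L, read_length = 60L, seed = 11L)
  rs <- simulate_reference_set(spec)
  masked <- mask_species(rs$genomes, rs$taxonomy, "S1")
  expect_identical(names(masked$genomes), c("T2", "T3"))
  expect_false("S1" %in% masked$taxonomy$names)
  expect_error(mask_species(rs$genomes, rs$taxonomy, "nope"),
               "unknown species")
  expect_error(mask_species(rs$genomes, rs$taxonomy, c("S1", "S2", "S3")),
               "every reference genome")
  # reads from the masked species can never be assigned to it
  reads <- simulate_reads(rs$genomes, spec)
  ref <- build_reference_index(masked$genomes, masked$taxonomy)
  cls <- classify_dataset(ref, build_read_index(reads), 25L)
  expect_false("S1" %in% cls$taxon_name)
})

test_that("clean full-length k-mers classify to ancestors of their source", {
  spec <- small_community(n_species = 3L, genome_length = 1000L,
                          n_reads = 60L, error_rate = 0, seed = 14L,
                          read_length = 50L)
  rs <- simulate_reference_set(spec)
  reads <- simulate_reads(rs$genomes, spec)
  ref <- build_reference_index(rs$genomes, rs$taxonomy)
  cls <- classify_dataset(ref, build_read_index(reads),
                          k = spec$read_length)
  expect_gt(nrow(cls), 0L)
  lin <- ref$taxonomy$lineages
  # with k = read length, each k-mer IS a read; find its source(s)
  for (r in seq_len(nrow(cls))) {
    srcs <- unique(c(reads$source[reads$sequences == cls$kmer[r]],
                     reads$source[oracle_rc(reads$sequences) == cls$kmer[r]]))
    on_lineage <- vapply(srcs, function(s) cls$taxon_id[r] %in% lin[s, ],
                         logical(1L))
    expect_true(any(on_lineage))
  }
})

test_that("invalid community specifications are rejected", {
  taxa <- even_community(3L, n_reads = 10L)$taxa
  taxa$cell_fraction <- c(0.5, 0.4, 0.2)
  expect_error(community_spec(taxa), "sum to 1")
  taxa <- even_community(3L)$taxa
  taxa$genome_length <- c(50L, 30000L, 30000L)
  expect_error(community_spec(taxa), "at least one read")
  expect_error(even_community(3L, divergence = c(phylum = 0.1)), "named")
})
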