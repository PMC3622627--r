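Package: kmertax
Title: Taxonomic Classification of Shotgun Metagenomic Reads by
    Synchronized BWT Traversal
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A k-mer based taxonomic classifier for environmental shotgun
    sequencing data. Builds a generalized Burrows-Wheeler transform (BWT)
    and generalized suffix array over a collection of reference genomes
    (and their reverse complements) annotated with an eight-level taxonomy,
    indexes the sequencing reads the same way, and enumerates all k-mers
    shared between the two indexes by a synchronized lexicographic interval
    traversal. Each shared k-mer is classified at the deepest taxonomic
    rank on which all of its reference occurrences agree; k-mers occurring
    more than once in any single genome are discarded, and the aggregated
    read counts are normalized by mean genome length to turn sequence
    abundance into cell abundance. Includes a metagenome read simulator
    for phylogenetically structured synthetic communities, taxonomic
    profile construction and comparison by Euclidean distance, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    Biostrings,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
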