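---
title: "Methods: k-mer taxonomic classification with generalized BWT indexes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: k-mer taxonomic classification with generalized BWT indexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its model, its tunable
parameters, the numerical conventions it commits to, and what its tests do
and do not demonstrate.

## The model

The classifier treats taxonomic assignment as an exact-matching problem
between two text indexes.

A **generalized BWT** over a collection of sequences conceptually appends a
distinct terminator $_j$ to member $j$, with
$\$_1 < \dots < \$_m < A < C < G < N < T$, sorts all suffixes, and records
for each rank $i$ the preceding symbol (`bwt[i]`), the suffix offset
(`A[i]`) and the member (`C[i]`). The positions whose suffixes begin with a
query $Q$ form the contiguous *Q-interval* $[b_Q, e_Q]$; its size is the
occurrence count of $Q$, and backward search extends $Q$ on the left one
symbol at a time.

The **reference index** holds every genome *and its reverse complement*
(members $2j$ and $2j+1$ map to genome $j$), plus an 8-vector of integer
taxon ids per genome. The **read index** holds the reads exactly as given —
no reverse complementing or canonicalization — because the reference side
already covers both orientations; reverse-complementing all reads provably
leaves aggregate per-taxon counts unchanged, and the test suite checks this.

The **synchronized traversal** advances both indexes through all k-mers in
lexicographic order. Stage $d$ makes one sequential pass over each BWT
string with running symbol counters; each surviving interval pair is
extended by A, C, G, N, T, and the per-symbol child lists are concatenated
in symbol order, which keeps the frontier sorted. Terminators are never
extension symbols, so k-mers cannot span sequence boundaries. After $k$
stages — at most read-length passes in total — every k-mer present in both
indexes has been visited exactly once.

One deliberate refinement: intervals are propagated only while non-empty in
*both* indexes. Since every suffix of a k-mer shared by reads and reference
is itself shared, this prunes nothing that could reach depth $k$; the
output is provably identical to propagating intervals alive in either
index, at a fraction of the frontier size.

Each shared k-mer is then

1. **counted** per genome from `C[b_Q..e_Q]`, pooling a genome's two strand
   members;
2. **filtered** if any single genome contains it more than once
   (copy-number filter);
3. **classified** at the deepest rank on which all occurring genomes'
   lineages agree, or discarded as unclassified if they disagree at
   superkingdom;
4. **weighted** by its occurrence count in the reads (the size of its
   read-index interval).

Aggregating read counts per taxon at a rank, dividing by the mean length of
the reference genomes under that taxon, and rescaling to percent yields the
profile. The genome-length division is what converts sequence abundance to
cell abundance: at equal cell fractions a 10× longer genome receives 10×
the reads, and exactly that factor is divided out.

## Parameters that matter

* **k (k-mer length)** — unitless, default 50 for 80 bp reads. Longer
  k-mers are more rank-specific but more fragile: a single substitution
  error destroys all $k$ overlapping k-mers, and a read of length $n$
  yields only $n-k+1$ of them. At 1% error, an 80 bp read keeps
  $0.99^{50} \approx 60\%$ of its 50-mers error-free. The choice is
  empirical per data set; the package exposes it everywhere.
* **error_rate** — per-base substitution probability of the simulator,
  default 0.01, matching a conservative short-read error profile.
  Substitution-only: indels would break the exact-match semantics the
  method relies on and are not part of the error model.
* **divergence** — per-rank substitution rates used when deriving a child
  taxon's sequence from its parent's during simulation; defaults decrease
  from 0.25 (phylum) to 0.005 (strain). Two sibling species at the default
  0.02 differ at ≈4% of sites, so they share ≈13% of their 50-mers — enough
  for genus-level signal, little enough for species resolution.
* **genome lengths and cell fractions** — the benchmark community is 15
  organisms at equal cell fractions with lengths 20–200 kb (a 10× spread),
  mirroring a published benchmark design whose genome sizes spanned
  0.2–11 Mb; read counts are drawn proportional to
  `cell_fraction × genome_length`, which is what "equal proportions of
  cells" implies for shotgun sequencing.

## Numerical and representational conventions

* Symbol order is fixed as terminators < A < C < G < N < T. The regular
  alphabet's order is alphabetical (N between G and T); N is a literal
  symbol with no wildcard semantics, so an N in a query matches only an N
  in the text.
* Internally a single sentinel code is stored, with suffix-sort ties broken
  by member index; this reproduces the distinct-terminator ordering
  exactly, and the terminator at BWT position `i` belongs to member `C[i]`.
  Forward members precede their reverse complements in member order, which
  fixes the (otherwise arbitrary) tie order among terminators.
* Q-intervals are 0-based, closed $[b, e]$; the empty interval is
  canonically $e = b - 1$.
* Suffix arrays are built in memory by prefix doubling with counting-sort
  passes ($O(n \log n)$); desk-scale inputs (tens of Mbp) build in seconds
  to minutes. External-memory construction is explicitly out of scope.
* The copy-number filter pools strands, so a reverse-complement-palindromic
  k-mer (even $k$) occurring at a single site is seen once per strand
  member, counted twice, and filtered. This is documented behaviour: such
  k-mers are a vanishing fraction at $k = 50$ and are ambiguous evidence in
  any case.
* The Euclidean distance between profiles is the square root of the sum of
  squared differences of *percent* fractions over the union of taxa. An
  explicit `unclassified` bucket can be carried into the fractions
  (`include_unclassified = TRUE`, or the CLI switch); whether to include it
  is a convention, so both are computable. The bucket is normalized by the
  mean length of all reference genomes, the only sample-independent divisor
  available for mass with no taxon.
* The mean genome length of a taxon averages over **all** database genomes
  under it, not only detected ones: a deterministic, sample-independent
  divisor.
* Per-read assignment (`classify_reads()`) — a read gets the LCA of its
  classified k-mers' taxa — is a secondary convenience; the method's native
  unit is the k-mer, and no property of the per-read rule beyond lineage
  consistency is claimed.

## What the simulator emulates, and what it does not

The generator produces a tree of ancestor sequences (one per distinct taxon
per rank, independent per superkingdom) with point substitutions at each
split, then samples reads with uniform starts, uniform strand, and i.i.d.
substitution errors. It emulates the features the classifier actually
exploits: shared ancestry that decays with taxonomic distance, cell-vs-
sequence abundance, length spread, and error-induced k-mer loss.

It does **not** emulate: indels or structural variation, position- or
motif-dependent error profiles, GC or coverage bias, real gene content
(horizontally transferred segments, conserved operons shared across distant
taxa), plasmids, or chimeric reads. Passing tests therefore demonstrate the
correctness of the index/traversal/normalization machinery under the stated
model, not classifier accuracy on real communities — where shared mobile
elements and database incompleteness dominate the error budget.

## Problem sizes used by the test suite

The suite verifies exact agreement with independent brute-force oracles
(suffix enumeration, substring scans, hash-table k-mer tables with explicit
lineage LCA) on hundreds of randomized small instances, and runs the full
pipeline at its study conditions: 15 organisms, 100,000 reads of 80 bp,
$k = 50$, recovering every species fraction within 1.5 points of 6.67%.
The tandem-duplication experiment uses 100,000 reads so that binomial
read-sampling noise (≈0.2 points per species at that depth) is well below
the 0.5-point effect bound it demonstrates. The masking experiment keeps
one sibling species per masked species in the database and checks that
genus-level concordance exceeds species-level concordance and improves with
read depth.

## Known limitations

* Exact matching only: no mismatch-tolerant search, and no aggregation
  across multiple values of $k$.
* All reads must share one length (N-padding is provided for trimmed
  input); pairing information is ignored.
* The taxonomy is a fixed eight-rank lineage per genome; intermediate or
  missing ranks must be filled by the user (e.g. repeating the parent
  name).
* Indexes are held in memory; the on-disk layout is plain text chosen for
  transparency and byte-identical reproducibility, not compactness.
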