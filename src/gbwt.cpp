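// Core index machinery: generalized suffix array / BWT over a sequence
// collection with distinct per-member terminators, FM-style rank queries,
// BWT inversion, and the synchronized two-index k-mer interval traversal.
//
// Symbol codes throughout: 0 = terminator, 1 = A, 2 = C, 3 = G, 4 = N, 5 = T
// (terminators sort below the regular alphabet; ties between terminators are
// broken by member index, so a single stored sentinel symbol reproduces the
// distinct-terminator suffix order exactly).

#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
#include <cstring>
using namespace Rcpp;

static const char DECODE[6] = {'$', 'A', 'C', 'G', 'N', 'T'};

// Prefix-doubling suffix array with radix (counting) sorts, O(n log n).
// t holds non-negative integer symbols; all suffixes are distinct because
// every member ends in a terminator with a unique initial rank.
static std::vector<int> suffix_array_int(const std::vector<int>& t, int K0) {
  const int n = (int)t.size();
  std::vector<int> sa(n), rk(n), tmp(n), rk2(n);
  int K = std::max(K0, n) + 1;
  std::vector<int> cnt;
  for (int i = 0; i < n; ++i) rk[i] = t[i];
  cnt.assign(K, 0);
  for (int i = 0; i < n; ++i) cnt[rk[i]]++;
  for (int i = 1; i < K; ++i) cnt[i] += cnt[i - 1];
  for (int i = n - 1; i >= 0; --i) sa[--cnt[rk[i]]] = i;
  for (int w = 1;; w <<= 1) {
    // order by second key (rank of suffix i+w; absent = smallest)
    int p = 0;
    for (int i = n - w; i < n; ++i) if (i >= 0) tmp[p++] = i;
    for (int i = 0; i < n; ++i) if (sa[i] >= w) tmp[p++] = sa[i] - w;
    // stable counting sort by first key
    cnt.assign(K, 0);
    for (int i = 0; i < n; ++i) cnt[rk[i]]++;
    for (int i = 1; i < K; ++i) cnt[i] += cnt[i - 1];
    for (int i = n - 1; i >= 0; --i) sa[--cnt[rk[tmp[i]]]] = tmp[i];
    // recompute ranks
    rk2[sa[0]] = 0;
    for (int i = 1; i < n; ++i) {
      int a = sa[i], b = sa[i - 1];
      int a2 = (a + w < n) ? rk[a + w] : -1;
      int b2 = (b + w < n) ? rk[b + w] : -1;
      rk2[a] = rk2[b] + ((rk[a] == rk[b] && a2 == b2) ? 0 : 1);
    }
    rk.swap(rk2);
    if (rk[sa[n - 1]] == n - 1) break;
  }
  return sa;
}

static const int OCC_BLOCK = 64;

static IntegerMatrix occ_checkpoints(const IntegerVector& bwt) {
  const int n = bwt.size();
  const int nb = n / OCC_BLOCK;
  IntegerMatrix occ(6, nb + 1);
  int run[6] = {0, 0, 0, 0, 0, 0};
  for (int t = 0; t <= nb; ++t) {
    for (int c = 0; c < 6; ++c) occ(c, t) = run[c];
    if (t == nb) break;
    const int lo = t * OCC_BLOCK, hi = lo + OCC_BLOCK;
    for (int i = lo; i < hi; ++i) run[bwt[i]]++;
  }
  return occ;
}

// Auxiliary structures (occurrence checkpoints + cumulative symbol counts)
// recomputed from a BWT symbol vector; used at build time and after
// deserialization.
// [[Rcpp::export]]
List cpp_index_aux(IntegerVector bwt) {
  const int n = bwt.size();
  IntegerMatrix occ = occ_checkpoints(bwt);
  int tot[6] = {0, 0, 0, 0, 0, 0};
  for (int i = 0; i < n; ++i) tot[bwt[i]]++;
  IntegerVector cumF(7);
  cumF[0] = 0;
  for (int c = 0; c < 6; ++c) cumF[c + 1] = cumF[c] + tot[c];
  return List::create(_["occ"] = occ, _["cumF"] = cumF);
}

// Build the generalized suffix array and BWT of a collection.
// codes: concatenated base codes (1..5) of all members, no terminators;
// lengths: per-member lengths. Member j's conceptual terminator $_{j+1}
// receives initial rank j so terminators sort by member index.
// [[Rcpp::export]]
List cpp_build_gsa(IntegerVector codes, IntegerVector lengths) {
  const int m = lengths.size();
  long total = 0;
  for (int j = 0; j < m; ++j) total += lengths[j];
  const int L = (int)(total + m);
  std::vector<int> text(L);
  std::vector<int> member_of(L), member_start(m);
  int p = 0, q = 0;
  for (int j = 0; j < m; ++j) {
    member_start[j] = p;
    for (int i = 0; i < lengths[j]; ++i) {
      text[p] = m + (codes[q++] - 1);
      member_of[p++] = j;
    }
    text[p] = j;  // terminator of member j
    member_of[p++] = j;
  }
  std::vector<int> sa = suffix_array_int(text, m + 5);
  IntegerVector bwt(L), A(L), C(L);
  for (int i = 0; i < L; ++i) {
    const int pos = sa[i];
    const int j = member_of[pos];
    C[i] = j;
    A[i] = pos - member_start[j];
    if (pos == member_start[j]) {
      bwt[i] = 0;  // terminator of member j precedes its full suffix
    } else {
      const int v = text[pos - 1];
      bwt[i] = v - m + 1;  // regular symbol (pos-1 is never a terminator here)
    }
  }
  List aux = cpp_index_aux(bwt);
  return List::create(_["bwt"] = bwt, _["A"] = A, _["C"] = C,
                      _["occ"] = aux["occ"], _["cumF"] = aux["cumF"]);
}

static inline int rank_at(const IntegerVector& bwt, const IntegerMatrix& occ,
                          int pos, int c) {
  const int t = pos / OCC_BLOCK;
  int r = occ(c, t);
  for (int i = t * OCC_BLOCK; i < pos; ++i) r += (bwt[i] == c);
  return r;
}

// Number of occurrences of symbol code c in bwt[0..pos-1].
// [[Rcpp::export]]
int cpp_rank(IntegerVector bwt, IntegerMatrix occ, int pos, int c) {
  return rank_at(bwt, occ, pos, c);
}

// Backward-extension of a Q-interval [b,e] by symbol c -> interval of cQ.
// Returns c(b', e'); empty intervals come back as c(0, -1).
// [[Rcpp::export]]
IntegerVector cpp_extend(IntegerVector bwt, IntegerMatrix occ,
                         IntegerVector cumF, int b, int e, int c) {
  if (e < b) return IntegerVector::create(0, -1);
  const int nb = cumF[c] + rank_at(bwt, occ, b, c);
  const int ne = cumF[c] + rank_at(bwt, occ, e + 1, c) - 1;
  if (ne < nb) return IntegerVector::create(0, -1);
  return IntegerVector::create(nb, ne);
}

// Invert a generalized BWT back to its member sequences.  C supplies the
// member index of each position, which identifies terminators (the LF step
// of member j's terminator is row j).
// [[Rcpp::export]]
CharacterVector cpp_invert(IntegerVector bwt, IntegerVector C, int m) {
  const int L = bwt.size();
  // LF mapping in one pass
  int tot[6] = {0, 0, 0, 0, 0, 0};
  for (int i = 0; i < L; ++i) tot[bwt[i]]++;
  int cumF[7];
  cumF[0] = 0;
  for (int c = 0; c < 6; ++c) cumF[c + 1] = cumF[c] + tot[c];
  std::vector<int> LF(L);
  int seen[6] = {0, 0, 0, 0, 0, 0};
  for (int i = 0; i < L; ++i) {
    const int c = bwt[i];
    LF[i] = (c == 0) ? C[i] : cumF[c] + seen[c];
    seen[c]++;
  }
  CharacterVector out(m);
  std::string buf;
  for (int j = 0; j < m; ++j) {
    buf.clear();
    int i = j;  // row of suffix "$_{j+1}"; bwt[i] is the member's last symbol
    int steps = 0;
    while (bwt[i] != 0) {
      buf.push_back(DECODE[bwt[i]]);
      i = LF[i];
      if (++steps > L) stop("malformed BWT: cycle while inverting member %d", j + 1);
    }
    if (C[i] != j) stop("malformed BWT: terminator of member %d not found", j + 1);
    std::reverse(buf.begin(), buf.end());
    out[j] = buf;
  }
  return out;
}

struct Frontier {
  std::vector<int> rb, re, qb, qe;
  size_t size() const { return rb.size(); }
  void clear() { rb.clear(); re.clear(); qb.clear(); qe.clear(); }
  void push(int a, int b, int c, int d) {
    rb.push_back(a); re.push_back(b); qb.push_back(c); qe.push_back(d);
  }
};

// Synchronized staged traversal of the reference and read BWTs.
//
// Starting from the five single-symbol intervals, each stage makes one
// sequential pass over both BWT strings with running symbol counters and
// extends every surviving interval pair on the left by A, C, G, N, T.
// Interval pairs are kept only while non-empty in BOTH indexes (a k-mer
// shared by reads and reference has every suffix shared too, so this prunes
// nothing that could reach depth k).  Frontiers stay sorted in lexicographic
// k-mer order by construction.  Terminators are never extension symbols, so
// k-mers cannot span member boundaries.
//
// If do_classify is false: returns every shared k-mer with both intervals.
// If true: additionally resolves per-genome occurrence counts (forward and
// reverse-complement members pooled), applies the once-per-genome copy
// filter, classifies by deepest agreeing taxonomic rank, and returns only
// surviving k-mers plus a traversal summary.
// [[Rcpp::export]]
List cpp_traverse(IntegerVector ref_bwt, IntegerVector ref_cumF,
                  IntegerVector read_bwt, IntegerVector read_cumF,
                  int k,
                  IntegerVector ref_gpos, IntegerVector ref_text,
                  bool do_classify,
                  IntegerVector member_at, IntegerVector genome_of_member,
                  IntegerMatrix lineages) {
  const int Lr = ref_bwt.size(), Lq = read_bwt.size();
  Frontier cur;
  for (int c = 1; c <= 5; ++c) {
    const int rb = ref_cumF[c], re = ref_cumF[c + 1] - 1;
    const int qb = read_cumF[c], qe = read_cumF[c + 1] - 1;
    if (rb <= re && qb <= qe) cur.push(rb, re, qb, qe);
  }
  const int* rB = INTEGER(ref_bwt);
  const int* qB = INTEGER(read_bwt);
  for (int depth = 1; depth < k && cur.size() > 0; ++depth) {
    Frontier nxt[6];
    long pr = 0, pq = 0;
    int occ_r[6] = {0, 0, 0, 0, 0, 0};
    int occ_q[6] = {0, 0, 0, 0, 0, 0};
    int o1[6], o2[6], p1[6], p2[6];
    for (size_t i = 0; i < cur.size(); ++i) {
      while (pr < cur.rb[i]) occ_r[rB[pr++]]++;
      std::memcpy(o1, occ_r, sizeof o1);
      while (pr <= cur.re[i]) occ_r[rB[pr++]]++;
      std::memcpy(o2, occ_r, sizeof o2);
      while (pq < cur.qb[i]) occ_q[qB[pq++]]++;
      std::memcpy(p1, occ_q, sizeof p1);
      while (pq <= cur.qe[i]) occ_q[qB[pq++]]++;
      std::memcpy(p2, occ_q, sizeof p2);
      for (int c = 1; c <= 5; ++c) {
        if (o2[c] == o1[c] || p2[c] == p1[c]) continue;
        nxt[c].push(ref_cumF[c] + o1[c], ref_cumF[c] + o2[c] - 1,
                    read_cumF[c] + p1[c], read_cumF[c] + p2[c] - 1);
      }
    }
    cur.clear();
    for (int c = 1; c <= 5; ++c) {
      cur.rb.insert(cur.rb.end(), nxt[c].rb.begin(), nxt[c].rb.end());
      cur.re.insert(cur.re.end(), nxt[c].re.begin(), nxt[c].re.end());
      cur.qb.insert(cur.qb.end(), nxt[c].qb.begin(), nxt[c].qb.end());
      cur.qe.insert(cur.qe.end(), nxt[c].qe.begin(), nxt[c].qe.end());
    }
    (void)Lr; (void)Lq;
  }

  const size_t n_shared = cur.size();
  // extract k-mer strings from the reference text via the suffix array
  std::vector<std::string> kmers;
  kmers.reserve(n_shared);
  std::string buf(k, 'x');
  std::vector<int> keep_taxon, keep_level, keep_rc, keep_cc;
  std::vector<std::string> keep_kmer;
  long n_filtered = 0, n_unclassified = 0;
  long total_read_occ = 0;
  std::vector<int> gs;
  for (size_t i = 0; i < n_shared; ++i) {
    const int b = cur.rb[i];
    const int pos = ref_gpos[b];
    for (int t = 0; t < k; ++t) buf[t] = DECODE[ref_text[pos + t]];
    if (!do_classify) {
      kmers.push_back(buf);
      continue;
    }
    const int read_count = cur.qe[i] - cur.qb[i] + 1;
    total_read_occ += read_count;
    // per-genome occurrence counts, strands pooled
    gs.clear();
    for (int r = b; r <= cur.re[i]; ++r)
      gs.push_back(genome_of_member[member_at[r]]);
    std::sort(gs.begin(), gs.end());
    bool multi = false;
    for (size_t r = 1; r < gs.size(); ++r)
      if (gs[r] == gs[r - 1]) { multi = true; break; }
    if (multi) { n_filtered++; continue; }
    // deepest rank on which all occurring genomes agree
    int lvl = 7;
    const int g0 = gs[0];
    for (size_t r = 1; r < gs.size() && lvl >= 0; ++r) {
      int agree = -1;
      for (int l = 0; l <= lvl; ++l) {
        if (lineages(gs[r], l) == lineages(g0, l)) agree = l; else break;
      }
      lvl = std::min(lvl, agree);
    }
    if (lvl < 0) { n_unclassified++; continue; }
    keep_kmer.push_back(buf);
    keep_taxon.push_back(lineages(g0, lvl));
    keep_level.push_back(lvl);
    keep_rc.push_back(read_count);
    keep_cc.push_back(cur.re[i] - b + 1);
  }

  if (!do_classify) {
    return List::create(
      _["kmer"] = wrap(kmers),
      _["ref_b"] = wrap(cur.rb), _["ref_e"] = wrap(cur.re),
      _["read_b"] = wrap(cur.qb), _["read_e"] = wrap(cur.qe));
  }
  return List::create(
    _["kmer"] = wrap(keep_kmer),
    _["taxon"] = wrap(keep_taxon),
    _["level"] = wrap(keep_level),
    _["read_count"] = wrap(keep_rc),
    _["ref_count"] = wrap(keep_cc),
    _["n_shared"] = (double)n_shared,
    _["n_copy_filtered"] = (double)n_filtered,
    _["n_unclassified"] = (double)n_unclassified,
    _["total_read_occurrences"] = (double)total_read_occ);
}
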