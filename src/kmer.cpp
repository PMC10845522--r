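#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <unordered_set>
#include <unordered_map>
#include <cstdint>
using namespace Rcpp;

// 2-bit base codes; 4 marks anything that is not A/C/G/T
static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return 4;
  }
}

// sorted unique canonical k-mers of one sequence
static std::vector<uint64_t> canonical_kmers(const char* s, int len, int k) {
  std::vector<uint64_t> out;
  if (len < k) return out;
  const uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  uint64_t fwd = 0, rev = 0;
  int valid = 0;
  for (int i = 0; i < len; i++) {
    int c = base_code(s[i]);
    if (c == 4) { valid = 0; fwd = 0; rev = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)c) & mask;
    rev = (rev >> 2) | ((uint64_t)(3 - c) << (2 * (k - 1)));
    valid++;
    if (valid >= k) out.push_back(fwd < rev ? fwd : rev);
  }
  std::sort(out.begin(), out.end());
  out.erase(std::unique(out.begin(), out.end()), out.end());
  return out;
}

struct UnionFind {
  std::vector<int> parent, rank_;
  UnionFind(int n) : parent(n), rank_(n, 0) {
    for (int i = 0; i < n; i++) parent[i] = i;
  }
  int find(int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  }
  bool unite(int a, int b) {
    a = find(a); b = find(b);
    if (a == b) return false;
    if (rank_[a] < rank_[b]) std::swap(a, b);
    parent[b] = a;
    if (rank_[a] == rank_[b]) rank_[a]++;
    return true;
  }
};

static int shared_count(const std::vector<uint64_t>& a,
                        const std::vector<uint64_t>& b, int stop_at) {
  int n = 0;
  size_t i = 0, j = 0;
  while (i < a.size() && j < b.size()) {
    if (a[i] < b[j]) i++;
    else if (a[i] > b[j]) j++;
    else { n++; if (n >= stop_at) return n; i++; j++; }
  }
  return n;
}

// Connected components of the shared-k-mer read graph.
//
// An edge joins two reads sharing >= min_shared canonical k-mers. Candidate
// pairs are generated from k-mer occurrence buckets (all pairs for buckets of
// <= small_bucket reads; a chain over consecutive reads plus a star to the
// first read for larger buckets) and every candidate is verified exactly by
// intersecting the two reads' sorted k-mer sets. Exhaustive pair enumeration
// inside large buckets is quadratic and unnecessary: reads of an abundant
// repeat are densely interlinked, so chain+star candidates connect the same
// components.
// [[Rcpp::export(name = ".kmer_components")]]
IntegerVector kmer_components(CharacterVector reads, int k, int min_shared,
                              int small_bucket = 12) {
  int n = reads.size();
  std::vector<std::vector<uint64_t> > sets(n);
  std::vector<std::pair<uint64_t, int> > occ;
  for (int i = 0; i < n; i++) {
    const char* s = CHAR(STRING_ELT(reads, i));
    int len = LENGTH(STRING_ELT(reads, i));
    if (len < k) stop("k exceeds read length");
    sets[i] = canonical_kmers(s, len, k);
    for (uint64_t km : sets[i]) occ.push_back(std::make_pair(km, i));
  }
  std::sort(occ.begin(), occ.end());

  UnionFind uf(n);
  std::vector<std::pair<int, int> > cand;

  size_t b = 0;
  while (b < occ.size()) {
    size_t e = b;
    while (e < occ.size() && occ[e].first == occ[b].first) e++;
    size_t m = e - b;
    if (m > 1) {
      if ((int)m <= small_bucket) {
        for (size_t i = b; i < e; i++)
          for (size_t j = i + 1; j < e; j++)
            cand.push_back(std::make_pair(occ[i].second, occ[j].second));
      } else {
        for (size_t i = b + 1; i < e; i++) {
          cand.push_back(std::make_pair(occ[i - 1].second, occ[i].second));
          cand.push_back(std::make_pair(occ[b].second, occ[i].second));
        }
      }
    }
    // verify this bucket's candidates now so union-find can prune later ones
    for (size_t ci = 0; ci < cand.size(); ci++) {
      int a = cand[ci].first, c = cand[ci].second;
      if (a == c) continue;
      int lo = a < c ? a : c, hi = a < c ? c : a;
      if (uf.find(lo) == uf.find(hi)) continue;
      if (shared_count(sets[lo], sets[hi], min_shared) >= min_shared)
        uf.unite(lo, hi);
    }
    cand.clear();
    b = e;
  }

  IntegerVector comp(n);
  for (int i = 0; i < n; i++) comp[i] = uf.find(i) + 1;
  return comp;
}

// Shared-k-mer counts between each read and each reference sequence, plus the
// number of distinct canonical k-mers per read (the containment denominator).
// [[Rcpp::export(name = ".kmer_ref_counts")]]
List kmer_ref_counts(CharacterVector reads, CharacterVector refs, int k) {
  int n = reads.size(), r = refs.size();
  std::unordered_map<uint64_t, std::vector<int> > index;
  for (int j = 0; j < r; j++) {
    std::vector<uint64_t> ks = canonical_kmers(CHAR(STRING_ELT(refs, j)),
                                               LENGTH(STRING_ELT(refs, j)), k);
    for (uint64_t km : ks) index[km].push_back(j);
  }
  IntegerMatrix counts(n, r);
  IntegerVector nk(n);
  for (int i = 0; i < n; i++) {
    std::vector<uint64_t> ks = canonical_kmers(CHAR(STRING_ELT(reads, i)),
                                               LENGTH(STRING_ELT(reads, i)), k);
    nk[i] = ks.size();
    for (uint64_t km : ks) {
      std::unordered_map<uint64_t, std::vector<int> >::iterator it = index.find(km);
      if (it != index.end())
        for (int j : it->second) counts(i, j)++;
    }
  }
  return List::create(_["counts"] = counts, _["n_kmers"] = nk);
}

// Ungapped scan of a monomer along one strand of one chromosome: every offset
// whose identity reaches min_identity is reported. The inner loop bails out
// as soon as the mismatch budget is exhausted.
// [[Rcpp::export(name = ".scan_monomer")]]
DataFrame scan_monomer(std::string chrom, std::string monomer, double min_identity) {
  int L = chrom.size(), m = monomer.size();
  std::vector<int> pos;
  std::vector<double> ident;
  if (m > L) return DataFrame::create(_["pos"] = IntegerVector(0),
                                      _["identity"] = NumericVector(0));
  int budget = (int)std::floor((1.0 - min_identity) * m);
  for (int p = 0; p + m <= L; p++) {
    int mm = 0;
    for (int i = 0; i < m; i++) {
      if (chrom[p + i] != monomer[i]) {
        if (++mm > budget) break;
      }
    }
    if (mm <= budget) {
      pos.push_back(p);
      ident.push_back(1.0 - (double)mm / m);
    }
  }
  return DataFrame::create(_["pos"] = wrap(pos), _["identity"] = wrap(ident));
}
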