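// Canonical k-mer LCA index, Kraken-style read-pair classification, and
// seed-and-extend alignment against a strain panel. Hot loops live here;
// all user-facing contracts are defined in the R wrappers.
#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <string>
#include <algorithm>

using namespace Rcpp;

static inline int base2bits(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

// Enumerate valid k-mers of s, calling f(fwd, rc) for each window free of
// ambiguous bases. fwd/rc are 2-bit packed, rc is the reverse complement.
template <typename F>
static void forEachKmer(const std::string& s, int k, F f) {
  const uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  uint64_t fwd = 0, rc = 0;
  int filled = 0;
  const int shift = 2 * (k - 1);
  for (size_t i = 0; i < s.size(); ++i) {
    int b = base2bits(s[i]);
    if (b < 0) { filled = 0; fwd = 0; rc = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)b) & mask;
    rc = (rc >> 2) | ((uint64_t)(3 - b) << shift);
    if (++filled >= k) f(fwd, rc);
  }
}

struct TaxTree {
  std::unordered_map<int, int> parent;
  int root;

  int lca(int a, int b) const {
    if (a == b) return a;
    std::unordered_set<int> anc;
    int x = a;
    while (true) {
      anc.insert(x);
      int p = parent.at(x);
      if (p == x) break;
      x = p;
    }
    x = b;
    while (anc.find(x) == anc.end()) x = parent.at(x);
    return x;
  }
};

struct KIndex {
  int k;
  std::unordered_map<uint64_t, int> map; // canonical k-mer -> LCA taxid
  TaxTree tax;
};

// [[Rcpp::export]]
SEXP cpp_kmer_index_build(CharacterVector seqs, IntegerVector seq_taxids,
                          int k, IntegerVector taxids, IntegerVector parents,
                          int root) {
  KIndex* idx = new KIndex();
  idx->k = k;
  idx->tax.root = root;
  for (int i = 0; i < taxids.size(); ++i)
    idx->tax.parent[taxids[i]] = parents[i];
  for (int s = 0; s < seqs.size(); ++s) {
    std::string seq = as<std::string>(seqs[s]);
    int tid = seq_taxids[s];
    forEachKmer(seq, k, [&](uint64_t fwd, uint64_t rc) {
      uint64_t canon = std::min(fwd, rc);
      auto it = idx->map.find(canon);
      if (it == idx->map.end()) idx->map[canon] = tid;
      else if (it->second != tid) it->second = idx->tax.lca(it->second, tid);
    });
  }
  XPtr<KIndex> ptr(idx, true);
  return ptr;
}

// [[Rcpp::export]]
double cpp_kmer_index_size(SEXP p) {
  XPtr<KIndex> idx(p);
  return (double)idx->map.size();
}

// [[Rcpp::export]]
IntegerVector cpp_kmer_lookup(SEXP p, CharacterVector kmers) {
  XPtr<KIndex> idx(p);
  int k = idx->k;
  IntegerVector out(kmers.size(), NA_INTEGER);
  for (int i = 0; i < kmers.size(); ++i) {
    std::string s = as<std::string>(kmers[i]);
    if ((int)s.size() != k) continue;
    bool got = false;
    forEachKmer(s, k, [&](uint64_t fwd, uint64_t rc) {
      uint64_t canon = std::min(fwd, rc);
      auto it = idx->map.find(canon);
      if (it != idx->map.end()) { out[i] = it->second; }
      got = true;
    });
    (void)got;
  }
  return out;
}

// Classify one pooled hit multiset: root-to-leaf paths are scored by the sum
// of hit counts on their nodes; the result is the LCA of the leaves of all
// max-scoring paths. Equivalent reduced form: among hit nodes having no hit
// node strictly below them, score each by the hit-count sum along its
// root path, and take the LCA of the argmax set.
static int classifyHits(const std::unordered_map<int, int>& hits,
                        const TaxTree& tax) {
  if (hits.empty()) return NA_INTEGER;
  std::unordered_set<int> notDeepest;
  for (auto& h : hits) {
    int x = h.first;
    while (true) {
      int p = tax.parent.at(x);
      if (p == x) break;
      x = p;
      if (hits.find(x) != hits.end()) notDeepest.insert(x);
    }
  }
  int bestScore = -1;
  std::vector<int> bestNodes;
  for (auto& h : hits) {
    if (notDeepest.find(h.first) != notDeepest.end()) continue;
    int score = 0, x = h.first;
    while (true) {
      auto it = hits.find(x);
      if (it != hits.end()) score += it->second;
      int p = tax.parent.at(x);
      if (p == x) break;
      x = p;
    }
    if (score > bestScore) { bestScore = score; bestNodes.assign(1, h.first); }
    else if (score == bestScore) bestNodes.push_back(h.first);
  }
  int res = bestNodes[0];
  for (size_t i = 1; i < bestNodes.size(); ++i) res = tax.lca(res, bestNodes[i]);
  return res;
}

// Hit accumulation for one read pair without per-read allocation: taxa per
// read are few, so a linear-scan vector beats a hash map.
static void accumulateHits(const KIndex& idx, const char* s, int len,
                           std::vector<std::pair<int, int>>& hitv) {
  const int k = idx.k;
  const uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  const int shift = 2 * (k - 1);
  uint64_t fwd = 0, rc = 0;
  int filled = 0;
  for (int i = 0; i < len; ++i) {
    int b = base2bits(s[i]);
    if (b < 0) { filled = 0; fwd = 0; rc = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)b) & mask;
    rc = (rc >> 2) | ((uint64_t)(3 - b) << shift);
    if (++filled < k) continue;
    auto it = idx.map.find(std::min(fwd, rc));
    if (it == idx.map.end()) continue;
    int tid = it->second;
    bool found = false;
    for (auto& h : hitv)
      if (h.first == tid) { h.second++; found = true; break; }
    if (!found) hitv.push_back(std::make_pair(tid, 1));
  }
}

// [[Rcpp::export]]
IntegerVector cpp_classify_pairs(SEXP p, CharacterVector mate1,
                                 CharacterVector mate2) {
  XPtr<KIndex> idx(p);
  int n = mate1.size();
  bool paired = mate2.size() > 0;
  IntegerVector out(n, NA_INTEGER);
  std::vector<std::pair<int, int>> hitv;
  std::unordered_map<int, int> hits;
  for (int i = 0; i < n; ++i) {
    hitv.clear();
    SEXP s1 = STRING_ELT(mate1, i);
    accumulateHits(*idx, CHAR(s1), LENGTH(s1), hitv);
    if (paired) {
      SEXP s2 = STRING_ELT(mate2, i);
      accumulateHits(*idx, CHAR(s2), LENGTH(s2), hitv);
    }
    if (hitv.empty()) continue;
    if (hitv.size() == 1) { out[i] = hitv[0].first; continue; }
    hits.clear();
    for (auto& h : hitv) hits[h.first] = h.second;
    out[i] = classifyHits(hits, idx->tax);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Strain-panel seed index: forward k-mer -> (strain, position) postings.

struct SeedIndex {
  int k;
  std::vector<std::string> genomes;
  std::unordered_map<uint64_t, std::vector<std::pair<int, int>>> pos;
};

// [[Rcpp::export]]
SEXP cpp_seed_index_build(CharacterVector seqs, int k) {
  SeedIndex* idx = new SeedIndex();
  idx->k = k;
  for (int s = 0; s < seqs.size(); ++s) {
    std::string seq = as<std::string>(seqs[s]);
    const uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
    uint64_t fwd = 0;
    int filled = 0;
    for (size_t i = 0; i < seq.size(); ++i) {
      int b = base2bits(seq[i]);
      if (b < 0) { filled = 0; fwd = 0; continue; }
      fwd = ((fwd << 2) | (uint64_t)b) & mask;
      if (++filled >= k)
        idx->pos[fwd].push_back(std::make_pair(s, (int)(i - k + 1)));
    }
    idx->genomes.push_back(seq);
  }
  XPtr<SeedIndex> ptr(idx, true);
  return ptr;
}

static int countMismatches(const std::string& g, int start,
                           const std::string& r, int cap) {
  int m = 0;
  for (size_t i = 0; i < r.size(); ++i) {
    char a = g[start + i], b = r[i];
    if (a >= 'a') a -= 32;
    if (b >= 'a') b -= 32;
    if (a != b && ++m > cap) return m;
  }
  return m;
}

static void alignOne(const SeedIndex& idx, const std::string& read,
                     int max_mm, int step, std::vector<int>& best) {
  int k = idx.k;
  int L = (int)read.size();
  if (L < k) return;
  const uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  std::vector<std::unordered_set<int>> tried(idx.genomes.size());
  for (int off = 0; off + k <= L; off += step) {
    uint64_t fwd = 0;
    bool ok = true;
    for (int j = 0; j < k; ++j) {
      int b = base2bits(read[off + j]);
      if (b < 0) { ok = false; break; }
      fwd = ((fwd << 2) | (uint64_t)b) & mask;
    }
    if (!ok) continue;
    auto it = idx.pos.find(fwd);
    if (it == idx.pos.end()) continue;
    for (auto& sp : it->second) {
      int strain = sp.first;
      int start = sp.second - off;
      if (start < 0 || start + L > (int)idx.genomes[strain].size()) continue;
      if (!tried[strain].insert(start).second) continue;
      int cap = (best[strain] == NA_INTEGER) ? max_mm : std::min(max_mm, best[strain]);
      int m = countMismatches(idx.genomes[strain], start, read, cap);
      if (m <= cap &&
          (best[strain] == NA_INTEGER || m < best[strain]))
        best[strain] = m;
    }
  }
}

static std::string revcompStr(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) {
    switch (c) {
    case 'A': case 'a': c = 'T'; break;
    case 'C': case 'c': c = 'G'; break;
    case 'G': case 'g': c = 'C'; break;
    case 'T': case 't': c = 'A'; break;
    default: c = 'N';
    }
  }
  return r;
}

// Best mismatch count per (read, strain), trying both orientations.
// NA entries mean no candidate placement within max_mm.
// [[Rcpp::export]]
IntegerMatrix cpp_align_reads(SEXP p, CharacterVector reads, int max_mm,
                              int step) {
  XPtr<SeedIndex> idx(p);
  int n = reads.size(), ns = (int)idx->genomes.size();
  IntegerMatrix out(n, ns);
  std::fill(out.begin(), out.end(), NA_INTEGER);
  for (int i = 0; i < n; ++i) {
    std::string r = as<std::string>(reads[i]);
    std::vector<int> best(ns, NA_INTEGER);
    alignOne(*idx, r, max_mm, step, best);
    alignOne(*idx, revcompStr(r), max_mm, step, best);
    for (int s = 0; s < ns; ++s) out(i, s) = best[s];
  }
  return out;
}
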