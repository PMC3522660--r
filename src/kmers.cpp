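// 2-bit encoded k-mer utilities shared by the assembler and the demux scorer.
#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <algorithm>
#include <cstdint>
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

static inline uint64_t revcomp_code(uint64_t code, int k) {
  uint64_t rc = 0;
  for (int i = 0; i < k; ++i) {
    rc = (rc << 2) | (3ULL - (code & 3ULL));
    code >>= 2;
  }
  return rc;
}

static std::string decode_kmer(uint64_t code, int k) {
  static const char bases[] = "ACGT";
  std::string s(k, 'A');
  for (int i = k - 1; i >= 0; --i) {
    s[i] = bases[code & 3ULL];
    code >>= 2;
  }
  return s;
}

// Walk a sequence, emitting the canonical code of every k-mer window that is
// free of non-ACGT characters; windows containing N (etc.) yield NA.
// [[Rcpp::export]]
IntegerVector cpp_kmer_codes(std::string seq, int k) {
  if (k < 1 || k > 15) stop("k must be in 1..15 for 32-bit codes");
  int n = (int)seq.size() - k + 1;
  if (n < 1) return IntegerVector(0);
  IntegerVector out(n, NA_INTEGER);
  uint64_t mask = (1ULL << (2 * k)) - 1;
  uint64_t code = 0;
  int valid = 0;
  for (int i = 0; i < (int)seq.size(); ++i) {
    int b = base2bits(seq[i]);
    if (b < 0) { valid = 0; code = 0; continue; }
    code = ((code << 2) | (uint64_t)b) & mask;
    if (++valid >= k) {
      uint64_t rc = revcomp_code(code, k);
      out[i - k + 1] = (int)std::min(code, rc);
    }
  }
  return out;
}

typedef std::unordered_map<uint64_t, uint32_t> KmerMap;

static void count_reads(const std::vector<std::string>& reads, int k, KmerMap& map) {
  uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  for (const std::string& r : reads) {
    uint64_t code = 0;
    int valid = 0;
    for (size_t i = 0; i < r.size(); ++i) {
      int b = base2bits(r[i]);
      if (b < 0) { valid = 0; code = 0; continue; }
      code = ((code << 2) | (uint64_t)b) & mask;
      if (++valid >= k) {
        uint64_t rc = revcomp_code(code, k);
        ++map[std::min(code, rc)];
      }
    }
  }
}

// [[Rcpp::export]]
List cpp_count_kmers(std::vector<std::string> reads, int k) {
  if (k < 1 || k > 31) stop("k must be in 1..31");
  KmerMap map;
  count_reads(reads, k, map);
  std::vector<uint64_t> keys;
  keys.reserve(map.size());
  for (auto& kv : map) keys.push_back(kv.first);
  std::sort(keys.begin(), keys.end());
  CharacterVector kmers(keys.size());
  IntegerVector counts(keys.size());
  for (size_t i = 0; i < keys.size(); ++i) {
    kmers[i] = decode_kmer(keys[i], k);
    counts[i] = (int)map[keys[i]];
  }
  return List::create(_["kmer"] = kmers, _["count"] = counts);
}

// ---- unitig extraction on the canonical (bidirected) de Bruijn graph ----

struct Graph {
  const KmerMap& map;
  int k;
  uint64_t mask;
  Graph(const KmerMap& m, int kk) : map(m), k(kk) {
    mask = (1ULL << (2 * k)) - 1;
  }
  inline uint64_t canon(uint64_t u) const {
    uint64_t rc = revcomp_code(u, k);
    return std::min(u, rc);
  }
  inline bool has(uint64_t u) const { return map.find(canon(u)) != map.end(); }
  // successors of oriented k-mer u; returns count, stores last found in succ
  inline int out_deg(uint64_t u, uint64_t& succ) const {
    int d = 0;
    for (uint64_t c = 0; c < 4; ++c) {
      uint64_t v = ((u << 2) | c) & mask;
      if (has(v)) { ++d; succ = v; }
    }
    return d;
  }
  inline int in_deg(uint64_t u, uint64_t& pred) const {
    uint64_t p_rc;
    int d = out_deg(revcomp_code(u, k), p_rc);
    if (d == 1) pred = revcomp_code(p_rc, k);
    return d;
  }
};

static std::string spell_path(const std::vector<uint64_t>& path, int k) {
  std::string s = decode_kmer(path[0], k);
  for (size_t i = 1; i < path.size(); ++i) {
    static const char bases[] = "ACGT";
    s.push_back(bases[path[i] & 3ULL]);
  }
  return s;
}

static List unitigs_from_map(const KmerMap& map, int k) {
  Graph g(map, k);
  std::vector<uint64_t> keys;
  keys.reserve(map.size());
  for (auto& kv : map) keys.push_back(kv.first);
  std::sort(keys.begin(), keys.end());
  std::unordered_set<uint64_t> visited;
  visited.reserve(map.size() * 2);

  std::vector<std::string> seqs;
  std::vector<double> abund;
  std::vector<bool> circ;

  auto emit = [&](std::string s, const std::vector<uint64_t>& path,
                  bool circular) {
    // canonical representation of the contig itself
    std::string rc(s.rbegin(), s.rend());
    for (char& c : rc)
      c = (c == 'A') ? 'T' : (c == 'C') ? 'G' : (c == 'G') ? 'C' : 'A';
    if (rc < s) s = rc;
    double ab = 0;
    for (uint64_t u : path) ab += map.at(g.canon(u));
    seqs.push_back(s);
    abund.push_back(ab / path.size());
    circ.push_back(circular);
  };

  // pass 1: unitigs with a defined start (branching or dead-end boundary)
  for (uint64_t key : keys) {
    uint64_t orients[2] = { key, revcomp_code(key, k) };
    for (uint64_t u : orients) {
      uint64_t pred = 0, dummy = 0;
      int ind = g.in_deg(u, pred);
      bool is_start = (ind != 1);
      if (!is_start && ind == 1) {
        uint64_t ps;
        if (g.out_deg(pred, ps) != 1) is_start = true;
      }
      if (!is_start) continue;
      if (visited.count(g.canon(u))) continue;
      std::vector<uint64_t> path;
      path.push_back(u);
      visited.insert(g.canon(u));
      uint64_t cur = u;
      for (;;) {
        uint64_t nxt;
        if (g.out_deg(cur, nxt) != 1) break;
        uint64_t p2;
        if (g.in_deg(nxt, p2) != 1) break;
        if (visited.count(g.canon(nxt))) break;
        path.push_back(nxt);
        visited.insert(g.canon(nxt));
        cur = nxt;
      }
      emit(spell_path(path, k), path, false);
    }
  }

  // pass 2: remaining nodes lie on isolated simple cycles
  for (uint64_t key : keys) {
    if (visited.count(key)) continue;
    std::vector<uint64_t> path;
    uint64_t cur = key;
    path.push_back(cur);
    visited.insert(g.canon(cur));
    for (;;) {
      uint64_t nxt;
      if (g.out_deg(cur, nxt) != 1) break;     // cannot happen on a clean cycle
      if (g.canon(nxt) == key && nxt == path[0]) break;  // closed the loop
      if (visited.count(g.canon(nxt))) break;
      path.push_back(nxt);
      visited.insert(g.canon(nxt));
      cur = nxt;
    }
    // the linear spelling of a closed cycle already ends with the
    // (k-1)-mer it starts with (p0 follows p_{m-1} on the cycle)
    emit(spell_path(path, k), path, true);
  }

  // deterministic output order: decreasing length, then lexicographic
  std::vector<size_t> ord(seqs.size());
  for (size_t i = 0; i < ord.size(); ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](size_t a, size_t b) {
    if (seqs[a].size() != seqs[b].size()) return seqs[a].size() > seqs[b].size();
    return seqs[a] < seqs[b];
  });
  CharacterVector oseq(ord.size());
  NumericVector oab(ord.size());
  LogicalVector ocirc(ord.size());
  for (size_t i = 0; i < ord.size(); ++i) {
    oseq[i] = seqs[ord[i]];
    oab[i] = abund[ord[i]];
    ocirc[i] = (bool)circ[ord[i]];
  }
  return List::create(_["seq"] = oseq, _["abundance"] = oab,
                      _["circular"] = ocirc);
}

// [[Rcpp::export]]
List cpp_unitigs(std::vector<std::string> kmers, IntegerVector counts, int k) {
  KmerMap map;
  map.reserve(kmers.size() * 2);
  for (size_t i = 0; i < kmers.size(); ++i) {
    uint64_t code = 0;
    for (char c : kmers[i]) {
      int b = base2bits(c);
      if (b < 0) stop("non-ACGT character in k-mer");
      code = (code << 2) | (uint64_t)b;
    }
    uint64_t rc = revcomp_code(code, k);
    map[std::min(code, rc)] = (uint32_t)counts[i];
  }
  return unitigs_from_map(map, k);
}

// [[Rcpp::export]]
List cpp_assemble(std::vector<std::string> reads, int k, int min_count) {
  if (k < 1 || k > 31) stop("k must be in 1..31");
  KmerMap map;
  count_reads(reads, k, map);
  if (min_count > 1) {
    for (auto it = map.begin(); it != map.end();) {
      if (it->second < (uint32_t)min_count) it = map.erase(it);
      else ++it;
    }
  }
  return unitigs_from_map(map, k);
}
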