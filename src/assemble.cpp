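#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <cstdint>
#include <algorithm>
using namespace Rcpp;

// de Bruijn unitig assembler over canonical k-mers (k odd, <= 31).

static inline int8_t enc_base2(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1; // N and anything else breaks k-mer runs
  }
}

static inline uint64_t rc_kmer(uint64_t x, int k) {
  uint64_t r = 0;
  for (int i = 0; i < k; ++i) { r = (r << 2) | (3 - (x & 3)); x >>= 2; }
  return r;
}

static inline uint64_t canon(uint64_t x, int k) {
  uint64_t r = rc_kmer(x, k);
  return x < r ? x : r;
}

static std::string decode_kmer(uint64_t x, int k) {
  static const char* B = "ACGT";
  std::string s(k, 'A');
  for (int i = k - 1; i >= 0; --i) { s[i] = B[x & 3]; x >>= 2; }
  return s;
}

struct DBG {
  int k;
  uint64_t mask;
  std::unordered_set<uint64_t> S; // canonical k-mers kept

  bool has(uint64_t oriented) const { return S.count(canon(oriented, k)) > 0; }
  // successors of oriented kmer x: ((x<<2)|b) & mask
  int outdeg(uint64_t x, uint64_t* succ = nullptr) const {
    int d = 0; uint64_t last = 0;
    for (uint64_t b = 0; b < 4; ++b) {
      uint64_t y = ((x << 2) | b) & mask;
      if (has(y)) { ++d; last = y; }
    }
    if (succ && d == 1) *succ = last;
    return d;
  }
  int indeg(uint64_t x, uint64_t* pred = nullptr) const {
    int d = 0; uint64_t last = 0;
    for (uint64_t b = 0; b < 4; ++b) {
      uint64_t y = (x >> 2) | (b << (2 * (k - 1)));
      if (has(y)) { ++d; last = y; }
    }
    if (pred && d == 1) *pred = last;
    return d;
  }
};

static void kmers_of(const std::string& s, int k, uint64_t mask,
                     std::vector<uint64_t>& out) {
  out.clear();
  uint64_t kv = 0; int run = 0;
  for (size_t i = 0; i < s.size(); ++i) {
    int8_t b = enc_base2(s[i]);
    if (b < 0) { run = 0; kv = 0; continue; }
    kv = ((kv << 2) | static_cast<uint64_t>(b)) & mask;
    if (++run >= k) out.push_back(kv);
  }
}

// [[Rcpp::export]]
List assemble_unitigs_cpp(CharacterVector reads, int k, int min_count, bool clip_tips) {
  if (k < 1 || k > 31 || k % 2 == 0) stop("k must be odd and between 1 and 31");
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  // count canonical k-mers
  std::unordered_map<uint64_t, int> counts;
  std::vector<uint64_t> buf;
  for (R_xlen_t i = 0; i < reads.size(); ++i) {
    std::string s = as<std::string>(reads[i]);
    kmers_of(s, k, mask, buf);
    for (uint64_t kv : buf) counts[canon(kv, k)]++;
  }
  DBG g; g.k = k; g.mask = mask;
  for (auto& kv : counts) if (kv.second >= min_count) g.S.insert(kv.first);
  // deterministic iteration order
  std::vector<uint64_t> keys(g.S.begin(), g.S.end());
  std::sort(keys.begin(), keys.end());

  std::unordered_set<uint64_t> visited;
  struct Path { std::vector<uint64_t> v; };
  std::vector<Path> paths;

  auto walk = [&](uint64_t start) {
    Path p; p.v.push_back(start);
    visited.insert(canon(start, k));
    uint64_t cur = start;
    while (true) {
      uint64_t nxt;
      if (g.outdeg(cur, &nxt) != 1) break;
      if (g.indeg(nxt) != 1) break;
      if (visited.count(canon(nxt, k))) break; // cycle guard
      p.v.push_back(nxt);
      visited.insert(canon(nxt, k));
      cur = nxt;
    }
    paths.push_back(p);
  };

  for (uint64_t c : keys) {
    if (visited.count(c)) continue;
    uint64_t r = rc_kmer(c, k);
    bool started = false;
    for (int o = 0; o < 2 && !started; ++o) {
      uint64_t x = o == 0 ? c : r;
      uint64_t pred;
      int ind = g.indeg(x, &pred);
      bool is_start = (ind != 1) || (g.outdeg(pred) != 1);
      if (is_start) { walk(x); started = true; }
    }
  }
  // leftover: pure cycles; start from smallest canonical member
  for (uint64_t c : keys) {
    if (!visited.count(c)) walk(c);
  }

  // build sequences, record end degrees for tip clipping
  std::vector<std::string> seqs;
  std::vector<std::vector<uint64_t>> path_canon;
  for (auto& p : paths) {
    std::string s = decode_kmer(p.v.front(), k);
    for (size_t i = 1; i < p.v.size(); ++i) {
      static const char* B = "ACGT";
      s.push_back(B[p.v[i] & 3]);
    }
    bool keep = true;
    if (clip_tips && static_cast<int>(s.size()) < 2 * k) {
      int left = g.indeg(p.v.front());
      int right = g.outdeg(p.v.back());
      // a short dead-end branch hanging off the graph: one free end, one attached
      if ((left == 0) != (right == 0)) keep = false;
    }
    if (!keep) continue;
    seqs.push_back(s);
    std::vector<uint64_t> pc(p.v.size());
    for (size_t i = 0; i < p.v.size(); ++i) pc[i] = canon(p.v[i], k);
    path_canon.push_back(pc);
  }
  // canonical orientation: lexicographic min of sequence and reverse complement
  for (auto& s : seqs) {
    std::string r(s.rbegin(), s.rend());
    for (auto& ch : r) ch = ch == 'A' ? 'T' : ch == 'C' ? 'G' : ch == 'G' ? 'C' : 'A';
    if (r < s) s = r;
  }
  // sort by sequence, keep path membership aligned
  std::vector<size_t> ord(seqs.size());
  for (size_t i = 0; i < ord.size(); ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](size_t a, size_t b) { return seqs[a] < seqs[b]; });

  std::unordered_map<uint64_t, int> kmer2node;
  CharacterVector out_seq(ord.size());
  for (size_t i = 0; i < ord.size(); ++i) {
    out_seq[i] = seqs[ord[i]];
    for (uint64_t c : path_canon[ord[i]]) kmer2node[c] = static_cast<int>(i);
  }
  // support: reads sharing at least one retained k-mer with a node
  std::vector<std::vector<int>> support(ord.size());
  for (R_xlen_t ri = 0; ri < reads.size(); ++ri) {
    std::string s = as<std::string>(reads[ri]);
    kmers_of(s, k, mask, buf);
    std::unordered_set<int> touched;
    for (uint64_t kv : buf) {
      auto it = kmer2node.find(canon(kv, k));
      if (it != kmer2node.end()) touched.insert(it->second);
    }
    for (int ni : touched) support[ni].push_back(static_cast<int>(ri) + 1);
  }
  List out_support(ord.size());
  for (size_t i = 0; i < ord.size(); ++i) {
    std::sort(support[i].begin(), support[i].end());
    out_support[i] = wrap(support[i]);
  }
  return List::create(_["sequence"] = out_seq, _["support"] = out_support);
}
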