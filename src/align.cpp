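#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <cstdint>
#include <algorithm>
using namespace Rcpp;

// ---------- encoding helpers ----------

static inline int8_t enc_base(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  case 'N': case 'n': return -1;
  default: return -2;
  }
}

static std::vector<int8_t> encode_seq(const std::string& s, const char* what) {
  std::vector<int8_t> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) {
    int8_t b = enc_base(s[i]);
    if (b == -2) stop("invalid character '%c' in %s (only A, C, G, T, N allowed)", s[i], what);
    v[i] = b;
  }
  return v;
}

static std::vector<int8_t> rc_enc(const std::vector<int8_t>& v) {
  std::vector<int8_t> r(v.size());
  for (size_t i = 0; i < v.size(); ++i) {
    int8_t b = v[v.size() - 1 - i];
    r[i] = (b < 0) ? b : static_cast<int8_t>(3 - b);
  }
  return r;
}

// ---------- Smith-Waterman (linear gap penalty) ----------

struct SWHit {
  int qs, qe, ts, te;   // 0-based half-open
  int score;
  int matches, cols;    // for identity
  bool found;
};

// Exact local alignment with traceback. N mismatches everything (including N).
static SWHit sw_core(const std::vector<int8_t>& q, const std::vector<int8_t>& t,
                     int match, int mismatch, int gap) {
  const int n = static_cast<int>(q.size()), m = static_cast<int>(t.size());
  SWHit best; best.found = false; best.score = 0;
  if (n == 0 || m == 0) return best;
  std::vector<int> H(static_cast<size_t>(n + 1) * (m + 1), 0);
  std::vector<int8_t> P(static_cast<size_t>(n + 1) * (m + 1), 0); // 0 stop, 1 diag, 2 up(query gap?), 3 left
  int best_score = 0;
  std::vector<std::pair<int,int>> ends;
  for (int i = 1; i <= n; ++i) {
    const size_t row = static_cast<size_t>(i) * (m + 1), prow = row - (m + 1);
    for (int j = 1; j <= m; ++j) {
      bool is_match = (q[i-1] >= 0 && q[i-1] == t[j-1]);
      int diag = H[prow + j - 1] + (is_match ? match : mismatch);
      int up   = H[prow + j] + gap;     // consume query base (gap in target)
      int left = H[row + j - 1] + gap;  // consume target base (gap in query)
      int v = 0; int8_t p = 0;
      if (diag > v) { v = diag; p = 1; }
      if (up   > v) { v = up;   p = 2; }
      if (left > v) { v = left; p = 3; }
      H[row + j] = v; P[row + j] = p;
      if (v > best_score) { best_score = v; ends.clear(); ends.push_back({i, j}); }
      else if (v == best_score && v > 0 && ends.size() < 64) ends.push_back({i, j});
    }
  }
  if (best_score < 1) return best;
  // traceback each tied end; choose smallest query_start, then target_start
  int sel = -1, sel_qs = -1, sel_ts = -1, sel_mat = 0, sel_cols = 0;
  for (size_t e = 0; e < ends.size(); ++e) {
    int i = ends[e].first, j = ends[e].second;
    int mat = 0, cols = 0;
    while (i > 0 && j > 0) {
      size_t pos = static_cast<size_t>(i) * (m + 1) + j;
      int8_t p = P[pos];
      if (p == 0) break;
      ++cols;
      if (p == 1) { if (q[i-1] >= 0 && q[i-1] == t[j-1]) ++mat; --i; --j; }
      else if (p == 2) { --i; }
      else { --j; }
    }
    if (sel < 0 || i < sel_qs || (i == sel_qs && j < sel_ts)) {
      sel = static_cast<int>(e); sel_qs = i; sel_ts = j; sel_mat = mat; sel_cols = cols;
    }
  }
  best.found = true;
  best.score = best_score;
  best.qs = sel_qs; best.qe = ends[sel].first;
  best.ts = sel_ts; best.te = ends[sel].second;
  best.matches = sel_mat; best.cols = sel_cols;
  return best;
}

// [[Rcpp::export]]
List sw_align_cpp(std::string query, std::string target,
                  int match, int mismatch, int gap) {
  std::vector<int8_t> q = encode_seq(query, "query");
  std::vector<int8_t> t = encode_seq(target, "target");
  SWHit h = sw_core(q, t, match, mismatch, gap);
  if (!h.found) return List::create();
  return List::create(
    _["query_start"] = h.qs, _["query_end"] = h.qe,
    _["target_start"] = h.ts, _["target_end"] = h.te,
    _["score"] = h.score,
    _["identity"] = h.cols > 0 ? static_cast<double>(h.matches) / h.cols : 0.0);
}

// ---------- k-mer index ----------

struct KmerIndex {
  int k;
  std::vector<std::string> names;
  std::vector<std::string> seqs;
  std::vector<std::vector<int8_t>> enc;
  std::unordered_map<uint64_t, std::vector<std::pair<int32_t,int32_t>>> map;
};

static inline uint64_t kmer_mask(int k) { return (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1); }

// [[Rcpp::export]]
SEXP kmer_index_build_cpp(CharacterVector names, CharacterVector seqs, int k) {
  if (k < 1 || k > 31) stop("k must be between 1 and 31");
  KmerIndex* idx = new KmerIndex();
  idx->k = k;
  bool any_long_enough = false;
  const uint64_t mask = kmer_mask(k);
  for (R_xlen_t ti = 0; ti < seqs.size(); ++ti) {
    std::string s = as<std::string>(seqs[ti]);
    idx->names.push_back(as<std::string>(names[ti]));
    idx->seqs.push_back(s);
    idx->enc.push_back(encode_seq(s, "index target"));
    const std::vector<int8_t>& e = idx->enc.back();
    const int L = static_cast<int>(e.size());
    if (L < k) continue;
    any_long_enough = true;
    uint64_t kv = 0; int run = 0;
    for (int i = 0; i < L; ++i) {
      if (e[i] < 0) { run = 0; kv = 0; continue; }
      kv = ((kv << 2) | static_cast<uint64_t>(e[i])) & mask;
      if (++run >= k)
        idx->map[kv].push_back({static_cast<int32_t>(ti), static_cast<int32_t>(i - k + 1)});
    }
  }
  if (!any_long_enough) { delete idx; stop("k = %d is larger than every target sequence", k); }
  XPtr<KmerIndex> ptr(idx, true);
  return ptr;
}

// [[Rcpp::export]]
int kmer_index_k_cpp(SEXP xp) { return XPtr<KmerIndex>(xp)->k; }

// [[Rcpp::export]]
double kmer_index_n_kmers_cpp(SEXP xp) {
  XPtr<KmerIndex> idx(xp);
  double n = 0;
  for (auto& kv : idx->map) n += kv.second.size();
  return n;
}

// [[Rcpp::export]]
CharacterVector kmer_index_targets_cpp(SEXP xp) {
  XPtr<KmerIndex> idx(xp);
  return wrap(idx->names);
}

// [[Rcpp::export]]
IntegerVector kmer_index_target_lengths_cpp(SEXP xp) {
  XPtr<KmerIndex> idx(xp);
  IntegerVector out(idx->seqs.size());
  for (size_t i = 0; i < idx->seqs.size(); ++i) out[i] = static_cast<int>(idx->seqs[i].size());
  return out;
}

// [[Rcpp::export]]
DataFrame kmer_index_lookup_cpp(SEXP xp, std::string kmer) {
  XPtr<KmerIndex> idx(xp);
  if (static_cast<int>(kmer.size()) != idx->k) stop("query k-mer length != index k");
  std::vector<int8_t> e = encode_seq(kmer, "k-mer");
  uint64_t kv = 0;
  for (int i = 0; i < idx->k; ++i) {
    if (e[i] < 0) return DataFrame::create(_["target"] = IntegerVector(0), _["offset"] = IntegerVector(0));
    kv = (kv << 2) | static_cast<uint64_t>(e[i]);
  }
  auto it = idx->map.find(kv);
  if (it == idx->map.end())
    return DataFrame::create(_["target"] = IntegerVector(0), _["offset"] = IntegerVector(0));
  IntegerVector tg(it->second.size()), off(it->second.size());
  for (size_t i = 0; i < it->second.size(); ++i) {
    tg[i] = it->second[i].first + 1;
    off[i] = it->second[i].second;
  }
  return DataFrame::create(_["target"] = tg, _["offset"] = off);
}

// ---------- seeded local alignment ----------

struct RawHit {
  int query;     // 0-based query number
  int target;    // 0-based target number
  int qs, qe, ts, te;
  char strand;
  int score, matches, cols;
};

static void seed_and_extend(const std::vector<int8_t>& oriented, char strand, int qi,
                            const KmerIndex& idx, int match, int mismatch, int gap,
                            int min_score, std::vector<RawHit>& hits) {
  const int k = idx.k, qlen = static_cast<int>(oriented.size());
  if (qlen < k) return;
  const uint64_t mask = kmer_mask(k);
  // collect seed diagonals per target
  std::unordered_map<int32_t, std::vector<int32_t>> diags; // target -> diagonals (o - i)
  uint64_t kv = 0; int run = 0;
  for (int i = 0; i < qlen; ++i) {
    if (oriented[i] < 0) { run = 0; kv = 0; continue; }
    kv = ((kv << 2) | static_cast<uint64_t>(oriented[i])) & mask;
    if (++run < k) continue;
    auto it = idx.map.find(kv);
    if (it == idx.map.end()) continue;
    int qpos = i - k + 1;
    for (auto& occ : it->second) diags[occ.first].push_back(occ.second - qpos);
  }
  const int band = 16;
  for (auto& kvp : diags) {
    const int ti = kvp.first;
    std::vector<int32_t>& ds = kvp.second;
    std::sort(ds.begin(), ds.end());
    ds.erase(std::unique(ds.begin(), ds.end()), ds.end());
    const std::vector<int8_t>& tenc = idx.enc[ti];
    const int tlen = static_cast<int>(tenc.size());
    size_t a = 0;
    while (a < ds.size()) {
      size_t b = a;
      while (b + 1 < ds.size() && ds[b + 1] - ds[b] <= band) ++b;
      int dmin = ds[a], dmax = ds[b];
      int t_lo = std::max(0, dmin - band);
      int t_hi = std::min(tlen, dmax + qlen + band);
      std::vector<int8_t> win(tenc.begin() + t_lo, tenc.begin() + t_hi);
      SWHit h = sw_core(oriented, win, match, mismatch, gap);
      if (h.found && h.score >= min_score) {
        RawHit r;
        r.query = qi; r.target = ti; r.strand = strand;
        r.ts = h.ts + t_lo; r.te = h.te + t_lo;
        if (strand == '+') { r.qs = h.qs; r.qe = h.qe; }
        else { r.qs = qlen - h.qe; r.qe = qlen - h.qs; }
        r.score = h.score; r.matches = h.matches; r.cols = h.cols;
        hits.push_back(r);
      }
      a = b + 1;
    }
  }
}

// [[Rcpp::export]]
DataFrame seeded_align_cpp(CharacterVector queries, SEXP xp,
                           int match, int mismatch, int gap, int min_score,
                           double max_query_overlap) {
  XPtr<KmerIndex> idx(xp);
  std::vector<RawHit> keep;
  for (R_xlen_t qi = 0; qi < queries.size(); ++qi) {
    std::string qs = as<std::string>(queries[qi]);
    std::vector<int8_t> q = encode_seq(qs, "query");
    std::vector<RawHit> hits;
    seed_and_extend(q, '+', static_cast<int>(qi), *idx, match, mismatch, gap, min_score, hits);
    std::vector<int8_t> qr = rc_enc(q);
    seed_and_extend(qr, '-', static_cast<int>(qi), *idx, match, mismatch, gap, min_score, hits);
    // drop duplicates produced by neighbouring seed bands
    std::sort(hits.begin(), hits.end(), [](const RawHit& a, const RawHit& b) {
      if (a.score != b.score) return a.score > b.score;
      if (a.target != b.target) return a.target < b.target;
      if (a.qs != b.qs) return a.qs < b.qs;
      if (a.ts != b.ts) return a.ts < b.ts;
      return a.strand < b.strand;
    });
    hits.erase(std::unique(hits.begin(), hits.end(), [](const RawHit& a, const RawHit& b) {
      return a.target == b.target && a.qs == b.qs && a.qe == b.qe &&
             a.ts == b.ts && a.te == b.te && a.strand == b.strand;
    }), hits.end());
    // greedy merge: a hit overlapping a better kept hit on the same target by
    // more than max_query_overlap of the shorter span is dropped; equal-score
    // co-optimal hits are kept so downstream ambiguity detection can see them
    std::vector<RawHit> mine;
    for (auto& h : hits) {
      bool ok = true;
      for (auto& g : mine) {
        if (g.target != h.target || g.score == h.score) continue;
        int ov = std::min(g.qe, h.qe) - std::max(g.qs, h.qs);
        if (ov <= 0) continue;
        int shorter = std::min(g.qe - g.qs, h.qe - h.qs);
        if (static_cast<double>(ov) > max_query_overlap * shorter) { ok = false; break; }
      }
      if (ok) mine.push_back(h);
    }
    for (auto& h : mine) keep.push_back(h);
  }
  const size_t n = keep.size();
  IntegerVector query(n), target(n), q_start(n), q_end(n), t_start(n), t_end(n), score(n);
  CharacterVector strand(n);
  NumericVector identity(n);
  for (size_t i = 0; i < n; ++i) {
    query[i] = keep[i].query + 1; target[i] = keep[i].target + 1;
    q_start[i] = keep[i].qs; q_end[i] = keep[i].qe;
    t_start[i] = keep[i].ts; t_end[i] = keep[i].te;
    strand[i] = std::string(1, keep[i].strand);
    score[i] = keep[i].score;
    identity[i] = keep[i].cols > 0 ? static_cast<double>(keep[i].matches) / keep[i].cols : 0.0;
  }
  return DataFrame::create(_["query"] = query, _["target"] = target,
                           _["q_start"] = q_start, _["q_end"] = q_end,
                           _["t_start"] = t_start, _["t_end"] = t_end,
                           _["strand"] = strand, _["score"] = score,
                           _["identity"] = identity, _["stringsAsFactors"] = false);
}

// ---------- read-vs-terminal classification hits ----------

// Best local hit of each read against the two element terminals (LE first,
// then RE), both strands, with a shared-k-mer prefilter. Coordinates are
// reported in the oriented query (reverse complement for '-' hits).
// [[Rcpp::export]]
DataFrame terminal_hits_cpp(CharacterVector reads, std::string left_term, std::string right_term,
                            int k, int match, int mismatch, int gap) {
  std::vector<std::vector<int8_t>> terms;
  terms.push_back(encode_seq(left_term, "left terminal"));
  terms.push_back(encode_seq(right_term, "right terminal"));
  // prefilter set: k-mers of both terminals and their reverse complements
  std::unordered_set<uint64_t> bait;
  const uint64_t mask = kmer_mask(k);
  for (int t = 0; t < 2; ++t) {
    for (int pass = 0; pass < 2; ++pass) {
      std::vector<int8_t> e = pass == 0 ? terms[t] : rc_enc(terms[t]);
      uint64_t kv = 0; int run = 0;
      for (size_t i = 0; i < e.size(); ++i) {
        if (e[i] < 0) { run = 0; kv = 0; continue; }
        kv = ((kv << 2) | static_cast<uint64_t>(e[i])) & mask;
        if (++run >= k) bait.insert(kv);
      }
    }
  }
  const R_xlen_t n = reads.size();
  LogicalVector has_hit(n);
  IntegerVector which_end(n), q_start(n), q_end(n), t_start(n), t_end(n), score(n);
  CharacterVector strand(n);
  NumericVector identity(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string s = as<std::string>(reads[i]);
    std::vector<int8_t> q = encode_seq(s, "read");
    bool seed = false;
    {
      uint64_t kv = 0; int run = 0;
      for (size_t j = 0; j < q.size(); ++j) {
        if (q[j] < 0) { run = 0; kv = 0; continue; }
        kv = ((kv << 2) | static_cast<uint64_t>(q[j])) & mask;
        if (++run >= k && bait.count(kv)) { seed = true; break; }
      }
    }
    has_hit[i] = false;
    which_end[i] = NA_INTEGER; q_start[i] = NA_INTEGER; q_end[i] = NA_INTEGER;
    t_start[i] = NA_INTEGER; t_end[i] = NA_INTEGER; score[i] = NA_INTEGER;
    strand[i] = NA_STRING; identity[i] = NA_REAL;
    if (!seed) continue;
    std::vector<int8_t> qr = rc_enc(q);
    SWHit best; best.found = false; best.score = 0;
    int best_end = 0; char best_strand = '+';
    for (int t = 0; t < 2; ++t) {
      for (int pass = 0; pass < 2; ++pass) {
        SWHit h = sw_core(pass == 0 ? q : qr, terms[t], match, mismatch, gap);
        if (h.found && h.score > best.score) {
          best = h; best_end = t; best_strand = pass == 0 ? '+' : '-';
        }
      }
    }
    if (!best.found) continue;
    has_hit[i] = true;
    which_end[i] = best_end + 1;               // 1 = LE, 2 = RE
    q_start[i] = best.qs; q_end[i] = best.qe;  // oriented-query coordinates
    t_start[i] = best.ts; t_end[i] = best.te;
    score[i] = best.score;
    strand[i] = std::string(1, best_strand);
    identity[i] = best.cols > 0 ? static_cast<double>(best.matches) / best.cols : 0.0;
  }
  return DataFrame::create(_["has_hit"] = has_hit, _["end"] = which_end,
                           _["strand"] = strand,
                           _["q_start"] = q_start, _["q_end"] = q_end,
                           _["t_start"] = t_start, _["t_end"] = t_end,
                           _["score"] = score, _["identity"] = identity,
                           _["stringsAsFactors"] = false);
}

// ---------- fast full-length read placement ----------

// Place whole reads on the indexed genome by exact k-mer seeding plus mismatch
// counting (no gaps). A read is ambiguous when two distinct placements tie at
// the best mismatch count. Used for bulk placement of genomic (type 2) pairs.
// [[Rcpp::export]]
DataFrame place_reads_cpp(CharacterVector reads, SEXP xp, int max_mismatch) {
  XPtr<KmerIndex> idx(xp);
  const int k = idx->k;
  const uint64_t mask = kmer_mask(k);
  const R_xlen_t n = reads.size();
  IntegerVector target(n), start(n), mismatches(n);
  CharacterVector strand(n);
  LogicalVector placed(n), ambiguous(n);
  for (R_xlen_t ri = 0; ri < n; ++ri) {
    std::string s = as<std::string>(reads[ri]);
    std::vector<int8_t> fwd = encode_seq(s, "read");
    const int L = static_cast<int>(fwd.size());
    placed[ri] = false; ambiguous[ri] = false;
    target[ri] = NA_INTEGER; start[ri] = NA_INTEGER; mismatches[ri] = NA_INTEGER;
    strand[ri] = NA_STRING;
    if (L < k) continue;
    std::vector<int8_t> rev = rc_enc(fwd);
    int best_mm = max_mismatch + 1;
    int best_t = -1, best_s = -1; char best_str = '+';
    bool tie = false;
    std::unordered_set<uint64_t> tried; // (strand, target, start) combos already scored
    for (int pass = 0; pass < 2; ++pass) {
      // pass 0: three spaced seeds; pass 1 (fallback): every 4th k-mer
      std::vector<int> offs;
      if (pass == 0) { offs = {0, (L - k) / 2, L - k}; }
      else { for (int o = 0; o + k <= L; o += 4) offs.push_back(o); }
      for (int st = 0; st < 2; ++st) {
        const std::vector<int8_t>& q = st == 0 ? fwd : rev;
        for (int o : offs) {
          uint64_t kv = 0; bool bad = false;
          for (int j = 0; j < k; ++j) {
            if (q[o + j] < 0) { bad = true; break; }
            kv = ((kv << 2) | static_cast<uint64_t>(q[o + j])) & mask;
          }
          if (bad) continue;
          auto it = idx->map.find(kv);
          if (it == idx->map.end()) continue;
          for (auto& occ : it->second) {
            int ti = occ.first, spos = occ.second - o;
            const std::vector<int8_t>& tenc = idx->enc[ti];
            if (spos < 0 || spos + L > static_cast<int>(tenc.size())) continue;
            uint64_t key = (static_cast<uint64_t>(st) << 62) |
                           (static_cast<uint64_t>(ti) << 40) |
                           static_cast<uint64_t>(spos + (1 << 20));
            if (!tried.insert(key).second) continue;
            int mm = 0;
            for (int j = 0; j < L && mm <= max_mismatch; ++j)
              if (q[j] < 0 || q[j] != tenc[spos + j]) ++mm;
            if (mm > max_mismatch) continue;
            if (mm < best_mm) {
              best_mm = mm; best_t = ti; best_s = spos; best_str = st == 0 ? '+' : '-';
              tie = false;
            } else if (mm == best_mm && !(ti == best_t && spos == best_s &&
                                          best_str == (st == 0 ? '+' : '-'))) {
              tie = true;
            }
          }
        }
      }
      if (best_t >= 0) break; // seeds worked; no fallback scan needed
    }
    if (best_t < 0) continue;
    if (tie) { ambiguous[ri] = true; continue; }
    placed[ri] = true;
    target[ri] = best_t + 1;
    start[ri] = best_s;          // 0-based
    mismatches[ri] = best_mm;
    strand[ri] = best_str == '+' ? "+" : "-";
  }
  return DataFrame::create(_["placed"] = placed, _["ambiguous"] = ambiguous,
                           _["target"] = target, _["start"] = start,
                           _["strand"] = strand, _["mismatches"] = mismatches,
                           _["stringsAsFactors"] = false);
}
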