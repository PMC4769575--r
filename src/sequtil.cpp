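#include <Rcpp.h>
using namespace Rcpp;

static inline char comp_base(char c) {
  switch (c) {
  case 'A': return 'T'; case 'C': return 'G'; case 'G': return 'C'; case 'T': return 'A';
  case 'a': return 't'; case 'c': return 'g'; case 'g': return 'c'; case 't': return 'a';
  case 'N': return 'N'; case 'n': return 'n';
  default: return 'N';
  }
}

// [[Rcpp::export]]
CharacterVector revcomp_cpp(CharacterVector seqs) {
  R_xlen_t n = seqs.size();
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (CharacterVector::is_na(seqs[i])) { out[i] = NA_STRING; continue; }
    std::string s = as<std::string>(seqs[i]);
    std::string r(s.rbegin(), s.rend());
    for (size_t j = 0; j < r.size(); ++j) r[j] = comp_base(r[j]);
    out[i] = r;
  }
  return out;
}

// [[Rcpp::export]]
List phred_decode_cpp(CharacterVector quals) {
  R_xlen_t n = quals.size();
  List out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string q = as<std::string>(quals[i]);
    IntegerVector v(q.size());
    for (size_t j = 0; j < q.size(); ++j) {
      int ph = static_cast<int>(static_cast<unsigned char>(q[j])) - 33;
      if (ph < 0 || ph > 93)
        stop("quality character '%c' outside the Phred+33 range", q[j]);
      v[j] = ph;
    }
    out[i] = v;
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector phred_encode_cpp(List scores) {
  R_xlen_t n = scores.size();
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    IntegerVector v = scores[i];
    std::string q(v.size(), '!');
    for (R_xlen_t j = 0; j < v.size(); ++j) {
      if (v[j] < 0 || v[j] > 93) stop("Phred score %d cannot be encoded in Phred+33", (int)v[j]);
      q[j] = static_cast<char>(v[j] + 33);
    }
    out[i] = q;
  }
  return out;
}

// Fraction of bases with Phred score (Phred+33 encoded) strictly below `threshold`.
// [[Rcpp::export]]
NumericVector low_quality_fraction_cpp(CharacterVector quals, int threshold) {
  R_xlen_t n = quals.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string q = as<std::string>(quals[i]);
    if (q.empty()) { out[i] = 0.0; continue; }
    int low = 0;
    for (size_t j = 0; j < q.size(); ++j) {
      int ph = static_cast<int>(static_cast<unsigned char>(q[j])) - 33;
      if (ph < 0) stop("quality character '%c' outside the Phred+33 range", q[j]);
      if (ph < threshold) ++low;
    }
    out[i] = static_cast<double>(low) / static_cast<double>(q.size());
  }
  return out;
}
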