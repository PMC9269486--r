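#include <Rcpp.h>
using namespace Rcpp;

// Best ungapped suffix(a)/prefix(b) overlap of length >= min_overlap.
// Returns c(overlap_length, matches); c(0, 0) when no overlap of the
// required length exists. Identity is maximised; ties favour the longer
// overlap so that error-free mates recover the full true overlap.
// [[Rcpp::export]]
IntegerVector best_overlap_c(std::string a, std::string b, int min_overlap) {
  const int na = (int)a.size(), nb = (int)b.size();
  const int maxo = std::min(na, nb);
  int best_o = 0, best_m = 0;
  double best_id = -1.0;
  for (int o = min_overlap; o <= maxo; ++o) {
    int m = 0;
    const char *pa = a.data() + (na - o);
    const char *pb = b.data();
    for (int i = 0; i < o; ++i)
      if (pa[i] == pb[i]) ++m;
    double id = (double)m / (double)o;
    if (id > best_id + 1e-12 || (std::abs(id - best_id) <= 1e-12 && o > best_o)) {
      best_id = id; best_o = o; best_m = m;
    }
  }
  return IntegerVector::create(best_o, best_m);
}

// Hamming distance between equal-length string vectors (recycled b allowed
// when length 1). Used for isotype signatures and consensus checks.
// [[Rcpp::export]]
IntegerVector hamming_c(CharacterVector a, CharacterVector b) {
  const int n = a.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    const char *sa = CHAR(STRING_ELT(a, i));
    const char *sb = CHAR(STRING_ELT(b, b.size() == 1 ? 0 : i));
    int la = (int)strlen(sa), lb = (int)strlen(sb);
    if (la != lb) { out[i] = NA_INTEGER; continue; }
    int d = 0;
    for (int j = 0; j < la; ++j)
      if (sa[j] != sb[j]) ++d;
    out[i] = d;
  }
  return out;
}

// Plurality consensus over equal-length member strings. qual holds summed
// tie-break weights per member (same order); ties between bases are broken
// by the larger summed weight of supporting members, then lexicographically.
// [[Rcpp::export]]
String consensus_c(CharacterVector members, NumericVector qual) {
  const int n = members.size();
  const char *first = CHAR(STRING_ELT(members, 0));
  const int len = (int)strlen(first);
  std::string out(len, 'N');
  for (int p = 0; p < len; ++p) {
    int cnt[256] = {0};
    double w[256] = {0.0};
    for (int i = 0; i < n; ++i) {
      unsigned char c = (unsigned char)CHAR(STRING_ELT(members, i))[p];
      cnt[c]++;
      w[c] += qual[i];
    }
    int best = -1;
    for (int c = 0; c < 256; ++c) {
      if (cnt[c] == 0) continue;
      if (best < 0 || cnt[c] > cnt[best] ||
          (cnt[c] == cnt[best] && (w[c] > w[best] ||
           (w[c] == w[best] && c < best)))) best = c;
    }
    out[p] = (char)best;
  }
  return String(out);
}
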