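#include <Rcpp.h>
using namespace Rcpp;

// Pairwise hamming distance of equal-length string pairs. Comparison stops
// early once the count exceeds `cap` (pass a negative cap to disable).
// Unequal lengths are an error: callers align end-to-end only.
// [[Rcpp::export]]
IntegerVector hamming_count(CharacterVector a, CharacterVector b, int cap = -1) {
  R_xlen_t n = a.size();
  if (b.size() != n) stop("a and b must have equal length");
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (a[i] == NA_STRING || b[i] == NA_STRING) { out[i] = NA_INTEGER; continue; }
    const char *x = CHAR(a[i]);
    const char *y = CHAR(b[i]);
    R_xlen_t la = LENGTH(a[i]), lb = LENGTH(b[i]);
    if (la != lb) stop("string %d: unequal lengths (%d vs %d)", (int)(i + 1), (int)la, (int)lb);
    int mm = 0;
    for (R_xlen_t j = 0; j < la; ++j) {
      if (x[j] != y[j]) {
        ++mm;
        if (cap >= 0 && mm > cap) break;
      }
    }
    out[i] = mm;
  }
  return out;
}

// Per-position mismatch indicator between two equal-length strings.
// [[Rcpp::export]]
LogicalVector mismatch_profile(std::string a, std::string b) {
  if (a.size() != b.size()) stop("unequal lengths");
  size_t n = a.size();
  LogicalVector out(n);
  for (size_t j = 0; j < n; ++j) out[j] = (a[j] != b[j]);
  return out;
}
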