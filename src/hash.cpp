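#include <Rcpp.h>
using namespace Rcpp;

// 32-bit FNV-1a string hash, returned as double (R integers are signed).
// Deterministic across platforms; used for Morgan environment hashing.
// [[Rcpp::export]]
NumericVector fnvHash(CharacterVector x) {
  NumericVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    uint32_t h = 2166136261u;
    const char *s = CHAR(STRING_ELT(x, i));
    for (; *s; ++s) {
      h ^= (uint32_t)(unsigned char)(*s);
      h *= 16777619u;
    }
    out[i] = (double)h;
  }
  return out;
}
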