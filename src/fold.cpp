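#include <Rcpp.h>
#include <vector>
#include <string>

using namespace Rcpp;

// Pair weights: GC/CG = 3, AT/TA (AU) = 2, GT/TG (GU wobble) = 1, else 0.
// 'N' (or any other character) pairs with nothing.
static inline int pair_weight(char a, char b) {
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return 3;
  if ((a == 'A' && b == 'T') || (a == 'T' && b == 'A')) return 2;
  if ((a == 'G' && b == 'T') || (a == 'T' && b == 'G')) return 1;
  return 0;
}

// Nussinov-style maximum pair-weight folding with a minimum hairpin loop of
// 3 unpaired nucleotides (a pair (i, j) requires j - i >= 4). Returns the
// maximum attainable total pair weight; the exported energy is its negative.
static int nussinov_max_weight(const std::string &s) {
  const int n = (int)s.size();
  if (n < 5) return 0;
  // dp[i][j] = max weight attainable on s[i..j], 0-based, j >= i.
  std::vector<std::vector<int> > dp(n, std::vector<int>(n, 0));
  for (int len = 5; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      int best = dp[i + 1][j]; // i unpaired
      for (int k = i + 4; k <= j; ++k) {
        int w = pair_weight(s[i], s[k]);
        if (w == 0) continue;
        int inner = dp[i + 1][k - 1];
        int rest = (k + 1 <= j) ? dp[k + 1][j] : 0;
        if (w + inner + rest > best) best = w + inner + rest;
      }
      dp[i][j] = best;
    }
  }
  return dp[0][n - 1];
}

// [[Rcpp::export(name = ".fold_mfe_internal")]]
NumericVector fold_mfe_internal(CharacterVector seqs) {
  const R_xlen_t n = seqs.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (CharacterVector::is_na(seqs[i])) { out[i] = NA_REAL; continue; }
    std::string s = as<std::string>(seqs[i]);
    out[i] = -(double)nussinov_max_weight(s);
  }
  return out;
}
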