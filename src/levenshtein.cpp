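#include <Rcpp.h>
#include <vector>
#include <algorithm>

// Token-level edit distance between two integer-coded sequences.
// Insertions and deletions cost 1; a substitution costs sub_cost
// (2 by default, the convention under which (m + n - dist) / (m + n)
// is a similarity in [0, 1]).
// [[Rcpp::export(name = ".token_edit_distance")]]
int token_edit_distance(Rcpp::IntegerVector a, Rcpp::IntegerVector b,
                        int sub_cost = 2) {
  const int m = a.size(), n = b.size();
  std::vector<int> prev(n + 1), cur(n + 1);
  for (int j = 0; j <= n; ++j) prev[j] = j;
  for (int i = 1; i <= m; ++i) {
    cur[0] = i;
    for (int j = 1; j <= n; ++j) {
      int sub = prev[j - 1] + (a[i - 1] == b[j - 1] ? 0 : sub_cost);
      cur[j] = std::min(sub, std::min(prev[j] + 1, cur[j - 1] + 1));
    }
    std::swap(prev, cur);
  }
  return prev[n];
}
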