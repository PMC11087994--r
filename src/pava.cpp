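#include <Rcpp.h>
using namespace Rcpp;

// Row-wise pool-adjacent-violators: makes each row non-decreasing in the
// least-squares sense (equal weights). Used to repair across-level
// monotonicity of estimated travel times; K (ncol) is small.
// [[Rcpp::export]]
NumericMatrix pava_rows(NumericMatrix x) {
  int n = x.nrow(), k = x.ncol();
  NumericMatrix out(n, k);
  std::vector<double> val(k);
  std::vector<int> wt(k), len(k);
  for (int i = 0; i < n; ++i) {
    int m = 0;  // active blocks
    for (int j = 0; j < k; ++j) {
      val[m] = x(i, j); wt[m] = 1; len[m] = 1; ++m;
      while (m > 1 && val[m - 2] > val[m - 1]) {
        val[m - 2] = (val[m - 2] * wt[m - 2] + val[m - 1] * wt[m - 1]) /
                     (wt[m - 2] + wt[m - 1]);
        wt[m - 2] += wt[m - 1];
        len[m - 2] += len[m - 1];
        --m;
      }
    }
    int j = 0;
    for (int b = 0; b < m; ++b)
      for (int r = 0; r < len[b]; ++r) out(i, j++) = val[b];
  }
  return out;
}
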