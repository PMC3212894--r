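#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Exact minimum within-bin sum-of-squares partition of sorted unique values u
// with multiplicities w into k contiguous bins (Fisher's dynamic program,
// O(k n^2)). Returns the segment start indices (1-based into u) and the
// optimal total SSE.
// [[Rcpp::export]]
List fisher_dp_cpp(NumericVector u, NumericVector w, int k) {
  const int n = u.size();
  if (k < 1 || k > n) stop("k must be between 1 and length(u)");
  std::vector<double> W(n + 1, 0.0), S1(n + 1, 0.0), S2(n + 1, 0.0);
  for (int i = 1; i <= n; ++i) {
    W[i] = W[i - 1] + w[i - 1];
    S1[i] = S1[i - 1] + w[i - 1] * u[i - 1];
    S2[i] = S2[i - 1] + w[i - 1] * u[i - 1] * u[i - 1];
  }
  auto cost = [&](int i, int j) {  // weighted SSE of u[i..j], 1-based inclusive
    double ww = W[j] - W[i - 1];
    double s1 = S1[j] - S1[i - 1];
    double s2 = S2[j] - S2[i - 1];
    double v = s2 - s1 * s1 / ww;
    return v > 0.0 ? v : 0.0;  // clamp tiny negative rounding
  };

  std::vector<std::vector<double>> D(k + 1,
                                     std::vector<double>(n + 1, R_PosInf));
  std::vector<std::vector<int>> B(k + 1, std::vector<int>(n + 1, 0));
  D[0][0] = 0.0;
  for (int m = 1; m <= k; ++m) {
    for (int j = m; j <= n; ++j) {
      for (int i = m; i <= j; ++i) {
        if (!R_finite(D[m - 1][i - 1])) continue;
        double cand = D[m - 1][i - 1] + cost(i, j);
        if (cand < D[m][j]) {
          D[m][j] = cand;
          B[m][j] = i;
        }
      }
    }
  }
  IntegerVector starts(k);
  int j = n;
  for (int m = k; m >= 1; --m) {
    starts[m - 1] = B[m][j];
    j = B[m][j] - 1;
  }
  return List::create(_["starts"] = starts, _["sse"] = D[k][n]);
}
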