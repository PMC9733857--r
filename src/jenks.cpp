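#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Exact Fisher-Jenks partition of a sorted vector into k contiguous classes
// minimising the total within-class sum of squared deviations.
// Returns 1-based indices of the last element of classes 1..k-1.
// O(k n^2) time, O(k n) memory, prefix sums for O(1) class costs.
// [[Rcpp::export]]
IntegerVector jenks_breaks_idx(NumericVector x_sorted, int k) {
  const int n = x_sorted.size();
  if (k < 1) stop("number of classes must be >= 1");
  if (n < k) stop("need at least as many values as classes");

  std::vector<long double> s1(n + 1, 0.0L), s2(n + 1, 0.0L);
  for (int i = 0; i < n; ++i) {
    s1[i + 1] = s1[i] + x_sorted[i];
    s2[i + 1] = s2[i] + (long double)x_sorted[i] * x_sorted[i];
  }
  // ssd of elements (i+1)..j, 1-based inclusive
  auto ssd = [&](int i, int j) -> long double {
    const int m = j - i;
    const long double sum = s1[j] - s1[i];
    return s2[j] - s2[i] - sum * sum / m;
  };

  const long double INF = std::numeric_limits<long double>::infinity();
  // cost[c][j]: best total ssd splitting first j values into c classes
  std::vector<std::vector<long double>> cost(k + 1,
      std::vector<long double>(n + 1, INF));
  std::vector<std::vector<int>> back(k + 1, std::vector<int>(n + 1, 0));
  for (int j = 1; j <= n; ++j) cost[1][j] = ssd(0, j);
  for (int c = 2; c <= k; ++c) {
    for (int j = c; j <= n; ++j) {
      long double bestv = INF;
      int bestm = c - 1;
      for (int m = c - 1; m < j; ++m) {
        const long double v = cost[c - 1][m] + ssd(m, j);
        if (v < bestv) { bestv = v; bestm = m; }
      }
      cost[c][j] = bestv;
      back[c][j] = bestm;
    }
  }
  IntegerVector out(k - 1);
  int j = n;
  for (int c = k; c >= 2; --c) {
    out[c - 2] = back[c][j];
    j = back[c][j];
  }
  return out;
}
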