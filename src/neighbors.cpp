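#include <Rcpp.h>
#include <algorithm>
#include <numeric>
#include <vector>

using namespace Rcpp;

// Fixed-radius neighbour counts in the (ag, ad) plane.
// A pair (i, j), i != j, are neighbours iff
//   (ag_i - ag_j)^2 + (ad_i - ad_j)^2 < r0^2   (strict).
// Genes are sorted by ag and only pairs with |ag_i - ag_j| < r0 are
// examined; squared distances are compared so the result is bit-identical
// to the O(N^2) definition, including points exactly at the radius.
// [[Rcpp::export]]
IntegerVector count_neighbors_cpp(NumericVector ag, NumericVector ad, double r0) {
  const int n = ag.size();
  if (ad.size() != n) stop("`ag` and `ad` must have equal length");
  IntegerVector counts(n);
  if (n < 2 || r0 <= 0.0) return counts;

  const double r2 = r0 * r0;
  std::vector<int> idx(n);
  std::iota(idx.begin(), idx.end(), 0);
  std::sort(idx.begin(), idx.end(),
            [&](int a, int b) { return ag[a] < ag[b]; });

  for (int ii = 0; ii < n; ++ii) {
    const int i = idx[ii];
    const double agi = ag[i], adi = ad[i];
    for (int jj = ii + 1; jj < n; ++jj) {
      const int j = idx[jj];
      const double dx = ag[j] - agi;
      if (dx >= r0) break;  // dx^2 >= r2 for all later j
      const double dy = ad[j] - adi;
      if (dx * dx + dy * dy < r2) {
        ++counts[i];
        ++counts[j];
      }
    }
  }
  return counts;
}
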