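#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Condensed (lower-triangle, stats::dist ordering) Gower dissimilarity.
// kind codes: 0 = numeric (range-scaled), 1 = asymmetric binary
// (0-0 pairs drop out of the average), 2 = symmetric binary.
// A numeric variable with zero range contributes 0 but stays in the
// denominator; the caller warns about it once.
// [[Rcpp::export]]
List gower_condensed_cpp(NumericMatrix x, IntegerVector kind,
                         NumericVector range, NumericVector weight) {
  const int n = x.nrow(), p = x.ncol();
  const R_xlen_t m = (R_xlen_t)n * (n - 1) / 2;
  NumericVector d(m);
  double zero_denom = 0;
  R_xlen_t idx = 0;
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j, ++idx) {
      double num = 0.0, den = 0.0;
      for (int v = 0; v < p; ++v) {
        const double a = x(i, v), b = x(j, v), w = weight[v];
        switch (kind[v]) {
        case 0:
          if (range[v] > 0) num += w * std::fabs(a - b) / range[v];
          den += w;
          break;
        case 1:
          if (a == 0.0 && b == 0.0) break;
          den += w;
          if (a != b) num += w;
          break;
        default:
          den += w;
          if (a != b) num += w;
        }
      }
      if (den > 0.0) {
        d[idx] = num / den;
      } else {
        d[idx] = 0.0;
        zero_denom += 1;
      }
    }
  }
  return List::create(_["d"] = d, _["n_zero_denom"] = zero_denom);
}
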