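#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// k-th nearest-neighbour Euclidean distance from each row of X to the rows
// of Y. When X and Y are the same sample (exclude_self = true) the zero
// self-distance is skipped by taking the (k+1)-th order statistic.
// [[Rcpp::export]]
NumericVector kth_nn_dist(NumericMatrix X, NumericMatrix Y, int k,
                          bool exclude_self) {
  const int n = X.nrow(), m = Y.nrow(), f = X.ncol();
  if (Y.ncol() != f) stop("X and Y must have the same number of columns");
  const int kk = exclude_self ? k + 1 : k;
  if (kk > m) stop("k too large for the number of reference points");
  NumericVector out(n);
  std::vector<double> d(m);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      double s = 0.0;
      for (int c = 0; c < f; ++c) {
        const double diff = X(i, c) - Y(j, c);
        s += diff * diff;
      }
      d[j] = s;
    }
    std::nth_element(d.begin(), d.begin() + (kk - 1), d.end());
    out[i] = std::sqrt(d[kk - 1]);
  }
  return out;
}
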