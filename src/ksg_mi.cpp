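#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Kraskov-Stoegbauer-Grassberger mutual information, algorithm 1, for a
// bivariate sample. Chebyshev (max-norm) k-th nearest neighbour distances are
// found with a sort-by-x window scan: after ordering the points by x, the k
// current-best distances bound how far the scan must extend in x, giving
// near O(n * sqrt(k n)) work on rank-uniform marginals. Marginal neighbour
// counts (strict inequality, as the estimator requires) come from binary
// searches on the sorted marginals.
//
// Inputs are assumed tie-free (the R wrapper jitters and rank-transforms).

// [[Rcpp::export]]
double ksg_mi_cpp(NumericVector x, NumericVector y, int k) {
  const int n = x.size();
  if (y.size() != n) stop("x and y must have equal length");
  if (k < 1 || k >= n) stop("require 1 <= k < n");

  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return x[a] < x[b]; });

  std::vector<double> xs(n), ys(n), ysort(n);
  for (int i = 0; i < n; ++i) {
    xs[i] = x[ord[i]];
    ys[i] = y[ord[i]];
    ysort[i] = y[i];
  }
  std::sort(ysort.begin(), ysort.end());

  double acc = 0.0;
  std::vector<double> best;  // max-heap of the k smallest distances seen
  best.reserve(k);

  for (int i = 0; i < n; ++i) {
    best.clear();
    int l = i - 1, r = i + 1;
    const double xi = xs[i], yi = ys[i];

    while (l >= 0 || r < n) {
      bool full = (int)best.size() == k;
      double bound = full ? best.front() : R_PosInf;
      double dl = (l >= 0) ? xi - xs[l] : R_PosInf;
      double dr = (r < n) ? xs[r] - xi : R_PosInf;
      if (dl >= bound && dr >= bound) break;
      int j;
      if (dl <= dr) { j = l; --l; } else { j = r; ++r; }
      double d = std::max(std::abs(xs[j] - xi), std::abs(ys[j] - yi));
      if (!full) {
        best.push_back(d);
        std::push_heap(best.begin(), best.end());
      } else if (d < best.front()) {
        std::pop_heap(best.begin(), best.end());
        best.back() = d;
        std::push_heap(best.begin(), best.end());
      }
    }

    const double eps = best.front();

    // strict counts |x_j - x_i| < eps (excluding self)
    long nx = (std::lower_bound(xs.begin(), xs.end(), xi + eps) -
               std::upper_bound(xs.begin(), xs.end(), xi - eps)) - 1;
    long ny = (std::lower_bound(ysort.begin(), ysort.end(), yi + eps) -
               std::upper_bound(ysort.begin(), ysort.end(), yi - eps)) - 1;

    acc += R::digamma((double)nx + 1.0) + R::digamma((double)ny + 1.0);
  }

  return R::digamma((double)k) + R::digamma((double)n) - acc / n;
}
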