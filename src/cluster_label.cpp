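#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Connected-component labelling of supra-threshold cells on a
// channel x time grid. Connectivity: temporal contiguity within a channel
// plus the supplied channel adjacency at the same time point. Positive and
// negative exceedances form separate clusters (two-sided statistic).
//
// tmat:  n_ch x n_time matrix of pointwise statistics
// thr:   cluster-forming threshold (> 0)
// adj:   list of integer vectors, 1-based neighbour channel indices
//
// Returns labels (0 = sub-threshold) and the signed mass (sum of the
// statistic) per cluster.

static void label_grid(const NumericMatrix& tmat, double thr, const List& adj,
                       IntegerMatrix* labels, std::vector<double>* masses) {
  const int nch = tmat.nrow(), nt = tmat.ncol();
  std::vector<signed char> sgn(nch * nt, 0);
  for (int t = 0; t < nt; ++t)
    for (int c = 0; c < nch; ++c) {
      double v = tmat(c, t);
      if (v > thr) sgn[c + nch * t] = 1;
      else if (v < -thr) sgn[c + nch * t] = -1;
    }

  std::vector<std::vector<int>> nb(nch);
  for (int c = 0; c < nch; ++c) {
    IntegerVector a = adj[c];
    for (int i = 0; i < a.size(); ++i) nb[c].push_back(a[i] - 1);
  }

  std::vector<int> lab(nch * nt, 0);
  std::vector<int> stack;
  int next = 0;

  for (int start = 0; start < nch * nt; ++start) {
    if (sgn[start] == 0 || lab[start] != 0) continue;
    ++next;
    double mass = 0.0;
    signed char s = sgn[start];
    stack.clear();
    stack.push_back(start);
    lab[start] = next;
    while (!stack.empty()) {
      int cell = stack.back();
      stack.pop_back();
      int c = cell % nch, t = cell / nch;
      mass += tmat(c, t);
      if (t > 0) {
        int q = cell - nch;
        if (sgn[q] == s && lab[q] == 0) { lab[q] = next; stack.push_back(q); }
      }
      if (t + 1 < nt) {
        int q = cell + nch;
        if (sgn[q] == s && lab[q] == 0) { lab[q] = next; stack.push_back(q); }
      }
      for (int c2 : nb[c]) {
        int q = c2 + nch * t;
        if (sgn[q] == s && lab[q] == 0) { lab[q] = next; stack.push_back(q); }
      }
    }
    masses->push_back(mass);
  }

  if (labels != nullptr) {
    for (int t = 0; t < nt; ++t)
      for (int c = 0; c < nch; ++c)
        (*labels)(c, t) = lab[c + nch * t];
  }
}

// [[Rcpp::export]]
List cluster_label_cpp(NumericMatrix tmat, double thr, List adj) {
  IntegerMatrix labels(tmat.nrow(), tmat.ncol());
  std::vector<double> masses;
  label_grid(tmat, thr, adj, &labels, &masses);
  return List::create(_["labels"] = labels,
                      _["masses"] = NumericVector(masses.begin(), masses.end()));
}

// [[Rcpp::export]]
double max_cluster_mass_cpp(NumericMatrix tmat, double thr, List adj) {
  std::vector<double> masses;
  label_grid(tmat, thr, adj, nullptr, &masses);
  double m = 0.0;
  for (double v : masses) m = std::max(m, std::abs(v));
  return m;
}
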