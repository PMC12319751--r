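// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

// Symmetric decorrelation: W <- (W W')^{-1/2} W
static void sym_decorrelate(mat& W) {
  vec eval;
  mat evec;
  eig_sym(eval, evec, W * W.t());
  eval = clamp(eval, 1e-300, datum::inf);
  W = evec * diagmat(1.0 / sqrt(eval)) * evec.t() * W;
}

// Fixed-point symmetric FastICA with the log-cosh (tanh) contrast on
// whitened data Z (components x samples). Returns the unmixing matrix in
// whitened space, the convergence flag and the iteration count.

// [[Rcpp::export]]
Rcpp::List fastica_core(const arma::mat& Z, const arma::mat& Winit,
                        int maxIter, double tol) {
  const double n = (double)Z.n_cols;
  mat W = Winit;
  sym_decorrelate(W);

  bool converged = false;
  int it = 0;
  mat G, Wnew;
  while (it < maxIter) {
    ++it;
    G = tanh(W * Z);
    vec beta = mean(1.0 - square(G), 1);
    Wnew = (G * Z.t()) / n - diagmat(beta) * W;
    sym_decorrelate(Wnew);
    double delta = (arma::abs(arma::abs(sum(Wnew % W, 1)) - 1.0)).max();
    W = Wnew;
    if (delta < tol) { converged = true; break; }
  }
  return Rcpp::List::create(Rcpp::_["W"] = W,
                            Rcpp::_["converged"] = converged,
                            Rcpp::_["iter"] = it);
}
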