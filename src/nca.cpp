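#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Regularized expected leave-one-out NCA objective and gradient.
// D2:   (n*n) x F matrix of per-feature squared differences, column-major
//       over ordered pairs (j, i) so column i of the reshaped matrix holds
//       the distances of every j to point i.
// same: n x n class-agreement indicator (0/1), diagonal irrelevant.
// w:    current weight vector (length F); distances use w^2.
// [[Rcpp::export(name = ".nca_eval_cpp")]]
List nca_eval_cpp(const arma::mat& D2, const arma::mat& same,
                  const arma::vec& w, double lambda, bool want_grad) {
  const arma::uword n = same.n_rows;
  const arma::vec w2 = arma::square(w);

  arma::vec dvec = D2 * w2;
  arma::mat d(dvec.memptr(), n, n, false);

  // softmax over -d per column, excluding self; shift by the column minimum
  arma::mat e(n, n);
  for (arma::uword i = 0; i < n; ++i) {
    double m = arma::datum::inf;
    for (arma::uword j = 0; j < n; ++j)
      if (j != i && d(j, i) < m) m = d(j, i);
    for (arma::uword j = 0; j < n; ++j)
      e(j, i) = (j == i) ? 0.0 : std::exp(-(d(j, i) - m));
  }
  arma::rowvec cs = arma::sum(e, 0);
  arma::mat P = e.each_row() / cs;
  arma::rowvec p = arma::sum(P % same, 0); // p_i, expected correct assignment

  double obj = arma::accu(p) - lambda * arma::accu(w2);
  if (!want_grad) return List::create(_["objective"] = obj);

  arma::mat M = P.each_row() % p;
  M -= P % same;
  arma::vec g = D2.t() * arma::vectorise(M);
  arma::vec grad = 2.0 * (w % g) - 2.0 * lambda * w;
  return List::create(_["objective"] = obj, _["gradient"] = grad);
}
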