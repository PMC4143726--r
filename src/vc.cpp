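// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Profile log-likelihood of a pedigree-block multivariate normal model
//   y_b ~ N(X_b beta, sum_k s[k] * G_bk)
// with beta profiled out by GLS.  blocks is a list of lists with elements
// y (vector), X (matrix), G (list of structure matrices, same order as s).
// Returns the profile log-likelihood, GLS beta and the GLS information X'S^-1X.

// [[Rcpp::export]]
List vc_profile_ll_cpp(List blocks, NumericVector s) {
  int K = s.size();
  int B = blocks.size();
  int pdim = -1;
  arma::mat XtSiX;
  arma::vec XtSiy;
  double yty = 0.0, logdet = 0.0;
  int ntot = 0;
  for (int b = 0; b < B; b++) {
    List blk = blocks[b];
    arma::vec y = as<arma::vec>(blk["y"]);
    arma::mat X = as<arma::mat>(blk["X"]);
    List G = blk["G"];
    int n = y.n_elem;
    if (pdim < 0) {
      pdim = X.n_cols;
      XtSiX.zeros(pdim, pdim);
      XtSiy.zeros(pdim);
    }
    arma::mat S(n, n, arma::fill::zeros);
    for (int k = 0; k < K; k++) {
      if (s[k] == 0.0) continue;
      S += s[k] * as<arma::mat>(G[k]);
    }
    arma::mat L;
    bool ok = arma::chol(L, S, "lower");
    if (!ok)
      return List::create(_["ok"] = false, _["loglik"] = R_NegInf);
    arma::mat Xy = arma::join_rows(X, y);
    arma::mat Z = arma::solve(arma::trimatl(L), Xy);
    arma::mat Zx = Z.cols(0, pdim - 1);
    arma::vec zy = Z.col(pdim);
    XtSiX += Zx.t() * Zx;
    XtSiy += Zx.t() * zy;
    yty += arma::dot(zy, zy);
    logdet += 2.0 * arma::sum(arma::log(L.diag()));
    ntot += n;
  }
  arma::vec beta;
  bool solved = arma::solve(beta, XtSiX, XtSiy, arma::solve_opts::no_approx);
  if (!solved) beta = arma::pinv(XtSiX) * XtSiy;
  double quad = yty - arma::dot(beta, XtSiy);
  double ll = -0.5 * (ntot * std::log(2.0 * M_PI) + logdet + quad);
  return List::create(_["ok"] = true, _["loglik"] = ll,
                      _["beta"] = beta, _["XtSiX"] = XtSiX);
}
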