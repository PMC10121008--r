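#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Weighted graphical lasso by block coordinate descent (Friedman-style):
// maximize log det(Theta) - tr(S Theta) - sum_ij P_ij |Theta_ij|,
// with a per-entry penalty matrix P (diagonal entries of P are ignored).
// Each column update solves a lasso subproblem by coordinate descent on the
// current covariance estimate W. Supports warm starts through W0/B0.
// [[Rcpp::export]]
Rcpp::List glasso_weighted_cpp(const arma::mat& S, const arma::mat& P,
                               double tol, int max_sweeps,
                               double inner_tol, int max_inner,
                               const arma::mat& W0, const arma::mat& B0,
                               bool warm) {
  const int p = S.n_rows;
  mat W = warm ? W0 : mat(S);
  mat B = warm ? B0 : zeros(p, p);
  if (!warm) W.diag() = S.diag();
  bool converged = false;
  int sweep;
  for (sweep = 0; sweep < max_sweeps; ++sweep) {
    double max_change = 0.0;
    for (int j = 0; j < p; ++j) {
      uvec idx = regspace<uvec>(0, p - 1);
      idx.shed_row(j);
      mat W11 = W.submat(idx, idx);
      vec s12 = S.col(j); s12.shed_row(j);
      vec pj = P.col(j); pj.shed_row(j);
      vec beta = B.col(j); beta.shed_row(j);
      vec v = W11 * beta;
      for (int it = 0; it < max_inner; ++it) {
        double ch = 0.0;
        for (int k = 0; k < p - 1; ++k) {
          double old = beta(k);
          double a = W11(k, k);
          if (a <= 0) Rcpp::stop("non-positive-definite intermediate");
          double r = s12(k) - (v(k) - a * old);
          double bnew = 0.0;
          if (r > pj(k)) bnew = (r - pj(k)) / a;
          else if (r < -pj(k)) bnew = (r + pj(k)) / a;
          if (bnew != old) {
            v += (bnew - old) * W11.col(k);
            beta(k) = bnew;
            double d = std::fabs(bnew - old);
            if (d > ch) ch = d;
          }
        }
        if (ch < inner_tol) break;
      }
      vec w12 = W11 * beta;
      int r = 0;
      for (int k = 0; k < p; ++k) {
        if (k == j) continue;
        double d = std::fabs(W(k, j) - w12(r));
        if (d > max_change) max_change = d;
        W(k, j) = w12(r);
        W(j, k) = w12(r);
        B(k, j) = beta(r);
        ++r;
      }
    }
    if (max_change < tol) { converged = true; break; }
  }
  // back out the precision matrix from W and the regression coefficients
  mat Theta = zeros(p, p);
  for (int j = 0; j < p; ++j) {
    vec beta = B.col(j); beta.shed_row(j);
    vec w12 = W.col(j); w12.shed_row(j);
    double denom = W(j, j) - dot(w12, beta);
    if (denom <= 0) Rcpp::stop("non-positive-definite intermediate");
    double t22 = 1.0 / denom;
    Theta(j, j) = t22;
    int r = 0;
    for (int k = 0; k < p; ++k) {
      if (k == j) continue;
      Theta(k, j) = -beta(r) * t22;
      ++r;
    }
  }
  Theta = 0.5 * (Theta + Theta.t());
  return Rcpp::List::create(Rcpp::Named("theta") = Theta,
                            Rcpp::Named("w") = W,
                            Rcpp::Named("b") = B,
                            Rcpp::Named("sweeps") = sweep + 1,
                            Rcpp::Named("converged") = converged);
}
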