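#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;
using namespace Rcpp;

// Fused batch-normalization kernels: these sit on the training hot path, so
// the multi-pass column broadcasting is done in compiled code.

// [[Rcpp::export]]
List bn_forward_cpp(const arma::mat& x, const arma::rowvec& gamma,
                    const arma::rowvec& beta, bool training,
                    arma::rowvec run_mean, arma::rowvec run_var,
                    double momentum, double eps) {
  rowvec mu, v;
  if (training) mu = mean(x, 0); else mu = run_mean;
  mat xc = x;
  xc.each_row() -= mu;
  if (training) {
    v = mean(square(xc), 0);
    run_mean = momentum * run_mean + (1 - momentum) * mu;
    run_var = momentum * run_var + (1 - momentum) * v;
  } else {
    v = run_var;
  }
  rowvec ivar = 1.0 / sqrt(v + eps);
  mat y = xc;
  y.each_row() %= (gamma % ivar);
  y.each_row() += beta;
  return List::create(_["y"] = y, _["xc"] = xc, _["ivar"] = ivar,
                      _["run_mean"] = run_mean, _["run_var"] = run_var);
}

// [[Rcpp::export]]
List bn_backward_cpp(const arma::mat& dy, const arma::mat& xc,
                     const arma::rowvec& ivar, const arma::rowvec& gamma) {
  double n = dy.n_rows;
  mat xhat = xc;
  xhat.each_row() %= ivar;
  rowvec dgamma = sum(dy % xhat, 0);
  rowvec dbeta = sum(dy, 0);
  mat dxhat = dy;
  dxhat.each_row() %= gamma;
  rowvec t1 = sum(dxhat, 0);
  rowvec t2 = sum(dxhat % xhat, 0);
  xhat.each_row() %= t2;             // xhat now holds xhat * t2
  mat dx = n * dxhat;
  dx.each_row() -= t1;
  dx -= xhat;
  dx.each_row() %= (ivar / n);
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// [[Rcpp::export]]
arma::mat relu_cpp(const arma::mat& x) {
  return clamp(x, 0.0, datum::inf);
}

// strided weighted pooling over contiguous sibling blocks of an
// n x m x F activation cube
// [[Rcpp::export]]
arma::cube pool_cpp(const arma::cube& h, const arma::vec& w, int ps) {
  int mc = h.n_cols / ps;
  cube out(h.n_rows, mc, h.n_slices, fill::zeros);
  for (uword f = 0; f < h.n_slices; ++f)
    for (int j = 0; j < mc; ++j)
      for (int k = 0; k < ps; ++k)
        out.slice(f).col(j) += w[j * ps + k] * h.slice(f).col(j * ps + k);
  return out;
}

// [[Rcpp::export]]
arma::cube unpool_cpp(const arma::cube& dp, const arma::vec& w, int ps, int m) {
  cube dh(dp.n_rows, m, dp.n_slices, fill::zeros);
  for (uword f = 0; f < dp.n_slices; ++f)
    for (uword j = 0; j < dp.n_cols; ++j)
      for (int k = 0; k < ps; ++k)
        dh.slice(f).col(j * ps + k) = w[j * ps + k] * dp.slice(f).col(j);
  return dh;
}

// [[Rcpp::export]]
arma::mat relu_backward_cpp(const arma::mat& dy, const arma::mat& y) {
  return dy % (y > 0);
}
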