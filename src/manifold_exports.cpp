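#include "manifold_core.h"
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export]]
arma::mat rot_exp_cpp(const arma::vec &w) { return so3_exp(w); }

// [[Rcpp::export]]
arma::vec rot_log_cpp(const arma::mat &R) { return so3_log(R); }

// [[Rcpp::export]]
arma::mat sphere_basis_cpp(const arma::vec &r) { return sphere_basis_c(r); }

// [[Rcpp::export]]
arma::vec sphere_retract_cpp(const arma::vec &r, const arma::vec &d) {
  return sphere_retract_c(r, vec2(d));
}

// [[Rcpp::export]]
arma::mat orthonormalize_cpp(const arma::mat &R) { return orthonormalize3(R); }
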