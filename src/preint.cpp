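// On-manifold IMU preintegration (Forster-style) with first-order covariance
// propagation and bias Jacobians. State ordering within the 9-dim delta:
// (rotation, velocity, position).
#include "manifold_core.h"
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;
using namespace Rcpp;

// gyro, accel: 3 x n (bias-uncorrected measurements); dt sample period;
// bg, ba: linearization biases; sg, sa: continuous white-noise densities.
// [[Rcpp::export]]
List preintegrate_cpp(const arma::mat &gyro, const arma::mat &accel, double dt,
                      const arma::vec &bg, const arma::vec &ba, double sg,
                      double sa) {
  const uword n = gyro.n_cols;
  if (n == 0) stop("preintegrate: empty measurement window");

  mat33 dR(fill::eye);
  vec3 dv(fill::zeros), dp(fill::zeros);
  mat cov(9, 9, fill::zeros);
  // bias Jacobians: d(delta)/d(bias); rows (phi, v, p), cols (bg, ba)
  mat33 JRbg(fill::zeros), Jvbg(fill::zeros), Jvba(fill::zeros),
      Jpbg(fill::zeros), Jpba(fill::zeros);

  const double sg2d = sg * sg / dt;  // discrete-time noise variances
  const double sa2d = sa * sa / dt;

  for (uword k = 0; k < n; ++k) {
    vec3 w = gyro.col(k) - bg;
    vec3 a = accel.col(k) - ba;
    mat33 E = so3_exp(w * dt);
    mat33 Jr = so3_jr(vec3(w * dt));
    mat33 aS = skew3(a);

    // covariance propagation: x_{k+1} = A x_k + B eta
    mat A(9, 9, fill::eye);
    A.submat(0, 0, 2, 2) = E.t();
    A.submat(3, 0, 5, 2) = -dR * aS * dt;
    A.submat(6, 0, 8, 2) = -0.5 * dR * aS * dt * dt;
    A.submat(6, 3, 8, 5) = mat33(fill::eye) * dt;
    mat B(9, 6, fill::zeros);
    B.submat(0, 0, 2, 2) = Jr * dt;
    B.submat(3, 3, 5, 5) = dR * dt;
    B.submat(6, 3, 8, 5) = 0.5 * dR * dt * dt;
    mat Q(6, 6, fill::zeros);
    Q.submat(0, 0, 2, 2) = sg2d * mat33(fill::eye);
    Q.submat(3, 3, 5, 5) = sa2d * mat33(fill::eye);
    cov = A * cov * A.t() + B * Q * B.t();

    // bias Jacobians (same linearization)
    Jpba += Jvba * dt - 0.5 * dR * dt * dt;
    Jpbg += Jvbg * dt - 0.5 * dR * aS * JRbg * dt * dt;
    Jvba += -dR * dt;
    Jvbg += -dR * aS * JRbg * dt;
    JRbg = E.t() * JRbg - Jr * dt;

    // mean propagation
    dp += dv * dt + 0.5 * dR * a * dt * dt;
    dv += dR * a * dt;
    dR = dR * E;
  }

  cov = 0.5 * (cov + cov.t());
  // whitener: r_w = Linv * r with cov = L L^T
  mat L;
  bool ok = chol(L, cov + 1e-18 * mat(9, 9, fill::eye), "lower");
  if (!ok) {
    cov.diag() += 1e-12;
    if (!chol(L, cov, "lower")) stop("preintegrate: covariance not PD");
  }
  mat Linv = solve(trimatl(L), mat(9, 9, fill::eye));

  mat Jb(9, 6, fill::zeros);
  Jb.submat(0, 0, 2, 2) = JRbg;
  Jb.submat(3, 0, 5, 2) = Jvbg;
  Jb.submat(3, 3, 5, 5) = Jvba;
  Jb.submat(6, 0, 8, 2) = Jpbg;
  Jb.submat(6, 3, 8, 5) = Jpba;

  return List::create(
      Named("dR") = mat(dR), Named("dv") = vec(dv), Named("dp") = vec(dp),
      Named("cov") = cov, Named("Linv") = Linv, Named("Jb") = Jb,
      Named("dT") = n * dt, Named("n") = (int)n,
      Named("lin_bias") = join_cols(bg, ba));
}
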