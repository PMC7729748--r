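// Whitened residual / sparse-Jacobian evaluation for the full lower-body
// factor graph. Variable layout (tangent coordinates, 0-based here):
//   state (keyframe k, imu s): base = ((k-1)*7 + (s-1)) * 18
//     +0 rotation (3), +3 position (3), +6 velocity (3),
//     +9 angular velocity (3), +12 bias (gyro 3, accel 3)
//   statics at S0 = 126*M:
//     knee axes (2 tangent dims each, 4 axes), then 12 offset vectors (3 each)
// Total tangent dimension 126*M + 44.
#include "manifold_core.h"
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;
using namespace Rcpp;

namespace {

struct TripletBuf {
  std::vector<int> ri, ci;
  std::vector<double> x;
  void reserve(size_t n) { ri.reserve(n); ci.reserve(n); x.reserve(n); }
  inline void push(int r, int c, double v) {
    if (v != 0.0) { ri.push_back(r + 1); ci.push_back(c + 1); x.push_back(v); }
  }
  // dense block: rows r0.., global columns in cols[]
  void push_block(int r0, const std::vector<int> &cols, const mat &B) {
    for (uword j = 0; j < B.n_cols; ++j)
      for (uword i = 0; i < B.n_rows; ++i) push(r0 + i, cols[j], B(i, j));
  }
};

inline int state_base(int k, int s, int /*M*/) { return ((k - 1) * 7 + (s - 1)) * 18; }

double yaw_of(const mat33 &R) { return std::atan2(R(1, 0), R(0, 0)); }

double window_penalty(double x, double lmin, double lmax, double a, double *grad) {
  if (x > lmax) {
    double t = std::tanh(a * (x - lmax));
    if (grad) *grad = t * t + 2.0 * a * (x - lmax) * t * (1.0 - t * t);
    return (x - lmax) * t * t;
  }
  if (x < lmin) {
    double t = std::tanh(a * (lmin - x));
    if (grad) *grad = -(t * t + 2.0 * a * (lmin - x) * t * (1.0 - t * t));
    return (lmin - x) * t * t;
  }
  if (grad) *grad = 0.0;
  return 0.0;
}

}  // namespace

// [[Rcpp::export]]
List linearize_graph_cpp(
    int M, const arma::cube &Rs, const arma::mat &ps, const arma::mat &vs,
    const arma::mat &ws, const arma::mat &bs, const arma::mat &axes,
    const arma::mat &offs, const arma::cube &pre_dR, const arma::mat &pre_dv,
    const arma::mat &pre_dp, const arma::cube &pre_Jb,
    const arma::cube &pre_Linv, const arma::mat &pre_bbar,
    const arma::vec &pre_dT, const arma::mat &kf_gyro, const arma::vec &g,
    const arma::mat &Linv_g, const arma::mat &Linv_K, const arma::mat &Linv_j,
    const arma::vec &bw_sigma, const arma::imat &jc_pairs,
    const arma::imat &hinge_rows, const arma::mat &axseg_rows,
    const arma::mat &len_rows, const arma::mat &win_rows,
    const arma::mat &disc_rows, bool gauge, const arma::vec &gauge_sigma,
    bool want_jac) {
  const int S0 = 126 * M;
  const int ncol = S0 + 44;
  const int n_pre = 7 * (M - 1);
  const int nrow = 9 * n_pre + 6 * n_pre + 3 * 7 * M + 3 * 4 * M + 3 * 6 * M +
                   4 + 5 + 5 + 2 + (gauge ? (3 + 3 + 1 + 42 + 3 * M) : 0);

  vec r(nrow, fill::zeros);
  TripletBuf T;
  if (want_jac) T.reserve((size_t)nrow * 22);
  int row = 0;
  const mat33 I3(fill::eye);

  double e_pre = 0, e_bias = 0, e_ang = 0, e_hinge = 0, e_jc = 0, e_stat = 0,
         e_gauge = 0;

  // ---- preintegration factors ----
  for (int k = 1; k <= M - 1; ++k) {
    for (int s = 1; s <= 7; ++s) {
      int idx = (k - 1) * 7 + (s - 1);
      int bi = state_base(k, s, M), bj = state_base(k + 1, s, M);
      mat33 Ri = Rs.slice(idx), Rj = Rs.slice(idx + 7);
      vec3 pi_ = ps.col(idx), pj = ps.col(idx + 7);
      vec3 vi = vs.col(idx), vj = vs.col(idx + 7);
      vec db = bs.col(idx) - pre_bbar.col(idx);
      vec3 dbg = db.subvec(0, 2), dba = db.subvec(3, 5);
      double dT = pre_dT(idx);

      mat Jb = pre_Jb.slice(idx);
      mat33 JRbg = Jb.submat(0, 0, 2, 2);
      mat33 Jvbg = Jb.submat(3, 0, 5, 2), Jvba = Jb.submat(3, 3, 5, 5);
      mat33 Jpbg = Jb.submat(6, 0, 8, 2), Jpba = Jb.submat(6, 3, 8, 5);

      vec3 corr = JRbg * dbg;
      mat33 dRc = pre_dR.slice(idx) * so3_exp(corr);
      vec3 rR = so3_log(mat33(dRc.t() * Ri.t() * Rj));
      vec3 uv = Ri.t() * (vj - vi - g * dT);
      vec3 rV = uv - (pre_dv.col(idx) + Jvbg * dbg + Jvba * dba);
      vec3 up = Ri.t() * (pj - pi_ - vi * dT - 0.5 * g * dT * dT);
      vec3 rP = up - (pre_dp.col(idx) + Jpbg * dbg + Jpba * dba);

      vec r9 = join_cols(rR, rV, rP);
      mat W = pre_Linv.slice(idx);
      vec rw = W * r9;
      r.subvec(row, row + 8) = rw;
      e_pre += dot(rw, rw);

      if (want_jac) {
        mat J(9, 24, fill::zeros);
        mat33 Jri = so3_jr_inv(rR);
        J.submat(0, 0, 2, 2) = -Jri * Rj.t() * Ri;              // phi_i
        J.submat(0, 15, 2, 17) = Jri;                           // phi_j
        J.submat(0, 9, 2, 11) = -Jri * so3_exp(vec3(-rR)) * so3_jr(corr) * JRbg; // bg_i
        J.submat(3, 0, 5, 2) = skew3(uv);                       // phi_i
        J.submat(3, 6, 5, 8) = -Ri.t();                         // v_i
        J.submat(3, 21, 5, 23) = Ri.t();                        // v_j
        J.submat(3, 9, 5, 11) = -Jvbg;
        J.submat(3, 12, 5, 14) = -Jvba;
        J.submat(6, 0, 8, 2) = skew3(up);                       // phi_i
        J.submat(6, 3, 8, 5) = -Ri.t();                         // p_i
        J.submat(6, 18, 8, 20) = Ri.t();                        // p_j
        J.submat(6, 6, 8, 8) = -Ri.t() * dT;                    // v_i
        J.submat(6, 9, 8, 11) = -Jpbg;
        J.submat(6, 12, 8, 14) = -Jpba;
        mat Jw = W * J;
        std::vector<int> cols(24);
        for (int c = 0; c < 3; ++c) {
          cols[0 + c] = bi + 0 + c;   // phi_i
          cols[3 + c] = bi + 3 + c;   // p_i
          cols[6 + c] = bi + 6 + c;   // v_i
          cols[9 + c] = bi + 12 + c;  // bg_i
          cols[12 + c] = bi + 15 + c; // ba_i
          cols[15 + c] = bj + 0 + c;  // phi_j
          cols[18 + c] = bj + 3 + c;  // p_j
          cols[21 + c] = bj + 6 + c;  // v_j
        }
        T.push_block(row, cols, Jw);
      }
      row += 9;
    }
  }

  // ---- bias random-walk factors ----
  for (int k = 1; k <= M - 1; ++k) {
    for (int s = 1; s <= 7; ++s) {
      int idx = (k - 1) * 7 + (s - 1);
      int bi = state_base(k, s, M) + 12, bj = state_base(k + 1, s, M) + 12;
      double sdT = std::sqrt(pre_dT(idx));
      for (int c = 0; c < 6; ++c) {
        double sig = bw_sigma(c) * sdT;
        double e = (bs(c, idx + 7) - bs(c, idx)) / sig;
        r(row) = e;
        e_bias += e * e;
        if (want_jac) {
          T.push(row, bi + c, -1.0 / sig);
          T.push(row, bj + c, 1.0 / sig);
        }
        ++row;
      }
    }
  }

  // ---- angular-velocity factors ----
  for (int k = 1; k <= M; ++k) {
    for (int s = 1; s <= 7; ++s) {
      int idx = (k - 1) * 7 + (s - 1);
      int b0 = state_base(k, s, M);
      vec3 e = ws.col(idx) + bs.col(idx).subvec(0, 2) - kf_gyro.col(idx);
      vec3 ew = Linv_g * e;
      r.subvec(row, row + 2) = ew;
      e_ang += dot(ew, ew);
      if (want_jac) {
        std::vector<int> cols(6);
        for (int c = 0; c < 3; ++c) { cols[c] = b0 + 9 + c; cols[3 + c] = b0 + 12 + c; }
        mat J = join_rows(Linv_g, Linv_g);
        T.push_block(row, cols, J);
      }
      row += 3;
    }
  }

  // ---- knee hinge factors (Eqs. 8/9 style, both knees) ----
  for (int k = 1; k <= M; ++k) {
    for (uword h = 0; h < hinge_rows.n_rows; ++h) {
      int a = hinge_rows(h, 0), A = hinge_rows(h, 1), B = hinge_rows(h, 2);
      int ia = (k - 1) * 7 + (A - 1), ib = (k - 1) * 7 + (B - 1);
      int bA = state_base(k, A, M), bB = state_base(k, B, M);
      int ca = S0 + 2 * (a - 1);
      vec3 rax = axes.col(a - 1);
      mat33 RAB = Rs.slice(ia).t() * Rs.slice(ib);
      vec3 wB = ws.col(ib), wA = ws.col(ia);
      vec3 u = RAB * wB;
      vec3 m = u - wA;
      mat33 P = I3 - rax * rax.t();
      vec3 e = P * m;
      vec3 ew = Linv_K * e;
      r.subvec(row, row + 2) = ew;
      e_hinge += dot(ew, ew);
      if (want_jac) {
        mat J(3, 14, fill::zeros);
        J.cols(0, 2) = P * skew3(u);            // phi_A
        J.cols(3, 5) = -P * RAB * skew3(wB);    // phi_B
        J.cols(6, 8) = -P;                      // w_A
        J.cols(9, 11) = P * RAB;                // w_B
        J.cols(12, 13) = -(rax * m.t() + dot(m, rax) * I3) * sphere_basis_c(rax);
        mat Jw = Linv_K * J;
        std::vector<int> cols(14);
        for (int c = 0; c < 3; ++c) {
          cols[0 + c] = bA + 0 + c;
          cols[3 + c] = bB + 0 + c;
          cols[6 + c] = bA + 9 + c;
          cols[9 + c] = bB + 9 + c;
        }
        cols[12] = ca; cols[13] = ca + 1;
        T.push_block(row, cols, Jw);
      }
      row += 3;
    }
  }

  // ---- joint-center factors ----
  for (int k = 1; k <= M; ++k) {
    for (uword j = 0; j < jc_pairs.n_rows; ++j) {
      int A = jc_pairs(j, 0), oA = jc_pairs(j, 1), B = jc_pairs(j, 2),
          oB = jc_pairs(j, 3);
      int ia = (k - 1) * 7 + (A - 1), ib = (k - 1) * 7 + (B - 1);
      int bA = state_base(k, A, M), bB = state_base(k, B, M);
      mat33 RA = Rs.slice(ia), RB = Rs.slice(ib);
      vec3 sA = offs.col(oA - 1), sB = offs.col(oB - 1);
      vec3 e = RA * sA + ps.col(ia) - RB * sB - ps.col(ib);
      vec3 ew = Linv_j * e;
      r.subvec(row, row + 2) = ew;
      e_jc += dot(ew, ew);
      if (want_jac) {
        mat J(3, 18, fill::zeros);
        J.cols(0, 2) = -RA * skew3(sA);  // phi_A
        J.cols(3, 5) = I3;               // p_A
        J.cols(6, 8) = RA;               // s_A
        J.cols(9, 11) = RB * skew3(sB);  // phi_B
        J.cols(12, 14) = -I3;            // p_B
        J.cols(15, 17) = -RB;            // s_B
        mat Jw = Linv_j * J;
        std::vector<int> cols(18);
        for (int c = 0; c < 3; ++c) {
          cols[0 + c] = bA + 0 + c;
          cols[3 + c] = bA + 3 + c;
          cols[6 + c] = S0 + 8 + 3 * (oA - 1) + c;
          cols[9 + c] = bB + 0 + c;
          cols[12 + c] = bB + 3 + c;
          cols[15 + c] = S0 + 8 + 3 * (oB - 1) + c;
        }
        T.push_block(row, cols, Jw);
      }
      row += 3;
    }
  }

  // ---- axis-segment angle priors (once; static variables only) ----
  for (uword q = 0; q < axseg_rows.n_rows; ++q) {
    int a = (int)axseg_rows(q, 0), op = (int)axseg_rows(q, 1),
        od = (int)axseg_rows(q, 2);
    double mu = axseg_rows(q, 3), sig = axseg_rows(q, 4);
    vec3 w = offs.col(op - 1) - offs.col(od - 1);
    double nw = norm(w);
    vec3 u = w / nw;
    vec3 rax = axes.col(a - 1);
    double c = dot(rax, u);
    c = std::max(-1.0, std::min(1.0, c));
    double e = (mu - std::acos(c)) / sig;
    r(row) = e;
    e_stat += e * e;
    if (want_jac) {
      double dedc = 1.0 / (std::sqrt(std::max(1.0 - c * c, 1e-12)) * sig);
      rowvec dcdr = u.t() * sphere_basis_c(rax);  // 1x2
      rowvec dcdw = (rax - c * u).t() / nw;
      int ca = S0 + 2 * (a - 1);
      T.push(row, ca, dedc * dcdr(0));
      T.push(row, ca + 1, dedc * dcdr(1));
      for (int cc = 0; cc < 3; ++cc) {
        T.push(row, S0 + 8 + 3 * (op - 1) + cc, dedc * dcdw(cc));
        T.push(row, S0 + 8 + 3 * (od - 1) + cc, -dedc * dcdw(cc));
      }
    }
    ++row;
  }

  // ---- anthropometric length priors ----
  for (uword q = 0; q < len_rows.n_rows; ++q) {
    int o1 = (int)len_rows(q, 0), o2 = (int)len_rows(q, 1);
    double mu = len_rows(q, 2), sig = len_rows(q, 3);
    vec3 w = offs.col(o1 - 1) - offs.col(o2 - 1);
    double nw = norm(w);
    double e = (nw - mu) / sig;
    r(row) = e;
    e_stat += e * e;
    if (want_jac) {
      vec3 u = w / nw;
      for (int cc = 0; cc < 3; ++cc) {
        T.push(row, S0 + 8 + 3 * (o1 - 1) + cc, u(cc) / sig);
        T.push(row, S0 + 8 + 3 * (o2 - 1) + cc, -u(cc) / sig);
      }
    }
    ++row;
  }

  // ---- length window penalties (unit noise; strength via a) ----
  for (uword q = 0; q < win_rows.n_rows; ++q) {
    int o1 = (int)win_rows(q, 0), o2 = (int)win_rows(q, 1);
    double lmin = win_rows(q, 2), lmax = win_rows(q, 3), a = win_rows(q, 4);
    vec3 w = offs.col(o1 - 1) - offs.col(o2 - 1);
    double nw = norm(w);
    double grad;
    double e = window_penalty(nw, lmin, lmax, a, &grad);
    r(row) = e;
    e_stat += e * e;
    if (want_jac && grad != 0.0) {
      vec3 u = w / nw;
      for (int cc = 0; cc < 3; ++cc) {
        T.push(row, S0 + 8 + 3 * (o1 - 1) + cc, grad * u(cc));
        T.push(row, S0 + 8 + 3 * (o2 - 1) + cc, -grad * u(cc));
      }
    }
    ++row;
  }

  // ---- cross-leg length discrepancy ----
  for (uword q = 0; q < disc_rows.n_rows; ++q) {
    int o1 = (int)disc_rows(q, 0), o2 = (int)disc_rows(q, 1),
        o3 = (int)disc_rows(q, 2), o4 = (int)disc_rows(q, 3);
    double sig = disc_rows(q, 4);
    vec3 wr = offs.col(o1 - 1) - offs.col(o2 - 1);
    vec3 wl = offs.col(o3 - 1) - offs.col(o4 - 1);
    double e = (norm(wr) - norm(wl)) / sig;
    r(row) = e;
    e_stat += e * e;
    if (want_jac) {
      vec3 ur = wr / norm(wr), ul = wl / norm(wl);
      for (int cc = 0; cc < 3; ++cc) {
        T.push(row, S0 + 8 + 3 * (o1 - 1) + cc, ur(cc) / sig);
        T.push(row, S0 + 8 + 3 * (o2 - 1) + cc, -ur(cc) / sig);
        T.push(row, S0 + 8 + 3 * (o3 - 1) + cc, -ul(cc) / sig);
        T.push(row, S0 + 8 + 3 * (o4 - 1) + cc, ul(cc) / sig);
      }
    }
    ++row;
  }

  // ---- gauge anchors + weak initial-bias priors ----
  if (gauge) {
    int b0 = state_base(1, 1, M);
    double sp = gauge_sigma(0), sv = gauge_sigma(1), sy = gauge_sigma(2);
    for (int c = 0; c < 3; ++c) {
      double e = ps(c, 0) / sp;
      r(row) = e; e_gauge += e * e;
      if (want_jac) T.push(row, b0 + 3 + c, 1.0 / sp);
      ++row;
    }
    for (int c = 0; c < 3; ++c) {
      double e = vs(c, 0) / sv;
      r(row) = e; e_gauge += e * e;
      if (want_jac) T.push(row, b0 + 6 + c, 1.0 / sv);
      ++row;
    }
    {
      mat33 R1 = Rs.slice(0);
      double e = yaw_of(R1) / sy;
      r(row) = e; e_gauge += e * e;
      if (want_jac) {
        const double h = 1e-6;
        for (int c = 0; c < 3; ++c) {
          vec3 d(fill::zeros);
          d(c) = h;
          double yp = yaw_of(mat33(R1 * so3_exp(d)));
          d(c) = -h;
          double ym = yaw_of(mat33(R1 * so3_exp(d)));
          T.push(row, b0 + c, (yp - ym) / (2 * h * sy));
        }
      }
      ++row;
    }
    for (int s = 1; s <= 7; ++s) {
      int bb = state_base(1, s, M) + 12;
      for (int c = 0; c < 6; ++c) {
        double sig = (c < 3) ? gauge_sigma(3) : gauge_sigma(4);
        double e = bs(c, s - 1) / sig;
        r(row) = e; e_gauge += e * e;
        if (want_jac) T.push(row, bb + c, 1.0 / sig);
        ++row;
      }
    }
    // weak bounded-speed prior on the lumbar velocity at every keyframe:
    // pins the tilt-with-drift flat mode that the first-keyframe anchors
    // alone leave unconstrained
    double svw = gauge_sigma(5);
    for (int k = 1; k <= M; ++k) {
      int b0 = state_base(k, 1, M);
      int idx = (k - 1) * 7;
      for (int c = 0; c < 3; ++c) {
        double e = vs(c, idx) / svw;
        r(row) = e; e_gauge += e * e;
        if (want_jac) T.push(row, b0 + 6 + c, 1.0 / svw);
        ++row;
      }
    }
  }

  if (row != nrow) stop("internal error: residual row count mismatch");

  double err = dot(r, r);
  List out = List::create(
      Named("err") = err, Named("r") = r, Named("nrow") = nrow,
      Named("ncol") = ncol,
      Named("group_err") = NumericVector::create(
          Named("preint") = e_pre, Named("bias") = e_bias,
          Named("angvel") = e_ang, Named("hinge") = e_hinge,
          Named("joint_center") = e_jc, Named("statics") = e_stat,
          Named("gauge") = e_gauge));
  if (want_jac) {
    out["i"] = IntegerVector(T.ri.begin(), T.ri.end());
    out["j"] = IntegerVector(T.ci.begin(), T.ci.end());
    out["x"] = NumericVector(T.x.begin(), T.x.end());
  }
  return out;
}

// Apply a tangent-space update to the full value assignment (same layout).
// [[Rcpp::export]]
List retract_values_cpp(const arma::cube &Rs, const arma::mat &ps,
                        const arma::mat &vs, const arma::mat &ws,
                        const arma::mat &bs, const arma::mat &axes,
                        const arma::mat &offs, const arma::vec &delta, int M) {
  cube R2 = Rs;
  mat p2 = ps, v2 = vs, w2 = ws, b2 = bs, ax2 = axes, of2 = offs;
  const int S0 = 126 * M;
  for (int k = 1; k <= M; ++k) {
    for (int s = 1; s <= 7; ++s) {
      int idx = (k - 1) * 7 + (s - 1);
      int b0 = idx * 18;
      vec3 dphi = delta.subvec(b0, b0 + 2);
      R2.slice(idx) = orthonormalize3(mat33(R2.slice(idx) * so3_exp(dphi)));
      p2.col(idx) += delta.subvec(b0 + 3, b0 + 5);
      v2.col(idx) += delta.subvec(b0 + 6, b0 + 8);
      w2.col(idx) += delta.subvec(b0 + 9, b0 + 11);
      b2.col(idx) += delta.subvec(b0 + 12, b0 + 17);
    }
  }
  for (int a = 0; a < 4; ++a) {
    vec2 d = delta.subvec(S0 + 2 * a, S0 + 2 * a + 1);
    ax2.col(a) = sphere_retract_c(vec3(ax2.col(a)), d);
  }
  for (int o = 0; o < 12; ++o)
    of2.col(o) += delta.subvec(S0 + 8 + 3 * o, S0 + 8 + 3 * o + 2);
  return List::create(Named("R") = R2, Named("p") = p2, Named("v") = v2,
                      Named("w") = w2, Named("b") = b2, Named("axes") = ax2,
                      Named("offs") = of2);
}
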