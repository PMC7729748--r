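// SO(3) / S^2 primitives shared by the preintegration and linearization code.
#include "manifold_core.h"

using namespace arma;

mat33 skew3(const vec3 &v) {
  mat33 S;
  S(0, 0) = 0.0;   S(0, 1) = -v(2); S(0, 2) = v(1);
  S(1, 0) = v(2);  S(1, 1) = 0.0;   S(1, 2) = -v(0);
  S(2, 0) = -v(1); S(2, 1) = v(0);  S(2, 2) = 0.0;
  return S;
}

mat33 so3_exp(const vec3 &w) {
  double th = norm(w);
  mat33 I(fill::eye);
  if (th < 1e-12) {
    mat33 S = skew3(w);
    return I + S + 0.5 * S * S;
  }
  mat33 S = skew3(w / th);
  return I + std::sin(th) * S + (1.0 - std::cos(th)) * S * S;
}

// Log map via unit-quaternion extraction (Shepperd's method picks the
// best-conditioned component), accurate for all angles including near pi.
vec3 so3_log(const mat33 &R) {
  double tr = trace(R);
  double qw, qx, qy, qz;
  if (tr > 0.0) {
    double s = std::sqrt(tr + 1.0) * 2.0;
    qw = 0.25 * s;
    qx = (R(2, 1) - R(1, 2)) / s;
    qy = (R(0, 2) - R(2, 0)) / s;
    qz = (R(1, 0) - R(0, 1)) / s;
  } else if (R(0, 0) >= R(1, 1) && R(0, 0) >= R(2, 2)) {
    double s = std::sqrt(1.0 + R(0, 0) - R(1, 1) - R(2, 2)) * 2.0;
    qw = (R(2, 1) - R(1, 2)) / s;
    qx = 0.25 * s;
    qy = (R(0, 1) + R(1, 0)) / s;
    qz = (R(0, 2) + R(2, 0)) / s;
  } else if (R(1, 1) >= R(2, 2)) {
    double s = std::sqrt(1.0 + R(1, 1) - R(0, 0) - R(2, 2)) * 2.0;
    qw = (R(0, 2) - R(2, 0)) / s;
    qx = (R(0, 1) + R(1, 0)) / s;
    qy = 0.25 * s;
    qz = (R(1, 2) + R(2, 1)) / s;
  } else {
    double s = std::sqrt(1.0 + R(2, 2) - R(0, 0) - R(1, 1)) * 2.0;
    qw = (R(1, 0) - R(0, 1)) / s;
    qx = (R(0, 2) + R(2, 0)) / s;
    qy = (R(1, 2) + R(2, 1)) / s;
    qz = 0.25 * s;
  }
  if (qw < 0.0) { qw = -qw; qx = -qx; qy = -qy; qz = -qz; }
  vec3 qv = {qx, qy, qz};
  double nv = norm(qv);
  if (nv < 1e-300) return vec3(fill::zeros);
  double th = 2.0 * std::atan2(nv, qw);  // in [0, pi] since qw >= 0
  vec3 a = qv / nv;
  if (qw == 0.0) {
    // exactly pi: canonical sign, first nonzero axis component positive
    for (uword i = 0; i < 3; ++i) {
      if (std::abs(a(i)) > 1e-12) { if (a(i) < 0) a = -a; break; }
    }
  }
  return th * a;
}

// Right Jacobian of SO(3): Exp(w + dw) ~ Exp(w) Exp(Jr(w) dw)
mat33 so3_jr(const vec3 &w) {
  double th = norm(w);
  mat33 I(fill::eye);
  mat33 S = skew3(w);
  if (th < 1e-7) return I - 0.5 * S + (1.0 / 6.0) * S * S;
  double th2 = th * th;
  return I - (1.0 - std::cos(th)) / th2 * S +
         (th - std::sin(th)) / (th2 * th) * S * S;
}

mat33 so3_jr_inv(const vec3 &w) {
  double th = norm(w);
  mat33 I(fill::eye);
  mat33 S = skew3(w);
  if (th < 1e-7) return I + 0.5 * S + (1.0 / 12.0) * S * S;
  double cot_half = 1.0 / std::tan(0.5 * th);
  return I + 0.5 * S + (1.0 / (th * th) - 0.5 * cot_half / th) * S * S;
}

// Deterministic orthonormal tangent basis at r on S^2 (3x2).
// Cross r with the canonical axis following its largest-magnitude component.
mat sphere_basis_c(const vec3 &r) {
  uword k = abs(r).index_max();
  vec3 e(fill::zeros);
  e((k + 1) % 3) = 1.0;
  vec3 b1 = cross(r, e);
  b1 /= norm(b1);
  vec3 b2 = cross(r, b1);
  mat B(3, 2);
  B.col(0) = b1;
  B.col(1) = b2;
  return B;
}

vec3 sphere_retract_c(const vec3 &r, const vec2 &d) {
  mat B = sphere_basis_c(r);
  vec3 v = B * d;
  double th = norm(v);
  if (th < 1e-300) return r;
  vec3 out = std::cos(th) * r + std::sin(th) * (v / th);
  return out / norm(out);
}

// Closest proper rotation (via SVD); used to keep stored rotations orthonormal.
mat33 orthonormalize3(const mat33 &R) {
  mat U, V;
  vec s;
  svd(U, s, V, R);
  mat33 Q = U * V.t();
  if (det(Q) < 0) {
    U.col(2) *= -1.0;
    Q = U * V.t();
  }
  return Q;
}
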