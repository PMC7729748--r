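#ifndef IMUMOCAP_MANIFOLD_CORE_H
#define IMUMOCAP_MANIFOLD_CORE_H

#include <RcppArmadillo.h>

arma::mat33 skew3(const arma::vec3 &v);
arma::mat33 so3_exp(const arma::vec3 &w);
arma::vec3 so3_log(const arma::mat33 &R);
arma::mat33 so3_jr(const arma::vec3 &w);
arma::mat33 so3_jr_inv(const arma::vec3 &w);
arma::mat sphere_basis_c(const arma::vec3 &r);  // 3x2
arma::vec3 sphere_retract_c(const arma::vec3 &r, const arma::vec2 &d);
arma::mat33 orthonormalize3(const arma::mat33 &R);

#endif
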