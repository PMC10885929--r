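// Batch pointwise kinematics: velocity gradient -> viscous stress spectrum
// and the two RBC orientation axes (stress-eigenvector and Lamb-vector
// models). One 3x3 symmetric eigendecomposition per grid point makes this
// the hot loop of the package, hence compiled.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

// Degeneracy codes shared with R/conductivity-field.R
// 0 ok, 1 zero-stress, 2 repeated-eigenvalue, 3 parallel-u-omega,
// 4 zero-velocity
constexpr int DEG_NONE = 0;
constexpr int DEG_ZERO_STRESS = 1;
constexpr int DEG_REPEATED = 2;
constexpr int DEG_PARALLEL = 3;
constexpr int DEG_ZERO_VELOCITY = 4;

// First component exceeding a small fraction of the norm becomes positive.
inline void normalize_sign(vec &v) {
  const double nrm = norm(v);
  if (nrm == 0.0) return;
  for (uword i = 0; i < v.n_elem; ++i) {
    if (std::abs(v(i)) > 1e-12 * nrm) {
      if (v(i) < 0) v = -v;
      return;
    }
  }
}

} // namespace

// grad: n x 9 matrix with columns du_i/dx_j in row-major order of the
//       gradient matrix, i.e. (dux_dx, dux_dy, dux_dz, duy_dx, ..., duz_dz).
// vel:  n x 3 velocities.
// Returns an n x 20 matrix, see `cn` below for the column schema.
// [[Rcpp::export]]
Rcpp::NumericMatrix stress_axes_batch(const arma::mat &grad,
                                      const arma::mat &vel,
                                      double eta_bl,
                                      double eps_tau,
                                      double eps_lamb,
                                      double eps_repeat,
                                      double eps_u) {
  const uword n = grad.n_rows;
  if (grad.n_cols != 9 || vel.n_rows != n || vel.n_cols != 3)
    Rcpp::stop("stress_axes_batch: grad must be n x 9 and vel n x 3.");

  Rcpp::NumericMatrix out(n, 20);
  Rcpp::CharacterVector cn = Rcpp::CharacterVector::create(
      "tau1", "tau2", "tau3", "tau_max", "gamma_dot_max", "trace_D",
      "ev_x", "ev_y", "ev_z", "deg_ev",
      "vv_x", "vv_y", "vv_z", "deg_vv",
      "omega_x", "omega_y", "omega_z", "e2_x", "e2_y", "e2_z");
  Rcpp::colnames(out) = cn;

  mat G(3, 3), D(3, 3), tau(3, 3), evec(3, 3);
  vec eval(3), u(3), w(3);

  for (uword p = 0; p < n; ++p) {
    if (p % 8192 == 0) Rcpp::checkUserInterrupt();
    // G(i, j) = du_i / dx_j
    for (uword i = 0; i < 3; ++i)
      for (uword j = 0; j < 3; ++j)
        G(i, j) = grad(p, 3 * i + j);
    if (!G.is_finite())
      Rcpp::stop("stress_axes_batch: non-finite velocity gradient at point %d.",
                 (int)(p + 1));

    D = 0.5 * (G + G.t());
    tau = 2.0 * eta_bl * D;
    if (!eig_sym(eval, evec, tau)) // ascending eigenvalues
      Rcpp::stop("stress_axes_batch: eigendecomposition failed at point %d.",
                 (int)(p + 1));

    const double tau3 = eval(0), tau2 = eval(1), tau1 = eval(2);
    const double tau_max = tau1 - tau3;
    const double nrm_tau = std::max(std::abs(tau1), std::abs(tau3));

    out(p, 0) = tau1;
    out(p, 1) = tau2;
    out(p, 2) = tau3;
    out(p, 3) = tau_max;
    out(p, 4) = tau_max / (2.0 * eta_bl);
    out(p, 5) = trace(D);

    u = vel.row(p).t();

    // eigenvector (EV) model
    int deg_ev = DEG_NONE;
    if (tau_max < eps_tau) {
      deg_ev = DEG_ZERO_STRESS;
      out(p, 6) = out(p, 7) = out(p, 8) = NA_REAL;
    } else {
      if (std::min(tau1 - tau2, tau2 - tau3) < eps_repeat * nrm_tau)
        deg_ev = DEG_REPEATED;
      vec e1 = evec.col(2), e3 = evec.col(0);
      vec cand_minus = (e1 - e3) / std::sqrt(2.0);
      vec cand_plus = (e1 + e3) / std::sqrt(2.0);
      vec e_alpha = (std::abs(dot(u, cand_plus)) > std::abs(dot(u, cand_minus)))
                        ? cand_minus
                        : cand_plus;
      normalize_sign(e_alpha);
      out(p, 6) = e_alpha(0);
      out(p, 7) = e_alpha(1);
      out(p, 8) = e_alpha(2);
    }
    out(p, 9) = deg_ev;

    // velocity-vorticity (VV) model
    w(0) = G(2, 1) - G(1, 2);
    w(1) = G(0, 2) - G(2, 0);
    w(2) = G(1, 0) - G(0, 1);
    out(p, 14) = w(0);
    out(p, 15) = w(1);
    out(p, 16) = w(2);

    const double nu = norm(u), nw = norm(w);
    int deg_vv = DEG_NONE;
    if (nu < eps_u) {
      deg_vv = DEG_ZERO_VELOCITY;
    } else {
      vec cp = cross(u, w);
      const double ncp = norm(cp);
      if (nw == 0.0 || ncp < eps_lamb * nu * nw) {
        deg_vv = DEG_PARALLEL;
      } else {
        cp /= ncp;
        normalize_sign(cp);
        out(p, 10) = cp(0);
        out(p, 11) = cp(1);
        out(p, 12) = cp(2);
      }
    }
    if (deg_vv != DEG_NONE)
      out(p, 10) = out(p, 11) = out(p, 12) = NA_REAL;
    out(p, 13) = deg_vv;

    // intermediate eigenvector, useful for diagnostics/tests
    vec e2 = evec.col(1);
    normalize_sign(e2);
    out(p, 17) = e2(0);
    out(p, 18) = e2(1);
    out(p, 19) = e2(2);
  }
  return out;
}
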