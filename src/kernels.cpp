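// Fast kernels for equal-interval k-pulse blocks: echo-train simulation,
// batched candidate trains for the fit screening stage, and Fisher/CRLB
// grid evaluation. The pure-R event-by-event simulator is the reference
// implementation; tests assert the two paths agree to near machine precision.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// Rotation by `flip` about the transverse axis at azimuth `phase` from x
// (both rad), right-handed: Rz(phase) * Rx(flip) * Rz(-phase).
static inline mat33 rot_rf(double flip, double phase) {
  const double cf = std::cos(flip), sf = std::sin(flip);
  const double cp = std::cos(phase), sp = std::sin(phase);
  mat33 R;
  R(0, 0) = cf + cp * cp * (1.0 - cf);
  R(0, 1) = cp * sp * (1.0 - cf);
  R(0, 2) = sp * sf;
  R(1, 0) = cp * sp * (1.0 - cf);
  R(1, 1) = cf + sp * sp * (1.0 - cf);
  R(1, 2) = -cp * sf;
  R(2, 0) = -sp * sf;
  R(2, 1) = cp * sf;
  R(2, 2) = cf;
  return R;
}

// Simulate readouts of `n_blocks` repeats of a k-pulse block with equal
// inter-pulse delays. e1/e2 are the per-interval longitudinal/transverse
// decay factors exp(-tau/T1), exp(-tau/T2); beta is the off-resonance
// phase per interval (rad); b1 scales all flip angles. One readout at the
// end of each interval: s = mx + i my.
static void sim_train_core(const vec &flip_rad, const vec &phase_rad,
                           int n_blocks, double e1, double e2, double pd,
                           double beta, double b1, const double m0[3],
                           std::complex<double> *out) {
  const unsigned k = flip_rad.n_elem;
  std::vector<mat33> R(k);
  for (unsigned j = 0; j < k; ++j)
    R[j] = rot_rf(b1 * flip_rad[j], phase_rad[j]);
  const double cb = std::cos(beta), sb = std::sin(beta);
  const double rec = pd * (1.0 - e1);
  double mx = m0[0], my = m0[1], mz = m0[2];
  unsigned idx = 0;
  for (int n = 0; n < n_blocks; ++n) {
    for (unsigned j = 0; j < k; ++j) {
      const mat33 &Rj = R[j];
      const double x = Rj(0, 0) * mx + Rj(0, 1) * my + Rj(0, 2) * mz;
      const double y = Rj(1, 0) * mx + Rj(1, 1) * my + Rj(1, 2) * mz;
      const double z = Rj(2, 0) * mx + Rj(2, 1) * my + Rj(2, 2) * mz;
      // free precession (Rz(beta)) and relaxation over one interval;
      // both act block-diagonally on the transverse plane so they commute
      mx = e2 * (cb * x - sb * y);
      my = e2 * (sb * x + cb * y);
      mz = e1 * z + rec;
      out[idx++] = std::complex<double>(mx, my);
    }
  }
}

// [[Rcpp::export]]
arma::cx_vec sim_train_cpp(const arma::vec &flip_deg, const arma::vec &phase_deg,
                           int n_blocks, double e1, double e2, double pd,
                           double beta, double b1, const arma::vec &m0) {
  const double d2r = datum::pi / 180.0;
  vec fr = flip_deg * d2r, pr = phase_deg * d2r;
  cx_vec out(n_blocks * flip_deg.n_elem);
  double m0a[3] = {m0[0], m0[1], m0[2]};
  sim_train_core(fr, pr, n_blocks, e1, e2, pd, beta, b1, m0a,
                 out.memptr());
  return out;
}

// Batched unit-amplitude model trains for candidate screening: one column
// per candidate row (E1, E2, beta, B1), equilibrium start (0,0,1), PD = 1.
// [[Rcpp::export]]
arma::cx_mat candidate_trains_cpp(const arma::mat &cand, const arma::vec &flip_deg,
                                  const arma::vec &phase_deg, int n_blocks) {
  const double d2r = datum::pi / 180.0;
  vec fr = flip_deg * d2r, pr = phase_deg * d2r;
  const unsigned n_echo = n_blocks * flip_deg.n_elem;
  cx_mat out(n_echo, cand.n_rows);
  double m0[3] = {0.0, 0.0, 1.0};
  for (unsigned i = 0; i < cand.n_rows; ++i)
    sim_train_core(fr, pr, n_blocks, cand(i, 0), cand(i, 1), 1.0,
                   cand(i, 2), cand(i, 3), m0, out.colptr(i));
  return out;
}

// Stacked-real Jacobian of the detected signal w.r.t.
// theta = [Re S0, Im S0, E1, E2, beta, B1]; S0 multiplies the unit train.
// Central differences, relative step `rel_step`, for the nonlinear four.
static mat signal_jacobian_core(const vec &flip_rad, const vec &phase_rad,
                                int n_blocks, const std::complex<double> S0,
                                double e1, double e2, double beta, double b1,
                                double rel_step) {
  const unsigned n_echo = n_blocks * flip_rad.n_elem;
  mat J(2 * n_echo, 6);
  const double m0[3] = {0.0, 0.0, 1.0};
  cx_vec u(n_echo), up(n_echo), um(n_echo);
  sim_train_core(flip_rad, phase_rad, n_blocks, e1, e2, 1.0, beta, b1, m0,
                 u.memptr());
  // signal is linear in S0: d/dReS0 = u, d/dImS0 = i*u
  J.col(0) = join_cols(real(u), imag(u));
  J.col(1) = join_cols(-imag(u), real(u));
  double th[4] = {e1, e2, beta, b1};
  for (int p = 0; p < 4; ++p) {
    const double x = th[p];
    const double h = rel_step * (std::abs(x) > 1e-8 ? std::abs(x) : 1.0);
    double tp[4] = {th[0], th[1], th[2], th[3]};
    tp[p] = x + h;
    sim_train_core(flip_rad, phase_rad, n_blocks, tp[0], tp[1], 1.0, tp[2],
                   tp[3], m0, up.memptr());
    tp[p] = x - h;
    sim_train_core(flip_rad, phase_rad, n_blocks, tp[0], tp[1], 1.0, tp[2],
                   tp[3], m0, um.memptr());
    cx_vec du = S0 * (up - um) / (2.0 * h);
    J.col(2 + p) = join_cols(real(du), imag(du));
  }
  return J;
}

// [[Rcpp::export]]
arma::mat signal_jacobian_cpp(const arma::vec &flip_deg, const arma::vec &phase_deg,
                              int n_blocks, double s0_re, double s0_im,
                              double e1, double e2, double beta, double b1,
                              double rel_step = 1e-6) {
  const double d2r = datum::pi / 180.0;
  vec fr = flip_deg * d2r, pr = phase_deg * d2r;
  return signal_jacobian_core(fr, pr, n_blocks,
                              std::complex<double>(s0_re, s0_im),
                              e1, e2, beta, b1, rel_step);
}

static inline void cv_from_fisher(const mat &J, double sigma, double tr_ip,
                                  double e1, double e2, double &cv_t1,
                                  double &cv_t2) {
  mat F = (J.t() * J) / (sigma * sigma);
  mat Finv;
  bool ok = inv_sympd(Finv, F);
  if (!ok) ok = pinv(Finv, F);
  if (!ok) {
    cv_t1 = cv_t2 = datum::inf;
    return;
  }
  // delta method: T = -tr/ln E  =>  CV_T = sd(E) / (E * |ln E|)
  cv_t1 = std::sqrt(std::max(Finv(2, 2), 0.0)) /
          (e1 * std::abs(std::log(e1)));
  cv_t2 = std::sqrt(std::max(Finv(3, 3), 0.0)) /
          (e2 * std::abs(std::log(e2)));
  (void)tr_ip;
}

// CV_T1/CV_T2 over a full (alpha, gamma, tissue, beta) factorial for one
// axis pattern. flip_is_gamma marks which pulses carry the gamma flip.
// Row order: alpha outermost, then gamma, tissue, beta innermost.
// [[Rcpp::export]]
arma::mat crlb_cv_grid_cpp(const arma::vec &axis_phase_deg,
                           const arma::uvec &flip_is_gamma,
                           const arma::vec &alpha_grid, const arma::vec &gamma_grid,
                           const arma::mat &tissues, const arma::vec &beta_grid,
                           double tr_ip, int n_blocks, double sigma) {
  const double d2r = datum::pi / 180.0;
  const unsigned k = axis_phase_deg.n_elem;
  vec pr = axis_phase_deg * d2r;
  const unsigned n_rows = alpha_grid.n_elem * gamma_grid.n_elem *
                          tissues.n_rows * beta_grid.n_elem;
  mat out(n_rows, 2);
  unsigned r = 0;
  vec fr(k);
  for (unsigned ia = 0; ia < alpha_grid.n_elem; ++ia) {
    for (unsigned ig = 0; ig < gamma_grid.n_elem; ++ig) {
      for (unsigned j = 0; j < k; ++j)
        fr[j] = (flip_is_gamma[j] ? gamma_grid[ig] : alpha_grid[ia]) * d2r;
      for (unsigned it = 0; it < tissues.n_rows; ++it) {
        const double e1 = std::exp(-tr_ip / tissues(it, 0));
        const double e2 = std::exp(-tr_ip / tissues(it, 1));
        for (unsigned ib = 0; ib < beta_grid.n_elem; ++ib) {
          mat J = signal_jacobian_core(fr, pr, n_blocks,
                                       std::complex<double>(1.0, 0.0),
                                       e1, e2, beta_grid[ib], 1.0, 1e-6);
          cv_from_fisher(J, sigma, tr_ip, e1, e2, out(r, 0), out(r, 1));
          ++r;
        }
      }
    }
    Rcpp::checkUserInterrupt();
  }
  return out;
}
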