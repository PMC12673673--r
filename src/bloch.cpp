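// Hard-pulse Bloch integrator for multi-channel transmit pulses.
//
// Each raster step applies an exact rotation about the instantaneous
// effective field in the rotating frame: transverse components from the
// superposition of the channel RF through the complex B1+ sensitivities,
// longitudinal component from off-resonance plus the gradient field.
// Relaxation is neglected (pulse durations of a few ms << T2).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// b1:   n_vox x n_ch complex sensitivities (unitless)
// rf:   n_t x n_ch complex RF samples (microtesla)
// grad: n_t x 3 gradient samples (mT/m)
// pos:  n_vox x 3 positions (m)
// off_hz: n_vox off-resonance incl. spectral offset (Hz)
// dt:   raster (s); gamma: rad/s/T
// returns n_vox x 3 magnetization, starting from (0,0,1)
// [[Rcpp::export]]
arma::mat bloch_run(const arma::cx_mat& b1, const arma::cx_mat& rf,
                    const arma::mat& grad, const arma::mat& pos,
                    const arma::vec& off_hz, double dt, double gamma) {
  const arma::uword n = b1.n_rows, n_t = rf.n_rows;
  if (rf.n_cols != b1.n_cols) stop("channel mismatch between b1 and rf");
  if (grad.n_rows != n_t) stop("gradient/RF length mismatch");
  if (pos.n_rows != n || off_hz.n_elem != n) stop("position/off-resonance size mismatch");

  // combined transverse field per voxel and time: n x n_t (tesla)
  arma::cx_mat bxy = b1 * rf.st();
  bxy *= 1e-6;

  const double two_pi = 2.0 * M_PI;
  arma::vec wz_off = two_pi * off_hz;              // rad/s
  arma::mat gp = pos * grad.t() * 1e-3;            // n x n_t, tesla

  arma::mat M(n, 3);
  M.col(0).zeros(); M.col(1).zeros(); M.col(2).ones();

  for (arma::uword t = 0; t < n_t; ++t) {
    for (arma::uword v = 0; v < n; ++v) {
      double wx = gamma * std::real(bxy(v, t));
      double wy = gamma * std::imag(bxy(v, t));
      double wz = wz_off(v) + gamma * gp(v, t);
      double w = std::sqrt(wx * wx + wy * wy + wz * wz);
      if (w <= 0.0) continue;
      double phi = -w * dt;                        // rotation angle
      double nx = wx / w, ny = wy / w, nz = wz / w;
      double c = std::cos(phi), s = std::sin(phi), omc = 1.0 - c;
      double mx = M(v, 0), my = M(v, 1), mz = M(v, 2);
      double ndm = nx * mx + ny * my + nz * mz;
      M(v, 0) = mx * c + (ny * mz - nz * my) * s + nx * ndm * omc;
      M(v, 1) = my * c + (nz * mx - nx * mz) * s + ny * ndm * omc;
      M(v, 2) = mz * c + (nx * my - ny * mx) * s + nz * ndm * omc;
    }
  }
  return M;
}
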