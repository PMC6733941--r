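#include <Rcpp.h>
using namespace Rcpp;

// Brownian-dynamics photon-count simulation for FCS.
//
// Particles take Gaussian steps of sd sqrt(2 D dt) per axis in a periodic
// box (half-widths Lxy, Lxy, Lz) and are detected through a 3D Gaussian
// focal volume exp(-2 (x^2+y^2)/w^2 - 2 z^2/wz^2). Per bin the expected
// count is amp * sum_i W(r_i) over bright particles and the observed count
// is a Poisson draw. Optional triplet blinking is a two-state telegraph
// process with bright->dark rate p_dark/tau_T and dark->bright rate
// (1-p_dark)/tau_T. Uses R's RNG, so seeding happens on the R side.
//
// [[Rcpp::export]]
IntegerVector fcs_sim_cpp(int n_bins, NumericMatrix init_pos,
                          double step_sd, double Lxy, double Lz,
                          double omega_xy, double omega_z,
                          double amp, double p_dark, double tau_T,
                          double dt) {
  const int n = init_pos.nrow();
  std::vector<double> x(n), y(n), z(n);
  std::vector<int> bright(n, 1);
  for (int i = 0; i < n; ++i) {
    x[i] = init_pos(i, 0);
    y[i] = init_pos(i, 1);
    z[i] = init_pos(i, 2);
  }
  const double q = 2.0 / (omega_xy * omega_xy);
  const double qz = 2.0 / (omega_z * omega_z);
  const bool blink = p_dark > 0.0;
  double p_bd = 0.0, p_db = 0.0;  // bright->dark, dark->bright per step
  if (blink) {
    p_bd = std::min(1.0, dt * p_dark / tau_T);
    p_db = std::min(1.0, dt * (1.0 - p_dark) / tau_T);
    for (int i = 0; i < n; ++i) bright[i] = (unif_rand() < p_dark) ? 0 : 1;
  }
  IntegerVector counts(n_bins);
  const double wx = 2.0 * Lxy, wzb = 2.0 * Lz;
  for (int t = 0; t < n_bins; ++t) {
    double lambda = 0.0;
    for (int i = 0; i < n; ++i) {
      if (bright[i]) {
        double arg = q * (x[i] * x[i] + y[i] * y[i]) + qz * z[i] * z[i];
        if (arg < 30.0) lambda += std::exp(-arg);
      }
    }
    counts[t] = (int) R::rpois(amp * lambda);
    for (int i = 0; i < n; ++i) {
      if (step_sd > 0.0) {
        x[i] += step_sd * norm_rand();
        y[i] += step_sd * norm_rand();
        z[i] += step_sd * norm_rand();
        // periodic wrap into [-L, L)
        x[i] -= wx * std::floor((x[i] + Lxy) / wx);
        y[i] -= wx * std::floor((y[i] + Lxy) / wx);
        z[i] -= wzb * std::floor((z[i] + Lz) / wzb);
      }
      if (blink) {
        if (bright[i]) {
          if (unif_rand() < p_bd) bright[i] = 0;
        } else {
          if (unif_rand() < p_db) bright[i] = 1;
        }
      }
    }
    if ((t & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
  }
  return counts;
}
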