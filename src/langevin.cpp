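#include <Rcpp.h>
using namespace Rcpp;

// Linear interpolation on a uniform grid; clamps to the grid range.
static inline double interp_uniform(const double *y, double g0, double dz_inv,
                                    int n, double z) {
  double x = (z - g0) * dz_inv;
  if (x <= 0.0) return y[0];
  if (x >= n - 1) return y[n - 1];
  int i = (int)x;
  double f = x - i;
  return y[i] * (1.0 - f) + y[i + 1] * f;
}

// One overdamped Euler-Maruyama step with spurious-drift correction and
// reflecting boundaries. bias_k is the half-convention force constant
// (bias force = -bias_k * (z - bias_c)); bias_k == 0 means unbiased.
static inline double bd_step(double z, const double *dG, const double *Dv,
                             const double *dD, double g0, double dz_inv,
                             int n, double beta, double dt, double sq_dt,
                             double bias_c, double bias_k, double zlo,
                             double zhi, bool *diverged) {
  double D = interp_uniform(Dv, g0, dz_inv, n, z);
  double force = -interp_uniform(dG, g0, dz_inv, n, z) - bias_k * (z - bias_c);
  double drift = beta * D * force + interp_uniform(dD, g0, dz_inv, n, z);
  double step = drift * dt + std::sqrt(2.0 * D) * sq_dt * norm_rand();
  if (std::fabs(step) > 5.0) {
    *diverged = true;
    return z;
  }
  double zn = z + step;
  // reflecting boundaries (repeat in case of overshoot past both walls)
  for (int it = 0; it < 64 && (zn < zlo || zn > zhi); ++it) {
    if (zn < zlo) zn = 2.0 * zlo - zn;
    if (zn > zhi) zn = 2.0 * zhi - zn;
  }
  if (zn < zlo) zn = zlo;
  if (zn > zhi) zn = zhi;
  return zn;
}

// [[Rcpp::export]]
List langevin_cpp(NumericVector grid, NumericVector dG, NumericVector Dv,
                  NumericVector dD, double beta, double dt, int n_steps,
                  double z0, double bias_center, double bias_k, int stride) {
  int n = grid.size();
  double g0 = grid[0], zhi = grid[n - 1];
  double dz_inv = (n - 1) / (zhi - g0);
  double sq_dt = std::sqrt(dt);
  int n_save = n_steps / stride;
  NumericVector out(n_save);
  bool diverged = false;
  double z = z0;
  RNGScope scope;
  int isave = 0;
  for (int s = 1; s <= n_steps; ++s) {
    z = bd_step(z, dG.begin(), Dv.begin(), dD.begin(), g0, dz_inv, n, beta,
                dt, sq_dt, bias_center, bias_k, g0, zhi, &diverged);
    if (diverged) break;
    if (s % stride == 0 && isave < n_save) out[isave++] = z;
  }
  return List::create(_["z"] = out, _["diverged"] = diverged,
                      _["n_saved"] = isave);
}

// Replica-exchange umbrella sampling on a 1D model: every window runs
// Brownian dynamics between exchange epochs; at each epoch alternating
// even/odd neighbour pairs attempt a Metropolis swap of configurations.
// [[Rcpp::export]]
List reus_cpp(NumericVector grid, NumericVector dG, NumericVector Dv,
              NumericVector dD, double beta, double dt, int n_steps,
              int exchange_interval, NumericVector centers,
              NumericVector khalf, NumericVector z_init, int stride) {
  int n = grid.size();
  int nw = centers.size();
  double g0 = grid[0], zhi = grid[n - 1];
  double dz_inv = (n - 1) / (zhi - g0);
  double sq_dt = std::sqrt(dt);
  int n_save = n_steps / stride;
  NumericMatrix out(n_save, nw);
  std::vector<double> z(z_init.begin(), z_init.end());
  bool diverged = false;

  std::vector<double> att_time, att_dU, att_u;
  std::vector<int> att_pair, att_acc;

  RNGScope scope;
  int isave = 0, epoch = 0;
  for (int s = 1; s <= n_steps; ++s) {
    for (int w = 0; w < nw; ++w) {
      z[w] = bd_step(z[w], dG.begin(), Dv.begin(), dD.begin(), g0, dz_inv, n,
                     beta, dt, sq_dt, centers[w], khalf[w], g0, zhi,
                     &diverged);
      if (diverged)
        stop("divergent Langevin step (|dz| > 5 A); reduce dt");
    }
    if (s % stride == 0 && isave < n_save) {
      for (int w = 0; w < nw; ++w) out(isave, w) = z[w];
      ++isave;
    }
    if (s % exchange_interval == 0) {
      int parity = epoch % 2;  // alternate even/odd neighbour pairs
      ++epoch;
      for (int i = parity; i + 1 < nw; i += 2) {
        int j = i + 1;
        double ui_zi = 0.5 * khalf[i] * (z[i] - centers[i]) * (z[i] - centers[i]);
        double uj_zj = 0.5 * khalf[j] * (z[j] - centers[j]) * (z[j] - centers[j]);
        double ui_zj = 0.5 * khalf[i] * (z[j] - centers[i]) * (z[j] - centers[i]);
        double uj_zi = 0.5 * khalf[j] * (z[i] - centers[j]) * (z[i] - centers[j]);
        double dU = ui_zj + uj_zi - ui_zi - uj_zj;
        double u = unif_rand();
        int acc = (dU <= 0.0 || u < std::exp(-beta * dU)) ? 1 : 0;
        att_time.push_back(s * dt);
        att_pair.push_back(i + 1);  // 1-based left window index
        att_dU.push_back(dU);
        att_u.push_back(u);
        att_acc.push_back(acc);
        if (acc) std::swap(z[i], z[j]);
      }
    }
  }
  return List::create(
      _["z"] = out,
      _["attempt_time"] = wrap(att_time), _["attempt_pair"] = wrap(att_pair),
      _["attempt_dU"] = wrap(att_dU), _["attempt_u"] = wrap(att_u),
      _["attempt_accepted"] = wrap(att_acc));
}
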