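#include <Rcpp.h>
using namespace Rcpp;

// Overdamped Langevin (Euler-Maruyama) on a 2-D landscape of negative
// isotropic Gaussian wells plus an optional harmonic confinement:
//   E(x) = -sum_m d_m exp(-|x - c_m|^2 / (2 w_m^2))
//          + (kx/2) (x1 - o1)^2 + (ky/2) (x2 - o2)^2              [kT]
// Update: x <- x + (D/kT) F dt + sqrt(2 D dt) eta,  F = -grad E.
// Uses R's RNG so set.seed() gives bitwise-reproducible paths.

static inline void grad_energy(const double *cx, const double *cy,
                               const double *depth, const double *w2,
                               int nw, double conf_kx, double conf_ky,
                               double ox, double oy,
                               double x, double y,
                               double &gx, double &gy) {
  gx = conf_kx * (x - ox);
  gy = conf_ky * (y - oy);
  for (int m = 0; m < nw; ++m) {
    double dx = x - cx[m], dy = y - cy[m];
    double e = depth[m] * std::exp(-(dx * dx + dy * dy) / (2.0 * w2[m]));
    gx += e * dx / w2[m];
    gy += e * dy / w2[m];
  }
}

// [[Rcpp::export]]
NumericMatrix langevin_path_cpp(NumericMatrix centers, NumericVector depths,
                                NumericVector widths, NumericVector conf_k,
                                NumericVector conf_origin,
                                NumericVector start, double dt,
                                double diffusion, double kT,
                                int n_steps, int record_stride,
                                double max_disp) {
  const int nw = depths.size();
  std::vector<double> cx(nw), cy(nw), w2(nw), dp(nw);
  for (int m = 0; m < nw; ++m) {
    cx[m] = centers(m, 0);
    cy[m] = centers(m, 1);
    w2[m] = widths[m] * widths[m];
    dp[m] = depths[m];
  }
  const double ox = conf_origin[0], oy = conf_origin[1];
  const double mob = diffusion / kT;
  const double sig = std::sqrt(2.0 * diffusion * dt);

  const int n_rec = n_steps / record_stride + 1;
  NumericMatrix out(n_rec, 2);
  double x = start[0], y = start[1];
  out(0, 0) = x;
  out(0, 1) = y;

  int irec = 1;
  for (int s = 1; s <= n_steps; ++s) {
    double gx, gy;
    grad_energy(cx.data(), cy.data(), dp.data(), w2.data(), nw,
                conf_k[0], conf_k[1], ox, oy, x, y, gx, gy);
    double ddx = -mob * gx * dt + sig * norm_rand();
    double ddy = -mob * gy * dt + sig * norm_rand();
    if (std::abs(ddx) > max_disp || std::abs(ddy) > max_disp ||
        !std::isfinite(ddx) || !std::isfinite(ddy)) {
      stop("integration diverged at step %d (|displacement| exceeds %f nm); reduce the timestep",
           s, max_disp);
    }
    x += ddx;
    y += ddy;
    if (s % record_stride == 0) {
      out(irec, 0) = x;
      out(irec, 1) = y;
      ++irec;
    }
  }
  return out;
}
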