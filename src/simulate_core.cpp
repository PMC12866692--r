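#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Overdamped self-propelled-particle integrator with soft repulsion,
// continuous-time Vicsek heading alignment, optional harmonic bonds and a
// periodic square box. Headings relax toward the local mean heading at
// rate J and receive rotational noise sqrt(2 D_r dt) * xi; positions obey
// dr/dt = v0 n(theta) + mu * (F_rep + F_bond). Noise is supplied from R so
// that determinism is governed entirely by R's RNG.
//
// Returns recorded frames of wrapped and unwrapped positions and headings.
// [[Rcpp::export]]
List simulate_core(NumericVector x0, NumericVector y0, NumericVector th0,
                   double box, double a, NumericVector v0, double J, double Dr,
                   double k_rep, double k_bond, double r_align, double mu,
                   double dt, int n_steps, int record_every,
                   NumericMatrix noise,
                   IntegerVector bond_i, IntegerVector bond_j,
                   NumericVector bond_r0) {
  const int n = x0.size();
  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> y(y0.begin(), y0.end());
  std::vector<double> xu(x0.begin(), x0.end());
  std::vector<double> yu(y0.begin(), y0.end());
  std::vector<double> th(th0.begin(), th0.end());
  std::vector<double> fx(n), fy(n), ax(n), ay(n);

  const int n_frames = n_steps / record_every + 1;
  NumericMatrix X(n_frames, n), Y(n_frames, n), XU(n_frames, n),
      YU(n_frames, n), TH(n_frames, n);
  const double half = box / 2.0;
  const double contact = 2.0 * a;
  const double sq_noise = std::sqrt(2.0 * Dr * dt);
  const int n_bonds = bond_i.size();

  int frame = 0;
  for (int i = 0; i < n; ++i) {
    X(0, i) = x[i]; Y(0, i) = y[i];
    XU(0, i) = xu[i]; YU(0, i) = yu[i]; TH(0, i) = th[i];
  }

  for (int s = 0; s < n_steps; ++s) {
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    // alignment accumulators start with self
    for (int i = 0; i < n; ++i) {
      ax[i] = std::cos(th[i]);
      ay[i] = std::sin(th[i]);
    }
    const double r2max = std::max(contact, r_align);
    const double r2cut = r2max * r2max;
    for (int i = 0; i < n - 1; ++i) {
      for (int j = i + 1; j < n; ++j) {
        double dx = x[j] - x[i];
        double dy = y[j] - y[i];
        if (dx > half) dx -= box; else if (dx < -half) dx += box;
        if (dy > half) dy -= box; else if (dy < -half) dy += box;
        double r2 = dx * dx + dy * dy;
        if (r2 >= r2cut || r2 == 0.0) continue;
        double r = std::sqrt(r2);
        if (k_rep > 0.0 && r < contact) {
          double f = k_rep * (contact - r) / r; // along unit vector
          fx[i] -= f * dx; fy[i] -= f * dy;
          fx[j] += f * dx; fy[j] += f * dy;
        }
        if (J != 0.0 && r < r_align) {
          double ci = std::cos(th[j]), si = std::sin(th[j]);
          ax[i] += ci; ay[i] += si;
          ax[j] += std::cos(th[i]); ay[j] += std::sin(th[i]);
        }
      }
    }
    if (k_bond > 0.0) {
      for (int b = 0; b < n_bonds; ++b) {
        int i = bond_i[b], j = bond_j[b];
        // bonded pairs stay within a bond length; minimum image keeps
        // the force right when the pair wraps the periodic boundary
        double dx = x[j] - x[i];
        double dy = y[j] - y[i];
        if (dx > half) dx -= box; else if (dx < -half) dx += box;
        if (dy > half) dy -= box; else if (dy < -half) dy += box;
        double r = std::sqrt(dx * dx + dy * dy);
        if (r == 0.0) continue;
        double f = k_bond * (r - bond_r0[b]) / r;
        fx[i] += f * dx; fy[i] += f * dy;
        fx[j] -= f * dx; fy[j] -= f * dy;
      }
    }
    double max_disp2 = 0.0;
    for (int i = 0; i < n; ++i) {
      if (J != 0.0) {
        double mean_th = std::atan2(ay[i], ax[i]);
        th[i] += J * std::sin(mean_th - th[i]) * dt;
      }
      th[i] += sq_noise * noise(s, i);
      double ux = v0[i] * std::cos(th[i]) + mu * fx[i];
      double uy = v0[i] * std::sin(th[i]) + mu * fy[i];
      double ddx = ux * dt, ddy = uy * dt;
      double d2 = ddx * ddx + ddy * ddy;
      if (d2 > max_disp2) max_disp2 = d2;
      xu[i] += ddx; yu[i] += ddy;
      x[i] += ddx; y[i] += ddy;
      x[i] -= box * std::floor(x[i] / box);
      y[i] -= box * std::floor(y[i] / box);
      if (!std::isfinite(x[i]) || !std::isfinite(y[i]) ||
          !std::isfinite(th[i])) {
        stop("simulation blew up at step %d: non-finite state "
             "(max displacement this step %.3g um); reduce dt or "
             "stiffness", s + 1, std::sqrt(max_disp2));
      }
    }
    if (std::sqrt(max_disp2) > a) {
      stop("simulation unstable at step %d: max displacement per step "
           "%.3g um exceeds the cell radius %.3g um; reduce dt or "
           "stiffness", s + 1, std::sqrt(max_disp2), a);
    }
    if ((s + 1) % record_every == 0) {
      ++frame;
      for (int i = 0; i < n; ++i) {
        X(frame, i) = x[i]; Y(frame, i) = y[i];
        XU(frame, i) = xu[i]; YU(frame, i) = yu[i]; TH(frame, i) = th[i];
      }
    }
  }
  return List::create(_["x"] = X, _["y"] = Y, _["x_unwrap"] = XU,
                      _["y_unwrap"] = YU, _["theta"] = TH);
}
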