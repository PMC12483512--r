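#include <Rcpp.h>
#include "ziggurat.h"
#include <cmath>
#include <random>
#include <vector>
using namespace Rcpp;

// Overdamped Langevin dynamics of the bead-spring TF (kT = 1, D = 1 per
// site, lengths in bp, times in t0 = bp^2/D).
//
// Potential (near-field):
//   U = sum_bonds  1/2 k (r_{i+1} - r_i)^2            k = 3 / l0^2
//     + sum_{site i, IDR target j}  -E_B exp(-|r_i - R_j|^2 / (2 w_d^2))
//     + sum_{site pairs} WCA(sigma)                   (excluded volume)
// The DBD target is absorbing in the search simulation and carries no well.

struct Force {
  int n;                        // number of sites
  double k;                     // spring constant
  double E_B, w_d, sigma;       // well depth, well width, WCA diameter
  const double* tx; const double* ty; const double* tz; int n_t;
};

static double energy(const Force& p, const double* x, const double* y, const double* z) {
  double U = 0.0;
  for (int i = 0; i + 1 < p.n; ++i) {
    double dx = x[i + 1] - x[i], dy = y[i + 1] - y[i], dz = z[i + 1] - z[i];
    U += 0.5 * p.k * (dx * dx + dy * dy + dz * dz);
  }
  if (p.E_B != 0.0) {
    double iw2 = 1.0 / (2.0 * p.w_d * p.w_d);
    for (int i = 0; i < p.n; ++i)
      for (int t = 0; t < p.n_t; ++t) {
        double dz = z[i] - p.tz[t];
        if (dz * dz * iw2 > 60.0) continue;   // axial prefilter
        double dx = x[i] - p.tx[t], dy = y[i] - p.ty[t];
        double a2 = (dx * dx + dy * dy + dz * dz) * iw2;
        if (a2 > 60.0) continue;          // well cutoff (exp < 1e-26)
        U -= p.E_B * std::exp(-a2);
      }
  }
  if (p.sigma > 0.0) {
    double s2 = p.sigma * p.sigma;
    for (int i = 0; i < p.n; ++i)
      for (int j = i + 1; j < p.n; ++j) {
        double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
        double r2 = dx * dx + dy * dy + dz * dz;
        if (r2 < s2) {
          double sr6 = (s2 / r2) * (s2 / r2) * (s2 / r2);
          U += sr6 * sr6 - 2.0 * sr6 + 1.0;
        }
      }
  }
  return U;
}

// forces = -grad U; returns max |f_i| (site-wise Euclidean norm)
static double forces(const Force& p, const double* x, const double* y, const double* z,
                     double* fx, double* fy, double* fz) {
  for (int i = 0; i < p.n; ++i) { fx[i] = 0.0; fy[i] = 0.0; fz[i] = 0.0; }
  for (int i = 0; i + 1 < p.n; ++i) {
    double dx = x[i + 1] - x[i], dy = y[i + 1] - y[i], dz = z[i + 1] - z[i];
    fx[i] += p.k * dx; fy[i] += p.k * dy; fz[i] += p.k * dz;
    fx[i + 1] -= p.k * dx; fy[i + 1] -= p.k * dy; fz[i + 1] -= p.k * dz;
  }
  if (p.E_B != 0.0) {
    double iw2 = 1.0 / (2.0 * p.w_d * p.w_d);
    for (int i = 0; i < p.n; ++i)
      for (int t = 0; t < p.n_t; ++t) {
        double dz = z[i] - p.tz[t];
        if (dz * dz * iw2 > 60.0) continue;   // axial prefilter
        double dx = x[i] - p.tx[t], dy = y[i] - p.ty[t];
        double a2 = (dx * dx + dy * dy + dz * dz) * iw2;
        if (a2 > 60.0) continue;          // well cutoff (exp < 1e-26)
        double g = p.E_B * std::exp(-a2) * 2.0 * iw2;
        // attractive: f = -dU/dr pulls the site toward the target
        fx[i] -= g * dx; fy[i] -= g * dy; fz[i] -= g * dz;
      }
  }
  if (p.sigma > 0.0) {
    double s2 = p.sigma * p.sigma;
    for (int i = 0; i < p.n; ++i)
      for (int j = i + 1; j < p.n; ++j) {
        double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
        double r2 = dx * dx + dy * dy + dz * dz;
        if (r2 < s2) {
          if (r2 < 1e-12) r2 = 1e-12;
          double sr6 = (s2 / r2) * (s2 / r2) * (s2 / r2);
          double mag = 12.0 * (sr6 * sr6 - sr6) / r2;   // -dU/dr / r
          double fmag2 = mag * mag * r2;
          if (fmag2 > 1e4) mag = 100.0 / std::sqrt(r2);  // capped core force
          fx[i] += mag * dx; fy[i] += mag * dy; fz[i] += mag * dz;
          fx[j] -= mag * dx; fy[j] -= mag * dy; fz[j] -= mag * dz;
        }
      }
  }
  double fmax = 0.0;
  for (int i = 0; i < p.n; ++i) {
    double f2 = fx[i] * fx[i] + fy[i] * fy[i] + fz[i] * fz[i];
    if (f2 > fmax) fmax = f2;
  }
  return std::sqrt(fmax);
}

// [[Rcpp::export]]
double total_energy_cpp(NumericMatrix pos, NumericMatrix targets,
                        double E_B, double w_d, double k_spring, double sigma) {
  int n = pos.nrow();
  std::vector<double> x(n), y(n), z(n);
  for (int i = 0; i < n; ++i) { x[i] = pos(i, 0); y[i] = pos(i, 1); z[i] = pos(i, 2); }
  int nt = targets.nrow();
  std::vector<double> tx(nt), ty(nt), tz(nt);
  for (int t = 0; t < nt; ++t) { tx[t] = targets(t, 0); ty[t] = targets(t, 1); tz[t] = targets(t, 2); }
  Force p{n, k_spring, E_B, w_d, sigma, tx.data(), ty.data(), tz.data(), nt};
  return energy(p, x.data(), y.data(), z.data());
}

// [[Rcpp::export]]
NumericMatrix total_force_cpp(NumericMatrix pos, NumericMatrix targets,
                              double E_B, double w_d, double k_spring, double sigma) {
  int n = pos.nrow();
  std::vector<double> x(n), y(n), z(n), fx(n), fy(n), fz(n);
  for (int i = 0; i < n; ++i) { x[i] = pos(i, 0); y[i] = pos(i, 1); z[i] = pos(i, 2); }
  int nt = targets.nrow();
  std::vector<double> tx(nt), ty(nt), tz(nt);
  for (int t = 0; t < nt; ++t) { tx[t] = targets(t, 0); ty[t] = targets(t, 1); tz[t] = targets(t, 2); }
  Force p{n, k_spring, E_B, w_d, sigma, tx.data(), ty.data(), tz.data(), nt};
  forces(p, x.data(), y.data(), z.data(), fx.data(), fy.data(), fz.data());
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) { out(i, 0) = fx[i]; out(i, 1) = fy[i]; out(i, 2) = fz[i]; }
  return out;
}

// Mirror reflection at the sphere |r| = R (applied repeatedly for safety).
static inline void reflect_sphere(double R, double& x, double& y, double& z) {
  for (int it = 0; it < 16; ++it) {
    double r = std::sqrt(x * x + y * y + z * z);
    if (r <= R) return;
    double scale = (2.0 * R - r) / r;
    x *= scale; y *= scale; z *= scale;
  }
}

// Generic fixed-step trajectory (no absorption), subsampled every `stride`
// steps.  R_sphere <= 0 disables the reflecting boundary.  Used for the
// integrator audits: free-diffusion MSD, Rouse centre-of-mass diffusion,
// Boltzmann sampling in a well, uniform measure in the sphere.
// [[Rcpp::export]]
NumericMatrix bd_trajectory_cpp(NumericMatrix pos0, NumericMatrix targets,
                                double E_B, double w_d, double k_spring,
                                double sigma, double R_sphere, double dt,
                                int n_steps, int stride, int seed) {
  int n = pos0.nrow();
  std::vector<double> x(n), y(n), z(n), fx(n), fy(n), fz(n);
  for (int i = 0; i < n; ++i) { x[i] = pos0(i, 0); y[i] = pos0(i, 1); z[i] = pos0(i, 2); }
  int nt = targets.nrow();
  std::vector<double> tx(nt), ty(nt), tz(nt);
  for (int t = 0; t < nt; ++t) { tx[t] = targets(t, 0); ty[t] = targets(t, 1); tz[t] = targets(t, 2); }
  Force p{n, k_spring, E_B, w_d, sigma, tx.data(), ty.data(), tz.data(), nt};

  ZigguratNormal rnorm(static_cast<uint64_t>(seed));
  double amp = std::sqrt(2.0 * dt);

  int n_samples = n_steps / stride;
  NumericMatrix out(n_samples, 3 * n);
  int row = 0;
  for (int step = 1; step <= n_steps; ++step) {
    forces(p, x.data(), y.data(), z.data(), fx.data(), fy.data(), fz.data());
    for (int i = 0; i < n; ++i) {
      x[i] += fx[i] * dt + amp * rnorm();
      y[i] += fy[i] * dt + amp * rnorm();
      z[i] += fz[i] * dt + amp * rnorm();
      if (R_sphere > 0.0) reflect_sphere(R_sphere, x[i], y[i], z[i]);
    }
    if (step % stride == 0 && row < n_samples) {
      for (int i = 0; i < n; ++i) {
        out(row, 3 * i) = x[i]; out(row, 3 * i + 1) = y[i]; out(row, 3 * i + 2) = z[i];
      }
      ++row;
    }
  }
  return out;
}

// distance from (x, y, z) to the antenna segment {x=y=0, z in [-L/2, L/2]}
static inline double antenna_dist(double x, double y, double z, double halfL) {
  double rho2 = x * x + y * y;
  double dz = std::fabs(z) > halfL ? std::fabs(z) - halfL : 0.0;
  return std::sqrt(rho2 + dz * dz);
}

// First-passage search simulation.  The antenna lies along z through the
// sphere centre; the absorbing DBD target (radius `a`) sits at the origin;
// IDR targets (Gaussian wells, depth E_B) sit at z = +-d, +-2d, ... within
// the span L.  Far from the antenna the chain moves as a rigid body with
// diffusion coefficient D/n.  Returns the first-passage record.
// [[Rcpp::export]]
List simulate_search_cpp(NumericMatrix pos0, int n_tilde, double l0, double R,
                         double a, double d, double L, double E_B, double w_d,
                         double sigma, double far_threshold, double dt_base,
                         double max_time, double capture_radius,
                         double detach_time, double sample_dt, int seed,
                         bool store_series) {
  int n = n_tilde;
  std::vector<double> x(n), y(n), z(n), fx(n), fy(n), fz(n);
  for (int i = 0; i < n; ++i) { x[i] = pos0(i, 0); y[i] = pos0(i, 1); z[i] = pos0(i, 2); }

  // Gaussian-well targets: the central DBD target plus IDR targets on both
  // sides (the site-target interaction sum runs over every pair; only the
  // DBD site is additionally absorbed at the centre)
  int per_side = static_cast<int>(std::floor(L / (2.0 * d) + 1e-9));
  std::vector<double> tx, ty, tz;
  tx.push_back(0.0); ty.push_back(0.0); tz.push_back(0.0);
  for (int k = 1; k <= per_side; ++k) {
    tx.push_back(0.0); ty.push_back(0.0); tz.push_back(k * d);
    tx.push_back(0.0); ty.push_back(0.0); tz.push_back(-k * d);
  }
  int nt = static_cast<int>(tx.size());
  double halfL = per_side * d;  // actual antenna half-span realised by targets
  if (halfL <= 0.0) halfL = a;  // bare-target limit
  Force p{n, (n > 1) ? 3.0 / (l0 * l0) : 0.0, E_B, w_d, sigma,
          tx.data(), ty.data(), tz.data(), nt};

  ZigguratNormal rnorm(static_cast<uint64_t>(seed));

  double D3 = 1.0 / n;
  double step_far = far_threshold / 5.0;
  double dt_far = step_far * step_far / (6.0 * D3);
  double cap2 = capture_radius * capture_radius;

  double t = 0.0, t_3d = -1.0;
  double n_steps = 0.0, n_near = 0.0;
  int n_rounds = 0;
  bool attached = false;
  double time_all_far = 0.0;
  bool success = false;
  std::vector<double> s_t, s_nb, s_zcom, s_mind;
  std::vector<double> ev_attach, ev_detach;
  double next_sample = 0.0;

  // t = 0: already inside the capture radius of the DBD target?
  {
    double r0 = std::sqrt(x[0] * x[0] + y[0] * y[0] + z[0] * z[0]);
    if (r0 < a) success = true;
  }

  while (!success && t < max_time) {
    double mind = antenna_dist(x[0], y[0], z[0], halfL);
    for (int i = 1; i < n; ++i) {
      double di = antenna_dist(x[i], y[i], z[i], halfL);
      if (di < mind) mind = di;
    }
    double dt;
    if (mind >= far_threshold) {
      // rigid-body far-field move
      dt = dt_far;
      double amp = std::sqrt(2.0 * D3 * dt);
      double ddx = amp * rnorm(), ddy = amp * rnorm(), ddz = amp * rnorm();
      for (int i = 0; i < n; ++i) { x[i] += ddx; y[i] += ddy; z[i] += ddz; }
      // keep the body inside the sphere: mirror the worst offender's radial
      // excess as a shift of the whole body, retrying a few times
      for (int it = 0; it < 16; ++it) {
        int worst = -1; double m = 0.0;
        for (int i = 0; i < n; ++i) {
          double r = std::sqrt(x[i] * x[i] + y[i] * y[i] + z[i] * z[i]);
          if (r - R > m) { m = r - R; worst = i; }
        }
        if (worst < 0) break;
        double r = std::sqrt(x[worst] * x[worst] + y[worst] * y[worst] + z[worst] * z[worst]);
        double shift = 2.0 * m / r;
        double sx = -x[worst] * shift, sy = -y[worst] * shift, sz = -z[worst] * shift;
        for (int i = 0; i < n; ++i) { x[i] += sx; y[i] += sy; z[i] += sz; }
      }
      time_all_far += dt;
    } else {
      // near-field: full forces, adaptive time step
      double fmax = forces(p, x.data(), y.data(), z.data(), fx.data(), fy.data(), fz.data());
      dt = dt_base * ((fmax > 1.0) ? 1.0 / fmax : 1.0);
      double amp = std::sqrt(2.0 * dt);
      for (int i = 0; i < n; ++i) {
        x[i] += fx[i] * dt + amp * rnorm();
        y[i] += fy[i] * dt + amp * rnorm();
        z[i] += fz[i] * dt + amp * rnorm();
        reflect_sphere(R, x[i], y[i], z[i]);
      }
      time_all_far = 0.0;
    }
    t += dt;
    n_steps += 1.0;
    if (mind < far_threshold) n_near += 1.0;

    // events: a capture scan is only needed while unattached and close to
    // the antenna (every target lies on the antenna segment, so the minimal
    // segment distance bounds every site-target distance from below)
    bool in_capture = false;
    if (!attached && mind < capture_radius + 1.0) {  // margin > one near step
      for (int i = 0; i < n && !in_capture; ++i) {
        double dx0 = x[i], dy0 = y[i], dz0 = z[i];
        if (dx0 * dx0 + dy0 * dy0 + dz0 * dz0 < cap2) { in_capture = true; break; }
        for (int tt = 0; tt < nt; ++tt) {
          double ddx = x[i] - tx[tt], ddy = y[i] - ty[tt], ddz = z[i] - tz[tt];
          if (ddx * ddx + ddy * ddy + ddz * ddz < cap2) { in_capture = true; break; }
        }
      }
    }
    if (in_capture && !attached) {
      attached = true;
      ++n_rounds;
      if (t_3d < 0.0) t_3d = t;
      ev_attach.push_back(t);
    }
    if (attached && time_all_far > detach_time) {
      attached = false;
      ev_detach.push_back(t);
    }

    double r0 = std::sqrt(x[0] * x[0] + y[0] * y[0] + z[0] * z[0]);
    if (r0 < a) success = true;

    if (store_series && t >= next_sample) {
      int nb = 0;
      for (int i = 0; i < n; ++i) {
        bool b = false;
        double dx0 = x[i], dy0 = y[i], dz0 = z[i];
        if (dx0 * dx0 + dy0 * dy0 + dz0 * dz0 < cap2) b = true;
        for (int tt = 0; tt < nt && !b; ++tt) {
          double ddx = x[i] - tx[tt], ddy = y[i] - ty[tt], ddz = z[i] - tz[tt];
          if (ddx * ddx + ddy * ddy + ddz * ddz < cap2) b = true;
        }
        if (b) ++nb;
      }
      double zc = 0.0, mind2 = antenna_dist(x[0], y[0], z[0], halfL);
      for (int i = 0; i < n; ++i) {
        zc += z[i];
        double di = antenna_dist(x[i], y[i], z[i], halfL);
        if (di < mind2) mind2 = di;
      }
      s_t.push_back(t); s_nb.push_back(nb); s_zcom.push_back(zc / n); s_mind.push_back(mind2);
      next_sample += sample_dt;
    }
  }

  List series = R_NilValue;
  if (store_series) {
    series = List::create(_["time"] = NumericVector(s_t.begin(), s_t.end()),
                          _["n_bound"] = NumericVector(s_nb.begin(), s_nb.end()),
                          _["z_com"] = NumericVector(s_zcom.begin(), s_zcom.end()),
                          _["min_antenna_dist"] = NumericVector(s_mind.begin(), s_mind.end()));
  }
  return List::create(
    _["t_total"] = t,
    _["t_3d"] = (t_3d < 0.0) ? NA_REAL : t_3d,
    _["n_rounds"] = n_rounds,
    _["terminated"] = success ? "success" : "max_time",
    _["n_steps"] = n_steps,
    _["n_near_steps"] = n_near,
    _["attach_times"] = NumericVector(ev_attach.begin(), ev_attach.end()),
    _["detach_times"] = NumericVector(ev_detach.begin(), ev_detach.end()),
    _["series"] = series);
}

// Point-searcher mean-first-passage reference with distance-adaptive time
// steps.  mode 0: central absorbing sphere of radius `a`; mode 1: absorbing
// cylinder (antenna) of half-length L/2 and capture radius r_p along z.
// Returns one first-passage time per run (D = 1).
// [[Rcpp::export]]
NumericVector point_mfpt_cpp(double R, int mode, double a, double L, double r_p,
                             int n_runs, double c_adapt, double min_step,
                             double max_time, int seed) {
  ZigguratNormal rnorm(static_cast<uint64_t>(seed));
  std::mt19937_64 rng(static_cast<uint64_t>(seed) + 0x9e3779b9u);
  std::uniform_real_distribution<double> runif(-1.0, 1.0);
  NumericVector out(n_runs);
  double halfL = L / 2.0;

  for (int run = 0; run < n_runs; ++run) {
    // uniform start in the sphere, outside the absorber
    double x, y, z;
    for (;;) {
      x = R * runif(rng); y = R * runif(rng); z = R * runif(rng);
      if (x * x + y * y + z * z > R * R) continue;
      double dist = (mode == 0)
        ? std::sqrt(x * x + y * y + z * z) - a
        : antenna_dist(x, y, z, halfL) - r_p;
      if (dist > 0.0) break;
    }
    double t = 0.0;
    for (;;) {
      double dist = (mode == 0)
        ? std::sqrt(x * x + y * y + z * z) - a
        : antenna_dist(x, y, z, halfL) - r_p;
      if (dist <= 0.0) break;
      double rms = c_adapt * dist;
      if (rms < min_step) rms = min_step;
      double dt = rms * rms / 6.0;
      double amp = std::sqrt(2.0 * dt);
      x += amp * rnorm(); y += amp * rnorm(); z += amp * rnorm();
      reflect_sphere(R, x, y, z);
      t += dt;
      if (t > max_time) break;
    }
    out[run] = t;
  }
  return out;
}
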