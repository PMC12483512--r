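#include <Rcpp.h>
#include <cmath>
#include <random>
#include <vector>
using namespace Rcpp;

// Continuous-space Metropolis sampler used as an independent check on the
// analytic configuration sum.  The chain (site 0 = DBD) has harmonic bonds
// with stiffness 3/l_i^2 (kT = 1); targets are square wells of radius
// r_well (volume V1 = 4/3 pi r_well^3): depth E_DBD between the DBD site
// and the DBD target, depth E_B between each IDR site and each IDR target.
// The simulation cell is periodic with side `box`; coordinates are kept
// unwrapped (bond energies use absolute positions) and site-target
// distances use the minimum image, so the centre-of-mass measure is exactly
// uniform over the cell of volume box^3.

struct MCState {
  int n_sites, n_t;
  double box, r2_well, E_B, E_DBD;
  std::vector<double> kspring;            // per bond, 3/l_i^2
  std::vector<double> x, y, z;            // site positions
  std::vector<double> tx, ty, tz;         // targets, index 0 = DBD target
};

static inline double min_img(double d, double box) {
  return d - box * std::round(d / box);
}

static double site_well_energy(const MCState& s, int i) {
  double e = 0.0;
  if (i == 0) {
    double dx = min_img(s.x[0] - s.tx[0], s.box);
    double dy = min_img(s.y[0] - s.ty[0], s.box);
    double dz = min_img(s.z[0] - s.tz[0], s.box);
    if (dx * dx + dy * dy + dz * dz < s.r2_well) e -= s.E_DBD;
  } else {
    for (int t = 1; t <= s.n_t; ++t) {
      double dx = min_img(s.x[i] - s.tx[t], s.box);
      double dy = min_img(s.y[i] - s.ty[t], s.box);
      double dz = min_img(s.z[i] - s.tz[t], s.box);
      if (dx * dx + dy * dy + dz * dz < s.r2_well) e -= s.E_B;
    }
  }
  return e;
}

static double bond_energy(const MCState& s, int i) {
  // bonds adjacent to site i
  double e = 0.0;
  if (i > 0) {
    double dx = s.x[i] - s.x[i - 1], dy = s.y[i] - s.y[i - 1], dz = s.z[i] - s.z[i - 1];
    e += 0.5 * s.kspring[i - 1] * (dx * dx + dy * dy + dz * dz);
  }
  if (i < s.n_sites - 1) {
    double dx = s.x[i + 1] - s.x[i], dy = s.y[i + 1] - s.y[i], dz = s.z[i + 1] - s.z[i];
    e += 0.5 * s.kspring[i] * (dx * dx + dy * dy + dz * dz);
  }
  return e;
}

static double total_well_energy(const MCState& s) {
  double e = 0.0;
  for (int i = 0; i < s.n_sites; ++i) e += site_well_energy(s, i);
  return e;
}

// single occupancy: no two sites inside the same target well (hard-core
// stand-in for the excluded-volume interaction of the dynamical model; the
// analytic configuration sum counts injective matchings only)
static bool state_valid(const MCState& s) {
  for (int t = 0; t <= s.n_t; ++t) {
    int occ = 0;
    for (int i = 0; i < s.n_sites; ++i) {
      double dx = min_img(s.x[i] - s.tx[t], s.box);
      double dy = min_img(s.y[i] - s.ty[t], s.box);
      double dz = min_img(s.z[i] - s.tz[t], s.box);
      if (dx * dx + dy * dy + dz * dz < s.r2_well && ++occ > 1) return false;
    }
  }
  return true;
}

// [[Rcpp::export]]
List metropolis_binding_cpp(NumericVector segment_lengths, NumericMatrix targets,
                            double E_B, double E_DBD, double r_well, double box,
                            double n_sweeps, double burnin, int n_batches,
                            double step_local, int seed) {
  MCState s;
  s.n_sites = segment_lengths.size() + 1;
  s.n_t = targets.nrow() - 1;
  s.box = box;
  s.r2_well = r_well * r_well;
  s.E_B = E_B;
  s.E_DBD = E_DBD;
  for (int b = 0; b < s.n_sites - 1; ++b)
    s.kspring.push_back(3.0 / (segment_lengths[b] * segment_lengths[b]));
  s.x.assign(s.n_sites, 0.0); s.y.assign(s.n_sites, 0.0); s.z.assign(s.n_sites, 0.0);
  for (int t = 0; t <= s.n_t; ++t) {
    s.tx.push_back(targets(t, 0)); s.ty.push_back(targets(t, 1)); s.tz.push_back(targets(t, 2));
  }

  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  std::uniform_real_distribution<double> runif(0.0, 1.0);
  std::normal_distribution<double> rnorm(0.0, 1.0);

  // initial state: site 0 uniform in the cell, bonds from their Gaussians
  s.x[0] = box * runif(rng); s.y[0] = box * runif(rng); s.z[0] = box * runif(rng);
  for (int i = 1; i < s.n_sites; ++i) {
    double sd = segment_lengths[i - 1] / std::sqrt(3.0);
    s.x[i] = s.x[i - 1] + sd * rnorm(rng);
    s.y[i] = s.y[i - 1] + sd * rnorm(rng);
    s.z[i] = s.z[i - 1] + sd * rnorm(rng);
  }

  long long total = static_cast<long long>(n_sweeps);
  long long nburn = static_cast<long long>(burnin);
  std::vector<double> batch_occ(n_batches, 0.0), batch_n(n_batches, 0.0);
  long long per_batch = (total - nburn) / n_batches;
  double acc_local = 0.0, n_local = 0.0;

  for (long long sweep = 0; sweep < total; ++sweep) {
    // local single-site displacements
    for (int i = 0; i < s.n_sites; ++i) {
      double ox = s.x[i], oy = s.y[i], oz = s.z[i];
      double e0 = bond_energy(s, i) + site_well_energy(s, i);
      s.x[i] += step_local * rnorm(rng);
      s.y[i] += step_local * rnorm(rng);
      s.z[i] += step_local * rnorm(rng);
      double e1 = bond_energy(s, i) + site_well_energy(s, i);
      n_local += 1.0;
      if (state_valid(s) && runif(rng) < std::exp(e0 - e1)) {
        acc_local += 1.0;
      } else {
        s.x[i] = ox; s.y[i] = oy; s.z[i] = oz;
      }
    }
    // rigid translation of the whole chain by a symmetric uniform shift
    // (up to half a cell per axis); with minimum-image interactions this
    // makes the centre-of-mass marginal uniform over the periodic cell
    {
      double e0 = total_well_energy(s);
      double dx = box * (runif(rng) - 0.5);
      double dy = box * (runif(rng) - 0.5);
      double dz = box * (runif(rng) - 0.5);
      for (int i = 0; i < s.n_sites; ++i) { s.x[i] += dx; s.y[i] += dy; s.z[i] += dz; }
      double e1 = total_well_energy(s);
      if (!state_valid(s) || runif(rng) >= std::exp(e0 - e1)) {
        for (int i = 0; i < s.n_sites; ++i) { s.x[i] -= dx; s.y[i] -= dy; s.z[i] -= dz; }
      }
    }
    // independence proposal on the internal conformation: redraw all bonds
    // from their exact Gaussians; the bond-energy terms cancel against the
    // proposal density, leaving a well-energy Metropolis ratio.
    if (s.n_sites > 1) {
      std::vector<double> ox = s.x, oy = s.y, oz = s.z;
      double e0 = total_well_energy(s);
      for (int i = 1; i < s.n_sites; ++i) {
        double sd = segment_lengths[i - 1] / std::sqrt(3.0);
        s.x[i] = s.x[i - 1] + sd * rnorm(rng);
        s.y[i] = s.y[i - 1] + sd * rnorm(rng);
        s.z[i] = s.z[i - 1] + sd * rnorm(rng);
      }
      double e1 = total_well_energy(s);
      if (!state_valid(s) || runif(rng) >= std::exp(e0 - e1)) { s.x = ox; s.y = oy; s.z = oz; }
    }

    if (sweep >= nburn) {
      long long k = (sweep - nburn) / per_batch;
      if (k >= n_batches) k = n_batches - 1;
      double dx = min_img(s.x[0] - s.tx[0], box);
      double dy = min_img(s.y[0] - s.ty[0], box);
      double dz = min_img(s.z[0] - s.tz[0], box);
      bool dbd_bound = dx * dx + dy * dy + dz * dz < s.r2_well;
      batch_occ[k] += dbd_bound ? 1.0 : 0.0;
      batch_n[k] += 1.0;
    }
  }
  NumericVector occ(n_batches);
  for (int k = 0; k < n_batches; ++k) occ[k] = batch_occ[k] / batch_n[k];
  return List::create(_["batch_occupancy"] = occ,
                      _["acceptance_local"] = acc_local / n_local);
}
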