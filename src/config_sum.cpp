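#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Log-sum-exp accumulator for statistical weights.
struct LogSum {
  double m;   // running max
  double s;   // sum of exp(x - m)
  LogSum() : m(R_NegInf), s(0.0) {}
  void add(double x) {
    if (x == R_NegInf) return;
    if (x <= m) {
      s += std::exp(x - m);
    } else {
      s = s * std::exp(m - x) + 1.0;
      m = x;
    }
  }
  double value() const { return (s > 0.0) ? m + std::log(s) : R_NegInf; }
};

static inline double log_propagator(double r2, double l2) {
  // log of (3/(2 pi l2))^{3/2} exp(-3 r2 / (2 l2))
  return 1.5 * std::log(3.0 / (2.0 * M_PI * l2)) - 1.5 * r2 / l2;
}

struct SumCtx {
  int n_b, n_t;
  const double* cum_l2;       // length n_b + 1, squared contour from DBD site
  const double* tx;           // target coords, rows 0..n_t (row 0 = DBD target)
  const double* ty;
  const double* tz;
  double E_B, logV1, logV;
  double log_prune;           // drop branches whose Gaussian log-product sank below
  std::vector<char> used;     // IDR target usage flags (1-based)
  LogSum w_free, w_idr, w_tf; // weight accumulators by state class
  double n_leaf;
};

// Depth-first enumeration over injective partial matchings of IDR sites
// (chain indices 1..n_b) onto IDR targets (1..n_t), on top of a fixed
// DBD-bound flag.  Weight convention: the totally free state carries the
// translational volume V; the first bound contact (lowest chain index, the
// DBD site if bound) carries exp(E) * V1; every further contact carries
// exp(E) * V1 * f(target separation, squared contour between the sites).
static void recurse(SumCtx& c, int site, int last_site, int last_tgt,
                    double logw, double log_gauss, bool dbd_bound, int n_contacts) {
  if (site > c.n_b) {
    c.n_leaf += 1.0;
    if (dbd_bound) c.w_tf.add(logw);
    else if (n_contacts > 0) c.w_idr.add(logw);
    else c.w_free.add(c.logV);
    return;
  }
  // site unbound
  recurse(c, site + 1, last_site, last_tgt, logw, log_gauss, dbd_bound, n_contacts);
  // site bound to each unused IDR target
  for (int t = 1; t <= c.n_t; ++t) {
    if (c.used[t]) continue;
    double g = 0.0;
    if (last_site >= 0) {
      double dx = c.tx[t] - c.tx[last_tgt];
      double dy = c.ty[t] - c.ty[last_tgt];
      double dz = c.tz[t] - c.tz[last_tgt];
      double l2 = c.cum_l2[site] - c.cum_l2[last_site];
      g = log_propagator(dx * dx + dy * dy + dz * dz, l2);
    }
    double lg = log_gauss + g;
    if (lg < c.log_prune) continue;
    c.used[t] = 1;
    recurse(c, site + 1, site, t, logw + c.E_B + c.logV1 + g, lg,
            dbd_bound, n_contacts + 1);
    c.used[t] = 0;
  }
}

// Exact configuration sum over all binding configurations.  Returns the
// log-weights of the three state classes (free, IDR-only, DBD-bound) and
// the number of enumerated configurations.
// [[Rcpp::export]]
List config_sum_cpp(int n_b, NumericVector cum_l2, NumericMatrix targets,
                    double E_B, double E_DBD, double V1, double V,
                    double log_prune = -690.0) {
  int n_t = targets.nrow() - 1;
  std::vector<double> tx(n_t + 1), ty(n_t + 1), tz(n_t + 1);
  for (int i = 0; i <= n_t; ++i) {
    tx[i] = targets(i, 0); ty[i] = targets(i, 1); tz[i] = targets(i, 2);
  }
  SumCtx c;
  c.n_b = n_b; c.n_t = n_t;
  c.cum_l2 = REAL(cum_l2);
  c.tx = tx.data(); c.ty = ty.data(); c.tz = tz.data();
  c.E_B = E_B; c.logV1 = std::log(V1); c.logV = std::log(V);
  c.log_prune = log_prune;
  c.used.assign(n_t + 1, 0);
  c.n_leaf = 0.0;

  // DBD-unbound branch
  recurse(c, 1, -1, -1, 0.0, 0.0, false, 0);
  // DBD-bound branch: DBD site (chain index 0) at the DBD target (row 0)
  recurse(c, 1, 0, 0, E_DBD + c.logV1, 0.0, true, 0);

  return List::create(
    _["log_w_free"] = c.w_free.value(),
    _["log_w_idr"] = c.w_idr.value(),
    _["log_w_tf"] = c.w_tf.value(),
    _["n_configs"] = c.n_leaf);
}
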