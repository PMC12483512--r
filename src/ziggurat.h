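#ifndef IDRSEARCH_ZIGGURAT_H
#define IDRSEARCH_ZIGGURAT_H

// Standard-normal sampler: direct port of the Marsaglia-Tsang (2000)
// 128-layer ziggurat, driven by mt19937_64.  Used in the Brownian-dynamics
// kernels where normal draws dominate the step cost; validated in the test
// suite by the moment, MSD and Boltzmann-sampling audits.

#include <cmath>
#include <cstdint>
#include <cstdlib>
#include <random>

class ZigguratNormal {
 public:
  explicit ZigguratNormal(uint64_t seed) : rng_(seed) { init(); }

  double operator()() {
    int32_t hz = static_cast<int32_t>(static_cast<uint32_t>(rng_()));
    uint32_t iz = static_cast<uint32_t>(hz) & 127u;
    if (std::abs(hz) < kn_[iz]) return hz * wn_[iz];
    return nfix(hz, iz);
  }

 private:
  std::mt19937_64 rng_;
  int32_t kn_[128];
  double wn_[128], fn_[128];
  static constexpr double R = 3.442619855899;

  double uni() {
    return (static_cast<double>(rng_() >> 11) + 0.5) * 1.11022302462515654e-16;
  }

  double nfix(int32_t hz, uint32_t iz) {
    for (;;) {
      double x = hz * wn_[iz];
      if (iz == 0) {                         // base strip: exact tail
        double y;
        do {
          x = -std::log(uni()) / R;
          y = -std::log(uni());
        } while (y + y < x * x);
        return (hz > 0) ? R + x : -(R + x);
      }
      if (fn_[iz] + uni() * (fn_[iz - 1] - fn_[iz]) < std::exp(-0.5 * x * x))
        return x;
      hz = static_cast<int32_t>(static_cast<uint32_t>(rng_()));
      iz = static_cast<uint32_t>(hz) & 127u;
      if (std::abs(hz) < kn_[iz]) return hz * wn_[iz];
    }
  }

  void init() {
    const double m1 = 2147483648.0;
    const double vn = 9.91256303526217e-3;
    double dn = R, tn = R;
    double q = vn / std::exp(-0.5 * dn * dn);
    kn_[0] = static_cast<int32_t>((dn / q) * m1);
    kn_[1] = 0;
    wn_[0] = q / m1;
    wn_[127] = dn / m1;
    fn_[0] = 1.0;
    fn_[127] = std::exp(-0.5 * dn * dn);
    for (int i = 126; i >= 1; i--) {
      dn = std::sqrt(-2.0 * std::log(vn / dn + std::exp(-0.5 * dn * dn)));
      kn_[i + 1] = static_cast<int32_t>((dn / tn) * m1);
      tn = dn;
      fn_[i] = std::exp(-0.5 * dn * dn);
      wn_[i] = dn / m1;
    }
  }
};

#endif
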