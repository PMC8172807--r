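#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// Fast deterministic shuffle RNG (xoshiro256+), seeded from R's RNG so
// every permutation stream is reproducible from set.seed().
namespace {

struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    // splitmix64 expansion of the seed
    for (int i = 0; i < 4; ++i) {
      seed += 0x9e3779b97f4a7c15ULL;
      uint64_t z = seed;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = s[0] + s[3];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  // unbiased integer in [0, m) (Lemire with rejection)
  inline uint32_t bounded(uint32_t m) {
    uint64_t x = next() >> 32;
    uint64_t prod = x * (uint64_t)m;
    uint32_t low = (uint32_t)prod;
    if (low < m) {
      uint32_t thresh = (uint32_t)(-(int32_t)m) % m;
      while (low < thresh) {
        x = next() >> 32;
        prod = x * (uint64_t)m;
        low = (uint32_t)prod;
      }
    }
    return (uint32_t)(prod >> 32);
  }
};

}  // namespace

// Permutation counting kernel. For each of B random permutations, refits
// the effect slope via the partitioned-regression identity
//   beta1* = <x*, M y> / <x*, M x*>,
// with M projecting out the nuisance columns (Qt: transposed orthonormal
// basis, pz x n), and counts |beta1*| >= target. Under the Freedman-Lane
// scheme the nuisance-only residuals are permuted instead and the
// denominator is fixed. Near-singular permuted designs count toward r
// (conservative) and are tallied separately.

static const double t0_dummy[1] = {0.0};

// [[Rcpp::export]]
List perm_count_cpp(NumericVector x, NumericVector ey, NumericMatrix Qt,
                    double ss_x, double denom_obs, double target, int B,
                    bool effect_scheme, NumericVector Mx, double tol) {
  const int n = x.size();
  const int pz = Qt.nrow();
  const double *px = REAL(x), *pey = REAL(ey), *pmx = REAL(Mx);
  const double *pq = pz > 0 ? REAL(Qt) : t0_dummy;
  std::vector<int> p(n);
  for (int i = 0; i < n; ++i) p[i] = i;
  double r = 0, nsing = 0;
  double bsum = 0.0, bsumsq = 0.0;
  double t[8] = {0};                    // pz <= 6 in every design used here
  if (pz > 8) stop("too many nuisance columns");

  GetRNGstate();
  Xoshiro rng((uint64_t)(unif_rand() * 4294967296.0) << 32 |
              (uint64_t)(unif_rand() * 4294967296.0));
  PutRNGstate();

  for (int b = 0; b < B; ++b) {
    for (int i = n - 1; i > 0; --i) {
      int j = (int)rng.bounded((uint32_t)(i + 1));
      std::swap(p[i], p[j]);
    }
    double num = 0.0, denom;
    if (effect_scheme) {
      for (int k = 0; k < pz; ++k) t[k] = 0.0;
      for (int i = 0; i < n; ++i) {
        const double xi = px[p[i]];
        num += xi * pey[i];
        const double *qrow = pq + (size_t)i * pz;
        for (int k = 0; k < pz; ++k) t[k] += qrow[k] * xi;
      }
      double q = 0.0;
      for (int k = 0; k < pz; ++k) q += t[k] * t[k];
      denom = ss_x - q;
    } else {
      for (int i = 0; i < n; ++i) num += pey[p[i]] * pmx[i];
      denom = denom_obs;
    }
    if (denom <= tol) { nsing += 1; r += 1; continue; }
    const double beta = num / denom;
    bsum += beta;
    bsumsq += beta * beta;
    if (std::fabs(beta) >= target) r += 1;
  }
  const double m = (double)B - nsing;
  const double perm_sd = m > 1 ?
    std::sqrt(std::max(0.0, (bsumsq - bsum * bsum / m) / (m - 1))) : NA_REAL;
  return List::create(_["r"] = r, _["n_singular"] = nsing,
                      _["perm_sd"] = perm_sd);
}
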