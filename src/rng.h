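#ifndef OLIGOSTORE_RNG_H
#define OLIGOSTORE_RNG_H

#include <cstdint>
#include <cmath>

// Deterministic, platform-independent 64-bit generator (splitmix64).
// Used for every stochastic component implemented in C++ so that results
// are byte-identical across platforms for a fixed integer seed.
struct SplitMix64 {
  uint64_t s;
  explicit SplitMix64(uint64_t seed) : s(seed) {}
  inline uint64_t next() {
    uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  // uniform double in [0, 1)
  inline double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  // uniform integer in [0, n)
  inline uint64_t below(uint64_t n) {
    // multiply-shift; bias is < 2^-64, irrelevant at these scales
    return (uint64_t)(((__uint128_t)next() * n) >> 64);
  }
  // Poisson via Knuth's product method; fine for the small means used here
  inline int poisson(double lambda) {
    if (lambda <= 0.0) return 0;
    double L = std::exp(-lambda), p = 1.0;
    int k = 0;
    do {
      ++k;
      p *= unif();
    } while (p > L);
    return k - 1;
  }
};

inline uint64_t mix64(uint64_t x) {
  x ^= x >> 33;
  x *= 0xFF51AFD7ED558CCDULL;
  x ^= x >> 33;
  x *= 0xC4CEB9FE1A85EC53ULL;
  x ^= x >> 33;
  return x;
}

#endif
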