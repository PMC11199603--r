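#ifndef GENEFOLD_RNG_H
#define GENEFOLD_RNG_H

#include <cstdint>

// Self-contained xoshiro256++ generator. The KMC kernels draw billions of
// variates per run; a local counter-free generator keeps trajectories
// bit-reproducible for a given integer seed, independently of R's RNG state.
struct Xoshiro {
  uint64_t s[4];

  static inline uint64_t splitmix64(uint64_t &x) {
    x += 0x9E3779B97F4A7C15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }

  explicit Xoshiro(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
    // avoid the all-zero state (cannot happen with splitmix64, but cheap)
    if (!(s[0] | s[1] | s[2] | s[3])) s[0] = 1;
  }

  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }

  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }

  // uniform double in [0, 1)
  inline double runif() {
    return (next() >> 11) * 0x1.0p-53;
  }

  // uniform integer in [0, n)
  inline int runif_int(int n) {
    return (int)(runif() * n);
  }
};

#endif
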