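#ifndef ADRNET_RNG_H
#define ADRNET_RNG_H

#include <cstdint>

// Small deterministic PRNG (xorshift128+ seeded via splitmix64), so walk
// sampling and embedding training are reproducible independently of R's
// RNG stream and of each other.
struct XRng {
  uint64_t s0, s1;
  explicit XRng(uint64_t seed) {
    uint64_t z = seed + 0x9E3779B97F4A7C15ULL;
    s0 = splitmix(z);
    s1 = splitmix(z);
    if (s0 == 0 && s1 == 0) s1 = 1;
  }
  static uint64_t splitmix(uint64_t &x) {
    uint64_t z = (x += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  uint64_t next() {
    uint64_t x = s0;
    const uint64_t y = s1;
    s0 = y;
    x ^= x << 23;
    s1 = x ^ y ^ (x >> 17) ^ (y >> 26);
    return s1 + y;
  }
  // uniform double in [0, 1)
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  // uniform integer in [0, n)
  uint64_t below(uint64_t n) { return next() % n; }
};

#endif
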