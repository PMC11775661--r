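#ifndef PBRSIM_PRNG_H
#define PBRSIM_PRNG_H

#include <cstdint>

// Counter-friendly PRNG: a splitmix64 finalizer seeds a xorshift128+ stream.
// Every photon / camera sample gets its own stream derived from
// (seed, band, pixel, sample), so results are bitwise reproducible and
// independent of evaluation order.

static inline uint64_t pbr_mix64(uint64_t z) {
  z += 0x9e3779b97f4a7c15ULL;
  z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
  z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
  return z ^ (z >> 31);
}

struct PbrRng {
  uint64_t s0, s1;
  void seed_from(uint64_t a, uint64_t b, uint64_t c, uint64_t d) {
    uint64_t h = pbr_mix64(a);
    h = pbr_mix64(h ^ pbr_mix64(b + 0x632be59bd9b4e019ULL));
    h = pbr_mix64(h ^ pbr_mix64(c + 0x9e6c63d0876a9a47ULL));
    h = pbr_mix64(h ^ pbr_mix64(d + 0xd1b54a32d192ed03ULL));
    s0 = pbr_mix64(h);
    s1 = pbr_mix64(s0 ^ 0x8cb92ba72f3d8dd7ULL);
    if (s0 == 0 && s1 == 0) s1 = 1;
  }
  inline uint64_t next() {
    uint64_t x = s0, y = s1;
    s0 = y;
    x ^= x << 23;
    s1 = x ^ y ^ (x >> 17) ^ (y >> 26);
    return s1 + y;
  }
  // uniform double in [0, 1)
  inline double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
};

#endif
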