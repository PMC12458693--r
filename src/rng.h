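#ifndef WATNET_RNG_H
#define WATNET_RNG_H

#include <Rcpp.h>
#include <cstdint>
#include <cstring>

// xoshiro256++ with splitmix64 seeding.  Own generator (not R's) so that each
// replica owns an independent, serialisable stream derived from (seed, stream)
// and trajectories are bit-reproducible across platforms.
struct Xoshiro {
  uint64_t s[4];

  static uint64_t splitmix64(uint64_t &x) {
    x += 0x9e3779b97f4a7c15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }

  void seed(uint64_t seed_, uint64_t stream_) {
    uint64_t x = seed_ ^ (0x632be59bd9b4e019ULL * (stream_ + 1));
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
  }

  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }

  uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }

  // uniform in (0,1); never exactly 0 so log(u) is safe
  double runif() {
    double u = (next() >> 11) * 1.1102230246251565e-16; // 2^-53
    return u > 0.0 ? u : 5.0e-324;
  }

  void to_raw(Rcpp::RawVector &rv) const {
    std::memcpy(RAW(rv), s, 32);
  }
  void from_raw(const Rcpp::RawVector &rv) {
    if (rv.size() != 32) Rcpp::stop("rng state must be 32 raw bytes");
    std::memcpy(s, RAW(rv), 32);
  }
};

#endif
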