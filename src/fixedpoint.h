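#ifndef IZHNODE_FIXEDPOINT_H
#define IZHNODE_FIXEDPOINT_H

#include <cstdint>

namespace fx {

constexpr int FRAC = 23;
constexpr int64_t RAW_MAX = (int64_t(1) << 39) - 1;
constexpr int64_t RAW_MIN = -(int64_t(1) << 39);
constexpr double SCALE = 8388608.0; // 2^23

inline int64_t sat(int64_t x, int& satcount) {
  if (x > RAW_MAX) { ++satcount; return RAW_MAX; }
  if (x < RAW_MIN) { ++satcount; return RAW_MIN; }
  return x;
}

inline int64_t add(int64_t a, int64_t b, int& satcount) {
  return sat(a + b, satcount); // |a|,|b| < 2^40: no int64 overflow possible
}

// full-precision product, arithmetic shift right by FRAC (truncation toward
// -inf), then saturation; __int128 holds the 80-bit product exactly
inline int64_t mul(int64_t a, int64_t b, int& satcount) {
  __int128 p = static_cast<__int128>(a) * static_cast<__int128>(b);
  __int128 q = p >> FRAC; // GCC: arithmetic shift == floor division by 2^23
  if (q > RAW_MAX) { ++satcount; return RAW_MAX; }
  if (q < RAW_MIN) { ++satcount; return RAW_MIN; }
  return static_cast<int64_t>(q);
}

int64_t enc(double x);

} // namespace fx

#endif
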