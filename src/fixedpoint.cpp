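// s16.23 fixed-point number system of the node's ODE pipelines.
// Raw values are carried across the R boundary as doubles; |raw| < 2^39 so
// every raw value is exactly representable.
#include <Rcpp.h>
#include <cfenv>
#include <cmath>
#include <cstdint>
#include "fixedpoint.h"

using namespace Rcpp;

namespace fx {

int64_t enc(double x) {
  // round-to-nearest-even, then saturate to the 40-bit range
  double y = std::nearbyint(x * SCALE);
  if (y >= static_cast<double>(RAW_MAX)) return RAW_MAX;
  if (y <= static_cast<double>(RAW_MIN)) return RAW_MIN;
  return static_cast<int64_t>(y);
}

} // namespace fx

static void check_finite(const NumericVector& x, const char* what) {
  for (double v : x)
    if (!R_finite(v)) stop("non-finite value passed to %s", what);
}

// [[Rcpp::export]]
NumericVector fx_encode_cpp(NumericVector x) {
  check_finite(x, "fx_encode");
  NumericVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i)
    out[i] = static_cast<double>(fx::enc(x[i]));
  return out;
}

// [[Rcpp::export]]
NumericVector fx_decode_cpp(NumericVector raw) {
  NumericVector out(raw.size());
  for (R_xlen_t i = 0; i < raw.size(); ++i)
    out[i] = static_cast<double>(static_cast<int64_t>(raw[i])) / fx::SCALE;
  return out;
}

// binary op plumbing: recycle the shorter operand, count saturation events
template <typename Op>
static NumericVector fx_binop(NumericVector a, NumericVector b, Op op) {
  R_xlen_t n = std::max(a.size(), b.size());
  if (n > 0 && (a.size() == 0 || b.size() == 0))
    stop("zero-length operand");
  NumericVector out(n);
  int sat = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    int64_t ra = static_cast<int64_t>(a[i % a.size()]);
    int64_t rb = static_cast<int64_t>(b[i % b.size()]);
    out[i] = static_cast<double>(op(ra, rb, sat));
  }
  out.attr("saturations") = sat;
  return out;
}

// [[Rcpp::export]]
NumericVector fx_add_cpp(NumericVector a, NumericVector b) {
  return fx_binop(a, b, [](int64_t x, int64_t y, int& s) { return fx::add(x, y, s); });
}

// [[Rcpp::export]]
NumericVector fx_sub_cpp(NumericVector a, NumericVector b) {
  return fx_binop(a, b, [](int64_t x, int64_t y, int& s) { return fx::add(x, -y, s); });
}

// [[Rcpp::export]]
NumericVector fx_mul_cpp(NumericVector a, NumericVector b) {
  return fx_binop(a, b, [](int64_t x, int64_t y, int& s) { return fx::mul(x, y, s); });
}
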