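#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// Direct-form-II-transposed biquad with initial state; used by the
// zero-phase filtering pipeline.
// [[Rcpp::export]]
NumericVector biquad_df2t(NumericVector x, NumericVector b, NumericVector a,
                          NumericVector zi) {
  const R_xlen_t n = x.size();
  NumericVector y(n);
  double z1 = zi[0], z2 = zi[1];
  const double b0 = b[0], b1 = b[1], b2 = b[2];
  const double a1 = a[0], a2 = a[1];
  for (R_xlen_t i = 0; i < n; ++i) {
    const double xi = x[i];
    const double yi = b0 * xi + z1;
    z1 = b1 * xi - a1 * yi + z2;
    z2 = b2 * xi - a2 * yi;
    y[i] = yi;
  }
  return y;
}

// ---- integer-only inference kernels -------------------------------------
// All arithmetic below is integer arithmetic: int32 accumulators and an
// int64 product inside the fixed-point requantization, exactly as an
// FPU-less microcontroller would execute the network.

static inline int64_t requant64(int64_t acc, int32_t m0, int n) {
  // round(acc * m0 * 2^-31 * 2^-n), half away from zero.
  int64_t p = acc * (int64_t)m0;
  int shift = 31 + n;
  if (shift <= 0) return p << (-shift);
  const int64_t d = (int64_t)1 << shift;
  const int64_t h = d >> 1;
  return p >= 0 ? (p + h) / d : -((-p + h) / d);
}

static inline int clamp8(int64_t v, int lo) {
  if (v < lo) v = lo;
  if (v < -128) v = -128;
  if (v > 127) v = 127;
  return (int)v;
}

// [[Rcpp::export]]
int requantize_core(double acc, double m0, int n) {
  int64_t r = requant64((int64_t)acc, (int32_t)m0, n);
  if (r > INT32_MAX) r = INT32_MAX;
  if (r < INT32_MIN) r = INT32_MIN;
  return (int)r;
}

// Valid (no padding) stride-1 int8 convolution.  input: T x Cin matrix of
// int8 values; weights: length K*Cin*Cout vector laid out [k, cin, cout]
// (k fastest); bias: int32 per output channel.  ReLU is fused as a clamp
// at the output zero point.
// [[Rcpp::export]]
IntegerMatrix conv1d_int8_core(IntegerMatrix input, IntegerVector weights,
                               IntegerVector bias, int k, int cout,
                               int zp_in, int zp_out, double m0, int nshift,
                               bool relu) {
  const int t_in = input.nrow();
  const int cin = input.ncol();
  const int t_out = t_in - k + 1;
  if (t_out < 1) stop("input shorter than kernel");
  if (weights.size() != (R_xlen_t)k * cin * cout)
    stop("weight size mismatch");
  IntegerMatrix out(t_out, cout);
  const int32_t m0i = (int32_t)m0;
  const int lo = relu ? zp_out : -128;
  for (int o = 0; o < cout; ++o) {
    const int base_o = o * k * cin;
    for (int t = 0; t < t_out; ++t) {
      int32_t acc = bias[o];
      for (int c = 0; c < cin; ++c) {
        const int base = base_o + c * k;
        for (int kk = 0; kk < k; ++kk)
          acc += (input(t + kk, c) - zp_in) * weights[base + kk];
      }
      int64_t q = requant64(acc, m0i, nshift) + zp_out;
      out(t, o) = clamp8(q, lo);
    }
  }
  return out;
}

// Fully connected int8 layer; weights: D x U matrix (column per unit).
// [[Rcpp::export]]
IntegerVector dense_int8_core(IntegerVector input, IntegerMatrix weights,
                              IntegerVector bias, int zp_in, int zp_out,
                              double m0, int nshift, bool relu) {
  const int d = input.size();
  if (weights.nrow() != d) stop("weight/input size mismatch");
  const int u = weights.ncol();
  IntegerVector out(u);
  const int32_t m0i = (int32_t)m0;
  const int lo = relu ? zp_out : -128;
  for (int j = 0; j < u; ++j) {
    int32_t acc = bias[j];
    for (int i = 0; i < d; ++i)
      acc += (input[i] - zp_in) * weights(i, j);
    int64_t q = requant64(acc, m0i, nshift) + zp_out;
    out[j] = clamp8(q, lo);
  }
  return out;
}

// Non-overlapping max pooling over time; quantization parameters pass
// through unchanged.
// [[Rcpp::export]]
IntegerMatrix maxpool_int8_core(IntegerMatrix input, int pool) {
  const int t_in = input.nrow();
  const int c = input.ncol();
  const int t_out = t_in / pool;
  IntegerMatrix out(t_out, c);
  for (int j = 0; j < c; ++j)
    for (int t = 0; t < t_out; ++t) {
      int m = input(t * pool, j);
      for (int p = 1; p < pool; ++p) {
        const int v = input(t * pool + p, j);
        if (v > m) m = v;
      }
      out(t, j) = m;
    }
  return out;
}
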