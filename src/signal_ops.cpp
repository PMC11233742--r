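#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Rational polyphase resampling: y = downsample(conv(upsample(x, p), h), q),
// compensated for the linear-phase delay of h (odd length). Only the taps that
// hit non-zero (stuffed) samples are evaluated, so cost is n_out * L/p.
// [[Rcpp::export]]
NumericVector resample_fir_cpp(NumericVector x, int p, int q, NumericVector h) {
  const R_xlen_t n = x.size();
  const R_xlen_t L = h.size();
  const R_xlen_t half = (L - 1) / 2;
  const R_xlen_t n_out = (R_xlen_t)std::llround((double)n * p / q);
  NumericVector y(n_out);
  for (R_xlen_t m = 0; m < n_out; ++m) {
    const R_xlen_t t = m * (R_xlen_t)q + half; // position on the upsampled grid
    double acc = 0.0;
    for (R_xlen_t j = t % p; j < L; j += p) {
      const R_xlen_t i = (t - j) / p;
      if (i >= 0 && i < n) acc += h[j] * x[i];
    }
    y[m] = acc;
  }
  return y;
}

// Sample-entropy template counts (Richman & Moorman): B = matching pairs of
// length-m templates, A = of length-(m+1), Chebyshev distance <= r, self-matches
// excluded. Template starts run over 0..N-m-1 for both lengths. Pairs are
// enumerated by lag d = j - i: for each lag the boolean sequence
// s_t = [|x_t - x_{t+d}| <= r] is scanned once and every maximal run of
// matches of length L contributes its eligible length-m and length-(m+1)
// windows. Exact, O(N^2) with sequential memory access.
// [[Rcpp::export]]
NumericVector sampen_counts_cpp(NumericVector x, int m, double r) {
  const R_xlen_t N = x.size();
  if (N - m < 2) return NumericVector::create(0.0, 0.0);
  const double *p = &x[0];
  double A = 0.0, B = 0.0;
  for (R_xlen_t d = 1; d <= N - m - 1; ++d) {
    const R_xlen_t tmax = N - d - 1;
    R_xlen_t c = 0;
    double Bd = 0.0, Ad = 0.0;
    for (R_xlen_t t = 0; t <= tmax; ++t) {
      c = (std::fabs(p[t] - p[t + d]) <= r) ? c + 1 : 0;
      if (c >= m) {            // a length-m window of matches ends at t
        Bd += (t < tmax);      // template start i = t-m+1 must be <= N-m-1-d
        Ad += (c > m);
      }
    }
    B += Bd; A += Ad;
  }
  return NumericVector::create(B, A);
}

// LZ76 exhaustive-history parsing (Kaspar & Schuster 1987): number of phrases
// c(n) of a binary sequence.
// [[Rcpp::export]]
int lz76_cpp(IntegerVector s) {
  const int n = s.size();
  if (n == 0) return 0;
  int i = 0, c = 1, u = 1, v = 1, vmax = 1;
  while (u + v <= n) {
    if (s[i + v - 1] == s[u + v - 1]) {
      ++v;
    } else {
      vmax = std::max(v, vmax);
      ++i;
      if (i == u) { // all history scanned: new phrase
        ++c;
        u += vmax;
        v = 1; i = 0; vmax = 1;
      } else {
        v = 1;
      }
    }
  }
  if (v != 1) ++c;
  return c;
}
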