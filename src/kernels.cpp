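#define USE_FC_LEN_T
#include <Rcpp.h>
#include <R_ext/BLAS.h>
#include <cmath>
#include <vector>
#ifndef FCONE
#define FCONE
#endif
using namespace Rcpp;

// Same-padding k x k convolution on (H, W, B, C) tensors, column-major.
//
// The input is copied once onto a zero-padded (H+2p, W+2p, B, C) grid.  On
// that grid, the neighbour at kernel tap (kh, kw) of every pixel sits at a
// fixed linear offset (kh - p) + Hp * (kw - p) in the flattened (Hp, Wp, B)
// block, so the whole convolution is k^2 dgemm calls on pointer-shifted
// views of the padded tensor -- no im2col buffer is ever materialised.
// Shifted reads that stray outside a channel column land either in padding
// (zero) or in guard slack at the buffer ends; both only influence padded
// output rows, which are cropped.  The weight matrix has k*k*C rows ordered
// (kh, kw, c) and Cout columns, so tap (kh, kw) is a C x Cout submatrix
// with leading dimension k*k.

struct PadSpec {
  int H, W, B, C, k, p, Hp, Wp;
  R_xlen_t N;   // padded rows per channel
  R_xlen_t G;   // guard rows at each buffer end
};

static PadSpec pad_spec(int H, int W, int B, int C, int k) {
  PadSpec s;
  s.H = H; s.W = W; s.B = B; s.C = C; s.k = k; s.p = (k - 1) / 2;
  s.Hp = H + 2 * s.p; s.Wp = W + 2 * s.p;
  s.N = (R_xlen_t)s.Hp * s.Wp * B;
  s.G = (R_xlen_t)s.p * (1 + s.Hp) + 8;
  return s;
}

// copy (H, W, B, C) -> guarded zero-padded buffer, returning base pointer
static std::vector<double> pad_in(const double* x, const PadSpec& s) {
  std::vector<double> buf(s.N * s.C + 2 * s.G, 0.0);
  double* P = buf.data() + s.G;
  for (int c = 0; c < s.C; ++c)
    for (int b = 0; b < s.B; ++b)
      for (int w = 0; w < s.W; ++w) {
        const double* src = x + (R_xlen_t)s.H * (w + (R_xlen_t)s.W * (b + (R_xlen_t)s.B * c));
        double* dst = P + s.N * c + (R_xlen_t)s.Hp * ((w + s.p) + (R_xlen_t)s.Wp * b) + s.p;
        std::copy(src, src + s.H, dst);
      }
  return buf;
}

static void crop_out(const double* P, const PadSpec& s, int C, double* y) {
  for (int c = 0; c < C; ++c)
    for (int b = 0; b < s.B; ++b)
      for (int w = 0; w < s.W; ++w) {
        const double* src = P + s.N * c + (R_xlen_t)s.Hp * ((w + s.p) + (R_xlen_t)s.Wp * b) + s.p;
        double* dst = y + (R_xlen_t)s.H * (w + (R_xlen_t)s.W * (b + (R_xlen_t)s.B * c));
        std::copy(src, src + s.H, dst);
      }
}

// [[Rcpp::export]]
NumericVector conv2d_same_fwd(NumericVector x, int H, int W, int B, int C,
                              NumericMatrix Wm, NumericVector bias, int k) {
  const PadSpec s = pad_spec(H, W, B, C, k);
  const int Cout = Wm.ncol();
  const int k2 = k * k;
  std::vector<double> xb = pad_in(x.begin(), s);
  std::vector<double> yb(s.N * Cout + 2 * s.G, 0.0);
  double* Xp = xb.data() + s.G;
  double* Yp = yb.data() + s.G;
  for (int c = 0; c < Cout; ++c)
    std::fill(Yp + s.N * c, Yp + s.N * (c + 1), bias[c]);
  const int M = (int)s.N;
  const double one = 1.0;
  std::vector<double> Wtap((size_t)C * Cout);
  for (int kw = 0; kw < k; ++kw)
    for (int kh = 0; kh < k; ++kh) {
      const R_xlen_t off = (R_xlen_t)(kh - s.p) + (R_xlen_t)s.Hp * (kw - s.p);
      const double* A = Xp + off;
      for (int co = 0; co < Cout; ++co)
        for (int c = 0; c < C; ++c)
          Wtap[(size_t)c + (size_t)C * co] =
              Wm[(R_xlen_t)(kh + k * kw + k2 * c) + (R_xlen_t)k2 * C * co];
      F77_CALL(dgemm)("N", "N", &M, &Cout, &C, &one, A, &M, Wtap.data(), &C,
                      &one, Yp, &M FCONE FCONE);
    }
  NumericVector y((R_xlen_t)H * W * B * Cout);
  crop_out(Yp, s, Cout, y.begin());
  y.attr("dim") = IntegerVector::create(H, W, B, Cout);
  return y;
}

// [[Rcpp::export]]
List conv2d_same_bwd(NumericVector dy, NumericVector x, int H, int W, int B,
                     int C, NumericMatrix Wm, int k) {
  const PadSpec s = pad_spec(H, W, B, C, k);
  const int Cout = Wm.ncol();
  const int k2 = k * k;
  std::vector<double> xb = pad_in(x.begin(), s);
  // dy padded on the same grid (zeros in the pad ring kill stray products)
  PadSpec sy = s; sy.C = Cout;
  std::vector<double> dyb = pad_in(dy.begin(), sy);
  std::vector<double> dxb(s.N * C + 2 * s.G, 0.0);
  double* Xp = xb.data() + s.G;
  double* dYp = dyb.data() + s.G;
  double* dXp = dxb.data() + s.G;
  NumericMatrix dW(k2 * C, Cout);
  const int M = (int)s.N;
  const double one = 1.0, zero = 0.0;
  std::vector<double> Wtap((size_t)C * Cout), dWtap((size_t)C * Cout);
  for (int kw = 0; kw < k; ++kw)
    for (int kh = 0; kh < k; ++kh) {
      const R_xlen_t off = (R_xlen_t)(kh - s.p) + (R_xlen_t)s.Hp * (kw - s.p);
      for (int co = 0; co < Cout; ++co)
        for (int c = 0; c < C; ++c)
          Wtap[(size_t)c + (size_t)C * co] =
              Wm[(R_xlen_t)(kh + k * kw + k2 * c) + (R_xlen_t)k2 * C * co];
      // dX(r + off) += dY(r) * W_tap^T
      F77_CALL(dgemm)("N", "T", &M, &C, &Cout, &one, dYp, &M, Wtap.data(), &C,
                      &one, dXp + off, &M FCONE FCONE);
      // dW_tap = X(r + off)^T * dY(r)
      F77_CALL(dgemm)("T", "N", &C, &Cout, &M, &one, Xp + off, &M, dYp, &M,
                      &zero, dWtap.data(), &C FCONE FCONE);
      for (int co = 0; co < Cout; ++co)
        for (int c = 0; c < C; ++c)
          dW[(R_xlen_t)(kh + k * kw + k2 * c) + (R_xlen_t)k2 * C * co] =
              dWtap[(size_t)c + (size_t)C * co];
    }
  NumericVector dx((R_xlen_t)H * W * B * C);
  crop_out(dXp, s, C, dx.begin());
  dx.attr("dim") = IntegerVector::create(H, W, B, C);
  NumericVector db(Cout);
  const double* pdy = dy.begin();
  const R_xlen_t n = (R_xlen_t)H * W * B;
  for (int c = 0; c < Cout; ++c) {
    double acc = 0.0;
    const double* col = pdy + n * c;
    for (R_xlen_t i = 0; i < n; ++i) acc += col[i];
    db[c] = acc;
  }
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

static inline int reflect_idx(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i;
    if (i >= n) i = 2 * n - 2 - i;
  }
  return i;
}

// Fast non-local means on a single-channel image (column-major H x W).
// For every translation t in the search window the squared-difference image
// is box-filtered with an integral image, giving the patch distance D(p, t)
// in O(1) per pixel; weights are exp(-D / h^2) with the identity translation
// contributing weight 1.  Overall cost O(N * search^2), independent of the
// template size.

// [[Rcpp::export]]
NumericVector nlm_denoise_cpp(NumericVector img, int H, int W,
                              double h, int template_window,
                              int search_window) {
  const int th = template_window / 2, sh = search_window / 2;
  const int pad = th + sh;
  const int PH = H + 2 * pad, PW = W + 2 * pad;
  std::vector<double> P((size_t)PH * PW);
  for (int w = 0; w < PW; ++w) {
    const int sw = reflect_idx(w - pad, W);
    for (int hh = 0; hh < PH; ++hh)
      P[(size_t)hh + (size_t)PH * w] =
          img[(R_xlen_t)reflect_idx(hh - pad, H) + (R_xlen_t)H * sw];
  }
  std::vector<double> num((size_t)H * W, 0.0), den((size_t)H * W, 0.0);
  // exp(-z) lookup: z quantised in steps of 1/256 up to 48 (weights below
  // exp(-48) are indistinguishable from zero)
  const int LN = 48 * 256;
  std::vector<double> lut(LN + 1);
  for (int i = 0; i <= LN; ++i) lut[i] = std::exp(-i / 256.0);
  const double patch_n = (double)template_window * template_window;
  const double zscale = 256.0 / (h * h * patch_n);
  // box sums needed at interior pixels span padded rows/cols
  // [pad - th, pad + H + th); within that band every shifted read stays
  // inside the padded image, so the loops are branch-free
  const int RH = H + 2 * th, RW = W + 2 * th;
  std::vector<double> integ((size_t)(RH + 1) * (RW + 1), 0.0);
  const int r0 = pad - th;
  for (int dx = -sh; dx <= sh; ++dx) {
    for (int dy = -sh; dy <= sh; ++dy) {
      if (dx == 0 && dy == 0) continue;
      // fused squared-difference + integral image over the band
      for (int w = 1; w <= RW; ++w) {
        const double* c0 = P.data() + (size_t)PH * (r0 + w - 1) + r0;
        const double* c1 = P.data() + (size_t)PH * (r0 + w - 1 + dx) + r0 + dy;
        const double* prev = integ.data() + (size_t)(RH + 1) * (w - 1);
        double* cur = integ.data() + (size_t)(RH + 1) * w;
        double colsum = 0.0;
        cur[0] = 0.0;
        for (int y = 1; y <= RH; ++y) {
          const double v = c0[y - 1] - c1[y - 1];
          colsum += v * v;
          cur[y] = prev[y] + colsum;
        }
      }
      const int tw = 2 * th + 1;
      for (int w = 0; w < W; ++w) {
        const double* iw1 = integ.data() + (size_t)(RH + 1) * (w + tw);
        const double* iw0 = integ.data() + (size_t)(RH + 1) * w;
        const double* Pq = P.data() + (size_t)PH * (w + pad + dx) + pad + dy;
        double* np = num.data() + (size_t)H * w;
        double* dp = den.data() + (size_t)H * w;
        for (int y = 0; y < H; ++y) {
          const double ssd = iw1[y + tw] - iw1[y] - iw0[y + tw] + iw0[y];
          const double z = ssd * zscale;
          const double wgt = (z >= LN) ? 0.0 : lut[(int)z];
          np[y] += wgt * Pq[y];
          dp[y] += wgt;
        }
      }
    }
  }
  NumericVector out((R_xlen_t)H * W);
  for (int w = 0; w < W; ++w)
    for (int y = 0; y < H; ++y) {
      const size_t i = (size_t)y + (size_t)H * w;
      out[i] = (num[i] + img[i]) / (den[i] + 1.0);
    }
  return out;
}
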