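// Numerical kernels: batched single-precision conv/pool/upsample primitives
// for the U-Net, plus double-precision image filtering, resampling and the
// analytic structured-light renderer.
#include <RcppArmadillo.h>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// helpers
// ---------------------------------------------------------------------------

static inline IntegerVector dims_of(const NumericVector& x, int need) {
  IntegerVector d = x.attr("dim");
  if (d.size() != need) stop("array with %d dimensions expected", need);
  return d;
}

static inline NumericVector alloc4(int a, int b, int c, int d) {
  NumericVector out((R_xlen_t)a * b * c * d);
  out.attr("dim") = IntegerVector::create(a, b, c, d);
  return out;
}

// reflect (symmetric) border index: (-1 -> 0, -2 -> 1, n -> n-1, ...)
static inline int reflect_idx(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -1 - i;
    if (i >= n) i = 2 * n - 1 - i;
  }
  return i;
}

static inline int clamp_idx(int i, int n) {
  return i < 0 ? 0 : (i >= n ? n - 1 : i);
}

// Catmull-Rom weights at fractional offset t for taps i0-1..i0+2
static inline void catmull_rom(double t, double w[4]) {
  double t2 = t * t, t3 = t2 * t;
  w[0] = -0.5 * t3 + t2 - 0.5 * t;
  w[1] = 1.5 * t3 - 2.5 * t2 + 1.0;
  w[2] = -1.5 * t3 + 2.0 * t2 + 0.5 * t;
  w[3] = 0.5 * t3 - 0.5 * t2;
}

// ---------------------------------------------------------------------------
// 3x3 convolution (zero padding 1), batched: x is H x W x C x B
// weights W: (9*Cin) x Cout (column-major flat of a (3,3,Cin,Cout) R array)
// ---------------------------------------------------------------------------

static void im2col3(const double* x, int H, int W, int C, int B,
                    arma::fmat& col) {
  const int HW = H * W;
  for (int b = 0; b < B; ++b) {
    for (int c = 0; c < C; ++c) {
      const double* xp = x + (size_t)HW * (c + (size_t)C * b);
      for (int kx = -1; kx <= 1; ++kx) {
        for (int ky = -1; ky <= 1; ++ky) {
          int row = (ky + 1) + 3 * (kx + 1) + 9 * c;
          for (int j = 0; j < W; ++j) {
            int js = j + kx;
            size_t colbase = (size_t)HW * b + (size_t)H * j;
            if (js < 0 || js >= W) {
              for (int i = 0; i < H; ++i) col(row, colbase + i) = 0.0f;
            } else {
              const double* src = xp + (size_t)H * js;
              for (int i = 0; i < H; ++i) {
                int is = i + ky;
                col(row, colbase + i) =
                  (is < 0 || is >= H) ? 0.0f : (float)src[is];
              }
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv3x3_fwd(NumericVector x, NumericVector w,
                              NumericVector bias) {
  IntegerVector d = dims_of(x, 4);
  int H = d[0], W = d[1], C = d[2], B = d[3];
  IntegerVector dw = dims_of(w, 4);  // (3,3,Cin,Cout)
  if (dw[0] != 3 || dw[1] != 3 || dw[2] != C) stop("weight shape mismatch");
  int Cout = dw[3];
  const int K = 9 * C;
  arma::fmat Wf(K, Cout);
  for (int i = 0; i < K * Cout; ++i) Wf[i] = (float)w[i];
  arma::fmat col(K, (size_t)H * W * B);
  im2col3(x.begin(), H, W, C, B, col);
  arma::fmat y = Wf.t() * col;  // Cout x HWB
  NumericVector out = alloc4(H, W, Cout, B);
  const int HW = H * W;
  for (int b = 0; b < B; ++b)
    for (int o = 0; o < Cout; ++o) {
      double bo = bias[o];
      double* op = out.begin() + (size_t)HW * (o + (size_t)Cout * b);
      const size_t pbase = (size_t)HW * b;
      for (int p = 0; p < HW; ++p) op[p] = (double)y(o, pbase + p) + bo;
    }
  return out;
}

// [[Rcpp::export]]
List cpp_conv3x3_bwd(NumericVector x, NumericVector w, NumericVector gy) {
  IntegerVector d = dims_of(x, 4);
  int H = d[0], W = d[1], C = d[2], B = d[3];
  IntegerVector dw = dims_of(w, 4);
  int Cout = dw[3];
  const int K = 9 * C;
  const int HW = H * W;
  arma::fmat Wf(K, Cout);
  for (int i = 0; i < K * Cout; ++i) Wf[i] = (float)w[i];
  arma::fmat col(K, (size_t)HW * B);
  im2col3(x.begin(), H, W, C, B, col);
  // gy as Cout x HWB
  arma::fmat G(Cout, (size_t)HW * B);
  for (int b = 0; b < B; ++b)
    for (int o = 0; o < Cout; ++o) {
      const double* gp = gy.begin() + (size_t)HW * (o + (size_t)Cout * b);
      const size_t pbase = (size_t)HW * b;
      for (int p = 0; p < HW; ++p) G(o, pbase + p) = (float)gp[p];
    }
  arma::fmat gW = col * G.t();       // K x Cout
  arma::fvec gb = arma::sum(G, 1);   // Cout
  arma::fmat gcol = Wf * G;          // K x HWB
  NumericVector gx = alloc4(H, W, C, B);
  double* gxp = gx.begin();
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c)
      for (int kx = -1; kx <= 1; ++kx)
        for (int ky = -1; ky <= 1; ++ky) {
          int row = (ky + 1) + 3 * (kx + 1) + 9 * c;
          double* gplane = gxp + (size_t)HW * (c + (size_t)C * b);
          for (int j = 0; j < W; ++j) {
            int js = j + kx;
            if (js < 0 || js >= W) continue;
            const size_t colbase = (size_t)HW * b + (size_t)H * j;
            double* gcolumn = gplane + (size_t)H * js;
            for (int i = 0; i < H; ++i) {
              int is = i + ky;
              if (is < 0 || is >= H) continue;
              gcolumn[is] += (double)gcol(row, colbase + i);
            }
          }
        }
  NumericVector gWout = alloc4(3, 3, C, Cout);
  for (int i = 0; i < K * Cout; ++i) gWout[i] = gW[i];
  NumericVector gbout(Cout);
  for (int o = 0; o < Cout; ++o) gbout[o] = gb[o];
  return List::create(_["gx"] = gx, _["gw"] = gWout, _["gb"] = gbout);
}

// ---------------------------------------------------------------------------
// 1x1 convolution (channel mixing): weights (Cin, Cout)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_conv1x1_fwd(NumericVector x, NumericMatrix w,
                              NumericVector bias) {
  IntegerVector d = dims_of(x, 4);
  int H = d[0], W = d[1], C = d[2], B = d[3];
  if (w.nrow() != C) stop("weight shape mismatch");
  int Cout = w.ncol();
  const int HW = H * W;
  NumericVector out = alloc4(H, W, Cout, B);
  for (int b = 0; b < B; ++b)
    for (int o = 0; o < Cout; ++o) {
      double* op = out.begin() + (size_t)HW * (o + (size_t)Cout * b);
      for (int p = 0; p < HW; ++p) op[p] = bias[o];
      for (int c = 0; c < C; ++c) {
        double wc = w(c, o);
        if (wc == 0.0) continue;
        const double* xp = x.begin() + (size_t)HW * (c + (size_t)C * b);
        for (int p = 0; p < HW; ++p) op[p] += wc * xp[p];
      }
    }
  return out;
}

// [[Rcpp::export]]
List cpp_conv1x1_bwd(NumericVector x, NumericMatrix w, NumericVector gy) {
  IntegerVector d = dims_of(x, 4);
  int H = d[0], W = d[1], C = d[2], B = d[3];
  int Cout = w.ncol();
  const int HW = H * W;
  NumericVector gx = alloc4(H, W, C, B);
  NumericMatrix gW(C, Cout);
  NumericVector gb(Cout);
  for (int b = 0; b < B; ++b)
    for (int o = 0; o < Cout; ++o) {
      const double* gp = gy.begin() + (size_t)HW * (o + (size_t)Cout * b);
      double acc = 0.0;
      for (int p = 0; p < HW; ++p) acc += gp[p];
      gb[o] += acc;
      for (int c = 0; c < C; ++c) {
        const double* xp = x.begin() + (size_t)HW * (c + (size_t)C * b);
        double* gxp = gx.begin() + (size_t)HW * (c + (size_t)C * b);
        double wc = w(c, o), gw = 0.0;
        for (int p = 0; p < HW; ++p) {
          gw += xp[p] * gp[p];
          gxp[p] += wc * gp[p];
        }
        gW(c, o) += gw;
      }
    }
  return List::create(_["gx"] = gx, _["gw"] = gW, _["gb"] = gb);
}

// ---------------------------------------------------------------------------
// 2x2 max pooling
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_maxpool2_fwd(NumericVector x) {
  IntegerVector d = dims_of(x, 4);
  int H = d[0], W = d[1], C = d[2], B = d[3];
  if (H % 2 || W % 2) stop("maxpool needs even spatial dims");
  int H2 = H / 2, W2 = W / 2;
  NumericVector y = alloc4(H2, W2, C, B);
  IntegerVector idx((size_t)H2 * W2 * C * B);
  size_t q = 0;
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c) {
      const double* xp = x.begin() + (size_t)H * W * (c + (size_t)C * b);
      for (int j = 0; j < W2; ++j)
        for (int i = 0; i < H2; ++i) {
          size_t p00 = (size_t)(2 * i) + (size_t)H * (2 * j);
          size_t best = p00;
          double v = xp[p00];
          size_t cand[3] = {p00 + 1, p00 + (size_t)H, p00 + (size_t)H + 1};
          for (int k = 0; k < 3; ++k)
            if (xp[cand[k]] > v) { v = xp[cand[k]]; best = cand[k]; }
          y[(size_t)i + (size_t)H2 * j +
            (size_t)H2 * W2 * (c + (size_t)C * b)] = v;
          idx[q++] = (int)(best + (size_t)H * W * (c + (size_t)C * b));
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_bwd(IntegerVector idx, NumericVector gy,
                               int H, int W) {
  IntegerVector d = dims_of(gy, 4);
  int C = d[2], B = d[3];
  NumericVector gx = alloc4(H, W, C, B);
  size_t n = gy.size();
  // outputs are visited in storage order by construction of idx
  size_t q = 0;
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c)
      for (int j = 0; j < d[1]; ++j)
        for (int i = 0; i < d[0]; ++i) {
          size_t yo = (size_t)i + (size_t)d[0] * j +
                      (size_t)d[0] * d[1] * (c + (size_t)C * b);
          gx[idx[q]] += gy[yo];
          ++q;
        }
  if (q != n) stop("maxpool bwd size mismatch");
  return gx;
}

// ---------------------------------------------------------------------------
// bicubic x2 upsampling (Catmull-Rom, half-pixel centers, clamped border)
// and its adjoint
// ---------------------------------------------------------------------------

static void up2_1d_weights(int o, int n, int taps[4], double w[4]) {
  // src coordinate of output sample o: (o + 0.5)/2 - 0.5
  int k = o / 2;
  double t;
  int i0;
  if (o % 2 == 0) { i0 = k - 1; t = 0.75; } else { i0 = k; t = 0.25; }
  catmull_rom(t, w);
  for (int m = 0; m < 4; ++m) taps[m] = clamp_idx(i0 - 1 + m, n);
}

// [[Rcpp::export]]
NumericVector cpp_upsample2_fwd(NumericVector x) {
  IntegerVector d = dims_of(x, 4);
  int H = d[0], W = d[1], C = d[2], B = d[3];
  int H2 = 2 * H, W2 = 2 * W;
  // precompute row/col taps
  std::vector<int> rt(4 * H2), ct(4 * W2);
  std::vector<double> rw(4 * H2), cw(4 * W2);
  for (int o = 0; o < H2; ++o) up2_1d_weights(o, H, &rt[4 * o], &rw[4 * o]);
  for (int o = 0; o < W2; ++o) up2_1d_weights(o, W, &ct[4 * o], &cw[4 * o]);
  NumericVector out = alloc4(H2, W2, C, B);
  std::vector<double> tmp((size_t)H2 * W);
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c) {
      const double* xp = x.begin() + (size_t)H * W * (c + (size_t)C * b);
      // rows
      for (int j = 0; j < W; ++j) {
        const double* colp = xp + (size_t)H * j;
        for (int o = 0; o < H2; ++o) {
          const int* tp = &rt[4 * o];
          const double* wp = &rw[4 * o];
          tmp[(size_t)o + (size_t)H2 * j] =
            wp[0] * colp[tp[0]] + wp[1] * colp[tp[1]] +
            wp[2] * colp[tp[2]] + wp[3] * colp[tp[3]];
        }
      }
      // cols
      double* op = out.begin() + (size_t)H2 * W2 * (c + (size_t)C * b);
      for (int o = 0; o < W2; ++o) {
        const int* tp = &ct[4 * o];
        const double* wp = &cw[4 * o];
        const double* s0 = &tmp[(size_t)H2 * tp[0]];
        const double* s1 = &tmp[(size_t)H2 * tp[1]];
        const double* s2 = &tmp[(size_t)H2 * tp[2]];
        const double* s3 = &tmp[(size_t)H2 * tp[3]];
        double* oc = op + (size_t)H2 * o;
        for (int i = 0; i < H2; ++i)
          oc[i] = wp[0] * s0[i] + wp[1] * s1[i] + wp[2] * s2[i] +
                  wp[3] * s3[i];
      }
    }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_upsample2_bwd(NumericVector gy) {
  IntegerVector d = dims_of(gy, 4);
  int H2 = d[0], W2 = d[1], C = d[2], B = d[3];
  int H = H2 / 2, W = W2 / 2;
  std::vector<int> rt(4 * H2), ct(4 * W2);
  std::vector<double> rw(4 * H2), cw(4 * W2);
  for (int o = 0; o < H2; ++o) up2_1d_weights(o, H, &rt[4 * o], &rw[4 * o]);
  for (int o = 0; o < W2; ++o) up2_1d_weights(o, W, &ct[4 * o], &cw[4 * o]);
  NumericVector gx = alloc4(H, W, C, B);
  std::vector<double> tmp((size_t)H2 * W);
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c) {
      const double* gp = gy.begin() + (size_t)H2 * W2 * (c + (size_t)C * b);
      std::fill(tmp.begin(), tmp.end(), 0.0);
      // adjoint of column pass: scatter columns
      for (int o = 0; o < W2; ++o) {
        const int* tp = &ct[4 * o];
        const double* wp = &cw[4 * o];
        const double* gc = gp + (size_t)H2 * o;
        for (int m = 0; m < 4; ++m) {
          double* dst = &tmp[(size_t)H2 * tp[m]];
          double wm = wp[m];
          for (int i = 0; i < H2; ++i) dst[i] += wm * gc[i];
        }
      }
      // adjoint of row pass
      double* gxp = gx.begin() + (size_t)H * W * (c + (size_t)C * b);
      for (int j = 0; j < W; ++j) {
        const double* tc = &tmp[(size_t)H2 * j];
        double* dst = gxp + (size_t)H * j;
        for (int o = 0; o < H2; ++o) {
          const int* tp = &rt[4 * o];
          const double* wp = &rw[4 * o];
          double g = tc[o];
          dst[tp[0]] += wp[0] * g;
          dst[tp[1]] += wp[1] * g;
          dst[tp[2]] += wp[2] * g;
          dst[tp[3]] += wp[3] * g;
        }
      }
    }
  return gx;
}


// workspace-caching variants: the forward pass returns the im2col matrix as
// an external pointer so the backward pass need not rebuild it
// [[Rcpp::export]]
List cpp_conv3x3_fwd_ws(NumericVector x, NumericVector w,
                        NumericVector bias) {
  IntegerVector d = dims_of(x, 4);
  int H = d[0], W = d[1], C = d[2], B = d[3];
  IntegerVector dw = dims_of(w, 4);
  if (dw[0] != 3 || dw[1] != 3 || dw[2] != C) stop("weight shape mismatch");
  int Cout = dw[3];
  const int K = 9 * C;
  arma::fmat Wf(K, Cout);
  for (int i = 0; i < K * Cout; ++i) Wf[i] = (float)w[i];
  XPtr<arma::fmat> ws(new arma::fmat(K, (size_t)H * W * B), true);
  im2col3(x.begin(), H, W, C, B, *ws);
  arma::fmat y = Wf.t() * (*ws);
  NumericVector out = alloc4(H, W, Cout, B);
  const int HW = H * W;
  for (int b = 0; b < B; ++b)
    for (int o = 0; o < Cout; ++o) {
      double bo = bias[o];
      double* op = out.begin() + (size_t)HW * (o + (size_t)Cout * b);
      const size_t pbase = (size_t)HW * b;
      for (int p = 0; p < HW; ++p) op[p] = (double)y(o, pbase + p) + bo;
    }
  return List::create(_["y"] = out, _["ws"] = ws);
}

// [[Rcpp::export]]
List cpp_conv3x3_bwd_ws(SEXP wsSexp, NumericVector w, NumericVector gy,
                        bool wantGx) {
  XPtr<arma::fmat> ws(wsSexp);
  IntegerVector dg = dims_of(gy, 4);
  int H = dg[0], W = dg[1], Cout = dg[2], B = dg[3];
  IntegerVector dw = dims_of(w, 4);
  int C = dw[2];
  const int K = 9 * C;
  const int HW = H * W;
  arma::fmat G(Cout, (size_t)HW * B);
  for (int b = 0; b < B; ++b)
    for (int o = 0; o < Cout; ++o) {
      const double* gp = gy.begin() + (size_t)HW * (o + (size_t)Cout * b);
      const size_t pbase = (size_t)HW * b;
      for (int p = 0; p < HW; ++p) G(o, pbase + p) = (float)gp[p];
    }
  arma::fmat gW = (*ws) * G.t();
  arma::fvec gb = arma::sum(G, 1);
  NumericVector gWout = alloc4(3, 3, C, Cout);
  for (int i = 0; i < K * Cout; ++i) gWout[i] = gW[i];
  NumericVector gbout(Cout);
  for (int o = 0; o < Cout; ++o) gbout[o] = gb[o];
  if (!wantGx)
    return List::create(_["gw"] = gWout, _["gb"] = gbout);
  arma::fmat Wf(K, Cout);
  for (int i = 0; i < K * Cout; ++i) Wf[i] = (float)w[i];
  arma::fmat gcol = Wf * G;
  NumericVector gx = alloc4(H, W, C, B);
  double* gxp = gx.begin();
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c)
      for (int kx = -1; kx <= 1; ++kx)
        for (int ky = -1; ky <= 1; ++ky) {
          int row = (ky + 1) + 3 * (kx + 1) + 9 * c;
          double* gplane = gxp + (size_t)HW * (c + (size_t)C * b);
          for (int j = 0; j < W; ++j) {
            int js = j + kx;
            if (js < 0 || js >= W) continue;
            const size_t colbase = (size_t)HW * b + (size_t)H * j;
            double* gcolumn = gplane + (size_t)H * js;
            for (int i = 0; i < H; ++i) {
              int is = i + ky;
              if (is < 0 || is >= H) continue;
              gcolumn[is] += (double)gcol(row, colbase + i);
            }
          }
        }
  return List::create(_["gx"] = gx, _["gw"] = gWout, _["gb"] = gbout);
}

// ---------------------------------------------------------------------------
// separable Gaussian filter, reflective border (double precision)

// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix cpp_gauss_filter(NumericMatrix x, double sigma, int ksize) {
  if (ksize % 2 != 1 || ksize < 1) stop("kernel size must be odd");
  int H = x.nrow(), W = x.ncol();
  if (ksize > H || ksize > W) stop("window larger than image");
  int r = ksize / 2;
  std::vector<double> k(ksize);
  double s = 0.0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * (double)i * i / (sigma * sigma));
    s += k[i + r];
  }
  for (int i = 0; i < ksize; ++i) k[i] /= s;
  NumericMatrix tmp(H, W), out(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      double acc = 0.0;
      for (int m = -r; m <= r; ++m)
        acc += k[m + r] * x(reflect_idx(i + m, H), j);
      tmp(i, j) = acc;
    }
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      double acc = 0.0;
      for (int m = -r; m <= r; ++m)
        acc += k[m + r] * tmp(i, reflect_idx(j + m, W));
      out(i, j) = acc;
    }
  return out;
}

// ---------------------------------------------------------------------------
// general bicubic resize (Catmull-Rom, half-pixel centers, clamped border)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix cpp_resize_bicubic(NumericMatrix x, int H2, int W2) {
  int H = x.nrow(), W = x.ncol();
  NumericMatrix tmp(H2, W), out(H2, W2);
  double sr = (double)H / H2, sc = (double)W / W2;
  for (int o = 0; o < H2; ++o) {
    double s = (o + 0.5) * sr - 0.5;
    int i0 = (int)std::floor(s);
    double w[4];
    catmull_rom(s - i0, w);
    int t0 = clamp_idx(i0 - 1, H), t1 = clamp_idx(i0, H),
        t2 = clamp_idx(i0 + 1, H), t3 = clamp_idx(i0 + 2, H);
    for (int j = 0; j < W; ++j)
      tmp(o, j) = w[0] * x(t0, j) + w[1] * x(t1, j) + w[2] * x(t2, j) +
                  w[3] * x(t3, j);
  }
  for (int o = 0; o < W2; ++o) {
    double s = (o + 0.5) * sc - 0.5;
    int j0 = (int)std::floor(s);
    double w[4];
    catmull_rom(s - j0, w);
    int t0 = clamp_idx(j0 - 1, W), t1 = clamp_idx(j0, W),
        t2 = clamp_idx(j0 + 1, W), t3 = clamp_idx(j0 + 2, W);
    for (int i = 0; i < H2; ++i)
      out(i, o) = w[0] * tmp(i, t0) + w[1] * tmp(i, t1) + w[2] * tmp(i, t2) +
                  w[3] * tmp(i, t3);
  }
  return out;
}

// ---------------------------------------------------------------------------
// bilinear sampling of a pattern image at fractional (col,row) positions;
// positions outside the pattern get ambient 0
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix cpp_bilinear_sample(NumericMatrix img, NumericMatrix X,
                                  NumericMatrix Y) {
  int H = img.nrow(), W = img.ncol();
  int n = X.nrow(), m = X.ncol();
  NumericMatrix out(n, m);
  for (int j = 0; j < m; ++j)
    for (int i = 0; i < n; ++i) {
      double u = X(i, j), v = Y(i, j);  // u: column, v: row (0-based)
      if (!(u >= 0.0 && u <= W - 1.0 && v >= 0.0 && v <= H - 1.0)) {
        out(i, j) = 0.0;
        continue;
      }
      int u0 = (int)std::floor(u), v0 = (int)std::floor(v);
      int u1 = std::min(u0 + 1, W - 1), v1 = std::min(v0 + 1, H - 1);
      double fu = u - u0, fv = v - v0;
      out(i, j) = (1 - fv) * ((1 - fu) * img(v0, u0) + fu * img(v0, u1)) +
                  fv * ((1 - fu) * img(v1, u0) + fu * img(v1, u1));
    }
  return out;
}

// ---------------------------------------------------------------------------
// analytic renderer geometry pass: ray-march a posed diamond heightfield in
// front of a frontal background plane. Camera at the origin looking along +z;
// rays are parameterised by their z coordinate so depth is the z-distance.
// ---------------------------------------------------------------------------

struct Surf {
  double a;        // diamond half-diagonal (mm)
  double amp;      // dome amplitude (mm)
  const double* pert;  // k x 4 matrix: amp, fx, fy, phase
  int npert;
};

// height (mm, toward the camera) in local surface coordinates
static inline double surf_height(const Surf& s, double x, double y) {
  double mdist = (std::fabs(x) + std::fabs(y)) / s.a;
  if (mdist >= 1.0) return 0.0;
  double cenv = std::cos(M_PI_2 * mdist);
  double env = cenv * cenv;
  double h = s.amp;
  for (int k = 0; k < s.npert; ++k) {
    double pa = s.pert[k];
    double fx = s.pert[k + s.npert];
    double fy = s.pert[k + 2 * s.npert];
    double ph = s.pert[k + 3 * s.npert];
    h += pa * std::cos(2.0 * M_PI * (fx * x / s.a + fy * y / s.a) + ph);
  }
  return env * h;
}

// [[Rcpp::export]]
List cpp_render_geometry(int W, int H, double fc, double u0, double v0,
                         NumericMatrix Rm, NumericVector scl,
                         NumericVector ctr, bool hasSample, double a,
                         double domeAmp, NumericMatrix pert,
                         double bgDepth, double bgHalfwidth,
                         double zStep, double zTol) {
  NumericMatrix depth(H, W), X(H, W), Y(H, W);
  IntegerMatrix hit(H, W);
  Surf s;
  s.a = a;
  s.amp = domeAmp;
  s.pert = pert.nrow() ? pert.begin() : nullptr;
  s.npert = pert.nrow();
  double R[3][3];
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) R[i][j] = Rm(i, j);
  double pertsum = 0.0;
  for (int k = 0; k < s.npert; ++k) pertsum += std::fabs(pert(k, 0));
  double maxscl = std::max(scl[0], std::max(scl[1], scl[2]));
  double rb = (a + domeAmp + pertsum + 1.0) * maxscl * 1.05;
  for (int j = 0; j < W; ++j) {
    double dx = (j - u0) / fc;
    for (int i = 0; i < H; ++i) {
      double dy = (i - v0) / fc;
      bool found = false;
      double zhit = 0.0;
      if (hasSample) {
        // ray-sphere test against the sample bound (quadratic in z)
        double A = dx * dx + dy * dy + 1.0;
        double Bq = -2.0 * (dx * ctr[0] + dy * ctr[1] + ctr[2]);
        double Cq = ctr[0] * ctr[0] + ctr[1] * ctr[1] + ctr[2] * ctr[2] -
                    rb * rb;
        double disc = Bq * Bq - 4.0 * A * Cq;
        if (disc > 0.0) {
          double sq = std::sqrt(disc);
          double z1 = (-Bq - sq) / (2.0 * A);
          double z2 = (-Bq + sq) / (2.0 * A);
          if (z2 > 0.0) {
            z1 = std::max(z1, 1.0);
            double prevf = 0.0;
            bool havePrev = false;
            double zprev = z1;
            for (double z = z1; z <= z2 + zStep; z += zStep) {
              // local coordinates of the ray point
              double px = z * dx - ctr[0], py = z * dy - ctr[1],
                     pz = z - ctr[2];
              double lx = (R[0][0] * px + R[1][0] * py + R[2][0] * pz) /
                          scl[0];
              double ly = (R[0][1] * px + R[1][1] * py + R[2][1] * pz) /
                          scl[1];
              double lz = (R[0][2] * px + R[1][2] * py + R[2][2] * pz) /
                          scl[2];
              double f = lz + surf_height(s, lx, ly);
              if (havePrev && prevf < 0.0 && f >= 0.0) {
                // bisect [zprev, z]
                double lo = zprev, hi = z;
                while (hi - lo > zTol) {
                  double mid = 0.5 * (lo + hi);
                  double qx = mid * dx - ctr[0], qy = mid * dy - ctr[1],
                         qz = mid - ctr[2];
                  double mx = (R[0][0] * qx + R[1][0] * qy + R[2][0] * qz) /
                              scl[0];
                  double my = (R[0][1] * qx + R[1][1] * qy + R[2][1] * qz) /
                              scl[1];
                  double mz = (R[0][2] * qx + R[1][2] * qy + R[2][2] * qz) /
                              scl[2];
                  double fm = mz + surf_height(s, mx, my);
                  if (fm < 0.0) lo = mid; else hi = mid;
                }
                double zr = 0.5 * (lo + hi);
                double qx = zr * dx - ctr[0], qy = zr * dy - ctr[1],
                       qz = zr - ctr[2];
                double mx = (R[0][0] * qx + R[1][0] * qy + R[2][0] * qz) /
                            scl[0];
                double my = (R[0][1] * qx + R[1][1] * qy + R[2][1] * qz) /
                            scl[1];
                if ((std::fabs(mx) + std::fabs(my)) / s.a < 1.0) {
                  found = true;
                  zhit = zr;
                  break;
                }
              }
              prevf = f;
              havePrev = true;
              zprev = z;
            }
          }
        }
      }
      if (found) {
        depth(i, j) = zhit;
        X(i, j) = zhit * dx;
        Y(i, j) = zhit * dy;
        hit(i, j) = 1;
      } else {
        double bx = bgDepth * dx, by = bgDepth * dy;
        if (std::fabs(bx) > bgHalfwidth || std::fabs(by) > bgHalfwidth)
          stop("ray at pixel (%d,%d) misses both sample and background", i, j);
        depth(i, j) = bgDepth;
        X(i, j) = bx;
        Y(i, j) = by;
        hit(i, j) = 0;
      }
    }
  }
  return List::create(_["depth"] = depth, _["x"] = X, _["y"] = Y,
                      _["hit"] = hit);
}
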