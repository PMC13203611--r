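// Float32 arena runtime for the conv-net engine.
//
// Activations live in two grow-only arenas (forward pass / backward pass),
// reset at pass boundaries, so an iteration performs no R allocation and no
// garbage-collector work for feature maps. An R-side tensor handle is a
// small numeric vector c(arena, offset, H, W, C). Weights and their
// gradients stay as R double arrays (authoritative for serialisation and
// the optimiser); kernels convert them on the fly (they are small compared
// with activations). All accumulation orders are fixed, so runs are
// deterministic on a given BLAS.
#define USE_FC_LEN_T
#include <Rcpp.h>
#include <R_ext/BLAS.h>
#ifndef FCONE
#define FCONE
#endif
// R's BLAS header declares only the double-precision routines; the linked
// BLAS provides the single-precision ones.
extern "C" void F77_NAME(sgemm)(const char *ta, const char *tb,
                                const int *m, const int *n, const int *k,
                                const float *alpha, const float *A,
                                const int *lda, const float *B,
                                const int *ldb, const float *beta, float *C,
                                const int *ldc FCLEN FCLEN);
#ifndef FCLEN
#define FCLEN
#endif
#include <vector>
#include <cstring>
#include <cstdint>
using namespace Rcpp;

static inline float fsig(float x) {
  x = x < -60.f ? -60.f : (x > 60.f ? 60.f : x);
  return 1.f / (1.f + std::exp(-x));
}

static std::vector<float> g_arena[2];   // 0 = forward, 1 = backward
static size_t g_top[2] = {0, 0};
static std::vector<int> g_iarena;       // argmax indices (maxpool caches)
static size_t g_itop = 0;
static std::vector<float> g_scratch1, g_scratch2, g_wbuf, g_wbuf2;

struct H {
  int arena; size_t off; int h, w, c;
  size_t n() const { return (size_t)h * w * c; }
  float *p() const { return g_arena[arena].data() + off; }
};

static H geth(const NumericVector &v) {
  H r; r.arena = (int)v[0]; r.off = (size_t)v[1];
  r.h = (int)v[2]; r.w = (int)v[3]; r.c = (int)v[4];
  return r;
}

static NumericVector mkh(int arena, size_t off, int h, int w, int c) {
  return NumericVector::create((double)arena, (double)off,
                               (double)h, (double)w, (double)c);
}

static size_t arena_alloc(int a, size_t n) {
  size_t off = g_top[a];
  if (off + n > g_arena[a].size()) g_arena[a].resize(off + n);
  g_top[a] += n;
  return off;
}

static H newh(int a, int h, int w, int c) {
  H r; r.arena = a; r.h = h; r.w = w; r.c = c;
  r.off = arena_alloc(a, r.n());
  return r;
}

static NumericVector wrap_h(const H &x) {
  return mkh(x.arena, x.off, x.h, x.w, x.c);
}

// [[Rcpp::export]]
void f_reset(int arena) { g_top[arena] = 0; if (arena == 0) g_itop = 0; }

// [[Rcpp::export]]
NumericVector f_from_dbl(NumericVector x, int h, int w, int c, int arena) {
  H y = newh(arena, h, w, c);
  const double *px = x.begin();
  float *py = y.p();
  const size_t n = y.n();
  for (size_t i = 0; i < n; ++i) py[i] = (float)px[i];
  return wrap_h(y);
}

// [[Rcpp::export]]
NumericVector f_to_dbl(NumericVector hv) {
  H x = geth(hv);
  NumericVector y(x.n());
  const float *px = x.p();
  double *py = y.begin();
  const size_t n = x.n();
  for (size_t i = 0; i < n; ++i) py[i] = (double)px[i];
  y.attr("dim") = IntegerVector::create(x.h, x.w, x.c);
  return y;
}

static void to_f(const double *src, float *dst, size_t n) {
  for (size_t i = 0; i < n; ++i) dst[i] = (float)src[i];
}

static inline int out_sz(int H_, int k, int stride, int pad) {
  return (H_ + 2 * pad - k) / stride + 1;
}

static void sgemm_(const char *ta, const char *tb, int m, int n, int kk,
                   float alpha, const float *A, int lda, const float *B,
                   int ldb, float beta, float *C, int ldc) {
  F77_CALL(sgemm)(ta, tb, &m, &n, &kk, &alpha, A, &lda, B, &ldb, &beta,
                  C, &ldc FCONE FCONE);
}

static void im2col_f(const float *px, int Hh, int W, int C, int k,
                     int stride, int pad, float *po) {
  const int Ho = out_sz(Hh, k, stride, pad);
  const int Wo = out_sz(W, k, stride, pad);
  for (int c = 0; c < C; ++c)
    for (int dj = 0; dj < k; ++dj)
      for (int di = 0; di < k; ++di) {
        float *col = po + ((size_t)c * k * k + dj * k + di) * (Ho * Wo);
        for (int ox = 0; ox < Wo; ++ox) {
          const int ix = ox * stride - pad + dj;
          float *dst = col + (size_t)ox * Ho;
          if (ix < 0 || ix >= W) { std::memset(dst, 0, Ho * sizeof(float)); continue; }
          const float *src = px + (size_t)c * Hh * W + (size_t)ix * Hh;
          int y0 = pad - di > 0 ? (pad - di + stride - 1) / stride : 0;
          int y1 = (Hh - 1 - di + pad) / stride + 1; if (y1 > Ho) y1 = Ho;
          for (int oy = 0; oy < y0; ++oy) dst[oy] = 0.f;
          if (stride == 1)
            std::memcpy(dst + y0, src + y0 - pad + di, (y1 - y0) * sizeof(float));
          else
            for (int oy = y0; oy < y1; ++oy) dst[oy] = src[oy * stride - pad + di];
          for (int oy = y1; oy < Ho; ++oy) dst[oy] = 0.f;
        }
      }
}

static void col2im_f(const float *pc, int Hh, int W, int C, int k,
                     int stride, int pad, float *pdx) {
  const int Ho = out_sz(Hh, k, stride, pad);
  const int Wo = out_sz(W, k, stride, pad);
  std::memset(pdx, 0, (size_t)Hh * W * C * sizeof(float));
  for (int c = 0; c < C; ++c)
    for (int dj = 0; dj < k; ++dj)
      for (int di = 0; di < k; ++di) {
        const float *col = pc + ((size_t)c * k * k + dj * k + di) * (Ho * Wo);
        for (int ox = 0; ox < Wo; ++ox) {
          const int ix = ox * stride - pad + dj;
          if (ix < 0 || ix >= W) continue;
          float *dst = pdx + (size_t)c * Hh * W + (size_t)ix * Hh - pad + di;
          const float *src = col + (size_t)ox * Ho;
          int y0 = pad - di > 0 ? (pad - di + stride - 1) / stride : 0;
          int y1 = (Hh - 1 - di + pad) / stride + 1; if (y1 > Ho) y1 = Ho;
          if (stride == 1)
            for (int oy = y0; oy < y1; ++oy) dst[oy] += src[oy];
          else
            for (int oy = y0; oy < y1; ++oy) dst[oy * stride] += src[oy];
        }
      }
}

// ---- convolution ---------------------------------------------------------

// [[Rcpp::export]]
NumericVector f_conv_fw(NumericVector hx, NumericMatrix w, int k,
                        int stride, int pad, int cout) {
  H x = geth(hx);
  const int Ho = out_sz(x.h, k, stride, pad);
  const int Wo = out_sz(x.w, k, stride, pad);
  const int M = Ho * Wo, K = x.c * k * k;
  H y = newh(x.arena, Ho, Wo, cout);
  g_wbuf.resize((size_t)K * cout);
  to_f(w.begin(), g_wbuf.data(), (size_t)K * cout);
  const float *A;
  if (k == 1 && stride == 1) A = x.p();
  else {
    g_scratch1.resize((size_t)M * K);
    im2col_f(x.p(), x.h, x.w, x.c, k, stride, pad, g_scratch1.data());
    A = g_scratch1.data();
  }
  sgemm_("N", "N", M, cout, K, 1.f, A, M, g_wbuf.data(), K, 0.f, y.p(), M);
  return wrap_h(y);
}

// weight gradient accumulates into gw (double, in place); returns dx handle
// [[Rcpp::export]]
NumericVector f_conv_bw(NumericVector hdy, NumericVector hx, NumericMatrix w,
                        NumericMatrix gw, int k, int stride, int pad,
                        int cout) {
  H dy = geth(hdy), x = geth(hx);
  const int Ho = dy.h, Wo = dy.w;
  const int M = Ho * Wo, K = x.c * k * k;
  H dx = newh(1, x.h, x.w, x.c);
  g_wbuf.resize((size_t)K * cout);
  to_f(w.begin(), g_wbuf.data(), (size_t)K * cout);
  g_wbuf2.resize((size_t)K * cout);
  const float *A;
  if (k == 1 && stride == 1) A = x.p();
  else {
    g_scratch1.resize((size_t)M * K);
    im2col_f(x.p(), x.h, x.w, x.c, k, stride, pad, g_scratch1.data());
    A = g_scratch1.data();
  }
  // dW = cols^T dy
  sgemm_("T", "N", K, cout, M, 1.f, A, M, dy.p(), M, 0.f, g_wbuf2.data(), K);
  {
    double *pg = gw.begin();
    const float *pf = g_wbuf2.data();
    const size_t n = (size_t)K * cout;
    for (size_t i = 0; i < n; ++i) pg[i] += (double)pf[i];
  }
  if (k == 1 && stride == 1) {
    sgemm_("N", "T", M, K, cout, 1.f, dy.p(), M, g_wbuf.data(), K, 0.f,
           dx.p(), M);
  } else {
    g_scratch2.resize((size_t)M * K);
    sgemm_("N", "T", M, K, cout, 1.f, dy.p(), M, g_wbuf.data(), K, 0.f,
           g_scratch2.data(), M);
    col2im_f(g_scratch2.data(), x.h, x.w, x.c, k, stride, pad, dx.p());
  }
  return wrap_h(dx);
}

// ---- depthwise convolution ------------------------------------------------

// [[Rcpp::export]]
NumericVector f_dw_fw(NumericVector hx, NumericVector w, int k, int stride,
                      int pad) {
  H x = geth(hx);
  const int Ho = out_sz(x.h, k, stride, pad);
  const int Wo = out_sz(x.w, k, stride, pad);
  H y = newh(x.arena, Ho, Wo, x.c);
  std::memset(y.p(), 0, y.n() * sizeof(float));
  const double *pw = w.begin();
  for (int c = 0; c < x.c; ++c) {
    const float *xc = x.p() + (size_t)c * x.h * x.w;
    float *yc = y.p() + (size_t)c * Ho * Wo;
    for (int dj = 0; dj < k; ++dj)
      for (int di = 0; di < k; ++di) {
        const float wv = (float)pw[di + dj * k + (size_t)c * k * k];
        int y0 = pad - di > 0 ? (pad - di + stride - 1) / stride : 0;
        int y1 = (x.h - 1 - di + pad) / stride + 1; if (y1 > Ho) y1 = Ho;
        for (int ox = 0; ox < Wo; ++ox) {
          const int ix = ox * stride - pad + dj;
          if (ix < 0 || ix >= x.w) continue;
          const float *src = xc + (size_t)ix * x.h - pad + di;
          float *dst = yc + (size_t)ox * Ho;
          if (stride == 1)
            for (int oy = y0; oy < y1; ++oy) dst[oy] += wv * src[oy];
          else
            for (int oy = y0; oy < y1; ++oy) dst[oy] += wv * src[oy * stride];
        }
      }
  }
  return wrap_h(y);
}

// [[Rcpp::export]]
NumericVector f_dw_bw(NumericVector hdy, NumericVector hx, NumericVector w,
                      NumericVector gw, int k, int stride, int pad) {
  H dy = geth(hdy), x = geth(hx);
  const int Ho = dy.h, Wo = dy.w;
  H dx = newh(1, x.h, x.w, x.c);
  std::memset(dx.p(), 0, dx.n() * sizeof(float));
  const double *pw = w.begin();
  double *pg = gw.begin();
  for (int c = 0; c < x.c; ++c) {
    const float *xc = x.p() + (size_t)c * x.h * x.w;
    const float *dyc = dy.p() + (size_t)c * Ho * Wo;
    float *dxc = dx.p() + (size_t)c * x.h * x.w;
    for (int dj = 0; dj < k; ++dj)
      for (int di = 0; di < k; ++di) {
        const float wv = (float)pw[di + dj * k + (size_t)c * k * k];
        double acc = 0.0;
        int y0 = pad - di > 0 ? (pad - di + stride - 1) / stride : 0;
        int y1 = (x.h - 1 - di + pad) / stride + 1; if (y1 > Ho) y1 = Ho;
        for (int ox = 0; ox < Wo; ++ox) {
          const int ix = ox * stride - pad + dj;
          if (ix < 0 || ix >= x.w) continue;
          const float *src = xc + (size_t)ix * x.h - pad + di;
          float *dst = dxc + (size_t)ix * x.h - pad + di;
          const float *g = dyc + (size_t)ox * Ho;
          if (stride == 1) {
            float a = 0.f;
            for (int oy = y0; oy < y1; ++oy) {
              a += g[oy] * src[oy];
              dst[oy] += wv * g[oy];
            }
            acc += a;
          } else {
            float a = 0.f;
            for (int oy = y0; oy < y1; ++oy) {
              a += g[oy] * src[oy * stride];
              dst[oy * stride] += wv * g[oy];
            }
            acc += a;
          }
        }
        pg[di + dj * k + (size_t)c * k * k] += acc;
      }
  }
  return wrap_h(dx);
}

// ---- fused channel norm + SiLU --------------------------------------------

// [[Rcpp::export]]
List f_ns_fw(NumericVector hz, NumericVector g, NumericVector b,
             double eps) {
  H z = geth(hz);
  const int n = z.h * z.w, C = z.c;
  H y = newh(z.arena, z.h, z.w, z.c);
  NumericVector mu(C), var(C);
  for (int c = 0; c < C; ++c) {
    const float *zc = z.p() + (size_t)n * c;
    double s = 0.0, s2 = 0.0;
    for (int i = 0; i < n; ++i) { s += zc[i]; s2 += (double)zc[i] * zc[i]; }
    const double m = s / n;
    double v = s2 / n - m * m; if (v < 0) v = 0;
    const float is = (float)(1.0 / std::sqrt(v + eps));
    const float gc = (float)g[c] * is;
    const float bc = (float)(b[c] - g[c] * m / std::sqrt(v + eps));
    float *yc = y.p() + (size_t)n * c;
    for (int i = 0; i < n; ++i) {
      const float yh = gc * zc[i] + bc;
      yc[i] = yh * fsig(yh);
    }
    mu[c] = m; var[c] = v;
  }
  return List::create(_["y"] = wrap_h(y), _["mu"] = mu, _["var"] = var);
}

// [[Rcpp::export]]
List f_ns_bw(NumericVector hdout, NumericVector hz, NumericVector mu,
             NumericVector var, NumericVector g, NumericVector b,
             double eps) {
  H dout = geth(hdout), z = geth(hz);
  const int n = z.h * z.w, C = z.c;
  H dz = newh(1, z.h, z.w, z.c);
  NumericVector gg(C), gb(C);
  for (int c = 0; c < C; ++c) {
    const float is = (float)(1.0 / std::sqrt(var[c] + eps));
    const float m = (float)mu[c], gc = (float)g[c], bc = (float)b[c];
    const float *dc = dout.p() + (size_t)n * c;
    const float *zc = z.p() + (size_t)n * c;
    float *xc = dz.p() + (size_t)n * c;
    double s1 = 0.0, s2 = 0.0;
    for (int i = 0; i < n; ++i) {
      const float h = (zc[i] - m) * is;
      const float yh = gc * h + bc;
      const float s = fsig(yh);
      const float dyh = dc[i] * s * (1.f + yh * (1.f - s));
      xc[i] = dyh;
      s1 += dyh;
      s2 += (double)dyh * h;
    }
    gg[c] = s2; gb[c] = s1;
    const float m1 = (float)(s1 / n), m2 = (float)(s2 / n);
    for (int i = 0; i < n; ++i) {
      const float h = (zc[i] - m) * is;
      xc[i] = gc * is * (xc[i] - m1 - h * m2);
    }
  }
  return List::create(_["dz"] = wrap_h(dz), _["gg"] = gg, _["gb"] = gb);
}

// [[Rcpp::export]]
NumericVector f_ns_eval(NumericVector hz, NumericVector g, NumericVector b,
                        NumericVector rm, NumericVector rv, double eps) {
  H z = geth(hz);
  const int n = z.h * z.w, C = z.c;
  H y = newh(z.arena, z.h, z.w, z.c);
  for (int c = 0; c < C; ++c) {
    const float sc = (float)(g[c] / std::sqrt(rv[c] + eps));
    const float off = (float)(b[c] - rm[c] * g[c] / std::sqrt(rv[c] + eps));
    const float *zc = z.p() + (size_t)n * c;
    float *yc = y.p() + (size_t)n * c;
    for (int i = 0; i < n; ++i) {
      const float yh = zc[i] * sc + off;
      yc[i] = yh * fsig(yh);
    }
  }
  return wrap_h(y);
}

// path normalisation without activation (cross-fusion modules)
// [[Rcpp::export]]
List f_norm_fw(NumericVector hz, NumericVector g, NumericVector b,
               double eps, bool training, NumericVector rm,
               NumericVector rv) {
  H z = geth(hz);
  const int n = z.h * z.w, C = z.c;
  H y = newh(z.arena, z.h, z.w, z.c);
  NumericVector mu(C), var(C);
  for (int c = 0; c < C; ++c) {
    const float *zc = z.p() + (size_t)n * c;
    double m, v;
    if (training) {
      double s = 0.0, s2 = 0.0;
      for (int i = 0; i < n; ++i) { s += zc[i]; s2 += (double)zc[i] * zc[i]; }
      m = s / n; v = s2 / n - m * m; if (v < 0) v = 0;
    } else { m = rm[c]; v = rv[c]; }
    const float sc = (float)(g[c] / std::sqrt(v + eps));
    const float off = (float)(b[c] - m * g[c] / std::sqrt(v + eps));
    float *yc = y.p() + (size_t)n * c;
    for (int i = 0; i < n; ++i) yc[i] = zc[i] * sc + off;
    mu[c] = m; var[c] = v;
  }
  return List::create(_["y"] = wrap_h(y), _["mu"] = mu, _["var"] = var);
}

// [[Rcpp::export]]
List f_norm_bw(NumericVector hdy, NumericVector hz, NumericVector mu,
               NumericVector var, NumericVector g, double eps) {
  H dy = geth(hdy), z = geth(hz);
  const int n = z.h * z.w, C = z.c;
  H dz = newh(1, z.h, z.w, z.c);
  NumericVector gg(C), gb(C);
  for (int c = 0; c < C; ++c) {
    const float is = (float)(1.0 / std::sqrt(var[c] + eps));
    const float m = (float)mu[c], gc = (float)g[c];
    const float *dc = dy.p() + (size_t)n * c;
    const float *zc = z.p() + (size_t)n * c;
    float *xc = dz.p() + (size_t)n * c;
    double s1 = 0.0, s2 = 0.0;
    for (int i = 0; i < n; ++i) {
      const float h = (zc[i] - m) * is;
      s1 += dc[i];
      s2 += (double)dc[i] * h;
    }
    gg[c] = s2; gb[c] = s1;
    const float m1 = (float)(s1 / n), m2 = (float)(s2 / n);
    for (int i = 0; i < n; ++i) {
      const float h = (zc[i] - m) * is;
      xc[i] = gc * is * (dc[i] - m1 - h * m2);
    }
  }
  return List::create(_["dz"] = wrap_h(dz), _["gg"] = gg, _["gb"] = gb);
}

// [[Rcpp::export]]
NumericVector f_silu_fw(NumericVector hx) {
  H x = geth(hx);
  H y = newh(x.arena, x.h, x.w, x.c);
  const float *px = x.p();
  float *py = y.p();
  const size_t n = x.n();
  for (size_t i = 0; i < n; ++i)
    py[i] = px[i] * fsig(px[i]);
  return wrap_h(y);
}

// [[Rcpp::export]]
NumericVector f_silu_bw(NumericVector hdy, NumericVector hx) {
  H dy = geth(hdy), x = geth(hx);
  H dx = newh(1, x.h, x.w, x.c);
  const float *pd = dy.p(), *px = x.p();
  float *pdx = dx.p();
  const size_t n = x.n();
  for (size_t i = 0; i < n; ++i) {
    const float s = fsig(px[i]);
    pdx[i] = pd[i] * s * (1.f + px[i] * (1.f - s));
  }
  return wrap_h(dx);
}

// ---- elementwise / shape ops ----------------------------------------------

// [[Rcpp::export]]
NumericVector f_add(NumericVector ha, NumericVector hb) {
  H a = geth(ha), b = geth(hb);
  H y = newh(a.arena, a.h, a.w, a.c);
  const float *pa = a.p(), *pb = b.p();
  float *py = y.p();
  const size_t n = a.n();
  for (size_t i = 0; i < n; ++i) py[i] = pa[i] + pb[i];
  return wrap_h(y);
}

// in-place a += b
// [[Rcpp::export]]
void f_add_ip(NumericVector ha, NumericVector hb) {
  H a = geth(ha), b = geth(hb);
  float *pa = a.p();
  const float *pb = b.p();
  const size_t n = a.n();
  for (size_t i = 0; i < n; ++i) pa[i] += pb[i];
}

// [[Rcpp::export]]
NumericVector f_concat(NumericVector ha, NumericVector hb) {
  H a = geth(ha), b = geth(hb);
  H y = newh(a.arena, a.h, a.w, a.c + b.c);
  std::memcpy(y.p(), a.p(), a.n() * sizeof(float));
  std::memcpy(y.p() + a.n(), b.p(), b.n() * sizeof(float));
  return wrap_h(y);
}

// channel slice [from, from+nc) as a zero-copy view
// [[Rcpp::export]]
NumericVector f_slice(NumericVector hx, int from, int nc) {
  H x = geth(hx);
  return mkh(x.arena, x.off + (size_t)(from - 1) * x.h * x.w, x.h, x.w, nc);
}

// [[Rcpp::export]]
NumericVector f_bias_add_ip(NumericVector hx, NumericVector b) {
  H x = geth(hx);
  const int n = x.h * x.w;
  for (int c = 0; c < x.c; ++c) {
    const float bc = (float)b[c];
    float *xc = x.p() + (size_t)n * c;
    for (int i = 0; i < n; ++i) xc[i] += bc;
  }
  return hx;
}

// per-channel sums (bias gradient)
// [[Rcpp::export]]
NumericVector f_colsum(NumericVector hx) {
  H x = geth(hx);
  const int n = x.h * x.w;
  NumericVector s(x.c);
  for (int c = 0; c < x.c; ++c) {
    const float *xc = x.p() + (size_t)n * c;
    double a = 0.0;
    for (int i = 0; i < n; ++i) a += xc[i];
    s[c] = a;
  }
  return s;
}

// ---- pooling / resampling --------------------------------------------------

// [[Rcpp::export]]
NumericVector f_avgpool2_fw(NumericVector hx) {
  H x = geth(hx);
  const int Ho = x.h / 2, Wo = x.w / 2;
  H y = newh(x.arena, Ho, Wo, x.c);
  for (int c = 0; c < x.c; ++c) {
    const float *xc = x.p() + (size_t)c * x.h * x.w;
    float *yc = y.p() + (size_t)c * Ho * Wo;
    for (int ox = 0; ox < Wo; ++ox) {
      const float *c0 = xc + (size_t)(2 * ox) * x.h;
      const float *c1 = xc + (size_t)(2 * ox + 1) * x.h;
      for (int oy = 0; oy < Ho; ++oy)
        yc[oy + (size_t)ox * Ho] = 0.25f *
          (c0[2 * oy] + c0[2 * oy + 1] + c1[2 * oy] + c1[2 * oy + 1]);
    }
  }
  return wrap_h(y);
}

// [[Rcpp::export]]
NumericVector f_avgpool2_bw(NumericVector hdy) {
  H dy = geth(hdy);
  const int Hh = 2 * dy.h, W = 2 * dy.w;
  H dx = newh(dy.arena, Hh, W, dy.c);
  for (int c = 0; c < dy.c; ++c) {
    const float *dyc = dy.p() + (size_t)c * dy.h * dy.w;
    float *dxc = dx.p() + (size_t)c * Hh * W;
    for (int ox = 0; ox < dy.w; ++ox) {
      float *c0 = dxc + (size_t)(2 * ox) * Hh;
      float *c1 = dxc + (size_t)(2 * ox + 1) * Hh;
      for (int oy = 0; oy < dy.h; ++oy) {
        const float gv = 0.25f * dyc[oy + (size_t)ox * dy.h];
        c0[2 * oy] = gv; c0[2 * oy + 1] = gv;
        c1[2 * oy] = gv; c1[2 * oy + 1] = gv;
      }
    }
  }
  return wrap_h(dx);
}

// [[Rcpp::export]]
NumericVector f_upsample2_fw(NumericVector hx) {
  H x = geth(hx);
  const int Ho = 2 * x.h, Wo = 2 * x.w;
  H y = newh(x.arena, Ho, Wo, x.c);
  for (int c = 0; c < x.c; ++c) {
    const float *xc = x.p() + (size_t)c * x.h * x.w;
    float *yc = y.p() + (size_t)c * Ho * Wo;
    for (int ix = 0; ix < x.w; ++ix) {
      float *c0 = yc + (size_t)(2 * ix) * Ho;
      float *c1 = yc + (size_t)(2 * ix + 1) * Ho;
      const float *src = xc + (size_t)ix * x.h;
      for (int iy = 0; iy < x.h; ++iy) {
        const float v = src[iy];
        c0[2 * iy] = v; c0[2 * iy + 1] = v;
        c1[2 * iy] = v; c1[2 * iy + 1] = v;
      }
    }
  }
  return wrap_h(y);
}

// [[Rcpp::export]]
NumericVector f_upsample2_bw(NumericVector hdy) {
  H dy = geth(hdy);
  const int Hh = dy.h / 2, W = dy.w / 2;
  H dx = newh(dy.arena, Hh, W, dy.c);
  for (int c = 0; c < dy.c; ++c) {
    const float *dyc = dy.p() + (size_t)c * dy.h * dy.w;
    float *dxc = dx.p() + (size_t)c * Hh * W;
    for (int ix = 0; ix < W; ++ix) {
      const float *c0 = dyc + (size_t)(2 * ix) * dy.h;
      const float *c1 = dyc + (size_t)(2 * ix + 1) * dy.h;
      float *dst = dxc + (size_t)ix * Hh;
      for (int iy = 0; iy < Hh; ++iy)
        dst[iy] = c0[2 * iy] + c0[2 * iy + 1] + c1[2 * iy] + c1[2 * iy + 1];
    }
  }
  return wrap_h(dx);
}

// max pooling, stride 1, same padding (spatial-pyramid bottleneck)
// [[Rcpp::export]]
List f_maxpool_fw(NumericVector hx, int k) {
  H x = geth(hx);
  const int pad = (k - 1) / 2;
  H y = newh(x.arena, x.h, x.w, x.c);
  size_t ioff = g_itop;
  if (ioff + y.n() > g_iarena.size()) g_iarena.resize(ioff + y.n());
  g_itop += y.n();
  int *pi = g_iarena.data() + ioff;
  for (int c = 0; c < x.c; ++c) {
    const float *xc = x.p() + (size_t)c * x.h * x.w;
    float *yc = y.p() + (size_t)c * x.h * x.w;
    int *ic = pi + (size_t)c * x.h * x.w;
    for (int ox = 0; ox < x.w; ++ox)
      for (int oy = 0; oy < x.h; ++oy) {
        float best = -1e30f; int bi = -1;
        for (int dj = 0; dj < k; ++dj) {
          const int ix = ox - pad + dj;
          if (ix < 0 || ix >= x.w) continue;
          for (int di = 0; di < k; ++di) {
            const int iy = oy - pad + di;
            if (iy < 0 || iy >= x.h) continue;
            const float v = xc[iy + (size_t)ix * x.h];
            if (v > best) { best = v; bi = iy + ix * x.h; }
          }
        }
        yc[oy + (size_t)ox * x.h] = best;
        ic[oy + (size_t)ox * x.h] = bi;
      }
  }
  return List::create(_["y"] = wrap_h(y), _["ioff"] = (double)ioff);
}

// [[Rcpp::export]]
NumericVector f_maxpool_bw(NumericVector hdy, double ioff) {
  H dy = geth(hdy);
  H dx = newh(1, dy.h, dy.w, dy.c);
  std::memset(dx.p(), 0, dx.n() * sizeof(float));
  const int *pi = g_iarena.data() + (size_t)ioff;
  for (int c = 0; c < dy.c; ++c) {
    const float *dyc = dy.p() + (size_t)c * dy.h * dy.w;
    float *dxc = dx.p() + (size_t)c * dy.h * dy.w;
    const int *ic = pi + (size_t)c * dy.h * dy.w;
    const size_t n = (size_t)dy.h * dy.w;
    for (size_t i = 0; i < n; ++i) dxc[ic[i]] += dyc[i];
  }
  return wrap_h(dx);
}

// adaptive average pooling to s x s
// [[Rcpp::export]]
NumericVector f_adapool_fw(NumericVector hx, int s) {
  H x = geth(hx);
  H y = newh(x.arena, s, s, x.c);
  for (int c = 0; c < x.c; ++c) {
    const float *xc = x.p() + (size_t)c * x.h * x.w;
    float *yc = y.p() + (size_t)c * s * s;
    for (int bx = 0; bx < s; ++bx) {
      const int x0 = (bx * x.w) / s, x1 = ((bx + 1) * x.w + s - 1) / s;
      for (int by = 0; by < s; ++by) {
        const int y0 = (by * x.h) / s, y1 = ((by + 1) * x.h + s - 1) / s;
        double acc = 0.0;
        for (int ix = x0; ix < x1; ++ix)
          for (int iy = y0; iy < y1; ++iy) acc += xc[iy + (size_t)ix * x.h];
        yc[by + bx * s] = (float)(acc / ((x1 - x0) * (y1 - y0)));
      }
    }
  }
  return wrap_h(y);
}

// [[Rcpp::export]]
NumericVector f_adapool_bw(NumericVector hdy, int Hh, int W) {
  H dy = geth(hdy);
  const int s = dy.h;
  H dx = newh(1, Hh, W, dy.c);
  std::memset(dx.p(), 0, dx.n() * sizeof(float));
  for (int c = 0; c < dy.c; ++c) {
    const float *dyc = dy.p() + (size_t)c * s * s;
    float *dxc = dx.p() + (size_t)c * Hh * W;
    for (int bx = 0; bx < s; ++bx) {
      const int x0 = (bx * W) / s, x1 = ((bx + 1) * W + s - 1) / s;
      for (int by = 0; by < s; ++by) {
        const int y0 = (by * Hh) / s, y1 = ((by + 1) * Hh + s - 1) / s;
        const float gv = dyc[by + bx * s] / ((x1 - x0) * (y1 - y0));
        for (int ix = x0; ix < x1; ++ix)
          for (int iy = y0; iy < y1; ++iy) dxc[iy + (size_t)ix * Hh] += gv;
      }
    }
  }
  return wrap_h(dx);
}

// nearest-neighbour resize from s x s to Ho x Wo
// [[Rcpp::export]]
NumericVector f_upto_fw(NumericVector hx, int Ho, int Wo) {
  H x = geth(hx);
  H y = newh(x.arena, Ho, Wo, x.c);
  for (int c = 0; c < x.c; ++c) {
    const float *xc = x.p() + (size_t)c * x.h * x.w;
    float *yc = y.p() + (size_t)c * Ho * Wo;
    for (int ox = 0; ox < Wo; ++ox) {
      const int ix = (int)((size_t)ox * x.w / Wo);
      for (int oy = 0; oy < Ho; ++oy) {
        const int iy = (int)((size_t)oy * x.h / Ho);
        yc[oy + (size_t)ox * Ho] = xc[iy + (size_t)ix * x.h];
      }
    }
  }
  return wrap_h(y);
}

// [[Rcpp::export]]
NumericVector f_upto_bw(NumericVector hdy, int Hh, int W) {
  H dy = geth(hdy);
  H dx = newh(1, Hh, W, dy.c);
  std::memset(dx.p(), 0, dx.n() * sizeof(float));
  for (int c = 0; c < dy.c; ++c) {
    const float *dyc = dy.p() + (size_t)c * dy.h * dy.w;
    float *dxc = dx.p() + (size_t)c * Hh * W;
    for (int ox = 0; ox < dy.w; ++ox) {
      const int ix = (int)((size_t)ox * W / dy.w);
      for (int oy = 0; oy < dy.h; ++oy) {
        const int iy = (int)((size_t)oy * Hh / dy.h);
        dxc[iy + (size_t)ix * Hh] += dyc[oy + (size_t)ox * dy.h];
      }
    }
  }
  return wrap_h(dx);
}

// space-to-depth (stem): (H, W, C) -> (H/2, W/2, 4C)
// [[Rcpp::export]]
NumericVector f_space2depth_fw(NumericVector hx) {
  H x = geth(hx);
  const int Ho = x.h / 2, Wo = x.w / 2;
  H y = newh(x.arena, Ho, Wo, 4 * x.c);
  for (int b = 0; b < 4; ++b) {
    const int ry = b & 1, rx = b >> 1;
    for (int c = 0; c < x.c; ++c) {
      const float *xc = x.p() + (size_t)c * x.h * x.w;
      float *yc = y.p() + (size_t)(b * x.c + c) * Ho * Wo;
      for (int ox = 0; ox < Wo; ++ox) {
        const float *src = xc + (size_t)(2 * ox + rx) * x.h + ry;
        float *dst = yc + (size_t)ox * Ho;
        for (int oy = 0; oy < Ho; ++oy) dst[oy] = src[2 * oy];
      }
    }
  }
  return wrap_h(y);
}

// [[Rcpp::export]]
NumericVector f_space2depth_bw(NumericVector hdy) {
  H dy = geth(hdy);
  const int C = dy.c / 4;
  const int Hh = 2 * dy.h, W = 2 * dy.w;
  H dx = newh(1, Hh, W, C);
  for (int b = 0; b < 4; ++b) {
    const int ry = b & 1, rx = b >> 1;
    for (int c = 0; c < C; ++c) {
      const float *dyc = dy.p() + (size_t)(b * C + c) * dy.h * dy.w;
      float *dxc = dx.p() + (size_t)c * Hh * W;
      for (int ox = 0; ox < dy.w; ++ox) {
        float *dst = dxc + (size_t)(2 * ox + rx) * Hh + ry;
        const float *src = dyc + (size_t)ox * dy.h;
        for (int oy = 0; oy < dy.h; ++oy) dst[2 * oy] = src[oy];
      }
    }
  }
  return wrap_h(dx);
}

// normalisation + SiLU with accumulated (running) statistics, used where
// the spatial extent is too small for per-sample statistics (pooled
// context branches); batch statistics are still measured to update the
// running averages, but normalisation and gradients use the accumulated
// values, which the backward pass treats as constants
// [[Rcpp::export]]
List f_nsfroz_fw(NumericVector hz, NumericVector g, NumericVector b,
                 NumericVector rm, NumericVector rv, double eps) {
  H z = geth(hz);
  const int n = z.h * z.w, C = z.c;
  H y = newh(z.arena, z.h, z.w, z.c);
  NumericVector mu(C), var(C);
  for (int c = 0; c < C; ++c) {
    const float *zc = z.p() + (size_t)n * c;
    double s = 0.0, s2 = 0.0;
    for (int i = 0; i < n; ++i) { s += zc[i]; s2 += (double)zc[i] * zc[i]; }
    const double m = s / n;
    double v = s2 / n - m * m; if (v < 0) v = 0;
    mu[c] = m; var[c] = v;
    const float sc = (float)(g[c] / std::sqrt(rv[c] + eps));
    const float off = (float)(b[c] - rm[c] * g[c] / std::sqrt(rv[c] + eps));
    float *yc = y.p() + (size_t)n * c;
    for (int i = 0; i < n; ++i) {
      const float yh = zc[i] * sc + off;
      yc[i] = yh * fsig(yh);
    }
  }
  return List::create(_["y"] = wrap_h(y), _["mu"] = mu, _["var"] = var);
}

// [[Rcpp::export]]
List f_nsfroz_bw(NumericVector hdout, NumericVector hz, NumericVector g,
                 NumericVector b, NumericVector rm, NumericVector rv,
                 double eps) {
  H dout = geth(hdout), z = geth(hz);
  const int n = z.h * z.w, C = z.c;
  H dz = newh(1, z.h, z.w, z.c);
  NumericVector gg(C), gb(C);
  for (int c = 0; c < C; ++c) {
    const float is = (float)(1.0 / std::sqrt(rv[c] + eps));
    const float m = (float)rm[c], gc = (float)g[c], bc = (float)b[c];
    const float *dc = dout.p() + (size_t)n * c;
    const float *zc = z.p() + (size_t)n * c;
    float *xc = dz.p() + (size_t)n * c;
    double s1 = 0.0, s2 = 0.0;
    for (int i = 0; i < n; ++i) {
      const float h = (zc[i] - m) * is;
      const float yh = gc * h + bc;
      const float s = fsig(yh);
      const float dyh = dc[i] * s * (1.f + yh * (1.f - s));
      xc[i] = dyh * gc * is;
      s1 += dyh;
      s2 += (double)dyh * h;
    }
    gg[c] = s2; gb[c] = s1;
  }
  return List::create(_["dz"] = wrap_h(dz), _["gg"] = gg, _["gb"] = gb);
}
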