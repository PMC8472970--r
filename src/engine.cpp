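// Single-precision training engine.
//
// Holds the full parameter set, Adam state and all activation/gradient
// workspaces in C++ between optimization steps, so one R call runs an
// entire forward + backward + update on a batch without intermediate R
// allocations. Workspaces are reused across batches. The double-precision
// per-operation path in ops.cpp remains the reference implementation; a
// test asserts both paths agree on the same batch.
//
// Parameters are addressed by the dotted paths produced by the R side
// (e.g. "enc.1.conv1.w", "down.3.bn.gamma", "up.2.w", "head.b").

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <map>
#include <string>
#include "conv_core.h"

using namespace Rcpp;

namespace {

struct FT {                      // float tensor, (H, W, C, N) column-major
  std::vector<float> v;
  int H = 0, W = 0, C = 0, N = 0;
  void resize(int h, int w, int c, int n) {
    H = h; W = w; C = c; N = n;
    v.resize((size_t)h * w * c * n);
  }
  size_t numel() const { return (size_t)H * W * C * N; }
  float* data() { return v.data(); }
  const float* data() const { return v.data(); }
};

struct Param {
  std::vector<float> w, g, m, v;  // value, gradient, Adam moments
  std::vector<int> dim;
  bool learnable = true;
  size_t n() const { return w.size(); }
};

struct Engine {
  std::map<std::string, Param> P;
  std::map<std::string, FT> A;
  arma::fmat kt, gm1, gm2;        // shared GEMM scratch
  int in_ch, bw, r;
  int mode;                       // 0 adaptive, 1 bilinear, 2 deconv
  bool gating, ms, deferred_order, gate_single;
  double beta1 = 0.9, beta2 = 0.999, eps = 1e-8, wd = 0.0;
  long t = 0;                     // Adam step counter
};

FT& at(Engine& E, const std::string& k) { return E.A[k]; }

Param& par(Engine& E, const std::string& k) {
  auto it = E.P.find(k);
  if (it == E.P.end()) stop("engine: unknown parameter %s", k.c_str());
  return it->second;
}

bool has_par(Engine& E, const std::string& k) { return E.P.count(k) > 0; }

// ---- primitive layers ---------------------------------------------------

void conv_fwd(Engine& E, const FT& x, const std::string& wkey, int s, int p,
              FT& y, bool bias) {
  Param& W = par(E, wkey + ".w");
  int k = W.dim[0], Cin = W.dim[2], Cout = W.dim[3];
  if (Cin != x.C) stop("engine conv %s: %d channels vs %d", wkey.c_str(), x.C, Cin);
  int Ho = (x.H + 2 * p - k) / s + 1, Wo = (x.W + 2 * p - k) / s + 1;
  y.resize(Ho, Wo, Cout, x.N);
  arma::fmat Wm(W.w.data(), (arma::uword)k * k * Cin, Cout, false, true);
  const arma::uword HoWo = (arma::uword)Ho * Wo;
  const float* b = bias ? par(E, wkey + ".b").w.data() : nullptr;
  const int NC = chunk_samples(HoWo * (size_t)k * k * Cin, x.N);
  for (int n0 = 0; n0 < x.N; n0 += NC) {
    int nc = std::min(NC, x.N - n0);
    im2col_t<float>(x.data() + (size_t)n0 * x.H * x.W * x.C,
                    x.H, x.W, x.C, nc, k, s, p, Ho, Wo, E.kt);
    E.gm1 = E.kt * Wm;
    for (int j = 0; j < nc; ++j)
      for (int c = 0; c < Cout; ++c) {
        const float* src = E.gm1.colptr(c) + HoWo * j;
        float* dst = y.data() + ((size_t)c + (size_t)Cout * (n0 + j)) * HoWo;
        float bb = b ? b[c] : 0.0f;
        for (arma::uword i = 0; i < HoWo; ++i) dst[i] = src[i] + bb;
      }
  }
}

void conv_bwd(Engine& E, const FT& x, const std::string& wkey, int s, int p,
              const FT& dy, FT* dx, bool bias) {
  Param& W = par(E, wkey + ".w");
  int k = W.dim[0], Cin = W.dim[2], Cout = W.dim[3];
  int Ho = dy.H, Wo = dy.W;
  const arma::uword HoWo = (arma::uword)Ho * Wo;
  arma::fmat Wm(W.w.data(), (arma::uword)k * k * Cin, Cout, false, true);
  arma::fmat dW(W.g.data(), (arma::uword)k * k * Cin, Cout, false, true);
  dW.zeros();
  Param* B = bias ? &par(E, wkey + ".b") : nullptr;
  if (B) std::fill(B->g.begin(), B->g.end(), 0.0f);
  if (dx) {
    dx->resize(x.H, x.W, x.C, x.N);
    std::fill(dx->v.begin(), dx->v.end(), 0.0f);
  }
  const int NC = chunk_samples(HoWo * (size_t)k * k * Cin, x.N);
  for (int n0 = 0; n0 < x.N; n0 += NC) {
    int nc = std::min(NC, x.N - n0);
    im2col_t<float>(x.data() + (size_t)n0 * x.H * x.W * x.C,
                    x.H, x.W, x.C, nc, k, s, p, Ho, Wo, E.kt);
    E.gm1.set_size(HoWo * nc, Cout);  // dy repack
    for (int j = 0; j < nc; ++j)
      for (int c = 0; c < Cout; ++c) {
        const float* src = dy.data() + ((size_t)c + (size_t)Cout * (n0 + j)) * HoWo;
        float* dst = E.gm1.colptr(c) + HoWo * j;
        float acc = 0;
        for (arma::uword i = 0; i < HoWo; ++i) { dst[i] = src[i]; acc += src[i]; }
        if (B) B->g[c] += acc;
      }
    dW += E.kt.t() * E.gm1;
    if (dx) {
      E.gm2 = E.gm1 * Wm.t();
      col2im_t<float>(E.gm2, x.H, x.W, x.C, nc, k, s, p, Ho, Wo,
                      dx->data() + (size_t)n0 * x.H * x.W * x.C);
    }
  }
}

// transposed convolution, weight (k, k, Cout, Cin), stride 2, pad 2, k = 6
void convt_fwd(Engine& E, const FT& x, const std::string& wkey, int s, int p,
               FT& y) {
  Param& W = par(E, wkey + ".w");
  int k = W.dim[0], Cout = W.dim[2], Cin = W.dim[3];
  int Oh = s * (x.H - 1) - 2 * p + k, Ow = s * (x.W - 1) - 2 * p + k;
  y.resize(Oh, Ow, Cout, x.N);
  std::fill(y.v.begin(), y.v.end(), 0.0f);
  arma::fmat Wm(W.w.data(), (arma::uword)k * k * Cout, Cin, false, true);
  const float* b = par(E, wkey + ".b").w.data();
  const arma::uword HW = (arma::uword)x.H * x.W;
  const int NC = chunk_samples(HW * (size_t)k * k * Cout, x.N);
  for (int n0 = 0; n0 < x.N; n0 += NC) {
    int nc = std::min(NC, x.N - n0);
    E.gm1.set_size(HW * nc, Cin);
    for (int j = 0; j < nc; ++j)
      for (int c = 0; c < Cin; ++c) {
        const float* src = x.data() + ((size_t)c + (size_t)Cin * (n0 + j)) * HW;
        std::copy(src, src + HW, E.gm1.colptr(c) + HW * j);
      }
    E.gm2 = E.gm1 * Wm.t();
    col2im_t<float>(E.gm2, Oh, Ow, Cout, nc, k, s, p, x.H, x.W,
                    y.data() + (size_t)n0 * (size_t)Oh * Ow * Cout);
  }
  const size_t OHW = (size_t)Oh * Ow;
  for (int n = 0; n < x.N; ++n)
    for (int c = 0; c < Cout; ++c) {
      float* dst = y.data() + ((size_t)c + (size_t)Cout * n) * OHW;
      for (size_t i = 0; i < OHW; ++i) dst[i] += b[c];
    }
}

void convt_bwd(Engine& E, const FT& x, const std::string& wkey, int s, int p,
               const FT& dy, FT* dx) {
  Param& W = par(E, wkey + ".w");
  Param& B = par(E, wkey + ".b");
  int k = W.dim[0], Cout = W.dim[2], Cin = W.dim[3];
  int Oh = dy.H, Ow = dy.W;
  const arma::uword HW = (arma::uword)x.H * x.W;
  const size_t OHW = (size_t)Oh * Ow;
  arma::fmat Wm(W.w.data(), (arma::uword)k * k * Cout, Cin, false, true);
  arma::fmat dW(W.g.data(), (arma::uword)k * k * Cout, Cin, false, true);
  dW.zeros();
  std::fill(B.g.begin(), B.g.end(), 0.0f);
  if (dx) dx->resize(x.H, x.W, x.C, x.N);
  const int NC = chunk_samples(HW * (size_t)k * k * Cout, x.N);
  for (int n0 = 0; n0 < x.N; n0 += NC) {
    int nc = std::min(NC, x.N - n0);
    im2col_t<float>(dy.data() + (size_t)n0 * OHW * Cout, Oh, Ow, Cout, nc,
                    k, s, p, x.H, x.W, E.kt);
    E.gm1.set_size(HW * nc, Cin);  // x repack
    for (int j = 0; j < nc; ++j)
      for (int c = 0; c < Cin; ++c) {
        const float* src = x.data() + ((size_t)c + (size_t)Cin * (n0 + j)) * HW;
        std::copy(src, src + HW, E.gm1.colptr(c) + HW * j);
      }
    dW += E.kt.t() * E.gm1;
    for (int j = 0; j < nc; ++j)
      for (int c = 0; c < Cout; ++c) {
        const float* src = dy.data() + ((size_t)c + (size_t)Cout * (n0 + j)) * OHW;
        float acc = 0;
        for (size_t i = 0; i < OHW; ++i) acc += src[i];
        B.g[c] += acc;
      }
    if (dx) {
      E.gm2 = E.kt * Wm;
      for (int j = 0; j < nc; ++j)
        for (int c = 0; c < Cin; ++c) {
          const float* src = E.gm2.colptr(c) + HW * j;
          float* dst = dx->data() + ((size_t)c + (size_t)Cin * (n0 + j)) * HW;
          std::copy(src, src + HW, dst);
        }
    }
  }
}

const float BN_EPS_F = 1e-5f;
const float BN_MOM_F = 0.1f;

// training-mode batch norm; saves mean/invstd and refreshes running stats
void bn_fwd(Engine& E, const FT& x, const std::string& key, FT& y, bool training) {
  Param& G = par(E, key + ".gamma");
  Param& Bt = par(E, key + ".beta");
  Param& RM = par(E, key + ".rmean");
  Param& RV = par(E, key + ".rvar");
  int C = x.C;
  const size_t HW = (size_t)x.H * x.W;
  const double M = (double)HW * x.N;
  y.resize(x.H, x.W, C, x.N);
  FT& mean = at(E, key + ".mean"); mean.resize(1, 1, C, 1);
  FT& istd = at(E, key + ".istd"); istd.resize(1, 1, C, 1);
  for (int c = 0; c < C; ++c) {
    float mu, is;
    if (training) {
      double s = 0, s2 = 0;
      for (int n = 0; n < x.N; ++n) {
        const float* src = x.data() + ((size_t)c + (size_t)C * n) * HW;
        for (size_t i = 0; i < HW; ++i) { s += src[i]; s2 += (double)src[i] * src[i]; }
      }
      double m0 = s / M, var = s2 / M - m0 * m0;
      if (var < 0) var = 0;
      mu = (float)m0;
      is = (float)(1.0 / std::sqrt(var + BN_EPS_F));
      double unbias = M > 1 ? M / (M - 1) : 1.0;
      RM.w[c] = (1 - BN_MOM_F) * RM.w[c] + BN_MOM_F * (float)m0;
      RV.w[c] = (1 - BN_MOM_F) * RV.w[c] + BN_MOM_F * (float)(var * unbias);
    } else {
      mu = RM.w[c];
      is = 1.0f / std::sqrt(RV.w[c] + BN_EPS_F);
    }
    mean.v[c] = mu; istd.v[c] = is;
    float g = G.w[c] * is, b = Bt.w[c] - mu * g;
    for (int n = 0; n < x.N; ++n) {
      const float* src = x.data() + ((size_t)c + (size_t)C * n) * HW;
      float* dst = y.data() + ((size_t)c + (size_t)C * n) * HW;
      for (size_t i = 0; i < HW; ++i) dst[i] = src[i] * g + b;
    }
  }
}

void bn_bwd(Engine& E, const FT& x, const std::string& key, const FT& dy, FT& dx) {
  Param& G = par(E, key + ".gamma");
  Param& Bt = par(E, key + ".beta");
  FT& mean = at(E, key + ".mean");
  FT& istd = at(E, key + ".istd");
  int C = x.C;
  const size_t HW = (size_t)x.H * x.W;
  const double M = (double)HW * x.N;
  dx.resize(x.H, x.W, C, x.N);
  for (int c = 0; c < C; ++c) {
    float mu = mean.v[c], is = istd.v[c];
    double sdy = 0, sdyx = 0;
    for (int n = 0; n < x.N; ++n) {
      const float* sx = x.data() + ((size_t)c + (size_t)C * n) * HW;
      const float* sd = dy.data() + ((size_t)c + (size_t)C * n) * HW;
      for (size_t i = 0; i < HW; ++i) {
        sdy += sd[i];
        sdyx += (double)sd[i] * (sx[i] - mu) * is;
      }
    }
    G.g[c] = (float)sdyx;
    Bt.g[c] = (float)sdy;
    float a = (float)(G.w[c] * is / M);
    float fdy = (float)sdy, fdyx = (float)sdyx;
    for (int n = 0; n < x.N; ++n) {
      const float* sx = x.data() + ((size_t)c + (size_t)C * n) * HW;
      const float* sd = dy.data() + ((size_t)c + (size_t)C * n) * HW;
      float* dd = dx.data() + ((size_t)c + (size_t)C * n) * HW;
      for (size_t i = 0; i < HW; ++i) {
        float xhat = (sx[i] - mu) * is;
        dd[i] = a * ((float)M * sd[i] - fdy - xhat * fdyx);
      }
    }
  }
}

void relu_fwd(const FT& x, FT& y) {
  y.resize(x.H, x.W, x.C, x.N);
  for (size_t i = 0; i < x.numel(); ++i) y.v[i] = x.v[i] > 0 ? x.v[i] : 0.0f;
}

void relu_bwd(const FT& dy, const FT& ref, FT& dx) {
  dx.resize(dy.H, dy.W, dy.C, dy.N);
  for (size_t i = 0; i < dy.numel(); ++i) dx.v[i] = ref.v[i] > 0 ? dy.v[i] : 0.0f;
}

void concat_c(const FT& a, const FT& b, FT& y) {
  y.resize(a.H, a.W, a.C + b.C, a.N);
  const size_t HW = (size_t)a.H * a.W;
  for (int n = 0; n < a.N; ++n) {
    std::copy(a.data() + (size_t)n * HW * a.C, a.data() + (size_t)(n + 1) * HW * a.C,
              y.data() + (size_t)n * HW * y.C);
    std::copy(b.data() + (size_t)n * HW * b.C, b.data() + (size_t)(n + 1) * HW * b.C,
              y.data() + (size_t)n * HW * y.C + HW * a.C);
  }
}

void split_c(const FT& x, int c1, FT& a, FT& b) {
  a.resize(x.H, x.W, c1, x.N);
  b.resize(x.H, x.W, x.C - c1, x.N);
  const size_t HW = (size_t)x.H * x.W;
  for (int n = 0; n < x.N; ++n) {
    std::copy(x.data() + (size_t)n * HW * x.C, x.data() + (size_t)n * HW * x.C + HW * c1,
              a.data() + (size_t)n * HW * c1);
    std::copy(x.data() + (size_t)n * HW * x.C + HW * c1, x.data() + (size_t)(n + 1) * HW * x.C,
              b.data() + (size_t)n * HW * (x.C - c1));
  }
}

void shuffle_fwd(const FT& x, int r, FT& y) {
  int Co = x.C / (r * r), Ho = x.H * r, Wo = x.W * r;
  y.resize(Ho, Wo, Co, x.N);
  for (int n = 0; n < x.N; ++n)
    for (int c = 0; c < Co; ++c)
      for (int xo = 0; xo < Wo; ++xo)
        for (int yo = 0; yo < Ho; ++yo) {
          int ci = c * r * r + (yo % r) * r + (xo % r);
          size_t src = (size_t)(yo / r) + (size_t)x.H * ((xo / r) + (size_t)x.W * (ci + (size_t)x.C * n));
          size_t dst = (size_t)yo + (size_t)Ho * (xo + (size_t)Wo * (c + (size_t)Co * n));
          y.v[dst] = x.v[src];
        }
}

void shuffle_bwd(const FT& dy, int r, FT& dx) {
  int Ci = dy.C * r * r, Hi = dy.H / r, Wi = dy.W / r;
  dx.resize(Hi, Wi, Ci, dy.N);
  for (int n = 0; n < dy.N; ++n)
    for (int c = 0; c < dy.C; ++c)
      for (int xo = 0; xo < dy.W; ++xo)
        for (int yo = 0; yo < dy.H; ++yo) {
          int ci = c * r * r + (yo % r) * r + (xo % r);
          size_t dst = (size_t)(yo / r) + (size_t)Hi * ((xo / r) + (size_t)Wi * (ci + (size_t)Ci * n));
          size_t src = (size_t)yo + (size_t)dy.H * (xo + (size_t)dy.W * (c + (size_t)dy.C * n));
          dx.v[dst] = dy.v[src];
        }
}

void coords(int i, int osz, int isz, int& i0, int& i1, float& f) {
  if (osz == 1 || isz == 1) { i0 = i1 = 0; f = 0.0f; return; }
  double s = (double)i * (isz - 1) / (osz - 1);
  i0 = (int)std::floor(s);
  if (i0 > isz - 2) i0 = isz - 2;
  i1 = i0 + 1;
  f = (float)(s - i0);
}

void bilinear_fwd(const FT& x, int oh, int ow, FT& y) {
  y.resize(oh, ow, x.C, x.N);
  std::vector<int> h0(oh), h1(oh), w0(ow), w1(ow);
  std::vector<float> fh(oh), fw(ow);
  for (int i = 0; i < oh; ++i) coords(i, oh, x.H, h0[i], h1[i], fh[i]);
  for (int j = 0; j < ow; ++j) coords(j, ow, x.W, w0[j], w1[j], fw[j]);
  for (int n = 0; n < x.N; ++n)
    for (int c = 0; c < x.C; ++c) {
      const float* xc = x.data() + ((size_t)c + (size_t)x.C * n) * x.H * x.W;
      float* oc = y.data() + ((size_t)c + (size_t)x.C * n) * oh * ow;
      for (int j = 0; j < ow; ++j)
        for (int i = 0; i < oh; ++i) {
          float a = xc[h0[i] + (size_t)x.H * w0[j]], bb = xc[h1[i] + (size_t)x.H * w0[j]];
          float cc = xc[h0[i] + (size_t)x.H * w1[j]], dd = xc[h1[i] + (size_t)x.H * w1[j]];
          float top = a + (cc - a) * fw[j];
          float bot = bb + (dd - bb) * fw[j];
          oc[i + (size_t)oh * j] = top + (bot - top) * fh[i];
        }
    }
}

void bilinear_bwd(const FT& dy, int ih, int iw, FT& dx) {
  dx.resize(ih, iw, dy.C, dy.N);
  std::fill(dx.v.begin(), dx.v.end(), 0.0f);
  std::vector<int> h0(dy.H), h1(dy.H), w0(dy.W), w1(dy.W);
  std::vector<float> fh(dy.H), fw(dy.W);
  for (int i = 0; i < dy.H; ++i) coords(i, dy.H, ih, h0[i], h1[i], fh[i]);
  for (int j = 0; j < dy.W; ++j) coords(j, dy.W, iw, w0[j], w1[j], fw[j]);
  for (int n = 0; n < dy.N; ++n)
    for (int c = 0; c < dy.C; ++c) {
      const float* gc = dy.data() + ((size_t)c + (size_t)dy.C * n) * dy.H * dy.W;
      float* xc = dx.data() + ((size_t)c + (size_t)dy.C * n) * ih * iw;
      for (int j = 0; j < dy.W; ++j)
        for (int i = 0; i < dy.H; ++i) {
          float g = gc[i + (size_t)dy.H * j];
          float wj1 = fw[j], wj0 = 1.0f - wj1, wi1 = fh[i], wi0 = 1.0f - wi1;
          xc[h0[i] + (size_t)ih * w0[j]] += g * wi0 * wj0;
          xc[h1[i] + (size_t)ih * w0[j]] += g * wi1 * wj0;
          xc[h0[i] + (size_t)ih * w1[j]] += g * wi0 * wj1;
          xc[h1[i] + (size_t)ih * w1[j]] += g * wi1 * wj1;
        }
    }
}

// ---- composite blocks ---------------------------------------------------

// conv -> bn -> [relu] -> conv -> bn -> relu; names <id>.conv1 / .bn1 / ...
void block_fwd(Engine& E, const std::string& id, const FT& x, FT& out, bool training) {
  conv_fwd(E, x, id + ".conv1", 1, 1, at(E, id + ".y1"), false);
  bn_fwd(E, at(E, id + ".y1"), id + ".bn1", at(E, id + ".n1"), training);
  FT& a1 = at(E, id + ".a1");
  if (E.deferred_order) a1 = at(E, id + ".n1");
  else relu_fwd(at(E, id + ".n1"), a1);
  conv_fwd(E, a1, id + ".conv2", 1, 1, at(E, id + ".y2"), false);
  bn_fwd(E, at(E, id + ".y2"), id + ".bn2", at(E, id + ".n2"), training);
  relu_fwd(at(E, id + ".n2"), out);
}

void block_bwd(Engine& E, const std::string& id, const FT& x, const FT& out,
               const FT& dy, FT* dx) {
  FT& t1 = at(E, id + ".t1");
  relu_bwd(dy, out, t1);
  bn_bwd(E, at(E, id + ".y2"), id + ".bn2", t1, at(E, id + ".t2"));
  conv_bwd(E, at(E, id + ".a1"), id + ".conv2", 1, 1, at(E, id + ".t2"),
           &at(E, id + ".t3"), false);
  FT* da1 = &at(E, id + ".t3");
  if (!E.deferred_order) {
    relu_bwd(*da1, at(E, id + ".a1"), at(E, id + ".t4"));
    da1 = &at(E, id + ".t4");
  }
  bn_bwd(E, at(E, id + ".y1"), id + ".bn1", *da1, at(E, id + ".t5"));
  conv_bwd(E, x, id + ".conv1", 1, 1, at(E, id + ".t5"), dx, false);
}

void down_fwd(Engine& E, const std::string& id, const FT& x, FT& out, bool training) {
  conv_fwd(E, x, id + ".conv", 2, 1, at(E, id + ".y"), false);
  bn_fwd(E, at(E, id + ".y"), id + ".bn", at(E, id + ".n"), training);
  relu_fwd(at(E, id + ".n"), out);
}

void down_bwd(Engine& E, const std::string& id, const FT& x, const FT& out,
              const FT& dy, FT& dx) {
  relu_bwd(dy, out, at(E, id + ".t1"));
  bn_bwd(E, at(E, id + ".y"), id + ".bn", at(E, id + ".t1"), at(E, id + ".t2"));
  conv_bwd(E, x, id + ".conv", 2, 1, at(E, id + ".t2"), &dx, false);
}

void sigmoid_ip(FT& x) {
  for (size_t i = 0; i < x.numel(); ++i) x.v[i] = 1.0f / (1.0f + std::exp(-x.v[i]));
}

// ---- network assembly ---------------------------------------------------

std::string sid(const char* base, int i) { return std::string(base) + "." + std::to_string(i); }

// forward pass; input already staged in A["x"]; returns name of prob tensor
void forward(Engine& E, bool training) {
  FT& x = at(E, "x");
  // multiscale pyramids
  if (E.ms)
    for (int t = 2; t <= 4; ++t) {
      bilinear_fwd(x, x.H >> (t - 1), x.W >> (t - 1), at(E, sid("msin", t)));
      conv_fwd(E, at(E, sid("msin", t)), sid("ms", t - 1) + ".conv", 1, 1,
               at(E, sid("msy", t)), false);
      bn_fwd(E, at(E, sid("msy", t)), sid("ms", t - 1) + ".bn",
             at(E, sid("msn", t)), training);
      relu_fwd(at(E, sid("msn", t)), at(E, sid("msa", t)));
    }
  block_fwd(E, "enc.1", x, at(E, "skip.1"), training);
  for (int t = 2; t <= 4; ++t) {
    down_fwd(E, sid("down", t - 1), at(E, sid("skip", t - 1)),
             at(E, sid("dn", t - 1)), training);
    FT* stage_in = &at(E, sid("dn", t - 1));
    if (E.ms) {
      concat_c(*stage_in, at(E, sid("msa", t)), at(E, sid("cat", t)));
      stage_in = &at(E, sid("cat", t));
    }
    block_fwd(E, sid("enc", t), *stage_in, at(E, sid("skip", t)), training);
  }
  down_fwd(E, "down.4", at(E, "skip.4"), at(E, "dn.4"), training);
  block_fwd(E, "bridge", at(E, "dn.4"), at(E, "cur.0"), training);
  for (int d = 1; d <= 4; ++d) {
    FT& cur = at(E, sid("cur", d - 1));
    FT& up = at(E, sid("upy", d));
    if (E.mode == 0) {
      conv_fwd(E, cur, sid("up", d), 1, 1, at(E, sid("upm", d)), false);
      shuffle_fwd(at(E, sid("upm", d)), E.r, up);
    } else if (E.mode == 1) {
      conv_fwd(E, cur, sid("up", d), 1, 1, at(E, sid("upm", d)), true);
      bilinear_fwd(at(E, sid("upm", d)), E.r * cur.H, E.r * cur.W, up);
    } else {
      convt_fwd(E, cur, sid("up", d), 2, 2, up);
    }
    FT& Eskip = at(E, sid("skip", 5 - d));
    FT& merged = at(E, sid("mrg", d));
    if (E.gating) {
      concat_c(Eskip, up, at(E, sid("gA", d)));
      conv_fwd(E, at(E, sid("gA", d)), sid("gate", d), 1, 0, at(E, sid("gz", d)), true);
      FT& alpha = at(E, sid("galpha", d));
      alpha = at(E, sid("gz", d));
      sigmoid_ip(alpha);
      FT& gated = at(E, sid("gC", d));
      gated.resize(Eskip.H, Eskip.W, Eskip.C, Eskip.N);
      if (E.gate_single) {
        const size_t HW = (size_t)Eskip.H * Eskip.W;
        for (int n = 0; n < Eskip.N; ++n)
          for (int c = 0; c < Eskip.C; ++c) {
            const float* e = Eskip.data() + ((size_t)c + (size_t)Eskip.C * n) * HW;
            const float* al = alpha.data() + (size_t)n * HW;
            float* g = gated.data() + ((size_t)c + (size_t)Eskip.C * n) * HW;
            for (size_t i = 0; i < HW; ++i) g[i] = e[i] * al[i] + e[i];
          }
      } else {
        for (size_t i = 0; i < Eskip.numel(); ++i)
          gated.v[i] = Eskip.v[i] * alpha.v[i] + Eskip.v[i];
      }
      concat_c(gated, up, merged);
    } else {
      concat_c(Eskip, up, merged);
    }
    block_fwd(E, sid("dec", d), merged, at(E, sid("cur", d)), training);
  }
  conv_fwd(E, at(E, "cur.4"), "head", 1, 0, at(E, "logits"), true);
  FT& prob = at(E, "prob");
  prob = at(E, "logits");
  sigmoid_ip(prob);
}

void backward(Engine& E) {
  // dlogits staged in A["dlogits"]
  conv_bwd(E, at(E, "cur.4"), "head", 1, 0, at(E, "dlogits"), &at(E, "dcur.4"), true);
  for (int d = 4; d >= 1; --d) {
    FT& merged = at(E, sid("mrg", d));
    block_bwd(E, sid("dec", d), merged, at(E, sid("cur", d)),
              at(E, sid("dcur", d)), &at(E, sid("dmrg", d)));
    FT& Eskip = at(E, sid("skip", 5 - d));
    FT& dE = at(E, sid("dskip", 5 - d));
    FT& dU = at(E, sid("dup", d));
    if (E.gating) {
      split_c(at(E, sid("dmrg", d)), Eskip.C, at(E, sid("dgC", d)), dU);
      FT& dYl = at(E, sid("dgC", d));
      FT& alpha = at(E, sid("galpha", d));
      // dE = dYl*(1 + alpha); dalpha = dYl * E
      dE.resize(Eskip.H, Eskip.W, Eskip.C, Eskip.N);
      FT& dz = at(E, sid("dgz", d));
      dz.resize(alpha.H, alpha.W, alpha.C, alpha.N);
      if (E.gate_single) {
        const size_t HW = (size_t)Eskip.H * Eskip.W;
        std::fill(dz.v.begin(), dz.v.end(), 0.0f);
        for (int n = 0; n < Eskip.N; ++n) {
          const float* al = alpha.data() + (size_t)n * HW;
          float* z = dz.data() + (size_t)n * HW;
          for (int c = 0; c < Eskip.C; ++c) {
            const float* e = Eskip.data() + ((size_t)c + (size_t)Eskip.C * n) * HW;
            const float* dyl = dYl.data() + ((size_t)c + (size_t)Eskip.C * n) * HW;
            float* de = dE.data() + ((size_t)c + (size_t)Eskip.C * n) * HW;
            for (size_t i = 0; i < HW; ++i) {
              de[i] = dyl[i] * (1.0f + al[i]);
              z[i] += dyl[i] * e[i];
            }
          }
          for (size_t i = 0; i < HW; ++i) z[i] *= al[i] * (1.0f - al[i]);
        }
      } else {
        for (size_t i = 0; i < Eskip.numel(); ++i) {
          dE.v[i] = dYl.v[i] * (1.0f + alpha.v[i]);
          dz.v[i] = dYl.v[i] * Eskip.v[i] * alpha.v[i] * (1.0f - alpha.v[i]);
        }
      }
      conv_bwd(E, at(E, sid("gA", d)), sid("gate", d), 1, 0, dz,
               &at(E, sid("dgA", d)), true);
      FT& dga = at(E, sid("dgA", d));
      split_c(dga, Eskip.C, at(E, sid("dgAe", d)), at(E, sid("dgAd", d)));
      FT& dgae = at(E, sid("dgAe", d));
      FT& dgad = at(E, sid("dgAd", d));
      for (size_t i = 0; i < dE.numel(); ++i) dE.v[i] += dgae.v[i];
      for (size_t i = 0; i < dU.numel(); ++i) dU.v[i] += dgad.v[i];
    } else {
      split_c(at(E, sid("dmrg", d)), Eskip.C, dE, dU);
    }
    FT& cur = at(E, sid("cur", d - 1));
    FT& dcur = at(E, sid("dcur", d - 1));
    if (E.mode == 0) {
      shuffle_bwd(dU, E.r, at(E, sid("dupm", d)));
      conv_bwd(E, cur, sid("up", d), 1, 1, at(E, sid("dupm", d)), &dcur, false);
    } else if (E.mode == 1) {
      FT& upm = at(E, sid("upm", d));
      bilinear_bwd(dU, upm.H, upm.W, at(E, sid("dupm", d)));
      conv_bwd(E, cur, sid("up", d), 1, 1, at(E, sid("dupm", d)), &dcur, true);
    } else {
      convt_bwd(E, cur, sid("up", d), 2, 2, dU, &dcur);
    }
  }
  block_bwd(E, "bridge", at(E, "dn.4"), at(E, "cur.0"), at(E, "dcur.0"),
            &at(E, "ddn.4"));
  down_bwd(E, "down.4", at(E, "skip.4"), at(E, "dn.4"), at(E, "ddn.4"),
           at(E, "dstage.4"));
  for (int t = 4; t >= 2; --t) {
    FT& dstage = at(E, sid("dstage", t));
    FT& dskip = at(E, sid("dskip", t));
    for (size_t i = 0; i < dstage.numel(); ++i) dstage.v[i] += dskip.v[i];
    FT* stage_in = E.ms ? &at(E, sid("cat", t)) : &at(E, sid("dn", t - 1));
    block_bwd(E, sid("enc", t), *stage_in, at(E, sid("skip", t)), dstage,
              &at(E, sid("dcat", t)));
    FT* ddown = &at(E, sid("dcat", t));
    if (E.ms) {
      FT& dn = at(E, sid("dn", t - 1));
      split_c(at(E, sid("dcat", t)), dn.C, at(E, sid("ddn2", t - 1)),
              at(E, sid("dmsa", t)));
      ddown = &at(E, sid("ddn2", t - 1));
      relu_bwd(at(E, sid("dmsa", t)), at(E, sid("msa", t)), at(E, sid("dmsn", t)));
      bn_bwd(E, at(E, sid("msy", t)), sid("ms", t - 1) + ".bn",
             at(E, sid("dmsn", t)), at(E, sid("dmsy", t)));
      conv_bwd(E, at(E, sid("msin", t)), sid("ms", t - 1) + ".conv", 1, 1,
               at(E, sid("dmsy", t)), nullptr, false);
    }
    down_bwd(E, sid("down", t - 1), at(E, sid("skip", t - 1)),
             at(E, sid("dn", t - 1)), *ddown, at(E, sid("dstage", t - 1)));
  }
  FT& dstage1 = at(E, "dstage.1");
  FT& dskip1 = at(E, "dskip.1");
  for (size_t i = 0; i < dstage1.numel(); ++i) dstage1.v[i] += dskip1.v[i];
  block_bwd(E, "enc.1", at(E, "x"), at(E, "skip.1"), dstage1, nullptr);
}

void adam_update(Engine& E, double lr) {
  E.t += 1;
  const double c1 = 1.0 - std::pow(E.beta1, (double)E.t);
  const double c2 = 1.0 - std::pow(E.beta2, (double)E.t);
  for (auto& kv : E.P) {
    Param& p = kv.second;
    if (!p.learnable) continue;
    const float b1 = (float)E.beta1, b2 = (float)E.beta2;
    for (size_t i = 0; i < p.n(); ++i) {
      float g = p.g[i] + (float)E.wd * p.w[i];
      p.m[i] = b1 * p.m[i] + (1 - b1) * g;
      p.v[i] = b2 * p.v[i] + (1 - b2) * g * g;
      double mh = p.m[i] / c1, vh = p.v[i] / c2;
      p.w[i] -= (float)(lr * mh / (std::sqrt(vh) + E.eps));
    }
  }
}

void stage_input(Engine& E, const NumericVector& x) {
  IntegerVector d = x.attr("dim");
  FT& xt = at(E, "x");
  xt.resize(d[0], d[1], d[2], d[3]);
  const double* px = REAL(x);
  for (size_t i = 0; i < xt.numel(); ++i) xt.v[i] = (float)px[i];
}

}  // namespace

// [[Rcpp::export]]
SEXP cpp_engine_create(List flat_params, List config) {
  Engine* E = new Engine();
  CharacterVector nms = flat_params.names();
  for (int i = 0; i < flat_params.size(); ++i) {
    NumericVector v = flat_params[i];
    std::string key = as<std::string>(nms[i]);
    Param p;
    p.w.resize(v.size());
    for (R_xlen_t j = 0; j < v.size(); ++j) p.w[j] = (float)v[j];
    if (v.hasAttribute("dim")) p.dim = as<std::vector<int>>(v.attr("dim"));
    else p.dim = { (int)v.size() };
    // running statistics are tracked but not optimized
    auto ends_with = [](const std::string& s, const char* suf) {
      std::string t(suf);
      return s.size() >= t.size() && s.compare(s.size() - t.size(), t.size(), t) == 0;
    };
    p.learnable = !(ends_with(key, ".rmean") || ends_with(key, ".rvar"));
    if (p.learnable) {
      p.g.assign(p.w.size(), 0.0f);
      p.m.assign(p.w.size(), 0.0f);
      p.v.assign(p.w.size(), 0.0f);
    }
    E->P[key] = std::move(p);
  }
  E->in_ch = as<int>(config["in_channels"]);
  E->bw = as<int>(config["base_width"]);
  std::string mode = as<std::string>(config["upsample_mode"]);
  E->mode = mode == "adaptive" ? 0 : (mode == "bilinear" ? 1 : 2);
  E->gating = as<bool>(config["gating"]);
  E->ms = as<bool>(config["multiscale_input"]);
  E->r = as<int>(config["r"]);
  E->deferred_order = as<std::string>(config["norm_order"]) == "deferred";
  E->gate_single = as<std::string>(config["gate_channels"]) == "single";
  return XPtr<Engine>(E, true);
}

// [[Rcpp::export]]
void cpp_engine_set_optim(SEXP ptr, double beta1, double beta2, double eps, double wd) {
  XPtr<Engine> E(ptr);
  E->beta1 = beta1; E->beta2 = beta2; E->eps = eps; E->wd = wd;
}

// one optimization step on a batch; returns the clipped mean BCE loss
// [[Rcpp::export]]
double cpp_engine_step(SEXP ptr, NumericVector x, NumericVector y, double lr) {
  XPtr<Engine> E(ptr);
  stage_input(*E, x);
  forward(*E, true);
  FT& prob = E->A["prob"];
  const double* py = REAL(y);
  if ((R_xlen_t)prob.numel() != y.size()) stop("engine: label shape mismatch");
  double loss = 0;
  const double eps = 1e-7;
  FT& dlog = E->A["dlogits"];
  dlog.resize(prob.H, prob.W, prob.C, prob.N);
  const double M = (double)prob.numel();
  for (size_t i = 0; i < prob.numel(); ++i) {
    double p = prob.v[i], yy = py[i];
    double pc = std::min(std::max(p, eps), 1 - eps);
    loss -= yy * std::log(pc) + (1 - yy) * std::log(1 - pc);
    dlog.v[i] = (float)((p - yy) / M);
  }
  loss /= M;
  backward(*E);
  adam_update(*E, lr);
  return loss;
}

// inference forward (running statistics); returns probabilities
// [[Rcpp::export]]
NumericVector cpp_engine_forward(SEXP ptr, NumericVector x) {
  XPtr<Engine> E(ptr);
  stage_input(*E, x);
  forward(*E, false);
  FT& prob = E->A["prob"];
  NumericVector out(prob.numel());
  for (size_t i = 0; i < prob.numel(); ++i) out[i] = prob.v[i];
  out.attr("dim") = IntegerVector::create(prob.H, prob.W, prob.C, prob.N);
  return out;
}

// export all parameters (including refreshed running statistics)
// [[Rcpp::export]]
List cpp_engine_params(SEXP ptr) {
  XPtr<Engine> E(ptr);
  List out;
  for (auto& kv : E->P) {
    NumericVector v(kv.second.w.size());
    for (size_t i = 0; i < kv.second.w.size(); ++i) v[i] = kv.second.w[i];
    if (kv.second.dim.size() > 1)
      v.attr("dim") = wrap(kv.second.dim);
    out[kv.first] = v;
  }
  return out;
}

// gradients after the last step, for diagnostics/tests
// [[Rcpp::export]]
List cpp_engine_grads(SEXP ptr) {
  XPtr<Engine> E(ptr);
  List out;
  for (auto& kv : E->P) {
    if (!kv.second.learnable) continue;
    NumericVector v(kv.second.g.size());
    for (size_t i = 0; i < kv.second.g.size(); ++i) v[i] = kv.second.g[i];
    if (kv.second.dim.size() > 1) v.attr("dim") = wrap(kv.second.dim);
    out[kv.first] = v;
  }
  return out;
}
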