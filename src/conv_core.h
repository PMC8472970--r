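#ifndef GSAUNET_CONV_CORE_H
#define GSAUNET_CONV_CORE_H

#include <RcppArmadillo.h>
#include <algorithm>

// ---- im2col / col2im ----------------------------------------------------
// Transposed layout: Kt is (L x k*k*C) with L = Ho*Wo*N,
// l = ho + Ho*(wo + Wo*n), column q = di + k*dj + k*k*c. Writing down each
// Kt column walks the output rows contiguously, and for stride 1 the reads
// from x are contiguous runs, so construction is memory-bandwidth bound.

template <typename eT>
static void im2col_t(const eT* x, int H, int W, int C, int N,
                     int k, int s, int p, int Ho, int Wo, arma::Mat<eT>& Kt) {
  Kt.set_size((arma::uword)Ho * Wo * N, (arma::uword)k * k * C);
  for (int c = 0; c < C; ++c)
    for (int dj = 0; dj < k; ++dj)
      for (int di = 0; di < k; ++di) {
        eT* dst = Kt.colptr(di + (size_t)k * dj + (size_t)k * k * c);
        for (int n = 0; n < N; ++n) {
          const eT* xc = x + ((size_t)c + (size_t)C * n) * H * W;
          for (int wo = 0; wo < Wo; ++wo) {
            eT* d2 = dst + (size_t)Ho * (wo + (size_t)Wo * n);
            int wj = wo * s - p + dj;
            if (wj < 0 || wj >= W) { std::fill(d2, d2 + Ho, eT(0)); continue; }
            const eT* xcol = xc + (size_t)H * wj;
            if (s == 1) {
              int hi0 = di - p;  // hi = ho + hi0
              int lo = std::max(0, -hi0);
              int hi = std::min(Ho, H - hi0);
              for (int ho = 0; ho < lo; ++ho) d2[ho] = eT(0);
              if (hi > lo) std::copy(xcol + lo + hi0, xcol + hi + hi0, d2 + lo);
              for (int ho = std::max(hi, lo); ho < Ho; ++ho) d2[ho] = eT(0);
            } else {
              for (int ho = 0; ho < Ho; ++ho) {
                int h2 = ho * s - p + di;
                d2[ho] = (h2 >= 0 && h2 < H) ? xcol[h2] : eT(0);
              }
            }
          }
        }
      }
}

template <typename eT>
static void col2im_t(const arma::Mat<eT>& Kt, int H, int W, int C, int N,
                     int k, int s, int p, int Ho, int Wo, eT* x) {
  for (int c = 0; c < C; ++c)
    for (int dj = 0; dj < k; ++dj)
      for (int di = 0; di < k; ++di) {
        const eT* src = Kt.colptr(di + (size_t)k * dj + (size_t)k * k * c);
        for (int n = 0; n < N; ++n) {
          eT* xc = x + ((size_t)c + (size_t)C * n) * H * W;
          for (int wo = 0; wo < Wo; ++wo) {
            const eT* s2 = src + (size_t)Ho * (wo + (size_t)Wo * n);
            int wj = wo * s - p + dj;
            if (wj < 0 || wj >= W) continue;
            eT* xcol = xc + (size_t)H * wj;
            if (s == 1) {
              int hi0 = di - p;
              int lo = std::max(0, -hi0);
              int hi = std::min(Ho, H - hi0);
              for (int ho = lo; ho < hi; ++ho) xcol[ho + hi0] += s2[ho];
            } else {
              for (int ho = 0; ho < Ho; ++ho) {
                int h2 = ho * s - p + di;
                if (h2 >= 0 && h2 < H) xcol[h2] += s2[ho];
              }
            }
          }
        }
      }
}


// samples per im2col chunk: keep the buffer around ~4 MB so deep layers
// with tiny spatial extent still feed BLAS adequately sized GEMMs
static inline int chunk_samples(size_t per_sample_elems, int N) {
  size_t target = 1000000;
  int c = (int)(target / (per_sample_elems ? per_sample_elems : 1));
  if (c < 1) c = 1;
  if (c > N) c = N;
  return c;
}



#endif
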