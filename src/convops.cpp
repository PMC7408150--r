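#include <Rcpp.h>
using namespace Rcpp;

// Images are stored as R arrays (H, W, C, N), column-major. im2col unrolls
// receptive fields so a convolution becomes one BLAS matrix product in R.
// Row order of the patch matrix: i (out row) fastest, then j, then n.
// Column order: ki fastest, then kj, then input channel, matching
// matrix(w, kh*kw*Cin, Cout) for a kernel array (kh, kw, Cin, Cout).

static inline int reflect_idx(int p, int n) {
  // reflect-101: -1 -> 1, n -> n-2; valid for pad < n
  if (p < 0) p = -p;
  if (p >= n) p = 2 * n - 2 - p;
  return p;
}

// [[Rcpp::export(name = ".im2col_batch")]]
NumericMatrix im2col_batch(NumericVector x, int H, int W, int C, int N,
                           int kh, int kw, int stride, int pad,
                           int pad_mode) {
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  const int rows = N * Ho * Wo;
  const int cols = kh * kw * C;
  NumericMatrix out(rows, cols);
  const double* xp = x.begin();
  double* op = out.begin();
  const R_xlen_t planeHW = (R_xlen_t)H * W;
  const R_xlen_t imgsz = planeHW * C;

  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int col = ki + kh * (kj + kw * c);
        double* ocol = op + (R_xlen_t)col * rows;
        for (int n = 0; n < N; ++n) {
          const double* img = xp + (R_xlen_t)n * imgsz + (R_xlen_t)c * planeHW;
          for (int j = 0; j < Wo; ++j) {
            int wsrc = j * stride - pad + kj;
            bool wok = (wsrc >= 0 && wsrc < W);
            int wref = pad_mode == 1 ? reflect_idx(wsrc, W) : wsrc;
            R_xlen_t base = (R_xlen_t)n * Ho * Wo + (R_xlen_t)j * Ho;
            for (int i = 0; i < Ho; ++i) {
              int hsrc = i * stride - pad + ki;
              double v = 0.0;
              if (pad_mode == 1) {
                v = img[(R_xlen_t)wref * H + reflect_idx(hsrc, H)];
              } else if (wok && hsrc >= 0 && hsrc < H) {
                v = img[(R_xlen_t)wsrc * H + hsrc];
              }
              ocol[base + i] = v;
            }
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col_batch: scatter-add patch-matrix values back to images.
// [[Rcpp::export(name = ".col2im_batch")]]
NumericVector col2im_batch(NumericMatrix cols, int H, int W, int C, int N,
                           int kh, int kw, int stride, int pad,
                           int pad_mode) {
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  const int rows = N * Ho * Wo;
  NumericVector x((R_xlen_t)H * W * C * N);
  double* xp = x.begin();
  const double* cp = cols.begin();
  const R_xlen_t planeHW = (R_xlen_t)H * W;
  const R_xlen_t imgsz = planeHW * C;

  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int col = ki + kh * (kj + kw * c);
        const double* ccol = cp + (R_xlen_t)col * rows;
        for (int n = 0; n < N; ++n) {
          double* img = xp + (R_xlen_t)n * imgsz + (R_xlen_t)c * planeHW;
          for (int j = 0; j < Wo; ++j) {
            int wsrc = j * stride - pad + kj;
            bool wok = (wsrc >= 0 && wsrc < W);
            int wref = pad_mode == 1 ? reflect_idx(wsrc, W) : wsrc;
            R_xlen_t base = (R_xlen_t)n * Ho * Wo + (R_xlen_t)j * Ho;
            for (int i = 0; i < Ho; ++i) {
              int hsrc = i * stride - pad + ki;
              if (pad_mode == 1) {
                img[(R_xlen_t)wref * H + reflect_idx(hsrc, H)] += ccol[base + i];
              } else if (wok && hsrc >= 0 && hsrc < H) {
                img[(R_xlen_t)wsrc * H + hsrc] += ccol[base + i];
              }
            }
          }
        }
      }
    }
  }
  return x;
}

// 2x2 max pooling, stride 2. Returns pooled values and 1-based argmax
// indices into the flattened input, for the backward scatter.
// [[Rcpp::export(name = ".maxpool2_fwd")]]
List maxpool2_fwd(NumericVector x, int H, int W, int C, int N) {
  const int Ho = H / 2, Wo = W / 2;
  NumericVector out((R_xlen_t)Ho * Wo * C * N);
  IntegerVector idx((R_xlen_t)Ho * Wo * C * N);
  const double* xp = x.begin();
  R_xlen_t o = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const R_xlen_t off = ((R_xlen_t)n * C + c) * H * W;
      for (int j = 0; j < Wo; ++j) {
        for (int i = 0; i < Ho; ++i) {
          R_xlen_t p00 = off + (R_xlen_t)(2 * j) * H + 2 * i;
          R_xlen_t best = p00;
          double v = xp[p00];
          if (xp[p00 + 1] > v) { v = xp[p00 + 1]; best = p00 + 1; }
          R_xlen_t p01 = p00 + H;
          if (xp[p01] > v) { v = xp[p01]; best = p01; }
          if (xp[p01 + 1] > v) { v = xp[p01 + 1]; best = p01 + 1; }
          out[o] = v;
          idx[o] = (int)(best + 1);
          ++o;
        }
      }
    }
  }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool2_bwd")]]
NumericVector maxpool2_bwd(NumericVector dout, IntegerVector idx,
                           R_xlen_t input_len) {
  NumericVector dx(input_len);
  for (R_xlen_t k = 0; k < dout.size(); ++k) dx[idx[k] - 1] += dout[k];
  return dx;
}
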