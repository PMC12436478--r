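#include <Rcpp.h>
#include <cstring>

using namespace Rcpp;

// Feature maps are stored as (C x H*W*N) matrices, pixel index runs h fastest,
// then w, then sample n (all 1-based on the R side). im2col unrolls k x k
// receptive fields (zero padding, arbitrary stride/dilation) into a
// (C*k*k) x (Ho*Wo*N) matrix whose row order is c fastest, then kh, then kw.

// [[Rcpp::export]]
NumericMatrix im2col_cpp(const NumericMatrix& x, int H, int W, int N,
                         int k, int stride, int dil) {
  const int C = x.nrow();
  const int pad = dil * (k - 1) / 2;
  const int Ho = (H + 2 * pad - dil * (k - 1) - 1) / stride + 1;
  const int Wo = (W + 2 * pad - dil * (k - 1) - 1) / stride + 1;
  const int R = C * k * k;
  NumericMatrix cols(R, Ho * Wo * N);
  const double* xp = REAL(x);
  double* cp = REAL(cols);
  const size_t cbytes = C * sizeof(double);
  for (int n = 0; n < N; ++n) {
    const size_t in_off = (size_t)n * H * W;
    const size_t out_off = (size_t)n * Ho * Wo;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        double* dst = cp + (out_off + (size_t)wo * Ho + ho) * R;
        for (int kw = 0; kw < k; ++kw) {
          const int wi = wo * stride - pad + kw * dil;
          const bool wok = (wi >= 0 && wi < W);
          for (int kh = 0; kh < k; ++kh) {
            const int hi = ho * stride - pad + kh * dil;
            double* d = dst + (kw * k + kh) * C;
            if (wok && hi >= 0 && hi < H)
              std::memcpy(d, xp + (in_off + (size_t)wi * H + hi) * C, cbytes);
            else
              std::memset(d, 0, cbytes);
          }
        }
      }
    }
  }
  return cols;
}

// Adjoint of im2col: scatter-add column gradients back onto the input grid.
// [[Rcpp::export]]
NumericMatrix col2im_cpp(const NumericMatrix& cols, int C, int H, int W,
                         int N, int k, int stride, int dil) {
  const int pad = dil * (k - 1) / 2;
  const int Ho = (H + 2 * pad - dil * (k - 1) - 1) / stride + 1;
  const int Wo = (W + 2 * pad - dil * (k - 1) - 1) / stride + 1;
  const int R = C * k * k;
  NumericMatrix x(C, H * W * N);
  const double* cp = REAL(cols);
  double* xp = REAL(x);
  std::memset(xp, 0, (size_t)C * H * W * N * sizeof(double));
  for (int n = 0; n < N; ++n) {
    const size_t in_off = (size_t)n * H * W;
    const size_t out_off = (size_t)n * Ho * Wo;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const double* src0 = cp + (out_off + (size_t)wo * Ho + ho) * R;
        for (int kw = 0; kw < k; ++kw) {
          const int wi = wo * stride - pad + kw * dil;
          if (wi < 0 || wi >= W) continue;
          for (int kh = 0; kh < k; ++kh) {
            const int hi = ho * stride - pad + kh * dil;
            if (hi < 0 || hi >= H) continue;
            double* dst = xp + (in_off + (size_t)wi * H + hi) * C;
            const double* src = src0 + (kw * k + kh) * C;
            for (int c = 0; c < C; ++c) dst[c] += src[c];
          }
        }
      }
    }
  }
  return x;
}

// Even-odd scanline fill of a closed polygon given in pixel-centre
// coordinates (x = column, y = row, both 1-based). Returns an H x W 0/1
// matrix marking pixels whose centre lies inside.
// [[Rcpp::export]]
IntegerMatrix fill_polygon_cpp(int H, int W, NumericVector xs, NumericVector ys) {
  IntegerMatrix out(H, W);
  const int nv = xs.size();
  std::vector<double> xc;
  for (int row = 1; row <= H; ++row) {
    const double yc = (double)row;
    xc.clear();
    for (int i = 0; i < nv; ++i) {
      const int j = (i + 1) % nv;
      const double y1 = ys[i], y2 = ys[j];
      if ((y1 <= yc && y2 > yc) || (y2 <= yc && y1 > yc)) {
        const double t = (yc - y1) / (y2 - y1);
        xc.push_back(xs[i] + t * (xs[j] - xs[i]));
      }
    }
    if (xc.empty()) continue;
    std::sort(xc.begin(), xc.end());
    for (size_t p = 0; p + 1 < xc.size(); p += 2) {
      int c0 = (int)std::ceil(xc[p] - 1e-9);
      int c1 = (int)std::floor(xc[p + 1] - 1e-9);
      if (c0 < 1) c0 = 1;
      if (c1 > W) c1 = W;
      for (int c = c0; c <= c1; ++c) out(row - 1, c - 1) = 1;
    }
  }
  return out;
}
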