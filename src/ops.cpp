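// Low-level kernels for the conv-net engine: im2col/col2im (convolution as
// matrix multiplication), ROI-Align with single-sample bilinear bins, and
// bilinear image resize. Tensors are R arrays in column-major layout with
// dim (H, W, C); patch rows are ordered (kh, kw, C) to match how the R side
// flattens the weight array (kh, kw, Cin, Cout).
#include <Rcpp.h>
using namespace Rcpp;

static inline int idx3(int h, int w, int c, int H, int W) {
  return h + H * (w + W * c);
}

// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector x, int H, int W, int C,
                         int kh, int kw, int stride, int pad) {
  int Ho = (H + 2 * pad - kh) / stride + 1;
  int Wo = (W + 2 * pad - kw) / stride + 1;
  NumericMatrix out(kh * kw * C, Ho * Wo);
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      int p = ho + Ho * wo;
      int h0 = ho * stride - pad, w0 = wo * stride - pad;
      for (int c = 0; c < C; ++c) {
        for (int j = 0; j < kw; ++j) {
          int w = w0 + j;
          for (int i = 0; i < kh; ++i) {
            int h = h0 + i;
            int r = i + kh * (j + kw * c);
            out(r, p) = (h >= 0 && h < H && w >= 0 && w < W)
                          ? x[idx3(h, w, c, H, W)] : 0.0;
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix cols, int H, int W, int C,
                         int kh, int kw, int stride, int pad) {
  int Ho = (H + 2 * pad - kh) / stride + 1;
  int Wo = (W + 2 * pad - kw) / stride + 1;
  NumericVector x(H * W * C);
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      int p = ho + Ho * wo;
      int h0 = ho * stride - pad, w0 = wo * stride - pad;
      for (int c = 0; c < C; ++c) {
        for (int j = 0; j < kw; ++j) {
          int w = w0 + j;
          if (w < 0 || w >= W) continue;
          for (int i = 0; i < kh; ++i) {
            int h = h0 + i;
            if (h < 0 || h >= H) continue;
            int r = i + kh * (j + kw * c);
            x[idx3(h, w, c, H, W)] += cols(r, p);
          }
        }
      }
    }
  }
  x.attr("dim") = IntegerVector::create(H, W, C);
  return x;
}

struct Corner { int h0, w0, h1, w1; double lh, lw; };

static inline Corner corners(double y, double x, int H, int W) {
  if (y < 0) y = 0; if (y > H - 1) y = H - 1;
  if (x < 0) x = 0; if (x > W - 1) x = W - 1;
  Corner c;
  c.h0 = (int)std::floor(y); c.w0 = (int)std::floor(x);
  c.h1 = std::min(c.h0 + 1, H - 1); c.w1 = std::min(c.w0 + 1, W - 1);
  c.lh = y - c.h0; c.lw = x - c.w0;
  return c;
}

// rois: n x 4 (r0, c0, r1, c1) half-open boxes in feature coordinates.
// One bilinear sample per output bin, taken at the bin centre.
// Output dim: (S, S, C, n).
// [[Rcpp::export]]
NumericVector roi_align_cpp(NumericVector feat, int H, int W, int C,
                            NumericMatrix rois, int S) {
  int n = rois.nrow();
  NumericVector out(S * S * C * n);
  for (int i = 0; i < n; ++i) {
    double r0 = rois(i, 0), c0 = rois(i, 1), r1 = rois(i, 2), c1 = rois(i, 3);
    double bh = std::max(r1 - r0, 1e-6) / S, bw = std::max(c1 - c0, 1e-6) / S;
    for (int b = 0; b < S; ++b) {
      for (int a = 0; a < S; ++a) {
        double y = r0 + (a + 0.5) * bh - 0.5;
        double x = c0 + (b + 0.5) * bw - 0.5;
        Corner cn = corners(y, x, H, W);
        for (int c = 0; c < C; ++c) {
          double v00 = feat[idx3(cn.h0, cn.w0, c, H, W)];
          double v01 = feat[idx3(cn.h0, cn.w1, c, H, W)];
          double v10 = feat[idx3(cn.h1, cn.w0, c, H, W)];
          double v11 = feat[idx3(cn.h1, cn.w1, c, H, W)];
          double v = v00 * (1 - cn.lh) * (1 - cn.lw) +
                     v01 * (1 - cn.lh) * cn.lw +
                     v10 * cn.lh * (1 - cn.lw) + v11 * cn.lh * cn.lw;
          out[a + S * (b + S * (c + C * (double)i))] = v;
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(S, S, C, n);
  return out;
}

// [[Rcpp::export]]
NumericVector roi_align_back_cpp(NumericVector dout, int H, int W, int C,
                                 NumericMatrix rois, int S) {
  int n = rois.nrow();
  NumericVector dfeat(H * W * C);
  for (int i = 0; i < n; ++i) {
    double r0 = rois(i, 0), c0 = rois(i, 1), r1 = rois(i, 2), c1 = rois(i, 3);
    double bh = std::max(r1 - r0, 1e-6) / S, bw = std::max(c1 - c0, 1e-6) / S;
    for (int b = 0; b < S; ++b) {
      for (int a = 0; a < S; ++a) {
        double y = r0 + (a + 0.5) * bh - 0.5;
        double x = c0 + (b + 0.5) * bw - 0.5;
        Corner cn = corners(y, x, H, W);
        for (int c = 0; c < C; ++c) {
          double g = dout[a + S * (b + S * (c + C * (double)i))];
          dfeat[idx3(cn.h0, cn.w0, c, H, W)] += g * (1 - cn.lh) * (1 - cn.lw);
          dfeat[idx3(cn.h0, cn.w1, c, H, W)] += g * (1 - cn.lh) * cn.lw;
          dfeat[idx3(cn.h1, cn.w0, c, H, W)] += g * cn.lh * (1 - cn.lw);
          dfeat[idx3(cn.h1, cn.w1, c, H, W)] += g * cn.lh * cn.lw;
        }
      }
    }
  }
  dfeat.attr("dim") = IntegerVector::create(H, W, C);
  return dfeat;
}

// [[Rcpp::export]]
NumericMatrix bilinear_resize_cpp(NumericMatrix img, int h2, int w2) {
  int H = img.nrow(), W = img.ncol();
  NumericMatrix out(h2, w2);
  double sy = (double)H / h2, sx = (double)W / w2;
  for (int b = 0; b < w2; ++b) {
    for (int a = 0; a < h2; ++a) {
      double y = (a + 0.5) * sy - 0.5, x = (b + 0.5) * sx - 0.5;
      Corner cn = corners(y, x, H, W);
      out(a, b) = img(cn.h0, cn.w0) * (1 - cn.lh) * (1 - cn.lw) +
                  img(cn.h0, cn.w1) * (1 - cn.lh) * cn.lw +
                  img(cn.h1, cn.w0) * cn.lh * (1 - cn.lw) +
                  img(cn.h1, cn.w1) * cn.lh * cn.lw;
    }
  }
  return out;
}
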