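#include <Rcpp.h>
using namespace Rcpp;

// Feature maps are stored column-major as (H, W, C) slabs per sample.
// im2col row ordering is (kh fastest, then kw, then c) so that a kernel
// array of dim (k, k, C_in, C_out) flattens to the matching weight matrix.

// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericVector x, int H, int W, int C,
                         int k, int stride, int pad, int dil) {
  int eff = dil * (k - 1) + 1;
  int Hout = (H + 2 * pad - eff) / stride + 1;
  int Wout = (W + 2 * pad - eff) / stride + 1;
  NumericMatrix cols(k * k * C, Hout * Wout);
  double *px = REAL(x);
  double *pc = REAL(cols);
  for (int wo = 0; wo < Wout; ++wo) {
    for (int ho = 0; ho < Hout; ++ho) {
      int col = wo * Hout + ho;
      double *dst = pc + (R_xlen_t)col * (k * k * C);
      int h0 = ho * stride - pad;
      int w0 = wo * stride - pad;
      for (int c = 0; c < C; ++c) {
        const double *src = px + (R_xlen_t)c * H * W;
        for (int kw = 0; kw < k; ++kw) {
          int wi = w0 + kw * dil;
          bool win = (wi >= 0 && wi < W);
          for (int kh = 0; kh < k; ++kh) {
            int hi = h0 + kh * dil;
            double v = 0.0;
            if (win && hi >= 0 && hi < H) v = src[(R_xlen_t)wi * H + hi];
            dst[c * k * k + kw * k + kh] = v;
          }
        }
      }
    }
  }
  return cols;
}

// adjoint of im2col: scatter-add columns back into an (H, W, C) slab
// [[Rcpp::export]]
NumericVector cpp_col2im(NumericMatrix cols, int H, int W, int C,
                         int k, int stride, int pad, int dil) {
  int eff = dil * (k - 1) + 1;
  int Hout = (H + 2 * pad - eff) / stride + 1;
  int Wout = (W + 2 * pad - eff) / stride + 1;
  NumericVector x((R_xlen_t)H * W * C);
  double *px = REAL(x);
  double *pc = REAL(cols);
  for (int wo = 0; wo < Wout; ++wo) {
    for (int ho = 0; ho < Hout; ++ho) {
      int col = wo * Hout + ho;
      double *src = pc + (R_xlen_t)col * (k * k * C);
      int h0 = ho * stride - pad;
      int w0 = wo * stride - pad;
      for (int c = 0; c < C; ++c) {
        double *dst = px + (R_xlen_t)c * H * W;
        for (int kw = 0; kw < k; ++kw) {
          int wi = w0 + kw * dil;
          if (wi < 0 || wi >= W) continue;
          for (int kh = 0; kh < k; ++kh) {
            int hi = h0 + kh * dil;
            if (hi < 0 || hi >= H) continue;
            dst[(R_xlen_t)wi * H + hi] += src[c * k * k + kw * k + kh];
          }
        }
      }
    }
  }
  return x;
}

// max pooling over an (H, W, C) slab; returns pooled values and the flat
// (0-based) argmax index of each window for the backward scatter
// [[Rcpp::export]]
List cpp_maxpool(NumericVector x, int H, int W, int C,
                 int k, int stride, int pad) {
  int Hout = (H + 2 * pad - k) / stride + 1;
  int Wout = (W + 2 * pad - k) / stride + 1;
  NumericVector out((R_xlen_t)Hout * Wout * C);
  IntegerVector arg((R_xlen_t)Hout * Wout * C);
  double *px = REAL(x);
  double *po = REAL(out);
  int *pa = INTEGER(arg);
  for (int c = 0; c < C; ++c) {
    const double *src = px + (R_xlen_t)c * H * W;
    for (int wo = 0; wo < Wout; ++wo) {
      for (int ho = 0; ho < Hout; ++ho) {
        double best = R_NegInf;
        int besti = -1;
        for (int kw = 0; kw < k; ++kw) {
          int wi = wo * stride - pad + kw;
          if (wi < 0 || wi >= W) continue;
          for (int kh = 0; kh < k; ++kh) {
            int hi = ho * stride - pad + kh;
            if (hi < 0 || hi >= H) continue;
            double v = src[(R_xlen_t)wi * H + hi];
            if (v > best) { best = v; besti = c * H * W + wi * H + hi; }
          }
        }
        R_xlen_t o = (R_xlen_t)c * Hout * Wout + (R_xlen_t)wo * Hout + ho;
        po[o] = (besti >= 0) ? best : 0.0;
        pa[o] = besti;
      }
    }
  }
  return List::create(_["value"] = out, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_backward(NumericVector dout, IntegerVector arg,
                                   int H, int W, int C) {
  NumericVector dx((R_xlen_t)H * W * C);
  double *pdx = REAL(dx);
  double *pdo = REAL(dout);
  int *pa = INTEGER(arg);
  R_xlen_t n = dout.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    if (pa[i] >= 0) pdx[pa[i]] += pdo[i];
  }
  return dx;
}
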