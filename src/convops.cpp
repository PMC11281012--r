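// Low-level array kernels for the compute engine.
// All arrays use the R layout dim = c(batch, channel, height, width),
// i.e. zero-based offset b + B*(c + C*(h + H*w)).
#include <Rcpp.h>
using namespace Rcpp;

static inline int off4(int b, int c, int h, int w, int B, int C, int H) {
  return b + B * (c + C * (h + H * (long) w));
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_forward(NumericVector x, NumericVector W,
                                 NumericVector bias, int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = W.attr("dim");
  const int B = xd[0], C = xd[1], H = xd[2], Wd = xd[3];
  const int O = wd[0], I = wd[1], KH = wd[2], KW = wd[3];
  if (I != C) stop("conv2d: input has %d channels but kernel expects %d", C, I);
  const int OH = (H + 2 * pad - KH) / stride + 1;
  const int OW = (Wd + 2 * pad - KW) / stride + 1;
  NumericVector y(B * O * OH * (long) OW);
  y.attr("dim") = IntegerVector::create(B, O, OH, OW);
  for (int ow = 0; ow < OW; ++ow)
    for (int oh = 0; oh < OH; ++oh)
      for (int o = 0; o < O; ++o)
        for (int b = 0; b < B; ++b) {
          double acc = bias[o];
          for (int q = 0; q < KW; ++q) {
            const int w = ow * stride + q - pad;
            if (w < 0 || w >= Wd) continue;
            for (int p = 0; p < KH; ++p) {
              const int h = oh * stride + p - pad;
              if (h < 0 || h >= H) continue;
              for (int i = 0; i < C; ++i)
                acc += x[off4(b, i, h, w, B, C, H)] *
                       W[off4(o, i, p, q, O, I, KH)];
            }
          }
          y[off4(b, o, oh, ow, B, O, OH)] = acc;
        }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_backward(NumericVector x, NumericVector W, NumericVector gy,
                         int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = W.attr("dim");
  IntegerVector gd = gy.attr("dim");
  const int B = xd[0], C = xd[1], H = xd[2], Wd = xd[3];
  const int O = wd[0], I = wd[1], KH = wd[2], KW = wd[3];
  const int OH = gd[2], OW = gd[3];
  NumericVector gx(x.size()), gW(W.size()), gb(O);
  gx.attr("dim") = xd;
  gW.attr("dim") = wd;
  for (int ow = 0; ow < OW; ++ow)
    for (int oh = 0; oh < OH; ++oh)
      for (int o = 0; o < O; ++o)
        for (int b = 0; b < B; ++b) {
          const double g = gy[off4(b, o, oh, ow, B, O, OH)];
          if (g == 0.0) { continue; }
          gb[o] += g;
          for (int q = 0; q < KW; ++q) {
            const int w = ow * stride + q - pad;
            if (w < 0 || w >= Wd) continue;
            for (int p = 0; p < KH; ++p) {
              const int h = oh * stride + p - pad;
              if (h < 0 || h >= H) continue;
              for (int i = 0; i < C; ++i) {
                gW[off4(o, i, p, q, O, I, KH)] += x[off4(b, i, h, w, B, C, H)] * g;
                gx[off4(b, i, h, w, B, C, H)] += W[off4(o, i, p, q, O, I, KH)] * g;
              }
            }
          }
        }
  return List::create(_["gx"] = gx, _["gW"] = gW, _["gb"] = gb);
}

// Same-size max pooling, stride 1, window k x k, pad (k-1)/2.
// Returns the pooled map and the 0-based linear spatial index (h + H*w) of
// the winning input cell, for gradient routing.
// [[Rcpp::export]]
List cpp_maxpool2d(NumericVector x, int k) {
  IntegerVector xd = x.attr("dim");
  const int B = xd[0], C = xd[1], H = xd[2], Wd = xd[3];
  const int pad = (k - 1) / 2;
  NumericVector y(x.size());
  IntegerVector am(x.size());
  y.attr("dim") = xd;
  am.attr("dim") = xd;
  for (int w = 0; w < Wd; ++w)
    for (int h = 0; h < H; ++h)
      for (int c = 0; c < C; ++c)
        for (int b = 0; b < B; ++b) {
          double best = R_NegInf;
          int besti = -1;
          for (int q = 0; q < k; ++q) {
            const int ww = w + q - pad;
            if (ww < 0 || ww >= Wd) continue;
            for (int p = 0; p < k; ++p) {
              const int hh = h + p - pad;
              if (hh < 0 || hh >= H) continue;
              const double v = x[off4(b, c, hh, ww, B, C, H)];
              if (v > best) { best = v; besti = hh + H * ww; }
            }
          }
          y[off4(b, c, h, w, B, C, H)] = best;
          am[off4(b, c, h, w, B, C, H)] = besti;
        }
  return List::create(_["y"] = y, _["argmax"] = am);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2d_backward(IntegerVector argmax, NumericVector gy) {
  IntegerVector xd = gy.attr("dim");
  const int B = xd[0], C = xd[1], H = xd[2], Wd = xd[3];
  NumericVector gx(gy.size());
  gx.attr("dim") = xd;
  for (int w = 0; w < Wd; ++w)
    for (int h = 0; h < H; ++h)
      for (int c = 0; c < C; ++c)
        for (int b = 0; b < B; ++b) {
          const int idx = off4(b, c, h, w, B, C, H);
          const int s = argmax[idx];
          gx[off4(b, c, s % H, s / H, B, C, H)] += gy[idx];
        }
  return gx;
}
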