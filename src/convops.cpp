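#include <Rcpp.h>
using namespace Rcpp;

// Feature maps are R arrays dim (H, W, C), column-major.
// im2col layout: (Ho*Wo) x (k*k*C); row = ho + Ho*wo, col = dh + k*(dw + k*c).
// This keeps the hot inner loop (over ho) contiguous in input and output.

// [[Rcpp::export(name = ".im2col")]]
NumericMatrix im2col_cpp(NumericVector x, int H, int W, int C,
                         int k, int stride, int pad) {
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  int N = Ho * Wo;
  NumericMatrix out(N, k * k * C);
  const double* px = x.begin();
  double* po = out.begin();
  for (int c = 0; c < C; ++c) {
    for (int dw = 0; dw < k; ++dw) {
      for (int dh = 0; dh < k; ++dh) {
        int col = dh + k * (dw + k * c);
        // valid ho range: 0 <= ho*stride - pad + dh <= H-1
        int lo = 0;
        while (lo * stride - pad + dh < 0) ++lo;
        int hi = Ho - 1;
        while (hi >= 0 && hi * stride - pad + dh > H - 1) --hi;
        for (int wo = 0; wo < Wo; ++wo) {
          int w = wo * stride - pad + dw;
          if (w < 0 || w >= W) continue;
          double* o = po + (size_t)N * col + Ho * wo;
          const double* xi = px + (size_t)H * (w + (size_t)W * c);
          if (stride == 1) {
            int h0 = lo - pad + dh;
            for (int ho = lo; ho <= hi; ++ho, ++h0) o[ho] = xi[h0];
          } else {
            for (int ho = lo; ho <= hi; ++ho)
              o[ho] = xi[ho * stride - pad + dh];
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export(name = ".col2im")]]
NumericVector col2im_cpp(NumericMatrix cols, int H, int W, int C,
                         int k, int stride, int pad) {
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  int N = Ho * Wo;
  NumericVector out((size_t)H * W * C);
  const double* pc = cols.begin();
  double* po = out.begin();
  for (int c = 0; c < C; ++c) {
    for (int dw = 0; dw < k; ++dw) {
      for (int dh = 0; dh < k; ++dh) {
        int col = dh + k * (dw + k * c);
        int lo = 0;
        while (lo * stride - pad + dh < 0) ++lo;
        int hi = Ho - 1;
        while (hi >= 0 && hi * stride - pad + dh > H - 1) --hi;
        for (int wo = 0; wo < Wo; ++wo) {
          int w = wo * stride - pad + dw;
          if (w < 0 || w >= W) continue;
          const double* ci = pc + (size_t)N * col + Ho * wo;
          double* xo = po + (size_t)H * (w + (size_t)W * c);
          if (stride == 1) {
            int h0 = lo - pad + dh;
            for (int ho = lo; ho <= hi; ++ho, ++h0) xo[h0] += ci[ho];
          } else {
            for (int ho = lo; ho <= hi; ++ho)
              xo[ho * stride - pad + dh] += ci[ho];
          }
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(H, W, C);
  return out;
}

// 2x2 max pooling, stride 2. Returns pooled values and flat argmax indices
// (1-based into the input array) for the backward pass.
// [[Rcpp::export(name = ".maxpool2")]]
List maxpool2_cpp(NumericVector x, int H, int W, int C) {
  int Ho = H / 2, Wo = W / 2;
  NumericVector out((size_t)Ho * Wo * C);
  IntegerVector arg((size_t)Ho * Wo * C);
  for (int c = 0; c < C; ++c) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        double best = R_NegInf; int bi = -1;
        for (int dw = 0; dw < 2; ++dw) {
          for (int dh = 0; dh < 2; ++dh) {
            int idx = (2 * ho + dh) + H * ((2 * wo + dw) + W * c);
            if (x[idx] > best) { best = x[idx]; bi = idx; }
          }
        }
        int o = ho + Ho * (wo + Wo * c);
        out[o] = best;
        arg[o] = bi + 1;
      }
    }
  }
  out.attr("dim") = IntegerVector::create(Ho, Wo, C);
  return List::create(_["out"] = out, _["argmax"] = arg);
}

// [[Rcpp::export(name = ".maxpool2_backward")]]
NumericVector maxpool2_backward_cpp(NumericVector dout, IntegerVector argmax,
                                    int H, int W, int C) {
  NumericVector dx((size_t)H * W * C);
  for (int i = 0; i < dout.size(); ++i) dx[argmax[i] - 1] += dout[i];
  dx.attr("dim") = IntegerVector::create(H, W, C);
  return dx;
}
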