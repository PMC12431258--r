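// Convolution and pooling kernels for the classifier.
//
// Tensor layout throughout: column-major R arrays with dim (H, W, C, N).
// Convolution weights: dim (kh, kw, Cin, Cout). im2col rows are ordered
// (kh fastest, then kw, then Cin), matching R's column-major vec() of the
// weight array, so a conv reduces to one GEMM per sample.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static void im2col(const double* x, int H, int W, int C,
                   int kh, int kw, int stride, int pad,
                   int Ho, int Wo, arma::mat& cols) {
  // cols: (C*kh*kw) x (Ho*Wo)
  for (int ow = 0; ow < Wo; ++ow) {
    for (int oh = 0; oh < Ho; ++oh) {
      int col = oh + Ho * ow;
      double* dst = cols.colptr(col);
      for (int c = 0; c < C; ++c) {
        const double* xc = x + (size_t)c * H * W;
        for (int j = 0; j < kw; ++j) {
          int wi = ow * stride - pad + j;
          for (int i = 0; i < kh; ++i) {
            int hi = oh * stride - pad + i;
            int r = i + kh * (j + kw * c);
            dst[r] = (hi >= 0 && hi < H && wi >= 0 && wi < W)
                         ? xc[hi + (size_t)wi * H]
                         : 0.0;
          }
        }
      }
    }
  }
}

static void col2im(const arma::mat& cols, int H, int W, int C,
                   int kh, int kw, int stride, int pad,
                   int Ho, int Wo, double* dx) {
  for (int ow = 0; ow < Wo; ++ow) {
    for (int oh = 0; oh < Ho; ++oh) {
      int col = oh + Ho * ow;
      const double* src = cols.colptr(col);
      for (int c = 0; c < C; ++c) {
        double* xc = dx + (size_t)c * H * W;
        for (int j = 0; j < kw; ++j) {
          int wi = ow * stride - pad + j;
          if (wi < 0 || wi >= W) continue;
          for (int i = 0; i < kh; ++i) {
            int hi = oh * stride - pad + i;
            if (hi < 0 || hi >= H) continue;
            xc[hi + (size_t)wi * H] += src[i + kh * (j + kw * c)];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fwd(NumericVector x, NumericVector w,
                         int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cin = wd[2], F = wd[3];
  if (Cin != C) stop("conv2d_fwd: channel mismatch");
  int Ho = (H + 2 * pad - kh) / stride + 1;
  int Wo = (W + 2 * pad - kw) / stride + 1;
  arma::mat Wm(const_cast<double*>(w.begin()), kh * kw * C, F, false, true);
  NumericVector y((R_xlen_t)Ho * Wo * F * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, F, N);
  arma::mat cols(kh * kw * C, Ho * Wo);
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (size_t)n * H * W * C;
    im2col(xn, H, W, C, kh, kw, stride, pad, Ho, Wo, cols);
    // y_n (HoWo x F) = cols' * Wm
    arma::mat yn(y.begin() + (size_t)n * Ho * Wo * F, Ho * Wo, F, false, true);
    yn = cols.t() * Wm;
  }
  return y;
}

// [[Rcpp::export]]
List conv2d_bwd(NumericVector x, NumericVector w, NumericVector dy,
                int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], F = wd[3];
  int Ho = (H + 2 * pad - kh) / stride + 1;
  int Wo = (W + 2 * pad - kw) / stride + 1;
  arma::mat Wm(const_cast<double*>(w.begin()), kh * kw * C, F, false, true);
  NumericVector dx((R_xlen_t)H * W * C * N);
  dx.attr("dim") = xd;
  NumericVector dw((R_xlen_t)kh * kw * C * F);
  dw.attr("dim") = wd;
  arma::mat dWm(dw.begin(), kh * kw * C, F, false, true);
  arma::mat cols(kh * kw * C, Ho * Wo);
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (size_t)n * H * W * C;
    arma::mat dyn(const_cast<double*>(dy.begin()) + (size_t)n * Ho * Wo * F,
                  Ho * Wo, F, false, true);
    im2col(xn, H, W, C, kh, kw, stride, pad, Ho, Wo, cols);
    dWm += cols * dyn;                       // (Ckhkw x F)
    arma::mat dcols = Wm * dyn.t();          // (Ckhkw x HoWo)
    col2im(dcols, H, W, C, kh, kw, stride, pad, Ho, Wo,
           dx.begin() + (size_t)n * H * W * C);
  }
  return List::create(_["dx"] = dx, _["dw"] = dw);
}

// [[Rcpp::export]]
List maxpool_fwd(NumericVector x, int k, int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  NumericVector y((R_xlen_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector idx(Ho * Wo * C * N);  // 0-based argmax into the input slab
  size_t o = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xs = x.begin() + ((size_t)n * C + c) * H * W;
      for (int ow = 0; ow < Wo; ++ow) {
        for (int oh = 0; oh < Ho; ++oh) {
          double best = R_NegInf;
          int best_i = -1;
          for (int j = 0; j < k; ++j) {
            int wi = ow * stride - pad + j;
            if (wi < 0 || wi >= W) continue;
            for (int i = 0; i < k; ++i) {
              int hi = oh * stride - pad + i;
              if (hi < 0 || hi >= H) continue;
              double v = xs[hi + (size_t)wi * H];
              if (v > best) { best = v; best_i = hi + wi * H; }
            }
          }
          // y is (Ho,Wo,C,N); we iterate oh fastest within (ow,c,n)
          size_t yo = (size_t)oh + Ho * ((size_t)ow + Wo * ((size_t)c + (size_t)C * n));
          y[yo] = best_i >= 0 ? best : 0.0;
          idx[yo] = best_i;
          ++o;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool_bwd(IntegerVector idx, NumericVector dy,
                          IntegerVector x_dim) {
  int H = x_dim[0], W = x_dim[1], C = x_dim[2], N = x_dim[3];
  IntegerVector yd = dy.attr("dim");
  int Ho = yd[0], Wo = yd[1];
  NumericVector dx((R_xlen_t)H * W * C * N);
  dx.attr("dim") = x_dim;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      double* dxs = dx.begin() + ((size_t)n * C + c) * H * W;
      for (size_t p = 0; p < (size_t)Ho * Wo; ++p) {
        size_t yo = p + (size_t)Ho * Wo * ((size_t)c + (size_t)C * n);
        int bi = idx[yo];
        if (bi >= 0) dxs[bi] += dy[yo];
      }
    }
  }
  return dx;
}
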