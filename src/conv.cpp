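// Minimal 2-D convolution kernels for the enhancement networks.
// Tensor layout follows R's column-major arrays:
//   activations: [H, W, C, N], weights: [K, K, C_in, C_out].
// im2col (patch-major layout, contiguous writes) + BLAS gemm;
// stride/zero-padding as used by the 3x3 (pad 1) and 4x4 stride-2
// (pad 1) layers.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int out_size(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

// Fill cols (Ho*Wo x K*K*Cin) for one sample: column r = (kh, kw, c)
// holds x[h0+kh, w0+kw, c] over output positions, zero outside the pad.
static void im2col(const double* x, int H, int W, int C,
                   int K, int stride, int pad, int Ho, int Wo,
                   arma::mat& cols) {
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * H * W;
    for (int kw = 0; kw < K; ++kw) {
      for (int kh = 0; kh < K; ++kh) {
        double* dst = cols.colptr(kh + K * kw + K * K * c);
        for (int wo = 0; wo < Wo; ++wo) {
          const int w = wo * stride - pad + kw;
          double* d = dst + (size_t)Ho * wo;
          if (w < 0 || w >= W) {
            std::fill(d, d + Ho, 0.0);
            continue;
          }
          const double* src = xc + (size_t)H * w;
          if (stride == 1) {
            const int h0 = -pad + kh; // h = ho + h0
            int lo = std::max(0, -h0), hi = std::min(Ho, H - h0);
            if (lo > 0) std::fill(d, d + lo, 0.0);
            if (hi > lo) std::copy(src + lo + h0, src + hi + h0, d + lo);
            if (hi < Ho) std::fill(d + std::max(hi, lo), d + Ho, 0.0);
          } else {
            for (int ho = 0; ho < Ho; ++ho) {
              const int h = ho * stride - pad + kh;
              d[ho] = (h < 0 || h >= H) ? 0.0 : src[h];
            }
          }
        }
      }
    }
  }
}

// Scatter-add the column gradient (same layout) onto the input gradient.
static void col2im(const arma::mat& cols, int H, int W, int C,
                   int K, int stride, int pad, int Ho, int Wo,
                   double* gx) {
  for (int c = 0; c < C; ++c) {
    double* gc = gx + (size_t)c * H * W;
    for (int kw = 0; kw < K; ++kw) {
      for (int kh = 0; kh < K; ++kh) {
        const double* src = cols.colptr(kh + K * kw + K * K * c);
        for (int wo = 0; wo < Wo; ++wo) {
          const int w = wo * stride - pad + kw;
          if (w < 0 || w >= W) continue;
          const double* s = src + (size_t)Ho * wo;
          double* g = gc + (size_t)H * w;
          for (int ho = 0; ho < Ho; ++ho) {
            const int h = ho * stride - pad + kh;
            if (h >= 0 && h < H) g[h] += s[ho];
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2d_fwd")]]
NumericVector conv2d_fwd(NumericVector x, NumericVector w, NumericVector b,
                         int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int K = wd[0], Cin = wd[2], Cout = wd[3];
  if (wd[1] != K) stop("non-square kernel");
  if (Cin != C) stop("channel mismatch: input %d vs kernel %d", C, Cin);
  const int Ho = out_size(H, K, stride, pad), Wo = out_size(W, K, stride, pad);
  if (Ho < 1 || Wo < 1) stop("kernel larger than padded input");

  NumericVector y((R_xlen_t)Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);

  const arma::mat Wm(const_cast<double*>(w.begin()), K * K * Cin, Cout, false);
  const arma::rowvec bv(const_cast<double*>(b.begin()), Cout, false);
  arma::mat cols(Ho * Wo, K * K * Cin);

  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, K, stride, pad, Ho, Wo, cols);
    arma::mat Yn(y.begin() + (size_t)n * Ho * Wo * Cout, Ho * Wo, Cout, false, true);
    Yn = cols * Wm;
    Yn.each_row() += bv;
  }
  return y;
}

// [[Rcpp::export(name = ".conv2d_bwd")]]
List conv2d_bwd(NumericVector x, NumericVector w, NumericVector gy,
                int stride, int pad, bool need_gx) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int K = wd[0], Cin = wd[2], Cout = wd[3];
  const int Ho = out_size(H, K, stride, pad), Wo = out_size(W, K, stride, pad);

  NumericVector gw((R_xlen_t)K * K * Cin * Cout);
  gw.attr("dim") = IntegerVector::create(K, K, Cin, Cout);
  NumericVector gb(Cout);
  NumericVector gx;
  if (need_gx) {
    gx = NumericVector((R_xlen_t)H * W * C * N);
    gx.attr("dim") = IntegerVector::create(H, W, C, N);
  }

  arma::mat Gw(gw.begin(), K * K * Cin, Cout, false, true);
  arma::rowvec Gb(gb.begin(), Cout, false, true);
  const arma::mat Wm(const_cast<double*>(w.begin()), K * K * Cin, Cout, false);
  arma::mat cols(Ho * Wo, K * K * Cin);
  arma::mat gcols(Ho * Wo, K * K * Cin);

  for (int n = 0; n < N; ++n) {
    const arma::mat Gy(const_cast<double*>(gy.begin()) + (size_t)n * Ho * Wo * Cout,
                       Ho * Wo, Cout, false);
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, K, stride, pad, Ho, Wo, cols);
    Gw += cols.t() * Gy;
    Gb += arma::sum(Gy, 0);
    if (need_gx) {
      gcols = Gy * Wm.t();
      col2im(gcols, H, W, C, K, stride, pad, Ho, Wo,
             gx.begin() + (size_t)n * H * W * C);
    }
  }
  return need_gx ? List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb)
                 : List::create(_["gw"] = gw, _["gb"] = gb);
}
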