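// Low-level tensor primitives for the counting network.
//
// Activation layout: a batch is a (H*W*C) x N matrix; within one image the
// element (h, w, c) sits at index h + H*w + H*W*c (column-major spatial
// plane per channel).  This makes "flatten" a no-op and channel
// concatenation a row-bind.
//
// All primitives allocate their outputs directly as R matrices and wrap
// them in Armadillo views, so nothing is copied on return; batchnorm and
// the rectifier are fused into a single pass.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline arma::mat view(NumericMatrix& m) {
  return arma::mat(m.begin(), m.nrow(), m.ncol(), false, true);
}
static inline arma::mat cview(const NumericMatrix& m) {
  return arma::mat(const_cast<double*>(m.begin()), m.nrow(), m.ncol(),
                   false, true);
}

// Patch matrix for one image: (Ho*Wo) x (kh*kw*C); row q = ho + Ho*wo,
// column r = ki + kh*(kj + kw*c).  Out-of-range taps read as zero.
static void im2col(const double* img, int H, int W, int C,
                   int kh, int kw, int stride, int padt, int padl,
                   int Ho, int Wo, double* colmem) {
  const std::size_t HoWo = (std::size_t)Ho * Wo;
  for (int c = 0; c < C; ++c) {
    const double* ch = img + (std::size_t)c * H * W;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        double* dst = colmem + HoWo * (ki + kh * (kj + kw * c));
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * stride - padl + kj;
          double* d = dst + (std::size_t)Ho * wo;
          if (wi < 0 || wi >= W) {
            std::fill(d, d + Ho, 0.0);
            continue;
          }
          const double* src = ch + (std::size_t)H * wi;
          int ho = 0;
          int lo = padt - ki;  // hi = ho*stride - padt + ki >= 0
          for (; ho < Ho && ho * stride < lo; ++ho) d[ho] = 0.0;
          for (; ho < Ho; ++ho) {
            int hi = ho * stride - padt + ki;
            if (hi >= H) { std::fill(d + ho, d + Ho, 0.0); break; }
            d[ho] = src[hi];
          }
        }
      }
    }
  }
}

static void col2im_add(const double* colmem, int H, int W, int C,
                       int kh, int kw, int stride, int padt, int padl,
                       int Ho, int Wo, double* img) {
  const std::size_t HoWo = (std::size_t)Ho * Wo;
  for (int c = 0; c < C; ++c) {
    double* ch = img + (std::size_t)c * H * W;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const double* src0 = colmem + HoWo * (ki + kh * (kj + kw * c));
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * stride - padl + kj;
          if (wi < 0 || wi >= W) continue;
          const double* s = src0 + (std::size_t)Ho * wo;
          double* dstc = ch + (std::size_t)H * wi;
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho * stride - padt + ki;
            if (hi >= 0 && hi < H) dstc[hi] += s[ho];
          }
        }
      }
    }
  }
}

// Convolution forward.  Wt is (Cout, kh*kw*C) with column order matching
// im2col rows.  Returns (Ho*Wo*Cout) x N.  For 1x1 stride-1 convolutions
// the activation layout already is the patch matrix, so the image memory
// feeds the GEMM directly with no im2col.
// [[Rcpp::export]]
NumericMatrix cpp_conv_forward(const NumericMatrix& X, int H, int W, int C,
                               const NumericMatrix& Wt, int kh, int kw,
                               int stride, int padt, int padl,
                               int Ho, int Wo) {
  const int N = X.ncol(), Cout = Wt.nrow();
  const std::size_t HoWo = (std::size_t)Ho * Wo;
  const std::size_t kkC = (std::size_t)kh * kw * C;
  const bool oneByOne = (kh == 1 && kw == 1 && stride == 1);
  arma::mat Wv = cview(Wt);
  NumericMatrix Y(no_init(HoWo * Cout, N));
  arma::mat Yv = view(Y);
  arma::mat WtT = Wv.t();
  arma::mat colBuf;
  if (!oneByOne) colBuf.set_size(HoWo, kkC);
  for (int n = 0; n < N; ++n) {
    double* cm;
    if (oneByOne) {
      cm = const_cast<double*>(X.begin()) + (std::size_t)n * X.nrow();
    } else {
      cm = colBuf.memptr();
      im2col(X.begin() + (std::size_t)n * X.nrow(), H, W, C, kh, kw,
             stride, padt, padl, Ho, Wo, cm);
    }
    arma::mat colV(cm, HoWo, kkC, false, true);
    arma::mat Yimg(Yv.colptr(n), HoWo, Cout, false, true);
    Yimg = colV * WtT;
  }
  return Y;
}

// [[Rcpp::export]]
List cpp_conv_backward(const NumericMatrix& X, const NumericMatrix& dY,
                       const NumericMatrix& Wt, int H, int W, int C,
                       int kh, int kw, int stride, int padt, int padl,
                       int Ho, int Wo) {
  const int N = X.ncol(), Cout = Wt.nrow();
  const std::size_t HoWo = (std::size_t)Ho * Wo;
  const std::size_t kkC = (std::size_t)kh * kw * C;
  const bool oneByOne = (kh == 1 && kw == 1 && stride == 1);
  arma::mat Wv = cview(Wt);
  NumericMatrix dX(no_init(X.nrow(), N));
  if (!oneByOne) std::fill(dX.begin(), dX.end(), 0.0);
  NumericMatrix dW(Cout, kkC);
  arma::mat dWv = view(dW);
  dWv.zeros();
  arma::mat colBuf;
  if (!oneByOne) colBuf.set_size(HoWo, kkC);
  arma::mat dcol;
  if (!oneByOne) dcol.set_size(HoWo, kkC);
  for (int n = 0; n < N; ++n) {
    const arma::mat dYimg(const_cast<double*>(dY.begin()) +
                            (std::size_t)n * dY.nrow(),
                          HoWo, Cout, false, true);
    if (oneByOne) {
      const arma::mat Ximg(const_cast<double*>(X.begin()) +
                             (std::size_t)n * X.nrow(),
                           HoWo, kkC, false, true);
      arma::mat dXimg(dX.begin() + (std::size_t)n * dX.nrow(),
                      HoWo, kkC, false, true);
      dWv += dYimg.t() * Ximg;
      dXimg = dYimg * Wv;
      continue;
    }
    im2col(X.begin() + (std::size_t)n * X.nrow(), H, W, C, kh, kw,
           stride, padt, padl, Ho, Wo, colBuf.memptr());
    dWv += dYimg.t() * colBuf;
    dcol = dYimg * Wv;  // (Ho*Wo) x (kh*kw*C)
    col2im_add(dcol.memptr(), H, W, C, kh, kw, stride, padt, padl, Ho, Wo,
               dX.begin() + (std::size_t)n * dX.nrow());
  }
  return List::create(_["dX"] = dX, _["dW"] = dW);
}

// Max pooling, VALID padding.  Returns pooled activations and the flat
// input index of each maximum (for the backward scatter).
// [[Rcpp::export]]
List cpp_maxpool_forward(const NumericMatrix& X, int H, int W, int C,
                         int kh, int kw, int stride, int Ho, int Wo) {
  const int N = X.ncol();
  const std::size_t outRows = (std::size_t)Ho * Wo * C;
  NumericMatrix Y(no_init(outRows, N));
  IntegerMatrix idx(no_init(outRows, N));
  for (int n = 0; n < N; ++n) {
    const double* img = X.begin() + (std::size_t)n * X.nrow();
    double* y = Y.begin() + (std::size_t)n * outRows;
    int* ix = idx.begin() + (std::size_t)n * outRows;
    for (int c = 0; c < C; ++c) {
      const double* ch = img + (std::size_t)c * H * W;
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          int h0 = ho * stride, w0 = wo * stride;
          double best = -std::numeric_limits<double>::infinity();
          int bi = 0;
          for (int kj = 0; kj < kw; ++kj) {
            const double* colp = ch + (std::size_t)H * (w0 + kj);
            for (int ki = 0; ki < kh; ++ki) {
              double v = colp[h0 + ki];
              if (v > best) { best = v; bi = (h0 + ki) + H * (w0 + kj); }
            }
          }
          std::size_t q = (std::size_t)ho + (std::size_t)Ho * wo +
            (std::size_t)Ho * Wo * c;
          y[q] = best;
          ix[q] = bi + c * H * W;
        }
      }
    }
  }
  return List::create(_["Y"] = Y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericMatrix cpp_maxpool_backward(const NumericMatrix& dY,
                                   const IntegerMatrix& idx, int inRows) {
  const int N = dY.ncol();
  NumericMatrix dX(inRows, N);
  std::fill(dX.begin(), dX.end(), 0.0);
  for (int n = 0; n < N; ++n) {
    const double* g = dY.begin() + (std::size_t)n * dY.nrow();
    const int* ix = idx.begin() + (std::size_t)n * idx.nrow();
    double* d = dX.begin() + (std::size_t)n * inRows;
    for (std::size_t q = 0; q < (std::size_t)dY.nrow(); ++q) d[ix[q]] += g[q];
  }
  return dX;
}

// Average pooling, VALID padding (full windows only).
// [[Rcpp::export]]
NumericMatrix cpp_avgpool_forward(const NumericMatrix& X, int H, int W,
                                  int C, int kh, int kw, int stride,
                                  int Ho, int Wo) {
  const int N = X.ncol();
  const double inv = 1.0 / (kh * kw);
  const std::size_t outRows = (std::size_t)Ho * Wo * C;
  NumericMatrix Y(no_init(outRows, N));
  for (int n = 0; n < N; ++n) {
    const double* img = X.begin() + (std::size_t)n * X.nrow();
    double* y = Y.begin() + (std::size_t)n * outRows;
    for (int c = 0; c < C; ++c) {
      const double* ch = img + (std::size_t)c * H * W;
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          double s = 0.0;
          for (int kj = 0; kj < kw; ++kj) {
            const double* colp = ch + (std::size_t)H * (wo * stride + kj);
            for (int ki = 0; ki < kh; ++ki) s += colp[ho * stride + ki];
          }
          y[(std::size_t)ho + (std::size_t)Ho * wo +
            (std::size_t)Ho * Wo * c] = s * inv;
        }
      }
    }
  }
  return Y;
}

// [[Rcpp::export]]
NumericMatrix cpp_avgpool_backward(const NumericMatrix& dY, int H, int W,
                                   int C, int kh, int kw, int stride,
                                   int Ho, int Wo) {
  const int N = dY.ncol();
  const double inv = 1.0 / (kh * kw);
  NumericMatrix dX((std::size_t)H * W * C, N);
  std::fill(dX.begin(), dX.end(), 0.0);
  for (int n = 0; n < N; ++n) {
    const double* g = dY.begin() + (std::size_t)n * dY.nrow();
    double* d = dX.begin() + (std::size_t)n * dX.nrow();
    for (int c = 0; c < C; ++c) {
      double* ch = d + (std::size_t)c * H * W;
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          double gv = g[(std::size_t)ho + (std::size_t)Ho * wo +
                        (std::size_t)Ho * Wo * c] * inv;
          for (int kj = 0; kj < kw; ++kj) {
            double* colp = ch + (std::size_t)H * (wo * stride + kj);
            for (int ki = 0; ki < kh; ++ki) colp[ho * stride + ki] += gv;
          }
        }
      }
    }
  }
  return dX;
}

// Batch normalization (training statistics) with an optionally fused
// rectifier, in one pass per channel; channel c occupies rows
// [c*HW, (c+1)*HW).
// [[Rcpp::export]]
List cpp_bn_forward(const NumericMatrix& X, int HW, int C,
                    const NumericVector& gamma, const NumericVector& beta,
                    double eps, bool relu) {
  const int N = X.ncol();
  const std::size_t rows = X.nrow();
  NumericMatrix Y(no_init(rows, N));
  NumericVector mean(C), var(C);
  const double m = (double)HW * N;
  for (int c = 0; c < C; ++c) {
    const std::size_t r0 = (std::size_t)c * HW;
    double s = 0.0, s2 = 0.0;
    for (int n = 0; n < N; ++n) {
      const double* x = X.begin() + (std::size_t)n * rows + r0;
      for (int i = 0; i < HW; ++i) { s += x[i]; s2 += x[i] * x[i]; }
    }
    double mu = s / m;
    double v = s2 / m - mu * mu;
    if (v < 0) v = 0;
    mean[c] = mu; var[c] = v;
    const double sc = gamma[c] / std::sqrt(v + eps);
    const double sh = beta[c] - mu * sc;
    for (int n = 0; n < N; ++n) {
      const double* x = X.begin() + (std::size_t)n * rows + r0;
      double* y = Y.begin() + (std::size_t)n * rows + r0;
      if (relu)
        for (int i = 0; i < HW; ++i) {
          double t = x[i] * sc + sh;
          y[i] = t > 0 ? t : 0;
        }
      else
        for (int i = 0; i < HW; ++i) y[i] = x[i] * sc + sh;
    }
  }
  return List::create(_["Y"] = Y, _["mean"] = mean, _["var"] = var);
}

// [[Rcpp::export]]
NumericMatrix cpp_bn_infer(const NumericMatrix& X, int HW, int C,
                           const NumericVector& gamma,
                           const NumericVector& beta,
                           const NumericVector& rmean,
                           const NumericVector& rvar, double eps,
                           bool relu) {
  const int N = X.ncol();
  const std::size_t rows = X.nrow();
  NumericMatrix Y(no_init(rows, N));
  for (int c = 0; c < C; ++c) {
    const std::size_t r0 = (std::size_t)c * HW;
    const double sc = gamma[c] / std::sqrt(rvar[c] + eps);
    const double sh = beta[c] - rmean[c] * sc;
    for (int n = 0; n < N; ++n) {
      const double* x = X.begin() + (std::size_t)n * rows + r0;
      double* y = Y.begin() + (std::size_t)n * rows + r0;
      if (relu)
        for (int i = 0; i < HW; ++i) {
          double t = x[i] * sc + sh;
          y[i] = t > 0 ? t : 0;
        }
      else
        for (int i = 0; i < HW; ++i) y[i] = x[i] * sc + sh;
    }
  }
  return Y;
}

// Backward through batchnorm (+ fused rectifier).  When relu, the incoming
// gradient is masked by Y > 0 (Y being the fused forward output) before the
// batchnorm backward proper.
// [[Rcpp::export]]
List cpp_bn_backward(const NumericMatrix& X, const NumericMatrix& Y,
                     const NumericMatrix& dY, int HW, int C,
                     const NumericVector& gamma, const NumericVector& mean,
                     const NumericVector& var, double eps, bool relu) {
  const int N = X.ncol();
  const std::size_t rows = X.nrow();
  NumericMatrix dX(no_init(rows, N));
  NumericVector dgamma(C), dbeta(C);
  const double m = (double)HW * N;
  for (int c = 0; c < C; ++c) {
    const std::size_t r0 = (std::size_t)c * HW;
    const double inv = 1.0 / std::sqrt(var[c] + eps);
    const double mu = mean[c];
    double sd = 0.0, sdx = 0.0;
    for (int n = 0; n < N; ++n) {
      const double* x = X.begin() + (std::size_t)n * rows + r0;
      const double* y = Y.begin() + (std::size_t)n * rows + r0;
      const double* g = dY.begin() + (std::size_t)n * rows + r0;
      for (int i = 0; i < HW; ++i) {
        double gi = (relu && y[i] <= 0) ? 0.0 : g[i];
        sd += gi;
        sdx += gi * (x[i] - mu) * inv;
      }
    }
    dbeta[c] = sd; dgamma[c] = sdx;
    const double k1 = gamma[c] * inv;
    const double k2 = sd / m, k3 = sdx / m;
    for (int n = 0; n < N; ++n) {
      const double* x = X.begin() + (std::size_t)n * rows + r0;
      const double* y = Y.begin() + (std::size_t)n * rows + r0;
      const double* g = dY.begin() + (std::size_t)n * rows + r0;
      double* d = dX.begin() + (std::size_t)n * rows + r0;
      for (int i = 0; i < HW; ++i) {
        double gi = (relu && y[i] <= 0) ? 0.0 : g[i];
        d[i] = k1 * (gi - k2 - (x[i] - mu) * inv * k3);
      }
    }
  }
  return List::create(_["dX"] = dX, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// [[Rcpp::export]]
NumericMatrix cpp_relu_forward(const NumericMatrix& X) {
  NumericMatrix Y(no_init(X.nrow(), X.ncol()));
  const double* x = X.begin();
  double* y = Y.begin();
  const std::size_t n = (std::size_t)X.nrow() * X.ncol();
  for (std::size_t i = 0; i < n; ++i) y[i] = x[i] > 0 ? x[i] : 0;
  return Y;
}

// [[Rcpp::export]]
NumericMatrix cpp_relu_backward(const NumericMatrix& dY,
                                const NumericMatrix& Y) {
  NumericMatrix dX(no_init(dY.nrow(), dY.ncol()));
  const double* g = dY.begin();
  const double* y = Y.begin();
  double* d = dX.begin();
  const std::size_t n = (std::size_t)dY.nrow() * dY.ncol();
  for (std::size_t i = 0; i < n; ++i) d[i] = y[i] > 0 ? g[i] : 0;
  return dX;
}

// z = a + s * b, elementwise, without intermediate copies.
// [[Rcpp::export]]
NumericMatrix cpp_axpy(const NumericMatrix& A, const NumericMatrix& B,
                       double s) {
  NumericMatrix Y(no_init(A.nrow(), A.ncol()));
  const double* a = A.begin();
  const double* b = B.begin();
  double* y = Y.begin();
  const std::size_t n = (std::size_t)A.nrow() * A.ncol();
  for (std::size_t i = 0; i < n; ++i) y[i] = a[i] + s * b[i];
  return Y;
}
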