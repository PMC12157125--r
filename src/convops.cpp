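// Convolution and pooling kernels used by the network engine.
//
// Array layout matches R's column-major convention:
//   2D tensors: (H, W, C, N); 3D tensors: (H, W, D, C, N).
// Convolution weights are stored as a K x F matrix with
//   K = prod(kernel) * C_in and kernel element (i, j[, l], c) mapped to
//   row i + kh*(j + kw*(l + kd*c)).
// Forward passes use im2col + GEMM. Convolution arithmetic runs in single
// precision (the conventional choice for CNN training; inputs and results
// are converted at the R boundary); 3D im2col is chunked along the output
// depth axis to bound the scratch buffer.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const size_t kMaxChunkElems = 24000000;  // ~96 MB float scratch cap

static arma::fvec toF(const NumericVector& x) {
  arma::fvec out(x.size());
  std::copy(x.begin(), x.end(), out.begin());
  return out;
}

static arma::fmat toF(const NumericMatrix& x) {
  arma::fmat out(x.nrow(), x.ncol());
  std::copy(x.begin(), x.end(), out.begin());
  return out;
}

// ---------------------------------------------------------------- 2D im2col

static void im2col2d(const float* xs, int H, int W, int C,
                     int kh, int kw, int stride, int pad,
                     int Hout, int Wout, arma::fmat& cols) {
  for (int c = 0; c < C; ++c) {
    const float* xc = xs + (size_t)c * H * W;
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        float* col = cols.colptr(i + kh * (j + kw * c));
        for (int ow = 0; ow < Wout; ++ow) {
          const int iw = ow * stride - pad + j;
          const bool wok = (iw >= 0 && iw < W);
          float* dst = col + (size_t)ow * Hout;
          for (int oh = 0; oh < Hout; ++oh) {
            const int ih = oh * stride - pad + i;
            dst[oh] = (wok && ih >= 0 && ih < H) ? xc[ih + (size_t)iw * H]
                                                 : 0.0f;
          }
        }
      }
    }
  }
}

static void col2im2d(const arma::fmat& cols, float* dxs, int H, int W,
                     int C, int kh, int kw, int stride, int pad,
                     int Hout, int Wout) {
  for (int c = 0; c < C; ++c) {
    float* xc = dxs + (size_t)c * H * W;
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        const float* col = cols.colptr(i + kh * (j + kw * c));
        for (int ow = 0; ow < Wout; ++ow) {
          const int iw = ow * stride - pad + j;
          if (iw < 0 || iw >= W) continue;
          const float* src = col + (size_t)ow * Hout;
          for (int oh = 0; oh < Hout; ++oh) {
            const int ih = oh * stride - pad + i;
            if (ih >= 0 && ih < H) xc[ih + (size_t)iw * H] += src[oh];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fwd(NumericVector x, IntegerVector xdim,
                         NumericMatrix Wk, NumericVector b,
                         int kh, int kw, int stride, int pad) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int Hout = (H + 2 * pad - kh) / stride + 1;
  const int Wout = (W + 2 * pad - kw) / stride + 1;
  const int K = kh * kw * C, F = Wk.ncol();
  if (Wk.nrow() != K) stop("conv2d: weight rows do not match kernel size");
  const size_t P = (size_t)Hout * Wout;
  const arma::fvec xf = toF(x);
  const arma::fmat Wf = toF(Wk);
  arma::frowvec bv(F);
  std::copy(b.begin(), b.end(), bv.begin());
  NumericVector out(P * F * (size_t)N);
  arma::fmat cols(P, K);
  for (int n = 0; n < N; ++n) {
    im2col2d(xf.memptr() + (size_t)n * H * W * C, H, W, C, kh, kw, stride,
             pad, Hout, Wout, cols);
    arma::fmat y = cols * Wf;
    y.each_row() += bv;
    std::copy(y.begin(), y.end(), out.begin() + (size_t)n * P * F);
  }
  return out;
}

// [[Rcpp::export]]
List conv2d_bwd(NumericVector x, IntegerVector xdim,
                NumericMatrix Wk, NumericVector dy,
                int kh, int kw, int stride, int pad) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int Hout = (H + 2 * pad - kh) / stride + 1;
  const int Wout = (W + 2 * pad - kw) / stride + 1;
  const int K = kh * kw * C, F = Wk.ncol();
  const size_t P = (size_t)Hout * Wout;
  const arma::fvec xf = toF(x);
  const arma::fvec dyf = toF(dy);
  const arma::fmat Wf = toF(Wk);
  arma::fvec dxf(x.size(), arma::fill::zeros);
  arma::fmat dW(K, F, arma::fill::zeros);
  arma::fvec db(F, arma::fill::zeros);
  arma::fmat cols(P, K);
  for (int n = 0; n < N; ++n) {
    im2col2d(xf.memptr() + (size_t)n * H * W * C, H, W, C, kh, kw, stride,
             pad, Hout, Wout, cols);
    const arma::fmat dyn(const_cast<float*>(dyf.memptr()) +
                             (size_t)n * P * F,
                         P, F, false, true);
    dW += cols.t() * dyn;
    db += arma::sum(dyn, 0).t();
    arma::fmat dcols = dyn * Wf.t();
    col2im2d(dcols, dxf.memptr() + (size_t)n * H * W * C, H, W, C,
             kh, kw, stride, pad, Hout, Wout);
  }
  NumericVector dx(x.size());
  std::copy(dxf.begin(), dxf.end(), dx.begin());
  NumericMatrix dWout(K, F);
  std::copy(dW.begin(), dW.end(), dWout.begin());
  NumericVector dbout(F);
  std::copy(db.begin(), db.end(), dbout.begin());
  return List::create(_["dx"] = dx, _["dW"] = dWout, _["db"] = dbout);
}

// ---------------------------------------------------------------- 3D im2col

static void im2col3d(const float* xs, int H, int W, int D, int C,
                     int kh, int kw, int kd, int stride, int pad,
                     int Hout, int Wout, int od0, int od1,
                     arma::fmat& cols) {
  const size_t HW = (size_t)Hout * Wout;
  for (int c = 0; c < C; ++c) {
    const float* xc = xs + (size_t)c * H * W * D;
    for (int l = 0; l < kd; ++l) {
      for (int j = 0; j < kw; ++j) {
        for (int i = 0; i < kh; ++i) {
          float* col = cols.colptr(i + kh * (j + kw * (l + kd * c)));
          for (int od = od0; od < od1; ++od) {
            const int id = od * stride - pad + l;
            const bool dok = (id >= 0 && id < D);
            float* dstd = col + (size_t)(od - od0) * HW;
            for (int ow = 0; ow < Wout; ++ow) {
              const int iw = ow * stride - pad + j;
              const bool wok = dok && (iw >= 0 && iw < W);
              float* dst = dstd + (size_t)ow * Hout;
              const float* xcol =
                  wok ? xc + (size_t)id * H * W + (size_t)iw * H : NULL;
              for (int oh = 0; oh < Hout; ++oh) {
                const int ih = oh * stride - pad + i;
                dst[oh] = (wok && ih >= 0 && ih < H) ? xcol[ih] : 0.0f;
              }
            }
          }
        }
      }
    }
  }
}

static void col2im3d(const arma::fmat& cols, float* dxs, int H, int W,
                     int D, int C, int kh, int kw, int kd, int stride,
                     int pad, int Hout, int Wout, int od0, int od1) {
  const size_t HW = (size_t)Hout * Wout;
  for (int c = 0; c < C; ++c) {
    float* xc = dxs + (size_t)c * H * W * D;
    for (int l = 0; l < kd; ++l) {
      for (int j = 0; j < kw; ++j) {
        for (int i = 0; i < kh; ++i) {
          const float* col = cols.colptr(i + kh * (j + kw * (l + kd * c)));
          for (int od = od0; od < od1; ++od) {
            const int id = od * stride - pad + l;
            if (id < 0 || id >= D) continue;
            const float* srcd = col + (size_t)(od - od0) * HW;
            for (int ow = 0; ow < Wout; ++ow) {
              const int iw = ow * stride - pad + j;
              if (iw < 0 || iw >= W) continue;
              const float* src = srcd + (size_t)ow * Hout;
              float* xcol = xc + (size_t)id * H * W + (size_t)iw * H;
              for (int oh = 0; oh < Hout; ++oh) {
                const int ih = oh * stride - pad + i;
                if (ih >= 0 && ih < H) xcol[ih] += src[oh];
              }
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv3d_fwd(NumericVector x, IntegerVector xdim,
                         NumericMatrix Wk, NumericVector b,
                         int kh, int kw, int kd, int stride, int pad) {
  const int H = xdim[0], W = xdim[1], D = xdim[2], C = xdim[3], N = xdim[4];
  const int Hout = (H + 2 * pad - kh) / stride + 1;
  const int Wout = (W + 2 * pad - kw) / stride + 1;
  const int Dout = (D + 2 * pad - kd) / stride + 1;
  const int K = kh * kw * kd * C, F = Wk.ncol();
  if (Wk.nrow() != K) stop("conv3d: weight rows do not match kernel size");
  const size_t P = (size_t)Hout * Wout * Dout;
  const arma::fvec xf = toF(x);
  const arma::fmat Wf = toF(Wk);
  arma::frowvec bv(F);
  std::copy(b.begin(), b.end(), bv.begin());
  NumericVector out(P * F * (size_t)N);
  int odChunk = (int)std::max((size_t)1,
      kMaxChunkElems / ((size_t)Hout * Wout * K));
  if (odChunk > Dout) odChunk = Dout;
  arma::fmat cols((size_t)Hout * Wout * odChunk, K);
  for (int n = 0; n < N; ++n) {
    const float* xs = xf.memptr() + (size_t)n * H * W * D * C;
    for (int od0 = 0; od0 < Dout; od0 += odChunk) {
      const int od1 = std::min(Dout, od0 + odChunk);
      const size_t Pc = (size_t)Hout * Wout * (od1 - od0);
      arma::fmat colsv(cols.memptr(), Pc, K, false, true);
      im2col3d(xs, H, W, D, C, kh, kw, kd, stride, pad, Hout, Wout,
               od0, od1, colsv);
      arma::fmat y = colsv * Wf;
      y.each_row() += bv;
      // chunk rows are contiguous in (Hout, Wout, Dout) but the channel
      // axis interleaves: copy column by column
      double* ob = out.begin() + (size_t)n * P * F;
      for (int f = 0; f < F; ++f)
        std::copy(y.colptr(f), y.colptr(f) + Pc,
                  ob + (size_t)f * P + (size_t)od0 * Hout * Wout);
    }
  }
  return out;
}

// [[Rcpp::export]]
List conv3d_bwd(NumericVector x, IntegerVector xdim,
                NumericMatrix Wk, NumericVector dy,
                int kh, int kw, int kd, int stride, int pad) {
  const int H = xdim[0], W = xdim[1], D = xdim[2], C = xdim[3], N = xdim[4];
  const int Hout = (H + 2 * pad - kh) / stride + 1;
  const int Wout = (W + 2 * pad - kw) / stride + 1;
  const int Dout = (D + 2 * pad - kd) / stride + 1;
  const int K = kh * kw * kd * C, F = Wk.ncol();
  const size_t P = (size_t)Hout * Wout * Dout;
  const arma::fvec xf = toF(x);
  const arma::fvec dyf = toF(dy);
  const arma::fmat Wf = toF(Wk);
  arma::fvec dxf(x.size(), arma::fill::zeros);
  arma::fmat dW(K, F, arma::fill::zeros);
  arma::fvec db(F, arma::fill::zeros);
  int odChunk = (int)std::max((size_t)1,
      kMaxChunkElems / ((size_t)Hout * Wout * K));
  if (odChunk > Dout) odChunk = Dout;
  arma::fmat cols((size_t)Hout * Wout * odChunk, K);
  arma::fmat dyc((size_t)Hout * Wout * odChunk, F);
  for (int n = 0; n < N; ++n) {
    const float* xs = xf.memptr() + (size_t)n * H * W * D * C;
    float* dxs = dxf.memptr() + (size_t)n * H * W * D * C;
    const float* dyb = dyf.memptr() + (size_t)n * P * F;
    for (int od0 = 0; od0 < Dout; od0 += odChunk) {
      const int od1 = std::min(Dout, od0 + odChunk);
      const size_t Pc = (size_t)Hout * Wout * (od1 - od0);
      arma::fmat colsv(cols.memptr(), Pc, K, false, true);
      arma::fmat dyv(dyc.memptr(), Pc, F, false, true);
      for (int f = 0; f < F; ++f)
        std::copy(dyb + (size_t)f * P + (size_t)od0 * Hout * Wout,
                  dyb + (size_t)f * P + (size_t)od0 * Hout * Wout + Pc,
                  dyv.colptr(f));
      im2col3d(xs, H, W, D, C, kh, kw, kd, stride, pad, Hout, Wout,
               od0, od1, colsv);
      dW += colsv.t() * dyv;
      db += arma::sum(dyv, 0).t();
      arma::fmat dcols = dyv * Wf.t();
      col2im3d(dcols, dxs, H, W, D, C, kh, kw, kd, stride, pad,
               Hout, Wout, od0, od1);
    }
  }
  NumericVector dx(x.size());
  std::copy(dxf.begin(), dxf.end(), dx.begin());
  NumericMatrix dWout(K, F);
  std::copy(dW.begin(), dW.end(), dWout.begin());
  NumericVector dbout(F);
  std::copy(db.begin(), db.end(), dbout.begin());
  return List::create(_["dx"] = dx, _["dW"] = dWout, _["db"] = dbout);
}

// ----------------------------------------------------------------- pooling

// [[Rcpp::export]]
List maxpool2d_fwd(NumericVector x, IntegerVector xdim,
                   int kh, int kw, int stride, int pad) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int Hout = (H + 2 * pad - kh) / stride + 1;
  const int Wout = (W + 2 * pad - kw) / stride + 1;
  const size_t P = (size_t)Hout * Wout * C;
  NumericVector y(P * N);
  IntegerVector arg(P * N);
  for (int n = 0; n < N; ++n) {
    const double* xs = x.begin() + (size_t)n * H * W * C;
    double* ys = y.begin() + (size_t)n * P;
    int* as = arg.begin() + (size_t)n * P;
    for (int c = 0; c < C; ++c) {
      const double* xc = xs + (size_t)c * H * W;
      for (int ow = 0; ow < Wout; ++ow) {
        for (int oh = 0; oh < Hout; ++oh) {
          double best = -INFINITY;
          int bidx = -1;
          for (int j = 0; j < kw; ++j) {
            const int iw = ow * stride - pad + j;
            if (iw < 0 || iw >= W) continue;
            for (int i = 0; i < kh; ++i) {
              const int ih = oh * stride - pad + i;
              if (ih < 0 || ih >= H) continue;
              const double v = xc[ih + (size_t)iw * H];
              if (v > best) { best = v; bidx = ih + H * (iw + W * c); }
            }
          }
          const size_t o = oh + Hout * ((size_t)ow + Wout * c);
          ys[o] = best;
          as[o] = bidx;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector maxpool_bwd(NumericVector dy, IntegerVector argmax,
                          int sampleInSize, int sampleOutSize, int N) {
  NumericVector dx((size_t)sampleInSize * N);
  for (int n = 0; n < N; ++n) {
    const double* dys = dy.begin() + (size_t)n * sampleOutSize;
    const int* as = argmax.begin() + (size_t)n * sampleOutSize;
    double* dxs = dx.begin() + (size_t)n * sampleInSize;
    for (int o = 0; o < sampleOutSize; ++o)
      if (as[o] >= 0) dxs[as[o]] += dys[o];
  }
  return dx;
}

// [[Rcpp::export]]
List maxpool3d_fwd(NumericVector x, IntegerVector xdim,
                   int kh, int kw, int kd, int stride, int pad) {
  const int H = xdim[0], W = xdim[1], D = xdim[2], C = xdim[3], N = xdim[4];
  const int Hout = (H + 2 * pad - kh) / stride + 1;
  const int Wout = (W + 2 * pad - kw) / stride + 1;
  const int Dout = (D + 2 * pad - kd) / stride + 1;
  const size_t P = (size_t)Hout * Wout * Dout * C;
  NumericVector y(P * N);
  IntegerVector arg(P * N);
  for (int n = 0; n < N; ++n) {
    const double* xs = x.begin() + (size_t)n * H * W * D * C;
    double* ys = y.begin() + (size_t)n * P;
    int* as = arg.begin() + (size_t)n * P;
    for (int c = 0; c < C; ++c) {
      const double* xc = xs + (size_t)c * H * W * D;
      for (int od = 0; od < Dout; ++od) {
        for (int ow = 0; ow < Wout; ++ow) {
          for (int oh = 0; oh < Hout; ++oh) {
            double best = -INFINITY;
            int bidx = -1;
            for (int l = 0; l < kd; ++l) {
              const int id = od * stride - pad + l;
              if (id < 0 || id >= D) continue;
              for (int j = 0; j < kw; ++j) {
                const int iw = ow * stride - pad + j;
                if (iw < 0 || iw >= W) continue;
                for (int i = 0; i < kh; ++i) {
                  const int ih = oh * stride - pad + i;
                  if (ih < 0 || ih >= H) continue;
                  const double v =
                      xc[ih + (size_t)H * (iw + (size_t)W * id)];
                  if (v > best) {
                    best = v;
                    bidx = ih + H * (iw + W * (id + D * c));
                  }
                }
              }
            }
            const size_t o =
                oh + Hout * ((size_t)ow + Wout * ((size_t)od + Dout * c));
            ys[o] = best;
            as[o] = bidx;
          }
        }
      }
    }
  }
  return List::create(_["y"] = y, _["argmax"] = arg);
}
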