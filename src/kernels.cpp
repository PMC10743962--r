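// Numerical kernels for the encoder-decoder segmentation network.
//
// Tensors are R arrays with dim (H, W, C, N), column-major, so the flat
// index of (h, w, c, n) is h + H*(w + W*(c + C*n)), all 0-based here.
// Convolutions use im2col + GEMM (via Armadillo, which calls R's BLAS);
// "same" zero padding of d*(k-1)/2 keeps spatial size, with d the dilation.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline NumericVector alloc4(int a, int b, int c, int d) {
  NumericVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}
static inline IntegerVector alloc4i(int a, int b, int c, int d) {
  IntegerVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

static inline arma::uword idx4(int h, int w, int c, int n,
                               int H, int W, int C) {
  return (arma::uword)h + (arma::uword)H * ((arma::uword)w +
         (arma::uword)W * ((arma::uword)c + (arma::uword)C * (arma::uword)n));
}

// Convolutions build a transposed im2col matrix colT (N*P x K),
// P = H*W, K = kh*kw*Cin, in single precision: the GEMMs run in float32,
// while weight updates and all accumulation outside the convolution stay
// double. Row n*P + p of colT corresponds to sample n, output pixel
// (h, w) with p = h + H*w; column order matches the flat layout of the
// weight array (kh, kw, Cin, Cout).

static arma::fmat toF(const double* p, int nr, int nc) {
  arma::fmat out(nr, nc);
  const arma::uword n = (arma::uword)nr * nc;
  float* o = out.memptr();
  for (arma::uword i = 0; i < n; ++i) o[i] = (float)p[i];
  return out;
}

static void fillColT(const double* x, int H, int W, int Cin, int n,
                     int kh, int kw, int dil, arma::fmat& colT) {
  const int ph = dil * (kh - 1) / 2, pw = dil * (kw - 1) / 2;
  const int P = H * W;
  colT.zeros();
  for (int ci = 0; ci < Cin; ++ci) {
    const double* xc = x + (arma::uword)H * W * (ci + (arma::uword)Cin * n);
    for (int j = 0; j < kw; ++j)
      for (int i = 0; i < kh; ++i) {
        const int r = i + kh * (j + kw * ci);
        float* dst = colT.colptr(r);
        for (int wcol = 0; wcol < W; ++wcol) {
          const int sw = wcol + dil * j - pw;
          if (sw < 0 || sw >= W) continue;
          const double* src = xc + (arma::uword)H * sw;
          float* d = dst + (arma::uword)H * wcol;
          const int h0 = std::max(0, ph - dil * i);
          const int h1 = std::min(H, H + ph - dil * i);
          for (int h = h0; h < h1; ++h) d[h] = (float)src[h + dil * i - ph];
        }
      }
  }
  (void)P;
}

static void scatterColT(const arma::fmat& dcolT, int H, int W, int Cin,
                        int n, int kh, int kw, int dil, double* dx) {
  const int ph = dil * (kh - 1) / 2, pw = dil * (kw - 1) / 2;
  for (int ci = 0; ci < Cin; ++ci) {
    double* xc = dx + (arma::uword)H * W * (ci + (arma::uword)Cin * n);
    for (int j = 0; j < kw; ++j)
      for (int i = 0; i < kh; ++i) {
        const int r = i + kh * (j + kw * ci);
        const float* src0 = dcolT.colptr(r);
        for (int wcol = 0; wcol < W; ++wcol) {
          const int sw = wcol + dil * j - pw;
          if (sw < 0 || sw >= W) continue;
          double* d = xc + (arma::uword)H * sw;
          const float* src = src0 + (arma::uword)H * wcol;
          const int h0 = std::max(0, ph - dil * i);
          const int h1 = std::min(H, H + ph - dil * i);
          for (int h = h0; h < h1; ++h) d[h + dil * i - ph] += src[h];
        }
      }
  }
}

// [[Rcpp::export(name = ".conv2dForward")]]
NumericVector conv2dForward(NumericVector x, NumericVector w,
                            NumericVector b, int dilation) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cout = wd[3];
  if (wd[2] != Cin) stop("channel mismatch in convolution");
  const int K = kh * kw * Cin, P = H * W;
  NumericVector y = alloc4(H, W, Cout, N);
  arma::fmat Wf = toF(w.begin(), K, Cout);
  arma::fmat colT(P, K), Yf(P, Cout);
  for (int n = 0; n < N; ++n) {
    fillColT(x.begin(), H, W, Cin, n, kh, kw, dilation, colT);
    Yf = colT * Wf;
    double* yp = y.begin() + (arma::uword)P * Cout * n;
    for (int co = 0; co < Cout; ++co) {
      const float* src = Yf.colptr(co);
      const double bb = b[co];
      double* d = yp + (arma::uword)P * co;
      for (int p = 0; p < P; ++p) d[p] = (double)src[p] + bb;
    }
  }
  return y;
}

// [[Rcpp::export(name = ".conv2dBackward")]]
List conv2dBackward(NumericVector x, NumericVector w, NumericVector dy,
                    int dilation) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cout = wd[3];
  const int K = kh * kw * Cin, P = H * W;
  NumericVector dx = alloc4(H, W, Cin, N);
  NumericVector dw = alloc4(kh, kw, Cin, Cout);
  NumericVector db(Cout);
  arma::fmat Wf = toF(w.begin(), K, Cout);
  arma::fmat dWf(K, Cout, arma::fill::zeros);
  arma::fmat colT(P, K), dcolT(P, K), dYf(P, Cout);
  for (int n = 0; n < N; ++n) {
    const double* dyp = dy.begin() + (arma::uword)P * Cout * n;
    for (int co = 0; co < Cout; ++co) {
      const double* s = dyp + (arma::uword)P * co;
      float* d = dYf.colptr(co);
      double acc = 0.0;
      for (int p = 0; p < P; ++p) { d[p] = (float)s[p]; acc += s[p]; }
      db[co] += acc;
    }
    fillColT(x.begin(), H, W, Cin, n, kh, kw, dilation, colT);
    dWf += colT.t() * dYf;
    dcolT = dYf * Wf.t();
    scatterColT(dcolT, H, W, Cin, n, kh, kw, dilation, dx.begin());
  }
  for (int i = 0; i < K * Cout; ++i) dw[i] = (double)dWf.memptr()[i];
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// 2x2 max pooling, stride 2; idx stores the winning offset (0..3, column
// major within the window) for the backward scatter.
// [[Rcpp::export(name = ".maxPoolForward")]]
List maxPoolForward(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y = alloc4(Ho, Wo, C, N);
  IntegerVector idx = alloc4i(Ho, Wo, C, N);
  const double* xp = x.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int w = 0; w < Wo; ++w)
        for (int h = 0; h < Ho; ++h) {
          double best = -1e300; int bi = 0;
          for (int dw2 = 0; dw2 < 2; ++dw2)
            for (int dh = 0; dh < 2; ++dh) {
              const double v = xp[idx4(2*h+dh, 2*w+dw2, c, n, H, W, C)];
              const int off = dh + 2 * dw2;
              if (v > best) { best = v; bi = off; }
            }
          const arma::uword o = idx4(h, w, c, n, Ho, Wo, C);
          y[o] = best; idx[o] = bi;
        }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxPoolBackward")]]
NumericVector maxPoolBackward(NumericVector dy, IntegerVector idx,
                              int H, int W) {
  IntegerVector yd = dy.attr("dim");
  const int Ho = yd[0], Wo = yd[1], C = yd[2], N = yd[3];
  NumericVector dx = alloc4(H, W, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int w = 0; w < Wo; ++w)
        for (int h = 0; h < Ho; ++h) {
          const arma::uword o = idx4(h, w, c, n, Ho, Wo, C);
          const int bi = idx[o];
          dx[idx4(2*h + bi % 2, 2*w + bi / 2, c, n, H, W, C)] += dy[o];
        }
  return dx;
}

// Bilinear x2 upsampling (half-pixel centers, clamped borders).
static void up2_weights(int i, int n, int& i0, int& i1, double& w1) {
  const double s = (i + 0.5) / 2.0 - 0.5;
  const double f = std::floor(s);
  i0 = (int)f; i1 = i0 + 1; w1 = s - f;
  if (i0 < 0) i0 = 0;
  if (i1 > n - 1) i1 = n - 1;
}

// [[Rcpp::export(name = ".upsample2Forward")]]
NumericVector upsample2Forward(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector y = alloc4(Ho, Wo, C, N);
  const double* xp = x.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int w = 0; w < Wo; ++w) {
        int w0, w1; double ww;
        up2_weights(w, W, w0, w1, ww);
        for (int h = 0; h < Ho; ++h) {
          int h0, h1; double wh;
          up2_weights(h, H, h0, h1, wh);
          const double v =
            (1-wh)*(1-ww)*xp[idx4(h0, w0, c, n, H, W, C)] +
            wh*(1-ww)    *xp[idx4(h1, w0, c, n, H, W, C)] +
            (1-wh)*ww    *xp[idx4(h0, w1, c, n, H, W, C)] +
            wh*ww        *xp[idx4(h1, w1, c, n, H, W, C)];
          y[idx4(h, w, c, n, Ho, Wo, C)] = v;
        }
      }
  return y;
}

// [[Rcpp::export(name = ".upsample2Backward")]]
NumericVector upsample2Backward(NumericVector dy) {
  IntegerVector yd = dy.attr("dim");
  const int Ho = yd[0], Wo = yd[1], C = yd[2], N = yd[3];
  const int H = Ho / 2, W = Wo / 2;
  NumericVector dx = alloc4(H, W, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int w = 0; w < Wo; ++w) {
        int w0, w1; double ww;
        up2_weights(w, W, w0, w1, ww);
        for (int h = 0; h < Ho; ++h) {
          int h0, h1; double wh;
          up2_weights(h, H, h0, h1, wh);
          const double g = dy[idx4(h, w, c, n, Ho, Wo, C)];
          dx[idx4(h0, w0, c, n, H, W, C)] += (1-wh)*(1-ww)*g;
          dx[idx4(h1, w0, c, n, H, W, C)] += wh*(1-ww)*g;
          dx[idx4(h0, w1, c, n, H, W, C)] += (1-wh)*ww*g;
          dx[idx4(h1, w1, c, n, H, W, C)] += wh*ww*g;
        }
      }
  return dx;
}

// Batch normalization over (H, W, N) per channel; population variance.
// [[Rcpp::export(name = ".bnForward")]]
List bnForward(NumericVector x, NumericVector gamma, NumericVector beta,
               NumericVector mean, NumericVector var, double eps,
               bool useBatchStats) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const arma::uword M = (arma::uword)H * W * N;
  NumericVector y = alloc4(H, W, C, N);
  NumericVector m(C), v(C);
  if (useBatchStats) {
    for (int c = 0; c < C; ++c) {
      double s = 0, s2 = 0;
      for (int n = 0; n < N; ++n) {
        const double* xp = x.begin() + idx4(0, 0, c, n, H, W, C);
        for (arma::uword i = 0; i < (arma::uword)H * W; ++i) {
          s += xp[i]; s2 += xp[i] * xp[i];
        }
      }
      m[c] = s / M;
      v[c] = s2 / M - m[c] * m[c];
      if (v[c] < 0) v[c] = 0;
    }
  } else {
    m = clone(mean); v = clone(var);
  }
  NumericVector invStd(C);
  for (int c = 0; c < C; ++c) {
    invStd[c] = 1.0 / std::sqrt(v[c] + eps);
    const double a = gamma[c] * invStd[c];
    const double b2 = beta[c] - a * m[c];
    for (int n = 0; n < N; ++n) {
      const double* xp = x.begin() + idx4(0, 0, c, n, H, W, C);
      double* yp = y.begin() + idx4(0, 0, c, n, H, W, C);
      for (arma::uword i = 0; i < (arma::uword)H * W; ++i)
        yp[i] = a * xp[i] + b2;
    }
  }
  return List::create(_["y"] = y, _["mean"] = m, _["var"] = v,
                      _["invStd"] = invStd);
}

// [[Rcpp::export(name = ".bnBackward")]]
List bnBackward(NumericVector dy, NumericVector x, NumericVector gamma,
                NumericVector mean, NumericVector invStd,
                bool usedBatchStats) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const arma::uword M = (arma::uword)H * W * N;
  NumericVector dx = alloc4(H, W, C, N);
  NumericVector dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    double sdy = 0, sdyx = 0;
    for (int n = 0; n < N; ++n) {
      const double* xp = x.begin() + idx4(0, 0, c, n, H, W, C);
      const double* dp = dy.begin() + idx4(0, 0, c, n, H, W, C);
      for (arma::uword i = 0; i < (arma::uword)H * W; ++i) {
        const double xh = (xp[i] - mean[c]) * invStd[c];
        sdy += dp[i];
        sdyx += dp[i] * xh;
      }
    }
    dbeta[c] = sdy;
    dgamma[c] = sdyx;
    const double g = gamma[c];
    for (int n = 0; n < N; ++n) {
      const double* xp = x.begin() + idx4(0, 0, c, n, H, W, C);
      const double* dp = dy.begin() + idx4(0, 0, c, n, H, W, C);
      double* dxp = dx.begin() + idx4(0, 0, c, n, H, W, C);
      for (arma::uword i = 0; i < (arma::uword)H * W; ++i) {
        if (usedBatchStats) {
          const double xh = (xp[i] - mean[c]) * invStd[c];
          dxp[i] = g * invStd[c] *
            (dp[i] - sdy / (double)M - xh * sdyx / (double)M);
        } else {
          dxp[i] = g * invStd[c] * dp[i];
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}
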