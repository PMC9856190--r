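// Low-level tensor ops for the small CNNs: 2-D convolution via im2col,
// max-pooling with argmax bookkeeping, and batch normalisation.
// Layout convention throughout: activations are R arrays with
// dim = c(H, W, C, N) (column-major), weights are F x (kh*kw*C) matrices
// with the patch unrolled dh-fastest, then dw, then c (matching im2col below).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int out_dim(int in, int k, int pad) { return in + 2 * pad - k + 1; }

static NumericVector array4(int d1, int d2, int d3, int d4) {
  NumericVector v((R_xlen_t)d1 * d2 * d3 * d4);
  v.attr("dim") = IntegerVector::create(d1, d2, d3, d4);
  return v;
}

static IntegerVector iarray4(int d1, int d2, int d3, int d4) {
  IntegerVector v((R_xlen_t)d1 * d2 * d3 * d4);
  v.attr("dim") = IntegerVector::create(d1, d2, d3, d4);
  return v;
}

// Unroll padded kh x kw x C patches of one image into a (Ho*Wo) x (kh*kw*C)
// matrix (position-major, so gemm consumes it without a transpose copy).
// Patch element order: dh fastest, then dw, then c.
static void im2col(const double* x, int H, int W, int C,
                   int kh, int kw, int padh, int padw, arma::mat& colsT) {
  const int Ho = out_dim(H, kh, padh);
  const int Wo = out_dim(W, kw, padw);
  colsT.zeros();
  int r = 0;
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)H * W * c;
    for (int dw = 0; dw < kw; ++dw) {
      for (int dh = 0; dh < kh; ++dh, ++r) {
        double* dst = colsT.colptr(r);
        const int ho0 = std::max(0, padh - dh), ho1 = std::min(Ho - 1, H - 1 - dh + padh);
        const int wo0 = std::max(0, padw - dw), wo1 = std::min(Wo - 1, W - 1 - dw + padw);
        const int len = ho1 - ho0 + 1;
        if (len <= 0) continue;
        for (int wo = wo0; wo <= wo1; ++wo) {
          const double* src = xc + (ho0 + dh - padh) + (size_t)H * (wo + dw - padw);
          std::copy(src, src + len, dst + ho0 + (size_t)Ho * wo);
        }
      }
    }
  }
}

// Scatter-add the (Ho*Wo) x (kh*kw*C) patch-gradient matrix onto dx.
static void col2im(const arma::mat& colsT, int H, int W, int C,
                   int kh, int kw, int padh, int padw, double* dx) {
  const int Ho = out_dim(H, kh, padh);
  const int Wo = out_dim(W, kw, padw);
  int r = 0;
  for (int c = 0; c < C; ++c) {
    double* xc = dx + (size_t)H * W * c;
    for (int dw = 0; dw < kw; ++dw) {
      for (int dh = 0; dh < kh; ++dh, ++r) {
        const double* src = colsT.colptr(r);
        const int ho0 = std::max(0, padh - dh), ho1 = std::min(Ho - 1, H - 1 - dh + padh);
        const int wo0 = std::max(0, padw - dw), wo1 = std::min(Wo - 1, W - 1 - dw + padw);
        const int len = ho1 - ho0 + 1;
        if (len <= 0) continue;
        for (int wo = wo0; wo <= wo1; ++wo) {
          double* dst = xc + (ho0 + dh - padh) + (size_t)H * (wo + dw - padw);
          const double* s = src + ho0 + (size_t)Ho * wo;
          for (int i = 0; i < len; ++i) dst[i] += s[i];
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".convForward")]]
NumericVector conv_forward(NumericVector x, NumericMatrix w, NumericVector b,
                           int kh, int kw, int padh, int padw) {
  IntegerVector dm = x.attr("dim");
  const int H = dm[0], W = dm[1], C = dm[2], N = dm[3];
  const int F = w.nrow();
  if (w.ncol() != C * kh * kw) stop("weight shape does not match kernel/channels");
  const int Ho = out_dim(H, kh, padh), Wo = out_dim(W, kw, padw);
  NumericVector y = array4(Ho, Wo, F, N);
  arma::mat wm(w.begin(), F, C * kh * kw, false, true);
  arma::vec bv(b.begin(), F, false, true);
  arma::mat colsT(Ho * Wo, C * kh * kw);
  const size_t xstride = (size_t)H * W * C, ystride = (size_t)Ho * Wo * F;
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + n * xstride, H, W, C, kh, kw, padh, padw, colsT);
    arma::mat out(y.begin() + n * ystride, Ho * Wo, F, false, true);
    out = colsT * wm.t();
    out.each_row() += bv.t();
  }
  return y;
}

// [[Rcpp::export(name = ".convBackward")]]
List conv_backward(NumericVector x, NumericMatrix w, NumericVector dy,
                   int kh, int kw, int padh, int padw, bool need_dx) {
  IntegerVector dm = x.attr("dim");
  const int H = dm[0], W = dm[1], C = dm[2], N = dm[3];
  const int F = w.nrow();
  const int Ho = out_dim(H, kh, padh), Wo = out_dim(W, kw, padw);
  NumericVector dx = need_dx ? array4(H, W, C, N) : array4(1, 1, 1, 1);
  NumericMatrix dw(F, C * kh * kw);
  NumericVector db(F);
  arma::mat wm(w.begin(), F, C * kh * kw, false, true);
  arma::mat dwm(dw.begin(), F, C * kh * kw, false, true);
  arma::vec dbv(db.begin(), F, false, true);
  arma::mat colsT(Ho * Wo, C * kh * kw);
  const size_t xstride = (size_t)H * W * C, ystride = (size_t)Ho * Wo * F;
  for (int n = 0; n < N; ++n) {
    arma::mat dyn(const_cast<double*>(dy.begin()) + n * ystride,
                  Ho * Wo, F, false, true);
    im2col(x.begin() + n * xstride, H, W, C, kh, kw, padh, padw, colsT);
    dwm += dyn.t() * colsT;
    dbv += arma::sum(dyn, 0).t();
    if (need_dx) {
      colsT = dyn * wm;  // reuse buffer: now d(im2col)
      col2im(colsT, H, W, C, kh, kw, padh, padw, dx.begin() + n * xstride);
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export(name = ".maxpoolForward")]]
List maxpool_forward(NumericVector x, int ph, int pw) {
  IntegerVector dm = x.attr("dim");
  const int H = dm[0], W = dm[1], C = dm[2], N = dm[3];
  const int Ho = H / ph, Wo = W / pw;
  NumericVector y = array4(Ho, Wo, C, N);
  IntegerVector idx = iarray4(Ho, Wo, C, N); // 0-based flat index into x
  const double* xp = x.begin();
  double* yp = y.begin();
  int* ip = idx.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t base = ((size_t)n * C + c) * H * W;
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double best = -1e300; size_t besti = 0;
          for (int dw = 0; dw < pw; ++dw)
            for (int dh = 0; dh < ph; ++dh) {
              const size_t xi = base + (ho * ph + dh) + (size_t)H * (wo * pw + dw);
              if (xp[xi] > best) { best = xp[xi]; besti = xi; }
            }
          // column-major target offset within (Ho,Wo,C,N)
          const size_t yi = (size_t)ho + (size_t)Ho * wo +
            (size_t)Ho * Wo * c + (size_t)Ho * Wo * C * n;
          yp[yi] = best; ip[yi] = (int)besti;

        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpoolBackward")]]
NumericVector maxpool_backward(NumericVector dy, IntegerVector idx,
                               IntegerVector xdim) {
  NumericVector dx = array4(xdim[0], xdim[1], xdim[2], xdim[3]);
  const double* dyp = dy.begin();
  const int* ip = idx.begin();
  double* dxp = dx.begin();
  const R_xlen_t n = dy.size();
  for (R_xlen_t i = 0; i < n; ++i) dxp[ip[i]] += dyp[i];
  return dx;
}

// Fused batch norm + LeakyReLU over (H,W,C,N), per channel c.
// Returns the activated output plus the batch mean/var; the backward pass
// recomputes the normalized values from x, so no intermediate tensor is
// stored.
// [[Rcpp::export(name = ".bnActForward")]]
List bn_act_forward(NumericVector x, NumericVector gamma, NumericVector beta,
                    double eps, double slope) {
  IntegerVector dm = x.attr("dim");
  const int H = dm[0], W = dm[1], C = dm[2], N = dm[3];
  const size_t hw = (size_t)H * W, cs = hw * C;
  NumericVector mean(C), var(C);
  const double* xp = x.begin();
  for (int c = 0; c < C; ++c) {
    double s = 0, s2 = 0;
    for (int n = 0; n < N; ++n) {
      const double* p = xp + n * cs + c * hw;
      for (size_t i = 0; i < hw; ++i) { s += p[i]; s2 += p[i] * p[i]; }
    }
    const double m = s / (hw * N);
    mean[c] = m; var[c] = s2 / (hw * N) - m * m;
  }
  NumericVector y = array4(H, W, C, N);
  double* yp = y.begin();
  for (int c = 0; c < C; ++c) {
    const double inv = 1.0 / std::sqrt(var[c] + eps);
    const double g = gamma[c], b = beta[c], m = mean[c];
    for (int n = 0; n < N; ++n) {
      const double* p = xp + n * cs + c * hw;
      double* q = yp + n * cs + c * hw;
      for (size_t i = 0; i < hw; ++i) {
        const double a = g * (p[i] - m) * inv + b;
        q[i] = a < 0 ? slope * a : a;
      }
    }
  }
  return List::create(_["y"] = y, _["mean"] = mean, _["var"] = var);
}

// Inference-mode fused batch norm + LeakyReLU using running statistics.
// [[Rcpp::export(name = ".bnActEval")]]
NumericVector bn_act_eval(NumericVector x, NumericVector gamma,
                          NumericVector beta, NumericVector mean,
                          NumericVector var, double eps, double slope) {
  IntegerVector dm = x.attr("dim");
  const int H = dm[0], W = dm[1], C = dm[2], N = dm[3];
  const size_t hw = (size_t)H * W, cs = hw * C;
  NumericVector y = array4(H, W, C, N);
  const double* xp = x.begin(); double* yp = y.begin();
  for (int c = 0; c < C; ++c) {
    const double inv = 1.0 / std::sqrt(var[c] + eps);
    const double g = gamma[c], b = beta[c], m = mean[c];
    for (int n = 0; n < N; ++n) {
      const double* p = xp + n * cs + c * hw;
      double* q = yp + n * cs + c * hw;
      for (size_t i = 0; i < hw; ++i) {
        const double a = g * (p[i] - m) * inv + b;
        q[i] = a < 0 ? slope * a : a;
      }
    }
  }
  return y;
}

// Backward of the fused BN + LeakyReLU. dy is the gradient w.r.t. the
// activated output; xhat and the pre-activation are recomputed from x.
// [[Rcpp::export(name = ".bnActBackward")]]
List bn_act_backward(NumericVector dy, NumericVector x, NumericVector gamma,
                     NumericVector beta, NumericVector mean, NumericVector var,
                     double eps, double slope) {
  IntegerVector dm = dy.attr("dim");
  const int H = dm[0], W = dm[1], C = dm[2], N = dm[3];
  const size_t hw = (size_t)H * W, cs = hw * C;
  const double mtot = (double)hw * N;
  NumericVector dx = array4(H, W, C, N), dgamma(C), dbeta(C);
  const double* dyp = dy.begin(); const double* xp = x.begin();
  double* dxp = dx.begin();
  for (int c = 0; c < C; ++c) {
    const double inv = 1.0 / std::sqrt(var[c] + eps);
    const double g = gamma[c], b = beta[c], m = mean[c];
    double sdy = 0, sdyh = 0;
    for (int n = 0; n < N; ++n) {
      const double* a = dyp + n * cs + c * hw;
      const double* p = xp + n * cs + c * hw;
      for (size_t i = 0; i < hw; ++i) {
        const double xh = (p[i] - m) * inv;
        double d = a[i];
        if (g * xh + b < 0) d *= slope;   // LeakyReLU gate
        sdy += d; sdyh += d * xh;
      }
    }
    dgamma[c] = sdyh; dbeta[c] = sdy;
    const double ginv = g * inv, c1 = sdy / mtot, c2 = sdyh / mtot;
    for (int n = 0; n < N; ++n) {
      const double* a = dyp + n * cs + c * hw;
      const double* p = xp + n * cs + c * hw;
      double* d = dxp + n * cs + c * hw;
      for (size_t i = 0; i < hw; ++i) {
        const double xh = (p[i] - m) * inv;
        double dd = a[i];
        if (g * xh + b < 0) dd *= slope;
        d[i] = ginv * (dd - c1 - xh * c2);
      }
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// One fused Adam update. m and v (the moment buffers) are updated in
// place; the returned vector is a fresh allocation so retained parameter
// checkpoints are never aliased.
// [[Rcpp::export(name = ".adamUpdate")]]
NumericVector adam_update(NumericVector param, NumericVector grad,
                          NumericVector m, NumericVector v,
                          double lr, double beta1, double beta2,
                          double eps, double bc1, double bc2) {
  const R_xlen_t n = param.size();
  NumericVector out = clone(param);
  double* mp = m.begin(); double* vp = v.begin();
  const double* gp = grad.begin();
  double* op = out.begin();
  for (R_xlen_t i = 0; i < n; ++i) {
    mp[i] = beta1 * mp[i] + (1 - beta1) * gp[i];
    vp[i] = beta2 * vp[i] + (1 - beta2) * gp[i] * gp[i];
    op[i] -= lr * (mp[i] / bc1) / (std::sqrt(vp[i] / bc2) + eps);
  }
  return out;
}

// Fully fused BN + LeakyReLU + 2x2 max-pool. The activated tensor is never
// materialized: each pooled cell evaluates its window's activations on the
// fly (the activation is not monotone in x when gamma < 0, so activations,
// not raw inputs, are compared). idx stores the flat position of the
// winning element within x.
// [[Rcpp::export(name = ".bnActPoolForward")]]
List bn_act_pool_forward(NumericVector x, NumericVector gamma,
                         NumericVector beta, double eps, double slope,
                         int ph, int pw) {
  IntegerVector dm = x.attr("dim");
  const int H = dm[0], W = dm[1], C = dm[2], N = dm[3];
  const int Ho = H / ph, Wo = W / pw;
  const size_t hw = (size_t)H * W, cs = hw * C;
  NumericVector mean(C), var(C);
  const double* xp = x.begin();
  for (int c = 0; c < C; ++c) {
    double s = 0, s2 = 0;
    for (int n = 0; n < N; ++n) {
      const double* p = xp + n * cs + c * hw;
      for (size_t i = 0; i < hw; ++i) { s += p[i]; s2 += p[i] * p[i]; }
    }
    const double m = s / (hw * N);
    mean[c] = m; var[c] = s2 / (hw * N) - m * m;
  }
  NumericVector y = array4(Ho, Wo, C, N);
  IntegerVector idx = iarray4(Ho, Wo, C, N);
  double* yp = y.begin(); int* ip = idx.begin();
  const size_t ohw = (size_t)Ho * Wo, ocs = ohw * C;
  for (int c = 0; c < C; ++c) {
    const double inv = 1.0 / std::sqrt(var[c] + eps);
    const double g = gamma[c], b = beta[c], m = mean[c];
    for (int n = 0; n < N; ++n) {
      const double* p = xp + n * cs + c * hw;
      double* q = yp + n * ocs + c * ohw;
      int* qi = ip + n * ocs + c * ohw;
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double best = -1e300; size_t besti = 0;
          for (int dw = 0; dw < pw; ++dw)
            for (int dh = 0; dh < ph; ++dh) {
              const size_t xi = (size_t)(ho * ph + dh) +
                (size_t)H * (wo * pw + dw);
              double a = g * (p[xi] - m) * inv + b;
              if (a < 0) a *= slope;
              if (a > best) { best = a; besti = xi; }
            }
          q[ho + (size_t)Ho * wo] = best;
          qi[ho + (size_t)Ho * wo] = (int)(besti + n * cs + c * hw);
        }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx,
                      _["mean"] = mean, _["var"] = var);
}

// Inference-mode fused BN + LeakyReLU + max-pool using running statistics.
// [[Rcpp::export(name = ".bnActPoolEval")]]
NumericVector bn_act_pool_eval(NumericVector x, NumericVector gamma,
                               NumericVector beta, NumericVector mean,
                               NumericVector var, double eps, double slope,
                               int ph, int pw) {
  IntegerVector dm = x.attr("dim");
  const int H = dm[0], W = dm[1], C = dm[2], N = dm[3];
  const int Ho = H / ph, Wo = W / pw;
  const size_t hw = (size_t)H * W, cs = hw * C;
  NumericVector y = array4(Ho, Wo, C, N);
  const double* xp = x.begin(); double* yp = y.begin();
  const size_t ohw = (size_t)Ho * Wo, ocs = ohw * C;
  for (int c = 0; c < C; ++c) {
    const double inv = 1.0 / std::sqrt(var[c] + eps);
    const double g = gamma[c], b = beta[c], m = mean[c];
    for (int n = 0; n < N; ++n) {
      const double* p = xp + n * cs + c * hw;
      double* q = yp + n * ocs + c * ohw;
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double best = -1e300;
          for (int dw = 0; dw < pw; ++dw)
            for (int dh = 0; dh < ph; ++dh) {
              const size_t xi = (size_t)(ho * ph + dh) +
                (size_t)H * (wo * pw + dw);
              double a = g * (p[xi] - m) * inv + b;
              if (a < 0) a *= slope;
              if (a > best) best = a;
            }
          q[ho + (size_t)Ho * wo] = best;
        }
    }
  }
  return y;
}

// Backward of the fused BN + LeakyReLU + max-pool. dy is the pooled
// gradient; the upstream gradient of the activated tensor is nonzero only
// at the argmax positions, so the BN reduction sums run over those alone,
// while dx receives the dense BN coupling term everywhere.
// [[Rcpp::export(name = ".bnActPoolBackward")]]
List bn_act_pool_backward(NumericVector dy, IntegerVector idx,
                          NumericVector x, NumericVector gamma,
                          NumericVector beta, NumericVector mean,
                          NumericVector var, double eps, double slope) {
  IntegerVector dm = x.attr("dim");
  const int H = dm[0], W = dm[1], C = dm[2], N = dm[3];
  IntegerVector pm = dy.attr("dim");
  const int Ho = pm[0], Wo = pm[1];
  const size_t hw = (size_t)H * W, cs = hw * C;
  const size_t ohw = (size_t)Ho * Wo, ocs = ohw * C;
  const double mtot = (double)hw * N;
  NumericVector dx = array4(H, W, C, N), dgamma(C), dbeta(C);
  const double* dyp = dy.begin(); const double* xp = x.begin();
  const int* ip = idx.begin();
  double* dxp = dx.begin();
  for (int c = 0; c < C; ++c) {
    const double inv = 1.0 / std::sqrt(var[c] + eps);
    const double g = gamma[c], b = beta[c], m = mean[c];
    double sdy = 0, sdyh = 0;
    for (int n = 0; n < N; ++n) {
      const double* a = dyp + n * ocs + c * ohw;
      const int* qi = ip + n * ocs + c * ohw;
      for (size_t i = 0; i < ohw; ++i) {
        const double xh = (xp[qi[i]] - m) * inv;
        double dd = a[i];
        if (g * xh + b < 0) dd *= slope;
        sdy += dd; sdyh += dd * xh;
      }
    }
    dgamma[c] = sdyh; dbeta[c] = sdy;
    const double ginv = g * inv, c1 = sdy / mtot, c2 = sdyh / mtot;
    for (int n = 0; n < N; ++n) {
      const double* p = xp + n * cs + c * hw;
      double* d = dxp + n * cs + c * hw;
      for (size_t i = 0; i < hw; ++i)
        d[i] = -ginv * (c1 + (p[i] - m) * inv * c2);
    }
    for (int n = 0; n < N; ++n) {
      const double* a = dyp + n * ocs + c * ohw;
      const int* qi = ip + n * ocs + c * ohw;
      for (size_t i = 0; i < ohw; ++i) {
        const double xh = (xp[qi[i]] - m) * inv;
        double dd = a[i];
        if (g * xh + b < 0) dd *= slope;
        dxp[qi[i]] += ginv * dd;
      }
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}
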