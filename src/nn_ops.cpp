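// Minimal CNN kernels for the detector: im2col convolution, depthwise
// convolution, batch norm, max pooling and nearest upsampling, with
// backward passes. Tensors are R double arrays laid out [H, W, C, N]
// (column-major, H fastest); conv weights are [k, k, Cin, Cout].

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_size(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

static void im2col(const double* x, int H, int W, int C, int k, int stride,
                   int pad, arma::mat& col, int Ho, int Wo) {
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)H * W * c;
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        int row = ki + k * kj + k * k * c;
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * stride - pad + kj;
          double* dst = col.colptr(0) + row;  // element (row, p)
          if (wi < 0 || wi >= W) {
            for (int ho = 0; ho < Ho; ++ho)
              col(row, ho + (size_t)Ho * wo) = 0.0;
            continue;
          }
          const double* xcol = xc + (size_t)H * wi;
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho * stride - pad + ki;
            col(row, ho + (size_t)Ho * wo) =
                (hi >= 0 && hi < H) ? xcol[hi] : 0.0;
          }
          (void)dst;
        }
      }
    }
  }
}

static void col2im_add(double* x, int H, int W, int C, int k, int stride,
                       int pad, const arma::mat& col, int Ho, int Wo) {
  for (int c = 0; c < C; ++c) {
    double* xc = x + (size_t)H * W * c;
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        int row = ki + k * kj + k * k * c;
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * stride - pad + kj;
          if (wi < 0 || wi >= W) continue;
          double* xcol = xc + (size_t)H * wi;
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho * stride - pad + ki;
            if (hi >= 0 && hi < H)
              xcol[hi] += col(row, ho + (size_t)Ho * wo);
          }
        }
      }
    }
  }
}

static IntegerVector tensor_dim(const NumericVector& x) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d [H,W,C,N] tensor");
  return d;
}

// [[Rcpp::export]]
NumericVector cpp_conv_fwd(NumericVector x, NumericVector w,
                           Nullable<NumericVector> bias, int stride,
                           int pad) {
  IntegerVector xd = tensor_dim(x);
  IntegerVector wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int k = wd[0], OC = wd[3];
  if (wd[2] != C) stop("conv: input has %d channels, weight expects %d", C,
                       wd[2]);
  int Ho = out_size(H, k, stride, pad), Wo = out_size(W, k, stride, pad);
  size_t P = (size_t)Ho * Wo, K = (size_t)k * k * C;
  NumericVector y(P * OC * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, OC, N);
  arma::mat Wm(w.begin(), K, OC, false, true);
  arma::mat col(K, P);
  arma::vec b = bias.isNotNull()
                    ? arma::vec(NumericVector(bias).begin(), OC)
                    : arma::vec();
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C, k, stride, pad, col,
           Ho, Wo);
    arma::mat Ym(y.begin() + P * OC * n, P, OC, false, true);
    Ym = col.t() * Wm;
    if (b.n_elem) Ym.each_row() += b.t();
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv_bwd(NumericVector x, NumericVector w, NumericVector dy,
                  int stride, int pad, bool need_dx, bool has_bias) {
  IntegerVector xd = tensor_dim(x), wd = w.attr("dim"),
                yd = tensor_dim(dy);
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int k = wd[0], OC = wd[3], Ho = yd[0], Wo = yd[1];
  size_t P = (size_t)Ho * Wo, K = (size_t)k * k * C;
  arma::mat Wm(w.begin(), K, OC, false, true);
  NumericVector dw(w.size());
  dw.attr("dim") = wd;
  arma::mat dWm(dw.begin(), K, OC, false, true);
  NumericVector db(OC);
  NumericVector dx;
  if (need_dx) {
    dx = NumericVector(x.size());
    dx.attr("dim") = xd;
  }
  arma::mat col(K, P);
  for (int n = 0; n < N; ++n) {
    arma::mat dYm(dy.begin() + P * OC * n, P, OC, false, true);
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C, k, stride, pad, col,
           Ho, Wo);
    dWm += col * dYm;
    if (has_bias) {
      arma::rowvec s = arma::sum(dYm, 0);
      for (int o = 0; o < OC; ++o) db[o] += s[o];
    }
    if (need_dx) {
      arma::mat dcol = Wm * dYm.t();
      col2im_add(dx.begin() + (size_t)H * W * C * n, H, W, C, k, stride,
                 pad, dcol, Ho, Wo);
    }
  }
  return List::create(_["dx"] = need_dx ? (SEXP)dx : R_NilValue,
                      _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export]]
NumericVector cpp_dw_fwd(NumericVector x, NumericVector w, int stride,
                         int pad) {
  IntegerVector xd = tensor_dim(x), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3], k = wd[0];
  if (wd[2] != C) stop("depthwise conv: channel mismatch");
  int Ho = out_size(H, k, stride, pad), Wo = out_size(W, k, stride, pad);
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      const double* wc = w.begin() + (size_t)k * k * c;
      double* yc = y.begin() + (size_t)Ho * Wo * (c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double acc = 0.0;
          for (int kj = 0; kj < k; ++kj) {
            int wi = wo * stride - pad + kj;
            if (wi < 0 || wi >= W) continue;
            for (int ki = 0; ki < k; ++ki) {
              int hi = ho * stride - pad + ki;
              if (hi >= 0 && hi < H)
                acc += xc[hi + (size_t)H * wi] * wc[ki + k * kj];
            }
          }
          yc[ho + (size_t)Ho * wo] = acc;
        }
    }
  return y;
}

// [[Rcpp::export]]
List cpp_dw_bwd(NumericVector x, NumericVector w, NumericVector dy,
                int stride, int pad) {
  IntegerVector xd = tensor_dim(x), wd = w.attr("dim"),
                yd = tensor_dim(dy);
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3], k = wd[0];
  int Ho = yd[0], Wo = yd[1];
  NumericVector dx(x.size());
  dx.attr("dim") = xd;
  NumericVector dw(w.size());
  dw.attr("dim") = wd;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      const double* wc = w.begin() + (size_t)k * k * c;
      double* dxc = dx.begin() + (size_t)H * W * (c + (size_t)C * n);
      double* dwc = dw.begin() + (size_t)k * k * c;
      const double* dyc = dy.begin() + (size_t)Ho * Wo * (c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double g = dyc[ho + (size_t)Ho * wo];
          if (g == 0.0) continue;
          for (int kj = 0; kj < k; ++kj) {
            int wi = wo * stride - pad + kj;
            if (wi < 0 || wi >= W) continue;
            for (int ki = 0; ki < k; ++ki) {
              int hi = ho * stride - pad + ki;
              if (hi >= 0 && hi < H) {
                dwc[ki + k * kj] += xc[hi + (size_t)H * wi] * g;
                dxc[hi + (size_t)H * wi] += wc[ki + k * kj] * g;
              }
            }
          }
        }
    }
  return List::create(_["dx"] = dx, _["dw"] = dw);
}

// [[Rcpp::export]]
List cpp_maxpool_fwd(NumericVector x, int k, int stride, int pad) {
  IntegerVector xd = tensor_dim(x);
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Ho = out_size(H, k, stride, pad), Wo = out_size(W, k, stride, pad);
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector idx(y.size());
  idx.attr("dim") = y.attr("dim");
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      size_t xoff = (size_t)H * W * (c + (size_t)C * n);
      const double* xc = x.begin() + xoff;
      size_t yoff = (size_t)Ho * Wo * (c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double best = -HUGE_VAL;
          int besti = -1;
          for (int kj = 0; kj < k; ++kj) {
            int wi = wo * stride - pad + kj;
            if (wi < 0 || wi >= W) continue;
            for (int ki = 0; ki < k; ++ki) {
              int hi = ho * stride - pad + ki;
              if (hi < 0 || hi >= H) continue;
              double v = xc[hi + (size_t)H * wi];
              if (v > best) { best = v; besti = hi + H * wi; }
            }
          }
          y[yoff + ho + (size_t)Ho * wo] = best;
          idx[yoff + ho + (size_t)Ho * wo] = (int)(xoff + besti);
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(NumericVector dy, IntegerVector idx,
                              IntegerVector xdim) {
  size_t n = (size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector dx(n);
  dx.attr("dim") = xdim;
  for (R_xlen_t i = 0; i < dy.size(); ++i) dx[idx[i]] += dy[i];
  return dx;
}

// [[Rcpp::export]]
NumericVector cpp_upsample2_fwd(NumericVector x) {
  IntegerVector xd = tensor_dim(x);
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  NumericVector y((size_t)4 * H * W * C * N);
  y.attr("dim") = IntegerVector::create(2 * H, 2 * W, C, N);
  for (int cn = 0; cn < C * N; ++cn) {
    const double* xc = x.begin() + (size_t)H * W * cn;
    double* yc = y.begin() + (size_t)4 * H * W * cn;
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h) {
        double v = xc[h + (size_t)H * w];
        size_t b = 2 * h + (size_t)2 * H * 2 * w;
        yc[b] = v;
        yc[b + 1] = v;
        yc[b + 2 * H] = v;
        yc[b + 2 * H + 1] = v;
      }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_upsample2_bwd(NumericVector dy) {
  IntegerVector yd = tensor_dim(dy);
  int H2 = yd[0], W2 = yd[1], C = yd[2], N = yd[3];
  int H = H2 / 2, W = W2 / 2;
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (int cn = 0; cn < C * N; ++cn) {
    const double* dyc = dy.begin() + (size_t)H2 * W2 * cn;
    double* dxc = dx.begin() + (size_t)H * W * cn;
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h) {
        size_t b = 2 * h + (size_t)H2 * 2 * w;
        dxc[h + (size_t)H * w] =
            dyc[b] + dyc[b + 1] + dyc[b + H2] + dyc[b + H2 + 1];
      }
  }
  return dx;
}

// [[Rcpp::export]]
List cpp_bn_fwd(NumericVector x, NumericVector gamma, NumericVector beta,
                NumericVector rmean, NumericVector rvar, bool training,
                double momentum, double eps) {
  IntegerVector xd = tensor_dim(x);
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  size_t plane = (size_t)H * W, per = plane * (size_t)N;
  NumericVector y(x.size());
  y.attr("dim") = xd;
  NumericVector mean(C), invstd(C), nrm(C), nrv(C);
  for (int c = 0; c < C; ++c) {
    double mu, var;
    if (training) {
      double s = 0.0, s2 = 0.0;
      for (int n = 0; n < N; ++n) {
        const double* xc = x.begin() + plane * (c + (size_t)C * n);
        for (size_t i = 0; i < plane; ++i) { s += xc[i]; s2 += xc[i] * xc[i]; }
      }
      mu = s / per;
      var = s2 / per - mu * mu;
      if (var < 0) var = 0;
      nrm[c] = (1 - momentum) * rmean[c] + momentum * mu;
      nrv[c] = (1 - momentum) * rvar[c] + momentum * var;
    } else {
      mu = rmean[c];
      var = rvar[c];
      nrm[c] = rmean[c];
      nrv[c] = rvar[c];
    }
    mean[c] = mu;
    invstd[c] = 1.0 / std::sqrt(var + eps);
    double a = gamma[c] * invstd[c], b = beta[c] - a * mu;
    for (int n = 0; n < N; ++n) {
      const double* xc = x.begin() + plane * (c + (size_t)C * n);
      double* yc = y.begin() + plane * (c + (size_t)C * n);
      for (size_t i = 0; i < plane; ++i) yc[i] = a * xc[i] + b;
    }
  }
  return List::create(_["y"] = y, _["mean"] = mean, _["invstd"] = invstd,
                      _["rmean"] = nrm, _["rvar"] = nrv);
}

// [[Rcpp::export]]
List cpp_bn_bwd(NumericVector x, NumericVector dy, NumericVector gamma,
                NumericVector mean, NumericVector invstd) {
  IntegerVector xd = tensor_dim(x);
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  size_t plane = (size_t)H * W;
  double per = plane * (double)N;
  NumericVector dx(x.size());
  dx.attr("dim") = xd;
  NumericVector dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    double sdy = 0.0, sdyx = 0.0;
    for (int n = 0; n < N; ++n) {
      const double* xc = x.begin() + plane * (c + (size_t)C * n);
      const double* dyc = dy.begin() + plane * (c + (size_t)C * n);
      for (size_t i = 0; i < plane; ++i) {
        sdy += dyc[i];
        sdyx += dyc[i] * (xc[i] - mean[c]) * invstd[c];
      }
    }
    dgamma[c] = sdyx;
    dbeta[c] = sdy;
    double a = gamma[c] * invstd[c];
    for (int n = 0; n < N; ++n) {
      const double* xc = x.begin() + plane * (c + (size_t)C * n);
      const double* dyc = dy.begin() + plane * (c + (size_t)C * n);
      double* dxc = dx.begin() + plane * (c + (size_t)C * n);
      for (size_t i = 0; i < plane; ++i) {
        double xhat = (xc[i] - mean[c]) * invstd[c];
        dxc[i] = a * (dyc[i] - sdy / per - xhat * sdyx / per);
      }
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}
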