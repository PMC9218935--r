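// Batched CPU kernels for the network runtime.
// Feature maps are column-major R arrays laid out (H, W, C, N);
// convolution weights are (K, K, Cin, Cout); depthwise weights (d, d, C).
// Stride-1 convolutions use "same" zero padding (odd K); transposed
// convolutions are handled in R as a pure GEMM because stride == kernel.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;


static NumericVector alloc4(int a, int b, int c, int d) {
  NumericVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

static IntegerVector alloc4i(int a, int b, int c, int d) {
  IntegerVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

static void get_dims4(const NumericVector& x, int& H, int& W, int& C, int& N) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d (H,W,C,N) array");
  H = d[0]; W = d[1]; C = d[2]; N = d[3];
}

// X: (H*W) x (K*K*C), column q = ki + K*kj + K*K*c, row p = i + H*j
static void im2col(const double* xn, int H, int W, int C, int K, int pad,
                   arma::mat& X) {
  for (int c = 0; c < C; ++c) {
    const double* xc = xn + (size_t)H * W * c;
    for (int kj = 0; kj < K; ++kj) {
      for (int ki = 0; ki < K; ++ki) {
        double* col = X.colptr((size_t)ki + K * kj + (size_t)K * K * c);
        int lo = std::max(0, pad - ki);
        int hi = std::min(H, H + pad - ki);
        for (int j = 0; j < W; ++j) {
          int sj = j + kj - pad;
          double* dst = col + (size_t)H * j;
          if (sj < 0 || sj >= W) { std::fill(dst, dst + H, 0.0); continue; }
          const double* src = xc + (size_t)H * sj;
          for (int i = 0; i < lo; ++i) dst[i] = 0.0;
          if (hi > lo)
            std::memcpy(dst + lo, src + lo + ki - pad, (size_t)(hi - lo) * sizeof(double));
          for (int i = hi; i < H; ++i) dst[i] = 0.0;
        }
      }
    }
  }
}

// scatter-add the column layout back into an image gradient
static void col2im_add(const arma::mat& X, int H, int W, int C, int K, int pad,
                       double* xn) {
  for (int c = 0; c < C; ++c) {
    double* xc = xn + (size_t)H * W * c;
    for (int kj = 0; kj < K; ++kj) {
      for (int ki = 0; ki < K; ++ki) {
        const double* col = X.colptr((size_t)ki + K * kj + (size_t)K * K * c);
        int lo = std::max(0, pad - ki);
        int hi = std::min(H, H + pad - ki);
        for (int j = 0; j < W; ++j) {
          int sj = j + kj - pad;
          if (sj < 0 || sj >= W) continue;
          const double* src = col + (size_t)H * j;
          double* dst = xc + (size_t)H * sj + (ki - pad);
          for (int i = lo; i < hi; ++i) dst[i] += src[i];
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector w,
                             Nullable<NumericVector> bias) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  IntegerVector wd = w.attr("dim");
  if (wd.size() != 4 || wd[2] != C) stop("weight/input channel mismatch");
  int K = wd[0], Cout = wd[3];
  if (K % 2 == 0) stop("stride-1 convolution requires odd kernel");
  int pad = (K - 1) / 2;
  NumericVector y = alloc4(H, W, Cout, N);
  arma::mat Wm(const_cast<double*>(w.begin()), (size_t)K * K * C, Cout, false, true);
  arma::mat X((size_t)H * W, (size_t)K * K * C);
  bool has_b = bias.isNotNull();
  NumericVector b;
  if (has_b) b = bias.get();
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C, K, pad, X);
    arma::mat Y(y.begin() + (size_t)H * W * Cout * n, (size_t)H * W, Cout, false, true);
    Y = X * Wm;
    if (has_b) Y.each_row() += arma::rowvec(b.begin(), Cout, false);
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, NumericVector w, NumericVector dy) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  IntegerVector wd = w.attr("dim");
  int K = wd[0], Cout = wd[3];
  int pad = (K - 1) / 2;
  NumericVector dx = alloc4(H, W, C, N);
  NumericVector dw = alloc4(K, K, C, Cout);
  NumericVector db(Cout);
  arma::mat Wm(const_cast<double*>(w.begin()), (size_t)K * K * C, Cout, false, true);
  arma::mat dWm(dw.begin(), (size_t)K * K * C, Cout, false, true);
  arma::rowvec dbv(db.begin(), Cout, false, true);
  arma::mat X((size_t)H * W, (size_t)K * K * C);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C, K, pad, X);
    arma::mat dY(const_cast<double*>(dy.begin()) + (size_t)H * W * Cout * n,
                 (size_t)H * W, Cout, false, true);
    dWm += X.t() * dY;
    dbv += arma::sum(dY, 0);
    arma::mat dX = dY * Wm.t();
    col2im_add(dX, H, W, C, K, pad, dx.begin() + (size_t)H * W * C * n);
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export]]
NumericVector cpp_dwconv_fwd(NumericVector x, NumericVector w,
                             Nullable<NumericVector> bias) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  IntegerVector wd = w.attr("dim");
  if (wd.size() != 3 || wd[2] != C) stop("depthwise weight/channel mismatch");
  int K = wd[0];
  if (K % 2 == 0) stop("depthwise convolution requires odd kernel");
  int pad = (K - 1) / 2;
  NumericVector y = alloc4(H, W, C, N);
  bool has_b = bias.isNotNull();
  NumericVector b;
  if (has_b) b = bias.get();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      double* yc = y.begin() + (size_t)H * W * (c + (size_t)C * n);
      if (has_b) std::fill(yc, yc + (size_t)H * W, b[c]);
      for (int kj = 0; kj < K; ++kj) {
        for (int ki = 0; ki < K; ++ki) {
          double wv = w[(size_t)ki + K * kj + (size_t)K * K * c];
          int lo = std::max(0, pad - ki);
          int hi = std::min(H, H + pad - ki);
          for (int j = 0; j < W; ++j) {
            int sj = j + kj - pad;
            if (sj < 0 || sj >= W) continue;
            const double* src = xc + (size_t)H * sj + (ki - pad);
            double* dst = yc + (size_t)H * j;
            for (int i = lo; i < hi; ++i) dst[i] += wv * src[i];
          }
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_dwconv_bwd(NumericVector x, NumericVector w, NumericVector dy) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  IntegerVector wd = w.attr("dim");
  int K = wd[0];
  int pad = (K - 1) / 2;
  NumericVector dx = alloc4(H, W, C, N);
  NumericVector dw(Dimension(K, K, C));
  NumericVector db(C);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      const double* dyc = dy.begin() + (size_t)H * W * (c + (size_t)C * n);
      double* dxc = dx.begin() + (size_t)H * W * (c + (size_t)C * n);
      double acc_b = 0.0;
      for (size_t p = 0; p < (size_t)H * W; ++p) acc_b += dyc[p];
      db[c] += acc_b;
      for (int kj = 0; kj < K; ++kj) {
        for (int ki = 0; ki < K; ++ki) {
          double wv = w[(size_t)ki + K * kj + (size_t)K * K * c];
          double acc_w = 0.0;
          int lo = std::max(0, pad - ki);
          int hi = std::min(H, H + pad - ki);
          for (int j = 0; j < W; ++j) {
            int sj = j + kj - pad;
            if (sj < 0 || sj >= W) continue;
            const double* src = xc + (size_t)H * sj + (ki - pad);
            double* dsrc = dxc + (size_t)H * sj + (ki - pad);
            const double* g = dyc + (size_t)H * j;
            for (int i = lo; i < hi; ++i) {
              acc_w += src[i] * g[i];
              dsrc[i] += wv * g[i];
            }
          }
          dw[(size_t)ki + K * kj + (size_t)K * K * c] += acc_w;
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export]]
List cpp_maxpool_fwd(NumericVector x, int f) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  if (H % f != 0 || W % f != 0) stop("spatial size not divisible by pooling factor");
  int Ho = H / f, Wo = W / f;
  NumericVector y = alloc4(Ho, Wo, C, N);
  IntegerVector idx = alloc4i(Ho, Wo, C, N); // 0-based linear index in source plane
  size_t q = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      for (int jo = 0; jo < Wo; ++jo) {
        for (int io = 0; io < Ho; ++io) {
          double best = -std::numeric_limits<double>::infinity();
          int besti = 0;
          for (int dj = 0; dj < f; ++dj) {
            for (int di = 0; di < f; ++di) {
              int i = io * f + di, j = jo * f + dj;
              double v = xc[(size_t)i + (size_t)H * j];
              if (v > best) { best = v; besti = i + H * j; }
            }
          }
          // column-major over (io, jo): io fastest, matches q ordering below
          y[q + (size_t)io + (size_t)Ho * jo] = best;
          idx[q + (size_t)io + (size_t)Ho * jo] = besti;
        }
      }
      q += (size_t)Ho * Wo;
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(NumericVector dy, IntegerVector idx, int H, int W) {
  IntegerVector d = dy.attr("dim");
  int Ho = d[0], Wo = d[1], C = d[2], N = d[3];
  NumericVector dx = alloc4(H, W, C, N);
  size_t planes = (size_t)C * N;
  for (size_t p = 0; p < planes; ++p) {
    const double* g = dy.begin() + (size_t)Ho * Wo * p;
    const int* id = idx.begin() + (size_t)Ho * Wo * p;
    double* out = dx.begin() + (size_t)H * W * p;
    for (size_t q = 0; q < (size_t)Ho * Wo; ++q) out[id[q]] += g[q];
  }
  return dx;
}

// half-pixel-centre bilinear interpolation by an integer factor
static void bilinear_index(int Ho, int H, int f, std::vector<int>& i0,
                           std::vector<int>& i1, std::vector<double>& w1) {
  i0.resize(Ho); i1.resize(Ho); w1.resize(Ho);
  for (int d = 0; d < Ho; ++d) {
    double s = (d + 0.5) / f - 0.5;
    if (s < 0) s = 0;
    if (s > H - 1) s = H - 1;
    int lo = (int)std::floor(s);
    int hi = std::min(lo + 1, H - 1);
    i0[d] = lo; i1[d] = hi; w1[d] = s - lo;
  }
}

// [[Rcpp::export]]
NumericVector cpp_bilinear_fwd(NumericVector x, int f) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  int Ho = H * f, Wo = W * f;
  NumericVector y = alloc4(Ho, Wo, C, N);
  std::vector<int> i0, i1, j0, j1;
  std::vector<double> wi, wj;
  bilinear_index(Ho, H, f, i0, i1, wi);
  bilinear_index(Wo, W, f, j0, j1, wj);
  size_t planes = (size_t)C * N;
  for (size_t p = 0; p < planes; ++p) {
    const double* xc = x.begin() + (size_t)H * W * p;
    double* yc = y.begin() + (size_t)Ho * Wo * p;
    for (int j = 0; j < Wo; ++j) {
      const double* cl = xc + (size_t)H * j0[j];
      const double* ch = xc + (size_t)H * j1[j];
      double b = wj[j];
      double* dst = yc + (size_t)Ho * j;
      for (int i = 0; i < Ho; ++i) {
        double a = wi[i];
        double top = (1 - a) * cl[i0[i]] + a * cl[i1[i]];
        double bot = (1 - a) * ch[i0[i]] + a * ch[i1[i]];
        dst[i] = (1 - b) * top + b * bot;
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_bilinear_bwd(NumericVector dy, int f) {
  IntegerVector d = dy.attr("dim");
  int Ho = d[0], Wo = d[1], C = d[2], N = d[3];
  if (Ho % f != 0 || Wo % f != 0) stop("gradient size not divisible by factor");
  int H = Ho / f, W = Wo / f;
  NumericVector dx = alloc4(H, W, C, N);
  std::vector<int> i0, i1, j0, j1;
  std::vector<double> wi, wj;
  bilinear_index(Ho, H, f, i0, i1, wi);
  bilinear_index(Wo, W, f, j0, j1, wj);
  size_t planes = (size_t)C * N;
  for (size_t p = 0; p < planes; ++p) {
    const double* g = dy.begin() + (size_t)Ho * Wo * p;
    double* out = dx.begin() + (size_t)H * W * p;
    for (int j = 0; j < Wo; ++j) {
      double b = wj[j];
      double* cl = out + (size_t)H * j0[j];
      double* ch = out + (size_t)H * j1[j];
      const double* src = g + (size_t)Ho * j;
      for (int i = 0; i < Ho; ++i) {
        double a = wi[i];
        double v = src[i];
        cl[i0[i]] += (1 - b) * (1 - a) * v;
        cl[i1[i]] += (1 - b) * a * v;
        ch[i0[i]] += b * (1 - a) * v;
        ch[i1[i]] += b * a * v;
      }
    }
  }
  return dx;
}

// ---- batchnorm (per-channel over H, W, N) and activations ----

// [[Rcpp::export]]
List cpp_bn_train_fwd(NumericVector x, NumericVector gamma, NumericVector beta) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  size_t plane = (size_t)H * W;
  double m = (double)plane * N;
  NumericVector mu(C), inv_sd(C);
  for (int c = 0; c < C; ++c) {
    double s = 0, s2 = 0;
    for (int n = 0; n < N; ++n) {
      const double* xc = x.begin() + plane * (c + (size_t)C * n);
      for (size_t p = 0; p < plane; ++p) { s += xc[p]; s2 += xc[p] * xc[p]; }
    }
    double mean = s / m;
    double var = s2 / m - mean * mean;
    if (var < 0) var = 0;
    mu[c] = mean;
    inv_sd[c] = 1.0 / std::sqrt(var + 1e-5);
  }
  NumericVector y = alloc4(H, W, C, N);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + plane * (c + (size_t)C * n);
      double* yc = y.begin() + plane * (c + (size_t)C * n);
      double a = gamma[c] * inv_sd[c];
      double b = beta[c] - a * mu[c];
      for (size_t p = 0; p < plane; ++p) yc[p] = a * xc[p] + b;
    }
  }
  return List::create(_["y"] = y, _["mu"] = mu, _["inv_sd"] = inv_sd);
}

// [[Rcpp::export]]
NumericVector cpp_bn_eval_fwd(NumericVector x, NumericVector gamma,
                              NumericVector beta, NumericVector rm,
                              NumericVector rv) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  size_t plane = (size_t)H * W;
  NumericVector y = alloc4(H, W, C, N);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + plane * (c + (size_t)C * n);
      double* yc = y.begin() + plane * (c + (size_t)C * n);
      double a = gamma[c] / std::sqrt(rv[c] + 1e-5);
      double b = beta[c] - a * rm[c];
      for (size_t p = 0; p < plane; ++p) yc[p] = a * xc[p] + b;
    }
  }
  return y;
}

// train-mode backward: mu/inv_sd from the forward batch statistics
// [[Rcpp::export]]
List cpp_bn_bwd(NumericVector x, NumericVector dy, NumericVector gamma,
                NumericVector mu, NumericVector inv_sd) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  size_t plane = (size_t)H * W;
  double m = (double)plane * N;
  NumericVector dx = alloc4(H, W, C, N);
  NumericVector dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    double s1 = 0, s2 = 0, sb = 0;
    for (int n = 0; n < N; ++n) {
      const double* xc = x.begin() + plane * (c + (size_t)C * n);
      const double* gc = dy.begin() + plane * (c + (size_t)C * n);
      for (size_t p = 0; p < plane; ++p) {
        double xh = (xc[p] - mu[c]) * inv_sd[c];
        sb += gc[p];
        s1 += gc[p];          // sum dxhat / gamma
        s2 += gc[p] * xh;     // sum dxhat*xhat / gamma
      }
    }
    dbeta[c] = sb;
    dgamma[c] = s2;
    double a = gamma[c] * inv_sd[c];
    double c1 = s1 / m, c2 = s2 / m;
    for (int n = 0; n < N; ++n) {
      const double* xc = x.begin() + plane * (c + (size_t)C * n);
      const double* gc = dy.begin() + plane * (c + (size_t)C * n);
      double* oc = dx.begin() + plane * (c + (size_t)C * n);
      for (size_t p = 0; p < plane; ++p) {
        double xh = (xc[p] - mu[c]) * inv_sd[c];
        oc[p] = a * (gc[p] - c1 - xh * c2);
      }
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// [[Rcpp::export]]
NumericVector cpp_relu(NumericVector x) {
  R_xlen_t n = x.size();
  NumericVector y(n);
  y.attr("dim") = x.attr("dim");
  const double* in = x.begin(); double* out = y.begin();
  for (R_xlen_t i = 0; i < n; ++i) out[i] = in[i] > 0 ? in[i] : 0;
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_relu_bwd(NumericVector dy, NumericVector y) {
  R_xlen_t n = dy.size();
  NumericVector dx(n);
  dx.attr("dim") = dy.attr("dim");
  const double* g = dy.begin(); const double* yv = y.begin();
  double* out = dx.begin();
  for (R_xlen_t i = 0; i < n; ++i) out[i] = yv[i] > 0 ? g[i] : 0;
  return dx;
}

// concatenate along the channel axis
// [[Rcpp::export]]
NumericVector cpp_concat_channels(List xs) {
  int H = 0, W = 0, N = 0, Ctot = 0;
  std::vector<int> cs(xs.size());
  for (int k = 0; k < xs.size(); ++k) {
    NumericVector xk = xs[k];
    int h, w, c, n; get_dims4(xk, h, w, c, n);
    if (k == 0) { H = h; W = w; N = n; }
    cs[k] = c; Ctot += c;
  }
  NumericVector y = alloc4(H, W, Ctot, N);
  size_t plane = (size_t)H * W;
  for (int n = 0; n < N; ++n) {
    int at = 0;
    for (int k = 0; k < xs.size(); ++k) {
      NumericVector xk = xs[k];
      std::memcpy(y.begin() + plane * (at + (size_t)Ctot * n),
                  xk.begin() + plane * ((size_t)cs[k] * n),
                  plane * cs[k] * sizeof(double));
      at += cs[k];
    }
  }
  return y;
}

// slice a channel range [from, from+count) (0-based from)
// [[Rcpp::export]]
NumericVector cpp_channel_slice(NumericVector x, int from, int count) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  NumericVector y = alloc4(H, W, count, N);
  size_t plane = (size_t)H * W;
  for (int n = 0; n < N; ++n)
    std::memcpy(y.begin() + plane * ((size_t)count * n),
                x.begin() + plane * (from + (size_t)C * n),
                plane * count * sizeof(double));
  return y;
}
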