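// Low-level neural-network primitives on (H, W, N, C) arrays.
// Convolutions use im2col + BLAS gemm via Armadillo; pooling, batch
// normalization and the rectifier are single-pass pointer loops. Backward
// passes are exact (finite-difference checked in the test suite).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline void get_dims4(const NumericVector &x, int d[4]) {
  IntegerVector dm = x.attr("dim");
  if (dm.size() != 4) stop("expected a 4-d array (H, W, N, C)");
  for (int i = 0; i < 4; ++i) d[i] = dm[i];
}

// Build the im2col matrix: rows index (oh, ow, n), columns index
// (kernel offset o = ki + KH*kj, input channel c) as col = o*Cin + c.
static arma::mat im2col(const double *x, int H, int W, int N, int Cin,
                        int KH, int KW, int stride, int pad, int OH, int OW) {
  arma::mat xcol(static_cast<arma::uword>(OH) * OW * N,
                 static_cast<arma::uword>(KH) * KW * Cin,
                 arma::fill::none);
  if (pad > 0) xcol.zeros();
  const long HW = static_cast<long>(H) * W;
  for (int c = 0; c < Cin; ++c) {
    for (int kj = 0; kj < KW; ++kj) {
      for (int ki = 0; ki < KH; ++ki) {
        const arma::uword col = static_cast<arma::uword>(ki + KH * kj) * Cin + c;
        double *dst = xcol.colptr(col);
        for (int n = 0; n < N; ++n) {
          const double *xb = x + (static_cast<long>(n) + static_cast<long>(N) * c) * HW;
          for (int ow = 0; ow < OW; ++ow) {
            const int w = ow * stride + kj - pad;
            double *drow = dst + static_cast<long>(OH) * (ow + static_cast<long>(OW) * n);
            if (w < 0 || w >= W) {
              if (pad == 0) for (int oh = 0; oh < OH; ++oh) drow[oh] = 0.0;
              continue;
            }
            const double *xcolp = xb + static_cast<long>(H) * w;
            int oh0 = 0, oh1 = OH;
            while (oh0 < OH && oh0 * stride + ki - pad < 0) ++oh0;
            while (oh1 > oh0 && (oh1 - 1) * stride + ki - pad >= H) --oh1;
            if (pad == 0) { for (int oh = 0; oh < oh0; ++oh) drow[oh] = 0.0;
                            for (int oh = oh1; oh < OH; ++oh) drow[oh] = 0.0; }
            for (int oh = oh0; oh < oh1; ++oh)
              drow[oh] = xcolp[oh * stride + ki - pad];
          }
        }
      }
    }
  }
  return xcol;
}

static arma::mat weight_mat(const NumericVector &w, int KH, int KW, int Cin, int Cout) {
  arma::mat wm(static_cast<arma::uword>(KH) * KW * Cin, Cout);
  const double *wp = w.begin();
  for (int oc = 0; oc < Cout; ++oc)
    for (int c = 0; c < Cin; ++c)
      for (int kj = 0; kj < KW; ++kj)
        for (int ki = 0; ki < KH; ++ki)
          wm(static_cast<arma::uword>(ki + KH * kj) * Cin + c, oc) =
            wp[ki + KH * (kj + KW * (static_cast<long>(c) + Cin * oc))];
  return wm;
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_forward(NumericVector x, NumericVector w,
                                 NumericVector b, int stride, int pad) {
  int dx[4], dw[4];
  get_dims4(x, dx); get_dims4(w, dw);
  const int H = dx[0], W = dx[1], N = dx[2], Cin = dx[3];
  const int KH = dw[0], KW = dw[1], Cout = dw[3];
  if (dw[2] != Cin) stop("weight input channels (%d) do not match input (%d)", dw[2], Cin);
  const int OH = (H + 2 * pad - KH) / stride + 1;
  const int OW = (W + 2 * pad - KW) / stride + 1;
  if (OH < 1 || OW < 1) stop("kernel larger than padded input");
  arma::mat xcol = im2col(x.begin(), H, W, N, Cin, KH, KW, stride, pad, OH, OW);
  arma::mat wm = weight_mat(w, KH, KW, Cin, Cout);
  const arma::uword rows = static_cast<arma::uword>(OH) * OW * N;
  NumericVector out(no_init(static_cast<R_xlen_t>(rows) * Cout));
  arma::mat ym(out.begin(), rows, Cout, false, true);
  ym = xcol * wm;
  ym.each_row() += arma::rowvec(b.begin(), Cout);
  out.attr("dim") = IntegerVector::create(OH, OW, N, Cout);
  return out;
}

// [[Rcpp::export]]
List cpp_conv2d_backward(NumericVector x, NumericVector w, NumericVector gy,
                         int stride, int pad, bool need_gx) {
  int dx[4], dw[4], dg[4];
  get_dims4(x, dx); get_dims4(w, dw); get_dims4(gy, dg);
  const int H = dx[0], W = dx[1], N = dx[2], Cin = dx[3];
  const int KH = dw[0], KW = dw[1], Cout = dw[3];
  const int OH = dg[0], OW = dg[1];
  const arma::uword rows = static_cast<arma::uword>(OH) * OW * N;
  arma::mat gym(gy.begin(), rows, Cout, false);
  arma::mat xcol = im2col(x.begin(), H, W, N, Cin, KH, KW, stride, pad, OH, OW);

  arma::rowvec gbv = arma::sum(gym, 0);
  NumericVector gb(gbv.begin(), gbv.end());

  arma::mat gwm = xcol.t() * gym;
  NumericVector gw(no_init(w.size()));
  gw.attr("dim") = w.attr("dim");
  for (int oc = 0; oc < Cout; ++oc)
    for (int c = 0; c < Cin; ++c)
      for (int kj = 0; kj < KW; ++kj)
        for (int ki = 0; ki < KH; ++ki)
          gw[ki + KH * (kj + KW * (static_cast<long>(c) + Cin * oc))] =
            gwm(static_cast<arma::uword>(ki + KH * kj) * Cin + c, oc);

  if (!need_gx) {
    return List::create(_["gx"] = R_NilValue, _["gw"] = gw, _["gb"] = gb);
  }
  arma::mat wm = weight_mat(w, KH, KW, Cin, Cout);
  arma::mat gxcol = gym * wm.t();
  NumericVector gx(x.size());
  gx.attr("dim") = x.attr("dim");
  double *gxp = gx.begin();
  const long HW = static_cast<long>(H) * W;
  for (int c = 0; c < Cin; ++c) {
    for (int kj = 0; kj < KW; ++kj) {
      for (int ki = 0; ki < KH; ++ki) {
        const arma::uword col = static_cast<arma::uword>(ki + KH * kj) * Cin + c;
        const double *src = gxcol.colptr(col);
        for (int n = 0; n < N; ++n) {
          double *gxb = gxp + (static_cast<long>(n) + static_cast<long>(N) * c) * HW;
          for (int ow = 0; ow < OW; ++ow) {
            const int wpos = ow * stride + kj - pad;
            if (wpos < 0 || wpos >= W) continue;
            const double *srow = src + static_cast<long>(OH) * (ow + static_cast<long>(OW) * n);
            double *gcolp = gxb + static_cast<long>(H) * wpos;
            int oh0 = 0, oh1 = OH;
            while (oh0 < OH && oh0 * stride + ki - pad < 0) ++oh0;
            while (oh1 > oh0 && (oh1 - 1) * stride + ki - pad >= H) --oh1;
            for (int oh = oh0; oh < oh1; ++oh)
              gcolp[oh * stride + ki - pad] += srow[oh];
          }
        }
      }
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export]]
List cpp_maxpool_forward(NumericVector x, int k, int stride, int pad) {
  int dx[4];
  get_dims4(x, dx);
  const int H = dx[0], W = dx[1], N = dx[2], C = dx[3];
  const int OH = (H + 2 * pad - k) / stride + 1;
  const int OW = (W + 2 * pad - k) / stride + 1;
  if (OH < 1 || OW < 1) stop("pool window larger than padded input");
  const R_xlen_t ylen = static_cast<R_xlen_t>(OH) * OW * N * C;
  NumericVector y(no_init(ylen));
  IntegerVector amax(no_init(ylen));
  y.attr("dim") = IntegerVector::create(OH, OW, N, C);
  const double *xp = x.begin();
  double *yp = y.begin();
  int *ap = amax.begin();
  const long HW = static_cast<long>(H) * W;
  long yi = 0;
  for (int c = 0; c < C; ++c) {
    for (int n = 0; n < N; ++n) {
      const long base = (static_cast<long>(n) + static_cast<long>(N) * c) * HW;
      // y index for (oh, ow, n, c): oh + OH*(ow + OW*(n + N*c)); iterate so
      // writes are contiguous: ow outer, oh inner.
      double *yb = yp + static_cast<long>(OH) * OW * (n + static_cast<long>(N) * c);
      int *ab = ap + static_cast<long>(OH) * OW * (n + static_cast<long>(N) * c);
      for (int ow = 0; ow < OW; ++ow) {
        const int w0 = std::max(0, ow * stride - pad);
        const int w1 = std::min(W, ow * stride - pad + k);
        for (int oh = 0; oh < OH; ++oh) {
          const int h0 = std::max(0, oh * stride - pad);
          const int h1 = std::min(H, oh * stride - pad + k);
          double best = R_NegInf;
          long besti = -1;
          for (int w = w0; w < w1; ++w) {
            const double *colp = xp + base + static_cast<long>(H) * w;
            for (int h = h0; h < h1; ++h) {
              if (colp[h] > best) { best = colp[h]; besti = base + h + static_cast<long>(H) * w; }
            }
          }
          yb[oh + static_cast<long>(OH) * ow] = best;
          ab[oh + static_cast<long>(OH) * ow] = static_cast<int>(besti);
          ++yi;
        }
      }
    }
  }
  return List::create(_["out"] = y, _["amax"] = amax);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_backward(NumericVector gy, IntegerVector amax,
                                   IntegerVector xdim) {
  R_xlen_t n = 1;
  for (int i = 0; i < xdim.size(); ++i) n *= xdim[i];
  NumericVector gx(n);
  gx.attr("dim") = xdim;
  double *gp = gx.begin();
  const double *gyp = gy.begin();
  const int *ap = amax.begin();
  for (R_xlen_t i = 0; i < gy.size(); ++i) gp[ap[i]] += gyp[i];
  return gx;
}

// Batch normalization over (H, W, N) per channel. Returns the normalized
// output, the cached xhat and invstd, and (in training mode) the updated
// running statistics.
// [[Rcpp::export]]
List cpp_bn_forward(NumericVector x, NumericVector gamma, NumericVector beta,
                    NumericVector rm, NumericVector rv, bool training,
                    double momentum, double eps) {
  int dx[4];
  get_dims4(x, dx);
  const long n = static_cast<long>(dx[0]) * dx[1] * dx[2];
  const int C = dx[3];
  NumericVector out(no_init(x.size())), xhat(no_init(x.size()));
  out.attr("dim") = x.attr("dim");
  NumericVector invstd(C), nrm(C), nrv(C);
  const double *xp = x.begin();
  double *op = out.begin(), *hp = xhat.begin();
  for (int c = 0; c < C; ++c) {
    const double *xc = xp + n * static_cast<long>(c);
    double mu, var;
    if (training) {
      double s = 0, s2 = 0;
      for (long i = 0; i < n; ++i) { s += xc[i]; s2 += xc[i] * xc[i]; }
      mu = s / n;
      var = s2 / n - mu * mu;
      if (var < 0) var = 0;
      nrm[c] = (1 - momentum) * rm[c] + momentum * mu;
      nrv[c] = (1 - momentum) * rv[c] + momentum * var;
    } else {
      mu = rm[c]; var = rv[c];
      nrm[c] = rm[c]; nrv[c] = rv[c];
    }
    const double is = 1.0 / std::sqrt(var + eps);
    invstd[c] = is;
    const double g = gamma[c], bt = beta[c];
    double *oc = op + n * static_cast<long>(c);
    double *hc = hp + n * static_cast<long>(c);
    for (long i = 0; i < n; ++i) {
      const double h = (xc[i] - mu) * is;
      hc[i] = h;
      oc[i] = h * g + bt;
    }
  }
  return List::create(_["out"] = out, _["xhat"] = xhat, _["invstd"] = invstd,
                      _["rm"] = nrm, _["rv"] = nrv);
}

// [[Rcpp::export]]
List cpp_bn_backward(NumericVector g, NumericVector xhat, NumericVector invstd,
                     NumericVector gamma, IntegerVector dims, bool training) {
  const long n = static_cast<long>(dims[0]) * dims[1] * dims[2];
  const int C = dims[3];
  NumericVector gx(no_init(g.size())), ggamma(C), gbeta(C);
  gx.attr("dim") = dims;
  const double *gp = g.begin(), *hp = xhat.begin();
  double *xp = gx.begin();
  for (int c = 0; c < C; ++c) {
    const double *gc = gp + n * static_cast<long>(c);
    const double *hc = hp + n * static_cast<long>(c);
    double s1 = 0, s2 = 0;
    for (long i = 0; i < n; ++i) { s1 += gc[i]; s2 += gc[i] * hc[i]; }
    gbeta[c] = s1;
    ggamma[c] = s2;
    double *xc = xp + n * static_cast<long>(c);
    if (training) {
      const double k = gamma[c] * invstd[c] / n;
      for (long i = 0; i < n; ++i)
        xc[i] = k * (n * gc[i] - s1 - hc[i] * s2);
    } else {
      const double k = gamma[c] * invstd[c];
      for (long i = 0; i < n; ++i) xc[i] = k * gc[i];
    }
  }
  return List::create(_["gx"] = gx, _["ggamma"] = ggamma, _["gbeta"] = gbeta);
}

// [[Rcpp::export]]
NumericVector cpp_relu_forward(NumericVector x) {
  NumericVector out(no_init(x.size()));
  out.attr("dim") = x.attr("dim");
  const double *xp = x.begin();
  double *op = out.begin();
  for (R_xlen_t i = 0; i < x.size(); ++i) op[i] = xp[i] > 0 ? xp[i] : 0.0;
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_relu_backward(NumericVector g, NumericVector out) {
  NumericVector gx(no_init(g.size()));
  gx.attr("dim") = g.attr("dim");
  const double *gp = g.begin(), *op = out.begin();
  double *xp = gx.begin();
  for (R_xlen_t i = 0; i < g.size(); ++i) xp[i] = op[i] > 0 ? gp[i] : 0.0;
  return gx;
}
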