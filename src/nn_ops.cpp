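#include <Rcpp.h>
using namespace Rcpp;

// Tensor layout (column-major, matching R arrays): dim = (D, H, W, C, B),
// flat index = d + D*(h + H*(w + W*(c + C*b))).
// Convolutions are "valid" with stride 1 and cubic kernels of edge K.

// [[Rcpp::export]]
NumericVector conv3d_fwd_cpp(NumericVector x, IntegerVector xdim,
                             NumericVector w, IntegerVector wdim,
                             NumericVector bias) {
  const int D = xdim[0], H = xdim[1], W = xdim[2], Ci = xdim[3], B = xdim[4];
  const int K = wdim[0], Co = wdim[4];
  const int Do = D - K + 1, Ho = H - K + 1, Wo = W - K + 1;
  if (Do < 1 || Ho < 1 || Wo < 1)
    stop("conv3d: kernel larger than input (%d,%d,%d)", D, H, W);
  NumericVector y(static_cast<R_xlen_t>(Do) * Ho * Wo * Co * B);
  const double *xp = x.begin(), *wp = w.begin();
  double *yp = y.begin();

  for (int b = 0; b < B; ++b) {
    for (int co = 0; co < Co; ++co) {
      // bias fill
      double bv = bias[co];
      double *ybase = yp + (R_xlen_t)Do * Ho * Wo * (co + (R_xlen_t)Co * b);
      for (R_xlen_t i = 0; i < (R_xlen_t)Do * Ho * Wo; ++i) ybase[i] = bv;
      for (int ci = 0; ci < Ci; ++ci) {
        const double *xc = xp + (R_xlen_t)D * H * W * (ci + (R_xlen_t)Ci * b);
        for (int kw = 0; kw < K; ++kw)
          for (int kh = 0; kh < K; ++kh)
            for (int kd = 0; kd < K; ++kd) {
              double wv = wp[kd + K * (kh + K * (kw + K * (ci + Ci * co)))];
              if (wv == 0.0) continue;
              for (int wo = 0; wo < Wo; ++wo) {
                for (int ho = 0; ho < Ho; ++ho) {
                  const double *xrow = xc + kd + (R_xlen_t)D * ((ho + kh) + (R_xlen_t)H * (wo + kw));
                  double *yrow = ybase + (R_xlen_t)Do * (ho + (R_xlen_t)Ho * wo);
                  for (int d = 0; d < Do; ++d) yrow[d] += wv * xrow[d];
                }
              }
            }
      }
    }
  }
  return y;
}

// Backward pass: given dL/dy, return gradients w.r.t. input, weights, bias.
// [[Rcpp::export]]
List conv3d_bwd_cpp(NumericVector x, IntegerVector xdim,
                    NumericVector w, IntegerVector wdim,
                    NumericVector dy) {
  const int D = xdim[0], H = xdim[1], W = xdim[2], Ci = xdim[3], B = xdim[4];
  const int K = wdim[0], Co = wdim[4];
  const int Do = D - K + 1, Ho = H - K + 1, Wo = W - K + 1;
  NumericVector dx(x.size()), dw(w.size()), db(Co);
  const double *xp = x.begin(), *wp = w.begin(), *dyp = dy.begin();
  double *dxp = dx.begin(), *dwp = dw.begin(), *dbp = db.begin();

  for (int b = 0; b < B; ++b) {
    for (int co = 0; co < Co; ++co) {
      const double *dybase = dyp + (R_xlen_t)Do * Ho * Wo * (co + (R_xlen_t)Co * b);
      double s = 0.0;
      for (R_xlen_t i = 0; i < (R_xlen_t)Do * Ho * Wo; ++i) s += dybase[i];
      dbp[co] += s;
      for (int ci = 0; ci < Ci; ++ci) {
        const double *xc = xp + (R_xlen_t)D * H * W * (ci + (R_xlen_t)Ci * b);
        double *dxc = dxp + (R_xlen_t)D * H * W * (ci + (R_xlen_t)Ci * b);
        for (int kw = 0; kw < K; ++kw)
          for (int kh = 0; kh < K; ++kh)
            for (int kd = 0; kd < K; ++kd) {
              const R_xlen_t widx = kd + K * (kh + K * (kw + K * (ci + Ci * co)));
              const double wv = wp[widx];
              double acc = 0.0;
              for (int wo = 0; wo < Wo; ++wo) {
                for (int ho = 0; ho < Ho; ++ho) {
                  const double *xrow = xc + kd + (R_xlen_t)D * ((ho + kh) + (R_xlen_t)H * (wo + kw));
                  double *dxrow = dxc + kd + (R_xlen_t)D * ((ho + kh) + (R_xlen_t)H * (wo + kw));
                  const double *dyrow = dybase + (R_xlen_t)Do * (ho + (R_xlen_t)Ho * wo);
                  for (int d = 0; d < Do; ++d) {
                    acc += xrow[d] * dyrow[d];
                    dxrow[d] += wv * dyrow[d];
                  }
                }
              }
              dwp[widx] += acc;
            }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// Max pooling with cubic window/stride `pool`, valid (floor) extent.
// Returns pooled values and, for the backward pass, the 1-based flat argmax
// index of each output voxel within the input tensor.
// [[Rcpp::export]]
List maxpool3d_fwd_cpp(NumericVector x, IntegerVector xdim, int pool) {
  const int D = xdim[0], H = xdim[1], W = xdim[2], C = xdim[3], B = xdim[4];
  const int Do = D / pool, Ho = H / pool, Wo = W / pool;
  NumericVector y(static_cast<R_xlen_t>(Do) * Ho * Wo * C * B);
  IntegerVector idx(y.size());
  const double *xp = x.begin();
  double *yp = y.begin();
  int *ip = idx.begin();
  R_xlen_t o = 0;
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c) {
      const R_xlen_t chan = (R_xlen_t)D * H * W * (c + (R_xlen_t)C * b);
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho)
          for (int d0 = 0; d0 < Do; ++d0) {
            double best = R_NegInf;
            R_xlen_t bidx = 0;
            for (int kw = 0; kw < pool; ++kw)
              for (int kh = 0; kh < pool; ++kh)
                for (int kd = 0; kd < pool; ++kd) {
                  R_xlen_t xi = chan + (d0 * pool + kd) +
                    (R_xlen_t)D * ((ho * pool + kh) + (R_xlen_t)H * (wo * pool + kw));
                  if (xp[xi] > best) { best = xp[xi]; bidx = xi; }
                }
            yp[o] = best;
            ip[o] = (int)(bidx + 1);
            ++o;
          }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool3d_bwd_cpp(NumericVector dy, IntegerVector idx,
                                R_xlen_t xlen) {
  NumericVector dx(xlen);
  const double *dyp = dy.begin();
  const int *ip = idx.begin();
  double *dxp = dx.begin();
  for (R_xlen_t i = 0; i < dy.size(); ++i) dxp[ip[i] - 1] += dyp[i];
  return dx;
}
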