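// Elementwise / normalization kernels for the network stack.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using Rcpp::NumericVector;
using Rcpp::NumericMatrix;
using Rcpp::List;

static NumericVector like(const NumericVector& x) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  return y;
}

// [[Rcpp::export]]
NumericVector lrelu_fwd_cpp(NumericVector x, double alpha) {
  NumericVector y = like(x);
  const double* xi = x.begin(); double* yi = y.begin();
  size_t n = x.size();
  for (size_t i = 0; i < n; ++i) yi[i] = xi[i] > 0 ? xi[i] : alpha * xi[i];
  return y;
}

// [[Rcpp::export]]
NumericVector lrelu_bwd_cpp(NumericVector x, NumericVector g, double alpha) {
  NumericVector d = like(x);
  const double* xi = x.begin(); const double* gi = g.begin(); double* di = d.begin();
  size_t n = x.size();
  for (size_t i = 0; i < n; ++i) di[i] = xi[i] > 0 ? gi[i] : alpha * gi[i];
  return d;
}

// (H, W, C, N) -> (2H, 2W, C, N) nearest neighbour
// [[Rcpp::export]]
NumericVector upsample2_fwd_cpp(NumericVector x) {
  Rcpp::IntegerVector d = x.attr("dim");
  int H = d[0], W = d[1]; size_t planes = (size_t)d[2] * d[3];
  NumericVector y((size_t)4 * H * W * planes);
  y.attr("dim") = Rcpp::IntegerVector::create(2 * H, 2 * W, d[2], d[3]);
  const double* xi = x.begin(); double* yi = y.begin();
  for (size_t p = 0; p < planes; ++p) {
    const double* xp = xi + p * H * W;
    double* yp = yi + p * 4 * H * W;
    for (int w = 0; w < W; ++w) {
      for (int h = 0; h < H; ++h) {
        double v = xp[(size_t)w * H + h];
        size_t b = (size_t)(2 * w) * 2 * H + 2 * h;
        yp[b] = v; yp[b + 1] = v;
        yp[b + 2 * H] = v; yp[b + 2 * H + 1] = v;
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector upsample2_bwd_cpp(NumericVector g, int H, int W) {
  Rcpp::IntegerVector d = g.attr("dim");
  size_t planes = (size_t)d[2] * d[3];
  NumericVector dx((size_t)H * W * planes);
  dx.attr("dim") = Rcpp::IntegerVector::create(H, W, d[2], d[3]);
  const double* gi = g.begin(); double* di = dx.begin();
  for (size_t p = 0; p < planes; ++p) {
    const double* gp = gi + p * 4 * H * W;
    double* dp = di + p * H * W;
    for (int w = 0; w < W; ++w) {
      for (int h = 0; h < H; ++h) {
        size_t b = (size_t)(2 * w) * 2 * H + 2 * h;
        dp[(size_t)w * H + h] = gp[b] + gp[b + 1] + gp[b + 2 * H] + gp[b + 2 * H + 1];
      }
    }
  }
  return dx;
}

// Instance norm over (H*W) per (C, N) plane; returns y, means, inverse sds.
// [[Rcpp::export]]
List instnorm_fwd_cpp(NumericVector x, double eps) {
  Rcpp::IntegerVector d = x.attr("dim");
  size_t hw = (size_t)d[0] * d[1], planes = (size_t)d[2] * d[3];
  NumericVector y = like(x);
  NumericVector isd(planes);
  const double* xi = x.begin(); double* yi = y.begin();
  for (size_t p = 0; p < planes; ++p) {
    const double* xp = xi + p * hw; double* yp = yi + p * hw;
    double mu = 0, v = 0;
    for (size_t i = 0; i < hw; ++i) mu += xp[i];
    mu /= hw;
    for (size_t i = 0; i < hw; ++i) { double c = xp[i] - mu; v += c * c; }
    v /= hw;
    double is = 1.0 / std::sqrt(v + eps);
    isd[p] = is;
    for (size_t i = 0; i < hw; ++i) yp[i] = (xp[i] - mu) * is;
  }
  return List::create(Rcpp::Named("y") = y, Rcpp::Named("isd") = isd);
}

// [[Rcpp::export]]
NumericVector instnorm_bwd_cpp(NumericVector y, NumericVector isd, NumericVector g) {
  Rcpp::IntegerVector d = y.attr("dim");
  size_t hw = (size_t)d[0] * d[1], planes = (size_t)d[2] * d[3];
  NumericVector dx = like(y);
  const double* yi = y.begin(); const double* gi = g.begin(); double* di = dx.begin();
  for (size_t p = 0; p < planes; ++p) {
    const double* yp = yi + p * hw; const double* gp = gi + p * hw;
    double* dp = di + p * hw;
    double gm = 0, gy = 0;
    for (size_t i = 0; i < hw; ++i) { gm += gp[i]; gy += gp[i] * yp[i]; }
    gm /= hw; gy /= hw;
    double is = isd[p];
    for (size_t i = 0; i < hw; ++i) dp[i] = (gp[i] - gm - yp[i] * gy) * is;
  }
  return dx;
}

// y = x * (1 + gain[c,n]) + bias[c,n]
// [[Rcpp::export]]
NumericVector chanaffine_fwd_cpp(NumericVector x, NumericMatrix gain, NumericMatrix bias) {
  Rcpp::IntegerVector d = x.attr("dim");
  size_t hw = (size_t)d[0] * d[1], planes = (size_t)d[2] * d[3];
  NumericVector y = like(x);
  const double* xi = x.begin(); double* yi = y.begin();
  for (size_t p = 0; p < planes; ++p) {
    double gmul = 1.0 + gain[p], badd = bias[p];
    const double* xp = xi + p * hw; double* yp = yi + p * hw;
    for (size_t i = 0; i < hw; ++i) yp[i] = xp[i] * gmul + badd;
  }
  return y;
}

// [[Rcpp::export]]
List chanaffine_bwd_cpp(NumericVector x, NumericMatrix gain, NumericVector g) {
  Rcpp::IntegerVector d = x.attr("dim");
  size_t hw = (size_t)d[0] * d[1], planes = (size_t)d[2] * d[3];
  NumericVector dx = like(x);
  NumericMatrix dgain(d[2], d[3]), dbias(d[2], d[3]);
  const double* xi = x.begin(); const double* gi = g.begin(); double* di = dx.begin();
  for (size_t p = 0; p < planes; ++p) {
    double gmul = 1.0 + gain[p], sg = 0, sgx = 0;
    const double* xp = xi + p * hw; const double* gp = gi + p * hw;
    double* dp = di + p * hw;
    for (size_t i = 0; i < hw; ++i) {
      dp[i] = gp[i] * gmul;
      sg += gp[i];
      sgx += gp[i] * xp[i];
    }
    dgain[p] = sgx; dbias[p] = sg;
  }
  return List::create(Rcpp::Named("dx") = dx, Rcpp::Named("dgain") = dgain,
                      Rcpp::Named("dbias") = dbias);
}

// Broadcast a (C, N) matrix over (H, W): backward of global average pooling.
// [[Rcpp::export]]
NumericVector expand_cn_cpp(NumericMatrix m, int H, int W) {
  size_t hw = (size_t)H * W, planes = (size_t)m.nrow() * m.ncol();
  NumericVector y(hw * planes);
  y.attr("dim") = Rcpp::IntegerVector::create(H, W, m.nrow(), m.ncol());
  double* yi = y.begin();
  for (size_t p = 0; p < planes; ++p) {
    double v = m[p];
    double* yp = yi + p * hw;
    for (size_t i = 0; i < hw; ++i) yp[i] = v;
  }
  return y;
}
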