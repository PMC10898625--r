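// Convolution primitives for the network stack.
// Feature maps are column-major R arrays with dim (H, W, C, N); kernels have
// dim (kh, kw, Cin, Cout).  im2col flattens each receptive field into a row so
// the convolution becomes one BLAS matmul per image.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static void im2col_one(const double* x, int H, int W, int C,
                       int kh, int kw, int stride, int pad,
                       int Ho, int Wo, mat& col) {
  // col: (Ho*Wo) x (kh*kw*C), column q = ki + kh*(kj + kw*c)
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * H * W;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        int q = ki + kh * (kj + kw * c);
        double* colq = col.colptr(q);
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * stride + kj - pad;
          bool win = (wi >= 0 && wi < W);
          const double* xcol = win ? xc + (size_t)wi * H : nullptr;
          double* dst = colq + (size_t)wo * Ho;
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho * stride + ki - pad;
            dst[ho] = (win && hi >= 0 && hi < H) ? xcol[hi] : 0.0;
          }
        }
      }
    }
  }
}

static void col2im_one(const mat& col, int H, int W, int C,
                       int kh, int kw, int stride, int pad,
                       int Ho, int Wo, double* dx) {
  for (int c = 0; c < C; ++c) {
    double* xc = dx + (size_t)c * H * W;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        int q = ki + kh * (kj + kw * c);
        const double* colq = col.colptr(q);
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * stride + kj - pad;
          if (wi < 0 || wi >= W) continue;
          double* xcol = xc + (size_t)wi * H;
          const double* src = colq + (size_t)wo * Ho;
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho * stride + ki - pad;
            if (hi >= 0 && hi < H) xcol[hi] += src[ho];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
Rcpp::NumericVector conv2d_fwd_cpp(Rcpp::NumericVector x, Rcpp::NumericVector w,
                                   Rcpp::NumericVector b, int stride, int pad) {
  Rcpp::IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) Rcpp::stop("channel mismatch in conv2d");
  int Ho = (H + 2 * pad - kh) / stride + 1;
  int Wo = (W + 2 * pad - kw) / stride + 1;

  mat Wm(const_cast<double*>(w.begin()), kh * kw * C, Cout, false, true);
  rowvec bv(const_cast<double*>(b.begin()), Cout, false, true);
  Rcpp::NumericVector out((size_t)Ho * Wo * Cout * N);
  out.attr("dim") = Rcpp::IntegerVector::create(Ho, Wo, Cout, N);
  mat col(Ho * Wo, kh * kw * C);

  for (int n = 0; n < N; ++n) {
    im2col_one(x.begin() + (size_t)n * H * W * C, H, W, C, kh, kw,
               stride, pad, Ho, Wo, col);
    mat o = col * Wm;
    o.each_row() += bv;
    std::copy(o.begin(), o.end(), out.begin() + (size_t)n * Ho * Wo * Cout);
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::List conv2d_bwd_cpp(Rcpp::NumericVector x, Rcpp::NumericVector w,
                          Rcpp::NumericVector dout, int stride, int pad) {
  Rcpp::IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cout = wd[3];
  int Ho = (H + 2 * pad - kh) / stride + 1;
  int Wo = (W + 2 * pad - kw) / stride + 1;

  mat Wm(const_cast<double*>(w.begin()), kh * kw * C, Cout, false, true);
  Rcpp::NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = Rcpp::IntegerVector::create(H, W, C, N);
  Rcpp::NumericVector dw((size_t)kh * kw * C * Cout);
  dw.attr("dim") = Rcpp::IntegerVector::create(kh, kw, C, Cout);
  Rcpp::NumericVector db(Cout);
  mat dWm(dw.begin(), kh * kw * C, Cout, false, true);
  rowvec dbv(db.begin(), Cout, false, true);
  mat col(Ho * Wo, kh * kw * C);

  for (int n = 0; n < N; ++n) {
    im2col_one(x.begin() + (size_t)n * H * W * C, H, W, C, kh, kw,
               stride, pad, Ho, Wo, col);
    mat dO(const_cast<double*>(dout.begin()) + (size_t)n * Ho * Wo * Cout,
           Ho * Wo, Cout, false, true);
    dWm += col.t() * dO;
    dbv += sum(dO, 0);
    mat dcol = dO * Wm.t();
    col2im_one(dcol, H, W, C, kh, kw, stride, pad, Ho, Wo,
               dx.begin() + (size_t)n * H * W * C);
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dw") = dw,
                            Rcpp::Named("db") = db);
}
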