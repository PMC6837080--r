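// Dense-prediction network primitives.
//
// Memory layout follows R column-major arrays throughout:
//   activations (H, W, C, N), conv weights (kh, kw, Cin, Cout).
// Convolutions are stride-1 with "same" zero padding; pooling and
// up-sampling are fixed 2x2.  Forward and backward passes use
// im2col/col2im with BLAS matrix products.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Gather one sample's receptive fields into colsT: (H*W) x (kh*kw*C).
// Column q = ki + kh*(kj + kw*c) holds input channel c shifted by the
// kernel offset (ki, kj); out-of-bounds taps are zero.
static void im2col(const double* x, int H, int W, int C,
                   int kh, int kw, int ph, int pw, arma::mat& colsT) {
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)H * W * c;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        int q = ki + kh * (kj + kw * c);
        double* col = colsT.colptr(q);
        for (int w = 0; w < W; ++w) {
          int sw = w + kj - pw;
          double* dst = col + (size_t)H * w;
          if (sw < 0 || sw >= W) { std::fill(dst, dst + H, 0.0); continue; }
          const double* src = xc + (size_t)H * sw;
          for (int h = 0; h < H; ++h) {
            int sh = h + ki - ph;
            dst[h] = (sh < 0 || sh >= H) ? 0.0 : src[sh];
          }
        }
      }
    }
  }
}

// Scatter-add the column representation back onto an image plane
// (adjoint of im2col); used for the gradient w.r.t. the input.
static void col2im_add(const arma::mat& colsT, int H, int W, int C,
                       int kh, int kw, int ph, int pw, double* dx) {
  for (int c = 0; c < C; ++c) {
    double* xc = dx + (size_t)H * W * c;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        int q = ki + kh * (kj + kw * c);
        const double* col = colsT.colptr(q);
        for (int w = 0; w < W; ++w) {
          int sw = w + kj - pw;
          if (sw < 0 || sw >= W) continue;
          double* dst = xc + (size_t)H * sw;
          const double* src = col + (size_t)H * w;
          for (int h = 0; h < H; ++h) {
            int sh = h + ki - ph;
            if (sh >= 0 && sh < H) dst[sh] += src[h];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_forward(NumericVector x, NumericVector w,
                                 NumericVector b) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("conv2d: input has %d channels, weights expect %d", C, Cin);
  int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  int K = kh * kw * C, HW = H * W;

  arma::mat Wm(w.begin(), K, Cout, false);
  NumericVector out((size_t)HW * Cout * N);
  out.attr("dim") = IntegerVector::create(H, W, Cout, N);
  arma::mat colsT(HW, K);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)HW * C * n, H, W, C, kh, kw, ph, pw, colsT);
    arma::mat o(out.begin() + (size_t)HW * Cout * n, HW, Cout, false, true);
    o = colsT * Wm;
    for (int co = 0; co < Cout; ++co) o.col(co) += b[co];
  }
  return out;
}

// [[Rcpp::export]]
List cpp_conv2d_backward(NumericVector x, NumericVector w, NumericVector dout) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cout = wd[3];
  int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  int K = kh * kw * C, HW = H * W;

  arma::mat Wm(w.begin(), K, Cout, false);
  NumericVector dx((size_t)HW * C * N);
  dx.attr("dim") = xd;
  NumericVector dw((size_t)K * Cout);
  dw.attr("dim") = wd;
  NumericVector db(Cout);
  arma::mat dWm(dw.begin(), K, Cout, false, true);
  arma::mat colsT(HW, K);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)HW * C * n, H, W, C, kh, kw, ph, pw, colsT);
    arma::mat dO(dout.begin() + (size_t)HW * Cout * n, HW, Cout, false);
    dWm += colsT.t() * dO;
    for (int co = 0; co < Cout; ++co) db[co] += arma::accu(dO.col(co));
    arma::mat dCols = dO * Wm.t();  // HW x K
    col2im_add(dCols, H, W, C, kh, kw, ph, pw, dx.begin() + (size_t)HW * C * n);
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// 2x2 max pooling, stride 2.  idx stores the 0-based offset of each
// winning element within the full input vector, for the backward scatter.
// [[Rcpp::export]]
List cpp_maxpool2_forward(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  if (H % 2 || W % 2) stop("maxpool: spatial size (%d, %d) not even", H, W);
  int Ho = H / 2, Wo = W / 2;
  NumericVector out((size_t)Ho * Wo * C * N);
  IntegerVector idx((size_t)Ho * Wo * C * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const double* xp = x.begin();
  size_t p = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      size_t base = (size_t)H * W * (c + (size_t)C * n);
      for (int w = 0; w < Wo; ++w) {
        for (int h = 0; h < Ho; ++h, ++p) {
          size_t i00 = base + 2 * h + (size_t)H * (2 * w);
          size_t best = i00;
          double bv = xp[i00];
          size_t cand[3] = {i00 + 1, i00 + (size_t)H, i00 + (size_t)H + 1};
          for (int t = 0; t < 3; ++t)
            if (xp[cand[t]] > bv) { bv = xp[cand[t]]; best = cand[t]; }
          out[p] = bv;
          idx[p] = (int)best;
        }
      }
    }
  }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_backward(NumericVector dout, IntegerVector idx,
                                    IntegerVector xdim) {
  size_t len = (size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector dx(len);
  dx.attr("dim") = xdim;
  for (R_xlen_t p = 0; p < dout.size(); ++p) dx[idx[p]] += dout[p];
  return dx;
}

// Nearest-neighbour 2x up-sampling and its adjoint (2x2 block sum).
// [[Rcpp::export]]
NumericVector cpp_upsample2_forward(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Ho = 2 * H, Wo = 2 * W;
  NumericVector out((size_t)Ho * Wo * C * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  size_t planes = (size_t)C * N;
  for (size_t pl = 0; pl < planes; ++pl) {
    const double* src = x.begin() + (size_t)H * W * pl;
    double* dst = out.begin() + (size_t)Ho * Wo * pl;
    for (int w = 0; w < W; ++w) {
      for (int h = 0; h < H; ++h) {
        double v = src[h + (size_t)H * w];
        size_t o = 2 * h + (size_t)Ho * (2 * w);
        dst[o] = v; dst[o + 1] = v;
        dst[o + Ho] = v; dst[o + Ho + 1] = v;
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_upsample2_backward(NumericVector dout) {
  IntegerVector od = dout.attr("dim");
  int Ho = od[0], Wo = od[1], C = od[2], N = od[3];
  int H = Ho / 2, W = Wo / 2;
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  size_t planes = (size_t)C * N;
  for (size_t pl = 0; pl < planes; ++pl) {
    const double* src = dout.begin() + (size_t)Ho * Wo * pl;
    double* dst = dx.begin() + (size_t)H * W * pl;
    for (int w = 0; w < W; ++w) {
      for (int h = 0; h < H; ++h) {
        size_t o = 2 * h + (size_t)Ho * (2 * w);
        dst[h + (size_t)H * w] =
            src[o] + src[o + 1] + src[o + Ho] + src[o + Ho + 1];
      }
    }
  }
  return dx;
}
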