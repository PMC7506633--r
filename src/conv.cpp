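// im2col/GEMM 3x3 convolution kernels for the CPU reference backend.
// Layouts (all column-major, matching R arrays):
//   activations: (H, W, C, N)
//   patch matrix P: (Ho*Wo) x (9*C), output pixel p = i + Ho*j,
//     patch column q = kr + 3*kc + 9*c
//   weights: (9*C) x F; bias: length F
// Padding is TF-style "same": out = ceil(H/stride),
// pad_total = max((out-1)*stride + 3 - H, 0), pad_begin = pad_total/2.

#include <RcppArmadillo.h>
using namespace Rcpp;

static inline void same_pad(int H, int stride, int &out, int &beg) {
  out = (H + stride - 1) / stride;
  int total = std::max((out - 1) * stride + 3 - H, 0);
  beg = total / 2;
}

static void im2col(const double *x, int H, int W, int C, int stride,
                   int Ho, int Wo, int begR, int begC, arma::mat &P) {
  P.zeros();
  for (int c = 0; c < C; ++c) {
    const double *xc = x + (size_t)H * W * c;
    for (int kc = 0; kc < 3; ++kc) {
      for (int kr = 0; kr < 3; ++kr) {
        double *col = P.colptr(kr + 3 * kc + 9 * c);
        for (int j = 0; j < Wo; ++j) {
          int cc = j * stride - begC + kc;
          if (cc < 0 || cc >= W) continue;
          const double *xcol = xc + (size_t)H * cc;
          double *pcol = col + (size_t)Ho * j;
          for (int i = 0; i < Ho; ++i) {
            int rr = i * stride - begR + kr;
            if (rr >= 0 && rr < H) pcol[i] = xcol[rr];
          }
        }
      }
    }
  }
}

static void col2im(const arma::mat &G, int H, int W, int C, int stride,
                   int Ho, int Wo, int begR, int begC, double *dx) {
  for (int c = 0; c < C; ++c) {
    double *xc = dx + (size_t)H * W * c;
    for (int kc = 0; kc < 3; ++kc) {
      for (int kr = 0; kr < 3; ++kr) {
        const double *col = G.colptr(kr + 3 * kc + 9 * c);
        for (int j = 0; j < Wo; ++j) {
          int cc = j * stride - begC + kc;
          if (cc < 0 || cc >= W) continue;
          double *xcol = xc + (size_t)H * cc;
          const double *pcol = col + (size_t)Ho * j;
          for (int i = 0; i < Ho; ++i) {
            int rr = i * stride - begR + kr;
            if (rr >= 0 && rr < H) xcol[rr] += pcol[i];
          }
        }
      }
    }
  }
}

// [[Rcpp::export(rng = false)]]
NumericVector hn_conv_forward(NumericVector x, NumericMatrix w,
                              NumericVector b, int stride) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("x must be (H, W, C, N)");
  int H = d[0], W = d[1], C = d[2], N = d[3];
  int F = w.ncol();
  if (w.nrow() != 9 * C) stop("weight rows must equal 9*C");
  int Ho, Wo, begR, begC;
  same_pad(H, stride, Ho, begR);
  same_pad(W, stride, Wo, begC);

  arma::mat Wm(w.begin(), 9 * C, F, false);
  arma::rowvec bv(b.begin(), F);
  NumericVector out(Rcpp::no_init((size_t)Ho * Wo * F * N));
  out.attr("dim") = IntegerVector::create(Ho, Wo, F, N);
  arma::mat P((size_t)Ho * Wo, 9 * C);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C, stride,
           Ho, Wo, begR, begC, P);
    arma::mat Y = P * Wm;
    Y.each_row() += bv;
    std::copy(Y.begin(), Y.end(), out.begin() + (size_t)Ho * Wo * F * n);
  }
  return out;
}

// [[Rcpp::export(rng = false)]]
List hn_conv_backward(NumericVector x, NumericMatrix w, NumericVector dy,
                      int stride, bool need_dx) {
  IntegerVector d = x.attr("dim");
  int H = d[0], W = d[1], C = d[2], N = d[3];
  int F = w.ncol();
  int Ho, Wo, begR, begC;
  same_pad(H, stride, Ho, begR);
  same_pad(W, stride, Wo, begC);
  IntegerVector dd = dy.attr("dim");
  if (dd[0] != Ho || dd[1] != Wo || dd[2] != F || dd[3] != N)
    stop("dy has unexpected shape");

  arma::mat Wm(w.begin(), 9 * C, F, false);
  arma::mat dW(9 * C, F, arma::fill::zeros);
  arma::rowvec db(F, arma::fill::zeros);
  NumericVector dx;
  if (need_dx) {
    dx = NumericVector((size_t)H * W * C * N);  // zero-initialized
    dx.attr("dim") = IntegerVector::create(H, W, C, N);
  }
  arma::mat P((size_t)Ho * Wo, 9 * C);
  for (int n = 0; n < N; ++n) {
    arma::mat dY(dy.begin() + (size_t)Ho * Wo * F * n,
                 (size_t)Ho * Wo, F, false);
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C, stride,
           Ho, Wo, begR, begC, P);
    dW += P.t() * dY;
    db += arma::sum(dY, 0);
    if (need_dx) {
      arma::mat G = dY * Wm.t();
      col2im(G, H, W, C, stride, Ho, Wo, begR, begC,
             dx.begin() + (size_t)H * W * C * n);
    }
  }
  NumericMatrix dWr(9 * C, F);
  std::copy(dW.begin(), dW.end(), dWr.begin());
  NumericVector dbr(F);
  std::copy(db.begin(), db.end(), dbr.begin());
  if (need_dx) return List::create(_["dw"] = dWr, _["db"] = dbr, _["dx"] = dx);
  return List::create(_["dw"] = dWr, _["db"] = dbr);
}
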