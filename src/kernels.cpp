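// Low-level numeric kernels for the nested-U segmentation networks.
//
// Feature maps are dense double arrays with dimensions (H, W, C, N) in
// column-major (R) order, so a single (h,w) plane of one channel is
// contiguous.  Convolutions are stride-1 "same" convolutions: a k x k
// kernel with dilation d uses padding d*(k-1)/2, which preserves the
// spatial size for the 3x3 and 1x1 kernels used throughout.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline arma::uword idx4(arma::uword h, arma::uword w, arma::uword c,
                               arma::uword n, arma::uword H, arma::uword W,
                               arma::uword C) {
  return h + H * (w + W * (c + C * n));
}

// im2col for one sample: output (kh*kw*Cin) x (H*W)
static void im2col(const double* x, arma::uword H, arma::uword W,
                   arma::uword C, int kh, int kw, int pad, int dil,
                   arma::mat& K) {
  K.zeros();
  for (arma::uword c = 0; c < C; ++c) {
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const arma::uword row = ki + kh * (kj + kw * c);
        const int dh = ki * dil - pad;
        const int dw = kj * dil - pad;
        for (arma::uword w = 0; w < W; ++w) {
          const int sw = (int)w + dw;
          if (sw < 0 || sw >= (int)W) continue;
          const double* src = x + H * (sw + W * c);
          double* dst = K.memptr() + row + K.n_rows * (H * w);
          for (arma::uword h = 0; h < H; ++h) {
            const int sh = (int)h + dh;
            if (sh < 0 || sh >= (int)H) continue;
            dst[K.n_rows * h] = src[sh];
          }
        }
      }
    }
  }
}

// col2im (scatter-add), inverse access pattern of im2col
static void col2im(const arma::mat& K, arma::uword H, arma::uword W,
                   arma::uword C, int kh, int kw, int pad, int dil,
                   double* gx) {
  for (arma::uword c = 0; c < C; ++c) {
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const arma::uword row = ki + kh * (kj + kw * c);
        const int dh = ki * dil - pad;
        const int dw = kj * dil - pad;
        for (arma::uword w = 0; w < W; ++w) {
          const int sw = (int)w + dw;
          if (sw < 0 || sw >= (int)W) continue;
          double* dst = gx + H * (sw + W * c);
          const double* src = K.memptr() + row + K.n_rows * (H * w);
          for (arma::uword h = 0; h < H; ++h) {
            const int sh = (int)h + dh;
            if (sh < 0 || sh >= (int)H) continue;
            dst[sh] += src[K.n_rows * h];
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2d_fw")]]
NumericVector conv2d_fw(NumericVector x, NumericVector w, NumericVector b,
                        int pad, int dil) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const arma::uword H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1];
  const arma::uword Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("conv2d: input has %d channels, kernel expects %d",
                     (int)C, (int)Cin);
  // weight as (kh*kw*Cin) x Cout matrix: exactly its column-major layout
  arma::mat Wm(const_cast<double*>(w.begin()), (arma::uword)(kh * kw) * Cin,
               Cout, false, true);
  NumericVector y((R_xlen_t)H * W * Cout * N);
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);
  arma::mat K((arma::uword)(kh * kw) * Cin, H * W);
  for (arma::uword n = 0; n < N; ++n) {
    im2col(x.begin() + idx4(0, 0, 0, n, H, W, C), H, W, C, kh, kw, pad, dil, K);
    arma::mat Y(y.begin() + idx4(0, 0, 0, n, H, W, Cout), H * W, Cout, false,
                true);
    Y = K.t() * Wm;
    for (arma::uword co = 0; co < Cout; ++co) Y.col(co) += b[co];
  }
  return y;
}

// [[Rcpp::export(name = ".conv2d_bw")]]
List conv2d_bw(NumericVector x, NumericVector w, NumericVector gy, int pad,
               int dil) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const arma::uword H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1];
  const arma::uword Cin = wd[2], Cout = wd[3];
  arma::mat Wm(const_cast<double*>(w.begin()), (arma::uword)(kh * kw) * Cin,
               Cout, false, true);
  NumericVector gx((R_xlen_t)H * W * C * N);
  gx.attr("dim") = xd;
  NumericVector gw((R_xlen_t)kh * kw * Cin * Cout);
  gw.attr("dim") = wd;
  NumericVector gb(Cout);
  arma::mat gWm(gw.begin(), (arma::uword)(kh * kw) * Cin, Cout, false, true);
  arma::vec gbv(gb.begin(), Cout, false, true);
  arma::mat K((arma::uword)(kh * kw) * Cin, H * W);
  for (arma::uword n = 0; n < N; ++n) {
    im2col(x.begin() + idx4(0, 0, 0, n, H, W, C), H, W, C, kh, kw, pad, dil, K);
    arma::mat G(const_cast<double*>(gy.begin()) + idx4(0, 0, 0, n, H, W, Cout),
                H * W, Cout, false, true);
    gWm += K * G;
    gbv += arma::sum(G, 0).t();
    arma::mat Kg = Wm * G.t();  // (kh*kw*Cin) x (H*W)
    col2im(Kg, H, W, C, kh, kw, pad, dil,
           gx.begin() + idx4(0, 0, 0, n, H, W, C));
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// 2x2 max pooling, stride 2, ceiling semantics (ragged edge windows kept).
// [[Rcpp::export(name = ".maxpool2_fw")]]
List maxpool2_fw(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const arma::uword H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const arma::uword Ho = (H + 1) / 2, Wo = (W + 1) / 2;
  NumericVector y((R_xlen_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector idx((R_xlen_t)Ho * Wo * C * N);  // 0-based index into x
  R_xlen_t o = 0;
  for (arma::uword n = 0; n < N; ++n)
    for (arma::uword c = 0; c < C; ++c)
      for (arma::uword wo = 0; wo < Wo; ++wo)
        for (arma::uword ho = 0; ho < Ho; ++ho, ++o) {
          double best = R_NegInf;
          arma::uword bi = 0;
          for (arma::uword dw = 0; dw < 2; ++dw) {
            arma::uword w = 2 * wo + dw;
            if (w >= W) continue;
            for (arma::uword dh = 0; dh < 2; ++dh) {
              arma::uword h = 2 * ho + dh;
              if (h >= H) continue;
              arma::uword i = idx4(h, w, c, n, H, W, C);
              if (x[i] > best) { best = x[i]; bi = i; }
            }
          }
          y[o] = best;
          idx[o] = (int)bi;
        }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool2_bw")]]
NumericVector maxpool2_bw(IntegerVector idx, NumericVector gy,
                          IntegerVector xdim) {
  R_xlen_t n = (R_xlen_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector gx(n);
  gx.attr("dim") = xdim;
  for (R_xlen_t o = 0; o < gy.size(); ++o) gx[idx[o]] += gy[o];
  return gx;
}
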