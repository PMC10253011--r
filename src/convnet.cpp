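// Minimal conv / transposed-conv primitives for the VAE training loop.
// Layout convention: image batches are R arrays of dim (H, W, C, N),
// column-major. Filter banks are matrices of dim F x (k*k*C) with row
// index r = dh + k*dw + k*k*c, matching im2col() below, so a forward
// convolution is a single GEMM per sample.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_size(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

static void im2col(const double* x, int H, int W, int C,
                   int k, int stride, int pad, int Ho, int Wo,
                   arma::mat& cols) {
  for (int c = 0; c < C; ++c) {
    for (int dw = 0; dw < k; ++dw) {
      for (int dh = 0; dh < k; ++dh) {
        const int row = dh + k * dw + k * k * c;
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * stride - pad + dw;
          const bool w_ok = (wi >= 0 && wi < W);
          for (int ho = 0; ho < Ho; ++ho) {
            const int hi = ho * stride - pad + dh;
            double v = 0.0;
            if (w_ok && hi >= 0 && hi < H)
              v = x[hi + (size_t)H * (wi + (size_t)W * c)];
            cols(row, ho + (size_t)Ho * wo) = v;
          }
        }
      }
    }
  }
}

// Adjoint of im2col: scatter-add columns back into an (H, W, C) image.
static void col2im(const arma::mat& cols, int H, int W, int C,
                   int k, int stride, int pad, int Ho, int Wo,
                   double* x) {
  for (int c = 0; c < C; ++c) {
    for (int dw = 0; dw < k; ++dw) {
      for (int dh = 0; dh < k; ++dh) {
        const int row = dh + k * dw + k * k * c;
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * stride - pad + dw;
          if (wi < 0 || wi >= W) continue;
          for (int ho = 0; ho < Ho; ++ho) {
            const int hi = ho * stride - pad + dh;
            if (hi < 0 || hi >= H) continue;
            x[hi + (size_t)H * (wi + (size_t)W * c)] +=
              cols(row, ho + (size_t)Ho * wo);
          }
        }
      }
    }
  }
}

// Forward convolution: x (H,W,C,N) -> out (Ho,Wo,F,N)
// [[Rcpp::export(name = ".conv_fwd")]]
NumericVector conv_fwd(NumericVector x, NumericMatrix Wm, NumericVector b,
                       int k, int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int F = Wm.nrow();
  if (Wm.ncol() != k * k * C) stop("filter matrix has %d columns, expected %d",
                                   Wm.ncol(), k * k * C);
  const int Ho = out_size(H, k, stride, pad);
  const int Wo = out_size(W, k, stride, pad);
  NumericVector out((R_xlen_t)Ho * Wo * F * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, F, N);

  arma::mat cols(k * k * C, Ho * Wo);
  const arma::mat Wa(const_cast<double*>(&Wm[0]), F, k * k * C, false, true);
  const arma::colvec ba(const_cast<double*>(&b[0]), F, false, true);
  for (int n = 0; n < N; ++n) {
    im2col(&x[0] + (size_t)n * H * W * C, H, W, C, k, stride, pad, Ho, Wo, cols);
    arma::mat o = Wa * cols;          // F x (Ho*Wo)
    o.each_col() += ba;
    arma::mat ot = o.t();             // (Ho*Wo) x F, matches array layout
    std::copy(ot.memptr(), ot.memptr() + (size_t)Ho * Wo * F,
              &out[0] + (size_t)n * Ho * Wo * F);
  }
  return out;
}

// Backward convolution: gradients w.r.t. input, filters and bias.
// [[Rcpp::export(name = ".conv_bwd")]]
List conv_bwd(NumericVector x, NumericMatrix Wm, NumericVector gout,
              int k, int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  IntegerVector gd = gout.attr("dim");
  const int Ho = gd[0], Wo = gd[1], F = gd[2];
  const arma::mat Wa(const_cast<double*>(&Wm[0]), F, k * k * C, false, true);

  NumericVector gx((R_xlen_t)H * W * C * N);
  gx.attr("dim") = xd;
  arma::mat gW(F, k * k * C, arma::fill::zeros);
  arma::colvec gb(F, arma::fill::zeros);
  arma::mat cols(k * k * C, Ho * Wo);

  for (int n = 0; n < N; ++n) {
    im2col(&x[0] + (size_t)n * H * W * C, H, W, C, k, stride, pad, Ho, Wo, cols);
    const arma::mat go_t(const_cast<double*>(&gout[0]) + (size_t)n * Ho * Wo * F,
                         Ho * Wo, F, false, true);
    arma::mat go = go_t.t();          // F x (Ho*Wo)
    gW += go * cols.t();
    gb += arma::sum(go, 1);
    arma::mat gcols = Wa.t() * go;    // (k*k*C) x (Ho*Wo)
    col2im(gcols, H, W, C, k, stride, pad, Ho, Wo,
           &gx[0] + (size_t)n * H * W * C);
  }
  return List::create(_["gx"] = gx,
                      _["gW"] = wrap(gW),
                      _["gb"] = wrap(arma::conv_to<std::vector<double>>::from(gb)));
}

// Transposed convolution forward: x (Hi,Wi,F,N) -> out (Ho,Wo,C,N), the
// adjoint of conv_fwd with the same filter bank (F filters over C channels).
// [[Rcpp::export(name = ".convt_fwd")]]
NumericVector convt_fwd(NumericVector x, NumericMatrix Wm, NumericVector b,
                        int k, int stride, int pad, int Ho, int Wo) {
  IntegerVector xd = x.attr("dim");
  const int Hi = xd[0], Wi = xd[1], F = xd[2], N = xd[3];
  const int C = Wm.ncol() / (k * k);
  const arma::mat Wa(const_cast<double*>(&Wm[0]), F, k * k * C, false, true);

  NumericVector out((R_xlen_t)Ho * Wo * C * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  for (int n = 0; n < N; ++n) {
    const arma::mat x_t(const_cast<double*>(&x[0]) + (size_t)n * Hi * Wi * F,
                        Hi * Wi, F, false, true);
    arma::mat cols = Wa.t() * x_t.t();  // (k*k*C) x (Hi*Wi)
    double* o = &out[0] + (size_t)n * Ho * Wo * C;
    col2im(cols, Ho, Wo, C, k, stride, pad, Hi, Wi, o);
    for (int c = 0; c < C; ++c) {
      const double bc = b[c];
      for (size_t i = 0; i < (size_t)Ho * Wo; ++i)
        o[i + (size_t)Ho * Wo * c] += bc;
    }
  }
  return out;
}

// Transposed convolution backward.
// [[Rcpp::export(name = ".convt_bwd")]]
List convt_bwd(NumericVector x, NumericMatrix Wm, NumericVector gout,
               int k, int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  const int Hi = xd[0], Wi = xd[1], F = xd[2], N = xd[3];
  IntegerVector gd = gout.attr("dim");
  const int Ho = gd[0], Wo = gd[1], C = gd[2];
  const arma::mat Wa(const_cast<double*>(&Wm[0]), F, k * k * C, false, true);

  NumericVector gx((R_xlen_t)Hi * Wi * F * N);
  gx.attr("dim") = xd;
  arma::mat gW(F, k * k * C, arma::fill::zeros);
  arma::colvec gb(C, arma::fill::zeros);
  arma::mat cols(k * k * C, Hi * Wi);

  for (int n = 0; n < N; ++n) {
    const double* go = &gout[0] + (size_t)n * Ho * Wo * C;
    im2col(go, Ho, Wo, C, k, stride, pad, Hi, Wi, cols);
    const arma::mat x_t(const_cast<double*>(&x[0]) + (size_t)n * Hi * Wi * F,
                        Hi * Wi, F, false, true);
    arma::mat xm = x_t.t();             // F x (Hi*Wi)
    arma::mat g = Wa * cols;            // F x (Hi*Wi)
    arma::mat gt = g.t();
    std::copy(gt.memptr(), gt.memptr() + (size_t)Hi * Wi * F,
              &gx[0] + (size_t)n * Hi * Wi * F);
    gW += xm * cols.t();
    for (int c = 0; c < C; ++c) {
      double s = 0.0;
      for (size_t i = 0; i < (size_t)Ho * Wo; ++i)
        s += go[i + (size_t)Ho * Wo * c];
      gb[c] += s;
    }
  }
  return List::create(_["gx"] = gx,
                      _["gW"] = wrap(gW),
                      _["gb"] = wrap(arma::conv_to<std::vector<double>>::from(gb)));
}
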