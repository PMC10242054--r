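// Batched 2-D convolution forward/backward via im2col + GEMM.
//
// Activations are passed as 3-D arrays of dim (H, W, C * N): slice s holds
// channel  s %% C  of image  s %/% C  (the natural layout of an R array with
// dim c(H, W, C, N)).  Weight matrices are (Cout x Cin*k*k) with column
// index  c*k*k + ky*k + kx.  Padding is (k-1)/2 ("same" for stride 1).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static void im2col_one(const cube &x, int n, int cin, int k, int stride,
                       int pad, int h2, int w2, mat &M) {
  const int H = x.n_rows, W = x.n_cols;
  for (int c = 0; c < cin; ++c) {
    const mat &xs = x.slice(n * cin + c);
    for (int ky = 0; ky < k; ++ky) {
      for (int kx = 0; kx < k; ++kx) {
        const int r = c * k * k + ky * k + kx;
        for (int ox = 0; ox < w2; ++ox) {
          const int ix = ox * stride - pad + kx;
          if (ix < 0 || ix >= W) {
            for (int oy = 0; oy < h2; ++oy) M(r, oy + h2 * ox) = 0.0;
            continue;
          }
          for (int oy = 0; oy < h2; ++oy) {
            const int iy = oy * stride - pad + ky;
            M(r, oy + h2 * ox) = (iy < 0 || iy >= H) ? 0.0 : xs(iy, ix);
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv_fw")]]
Rcpp::NumericVector conv_fw(Rcpp::NumericVector x, Rcpp::NumericMatrix w,
                            int cin, int nimg, int k, int stride) {
  Rcpp::IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1];
  if (d[2] != cin * nimg) Rcpp::stop("input slice count != cin * nimg");
  const int pad = (k - 1) / 2;
  const int h2 = (H + 2 * pad - k) / stride + 1;
  const int w2 = (W + 2 * pad - k) / stride + 1;
  const mat wm(w.begin(), w.nrow(), w.ncol(), false);
  const int cout = wm.n_rows;
  if ((int)wm.n_cols != cin * k * k) Rcpp::stop("weight columns != cin*k*k");
  const cube xc(x.begin(), H, W, cin * nimg, false);
  cube out(h2, w2, cout * nimg);
  mat M(cin * k * k, h2 * w2);
  for (int n = 0; n < nimg; ++n) {
    im2col_one(xc, n, cin, k, stride, pad, h2, w2, M);
    mat Y = wm * M;  // cout x (h2*w2)
    for (int co = 0; co < cout; ++co)
      out.slice(n * cout + co) = reshape(Y.row(co), h2, w2);
  }
  Rcpp::NumericVector res(out.begin(), out.end());
  res.attr("dim") = Rcpp::IntegerVector::create(h2, w2, cout * nimg);
  return res;
}

// [[Rcpp::export(name = ".conv_bw")]]
Rcpp::List conv_bw(Rcpp::NumericVector x, Rcpp::NumericMatrix w,
                   Rcpp::NumericVector dy, int cin, int nimg, int k,
                   int stride) {
  Rcpp::IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1];
  const int pad = (k - 1) / 2;
  const int h2 = (H + 2 * pad - k) / stride + 1;
  const int w2 = (W + 2 * pad - k) / stride + 1;
  const mat wm(w.begin(), w.nrow(), w.ncol(), false);
  const int cout = wm.n_rows;
  const cube xc(x.begin(), H, W, cin * nimg, false);
  const cube dyc(dy.begin(), h2, w2, cout * nimg, false);
  mat dW(cout, cin * k * k, fill::zeros);
  cube dX(H, W, cin * nimg, fill::zeros);
  mat M(cin * k * k, h2 * w2);
  mat dY(cout, h2 * w2);
  for (int n = 0; n < nimg; ++n) {
    im2col_one(xc, n, cin, k, stride, pad, h2, w2, M);
    for (int co = 0; co < cout; ++co)
      dY.row(co) = reshape(dyc.slice(n * cout + co), 1, h2 * w2);
    dW += dY * M.t();
    mat dM = wm.t() * dY;  // (cin*k*k) x (h2*w2)
    // col2im scatter-add
    for (int c = 0; c < cin; ++c) {
      mat &dxs = dX.slice(n * cin + c);
      for (int ky = 0; ky < k; ++ky) {
        for (int kx = 0; kx < k; ++kx) {
          const int r = c * k * k + ky * k + kx;
          for (int ox = 0; ox < w2; ++ox) {
            const int ix = ox * stride - pad + kx;
            if (ix < 0 || ix >= W) continue;
            for (int oy = 0; oy < h2; ++oy) {
              const int iy = oy * stride - pad + ky;
              if (iy < 0 || iy >= H) continue;
              dxs(iy, ix) += dM(r, oy + h2 * ox);
            }
          }
        }
      }
    }
  }
  Rcpp::NumericVector dXout(dX.begin(), dX.end());
  dXout.attr("dim") = Rcpp::IntegerVector::create(H, W, cin * nimg);
  return Rcpp::List::create(Rcpp::Named("dW") = dW,
                            Rcpp::Named("dX") = dXout);
}
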