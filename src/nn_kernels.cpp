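// Convolution kernels for the minimal CNN framework.
// Feature maps are dense cubes [H, W, C] (column-major, as R arrays).
// Weights are (k*k*C_in) x C_out matrices; row index dh + k*dw + k*k*c
// (0-based) so that R's array(w, c(k, k, C_in, C_out)) flattens to the
// same layout. Padding (zero or reflect) is folded into the index
// arithmetic. Armadillo matrices are views over R memory (no copies);
// the forward pass hands its im2col matrix to the backward pass.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// mirror an out-of-range coordinate back into [0, n) (edge not repeated);
// pad never exceeds n - 1, so one fold suffices
static inline int reflect_idx(int i, int n) {
  if (i < 0) return -i;
  if (i >= n) return 2 * n - 2 - i;
  return i;
}

static void im2col(const cube& x, int k, int stride, int pad, bool reflect,
                   int Ho, int Wo, mat& col) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  for (int c = 0; c < C; ++c) {
    for (int dw = 0; dw < k; ++dw) {
      for (int dh = 0; dh < k; ++dh) {
        double* dst = col.colptr(dh + k * dw + k * k * c);
        for (int ow = 0; ow < Wo; ++ow) {
          int w = ow * stride + dw - pad;
          if (w < 0 || w >= W) {
            if (!reflect) { for (int oh = 0; oh < Ho; ++oh) dst[oh + Ho * ow] = 0.0; continue; }
            w = reflect_idx(w, W);
          }
          const double* src = x.slice_colptr(c, w);
          for (int oh = 0; oh < Ho; ++oh) {
            int h = oh * stride + dh - pad;
            if (h < 0 || h >= H) {
              if (!reflect) { dst[oh + Ho * ow] = 0.0; continue; }
              h = reflect_idx(h, H);
            }
            dst[oh + Ho * ow] = src[h];
          }
        }
      }
    }
  }
}

static void col2im(const mat& col, int k, int stride, int pad, bool reflect,
                   int Ho, int Wo, cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  for (int c = 0; c < C; ++c) {
    for (int dw = 0; dw < k; ++dw) {
      for (int dh = 0; dh < k; ++dh) {
        const double* src = col.colptr(dh + k * dw + k * k * c);
        for (int ow = 0; ow < Wo; ++ow) {
          int w = ow * stride + dw - pad;
          if (w < 0 || w >= W) {
            if (!reflect) continue;
            w = reflect_idx(w, W);
          }
          double* dst = x.slice_colptr(c, w);
          for (int oh = 0; oh < Ho; ++oh) {
            int h = oh * stride + dh - pad;
            if (h < 0 || h >= H) {
              if (!reflect) continue;
              h = reflect_idx(h, H);
            }
            dst[h] += src[oh + Ho * ow];
          }
        }
      }
    }
  }
}

static cube cube_view(Rcpp::NumericVector& v) {
  Rcpp::IntegerVector d = v.attr("dim");
  return cube(v.begin(), d[0], d[1], d[2], false, true);
}

// [[Rcpp::export]]
Rcpp::List conv2d_forward(Rcpp::NumericVector x, Rcpp::NumericMatrix w,
                          Rcpp::NumericVector b, int k, int stride, int pad,
                          bool reflect) {
  cube xv = cube_view(x);
  const mat wv(w.begin(), w.nrow(), w.ncol(), false, true);
  const vec bv(b.begin(), b.size(), false, true);
  const int Ho = (xv.n_rows + 2 * pad - k) / stride + 1;
  const int Wo = (xv.n_cols + 2 * pad - k) / stride + 1;
  Rcpp::NumericMatrix colR(Ho * Wo, k * k * xv.n_slices);
  mat col(colR.begin(), colR.nrow(), colR.ncol(), false, true);
  im2col(xv, k, stride, pad, reflect, Ho, Wo, col);
  Rcpp::NumericVector outR(Ho * Wo * wv.n_cols);
  outR.attr("dim") = Rcpp::IntegerVector::create(Ho, Wo, wv.n_cols);
  mat out(outR.begin(), Ho * Wo, wv.n_cols, false, true);
  out = col * wv;
  out.each_row() += bv.t();
  return Rcpp::List::create(Rcpp::Named("out") = outR,
                            Rcpp::Named("col") = colR);
}

// [[Rcpp::export]]
Rcpp::List conv2d_backward(Rcpp::NumericMatrix colR, Rcpp::NumericMatrix w,
                           Rcpp::NumericVector gout, int H, int W, int C,
                           int k, int stride, int pad, bool reflect) {
  const mat col(colR.begin(), colR.nrow(), colR.ncol(), false, true);
  const mat wv(w.begin(), w.nrow(), w.ncol(), false, true);
  cube gv = cube_view(gout);
  const int Ho = gv.n_rows, Wo = gv.n_cols, Co = gv.n_slices;
  const mat gmat(gout.begin(), Ho * Wo, Co, false, true);
  Rcpp::NumericMatrix gwR(col.n_cols, Co);
  mat gw(gwR.begin(), col.n_cols, Co, false, true);
  gw = col.t() * gmat;
  Rcpp::NumericVector gbR(Co);
  vec gb(gbR.begin(), Co, false, true);
  gb = sum(gmat, 0).t();
  Rcpp::NumericVector gxR(H * W * C);
  gxR.attr("dim") = Rcpp::IntegerVector::create(H, W, C);
  cube gx(gxR.begin(), H, W, C, false, true);
  mat gcol = gmat * wv.t();
  col2im(gcol, k, stride, pad, reflect, Ho, Wo, gx);
  return Rcpp::List::create(Rcpp::Named("gx") = gxR,
                            Rcpp::Named("gw") = gwR,
                            Rcpp::Named("gb") = gbR);
}
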