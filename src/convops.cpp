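// Low-level kernels for the convolutional network engine.
//
// Layout conventions (shared with R/nn.R):
//   * feature maps are arma::cube / R arrays with dim (H, W, C); slices are
//     channels, column-major within a slice.
//   * a convolution weight is a matrix (C_out x kh*kw*C_in); the column index
//     enumerates (ki, kj, c_in) with ki fastest, matching im2col's row order.
//   * a transposed-convolution weight is (C_in x kh*kw*C_out): the transposed
//     convolution with stride s is the adjoint of an ordinary stride-s
//     convolution, so its forward pass is that convolution's backward-data
//     pass (col2im) and vice versa.
// All convolutions here are "valid"; padding/cropping is done by the caller.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static mat im2col_(const cube& x, const int kh, const int kw, const int stride) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = (H - kh) / stride + 1;
  const int Wo = (W - kw) / stride + 1;
  mat cols(kh * kw * C, (uword)Ho * Wo);
  for (int j = 0; j < Wo; ++j) {
    for (int i = 0; i < Ho; ++i) {
      const uword colidx = (uword)j * Ho + i;
      double* dst = cols.colptr(colidx);
      for (int c = 0; c < C; ++c) {
        const mat& sl = x.slice(c);
        for (int kj = 0; kj < kw; ++kj) {
          const double* src = sl.colptr(j * stride + kj) + i * stride;
          for (int ki = 0; ki < kh; ++ki) *dst++ = src[ki];
        }
      }
    }
  }
  return cols;
}

static cube col2im_(const mat& cols, const int H, const int W, const int C,
                    const int kh, const int kw, const int stride) {
  // adjoint of im2col_: scatter-accumulate patch columns back into an image
  const int Ho = (H - kh) / stride + 1;
  const int Wo = (W - kw) / stride + 1;
  cube out(H, W, C, fill::zeros);
  for (int j = 0; j < Wo; ++j) {
    for (int i = 0; i < Ho; ++i) {
      const uword colidx = (uword)j * Ho + i;
      const double* src = cols.colptr(colidx);
      for (int c = 0; c < C; ++c) {
        mat& sl = out.slice(c);
        for (int kj = 0; kj < kw; ++kj) {
          double* dst = sl.colptr(j * stride + kj) + i * stride;
          for (int ki = 0; ki < kh; ++ki) dst[ki] += *src++;
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
arma::mat cpp_im2col(const arma::cube& x, const int kh, const int kw,
                     const int stride) {
  return im2col_(x, kh, kw, stride);
}

// [[Rcpp::export]]
arma::cube cpp_col2im(const arma::mat& cols, const int H, const int W,
                      const int C, const int kh, const int kw,
                      const int stride) {
  return col2im_(cols, H, W, C, kh, kw, stride);
}

// [[Rcpp::export]]
arma::cube cpp_conv_fw(const arma::cube& x, const arma::mat& W,
                       const arma::vec& b, const int kh, const int kw,
                       const int stride) {
  const int H = x.n_rows, Wd = x.n_cols;
  const int Ho = (H - kh) / stride + 1;
  const int Wo = (Wd - kw) / stride + 1;
  const int Cout = W.n_rows;
  mat cols = im2col_(x, kh, kw, stride);
  mat out = W * cols;              // Cout x (Ho*Wo)
  out.each_col() += b;
  cube y(Ho, Wo, Cout);
  for (int c = 0; c < Cout; ++c)
    y.slice(c) = reshape(out.row(c), Ho, Wo);
  return y;
}

// [[Rcpp::export]]
Rcpp::List cpp_conv_bw(const arma::cube& x, const arma::mat& W,
                       const arma::cube& dy, const int kh, const int kw,
                       const int stride) {
  const int H = x.n_rows, Wd = x.n_cols, Cin = x.n_slices;
  const int Ho = dy.n_rows, Wo = dy.n_cols, Cout = dy.n_slices;
  mat dy_mat(Cout, (uword)Ho * Wo);
  for (int c = 0; c < Cout; ++c)
    dy_mat.row(c) = vectorise(dy.slice(c)).t();
  mat cols = im2col_(x, kh, kw, stride);
  mat dW = dy_mat * cols.t();
  vec db = sum(dy_mat, 1);
  cube dx = col2im_(W.t() * dy_mat, H, Wd, Cin, kh, kw, stride);
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}

// [[Rcpp::export]]
arma::cube cpp_convt_fw(const arma::cube& x, const arma::mat& W,
                        const arma::vec& b, const int kh, const int kw,
                        const int stride) {
  const int H = x.n_rows, Wd = x.n_cols, Cin = x.n_slices;
  const int Ho = (H - 1) * stride + kh;
  const int Wo = (Wd - 1) * stride + kw;
  const int Cout = W.n_cols / (kh * kw);
  mat x_mat(Cin, (uword)H * Wd);
  for (int c = 0; c < Cin; ++c)
    x_mat.row(c) = vectorise(x.slice(c)).t();
  cube y = col2im_(W.t() * x_mat, Ho, Wo, Cout, kh, kw, stride);
  for (int c = 0; c < Cout; ++c) y.slice(c) += b(c);
  return y;
}

// [[Rcpp::export]]
Rcpp::List cpp_convt_bw(const arma::cube& x, const arma::mat& W,
                        const arma::cube& dy, const int kh, const int kw,
                        const int stride) {
  const int H = x.n_rows, Wd = x.n_cols, Cin = x.n_slices;
  const int Cout = dy.n_slices;
  mat x_mat(Cin, (uword)H * Wd);
  for (int c = 0; c < Cin; ++c)
    x_mat.row(c) = vectorise(x.slice(c)).t();
  mat cols_d = im2col_(dy, kh, kw, stride);   // (kh*kw*Cout) x (H*W)
  mat dx_mat = W * cols_d;                    // Cin x (H*W)
  cube dx(H, Wd, Cin);
  for (int c = 0; c < Cin; ++c)
    dx.slice(c) = reshape(dx_mat.row(c), H, Wd);
  mat dW = x_mat * cols_d.t();
  vec db(Cout);
  for (int c = 0; c < Cout; ++c) db(c) = accu(dy.slice(c));
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}

// [[Rcpp::export]]
Rcpp::List cpp_maxpool(const arma::cube& x, const bool ceil_mode) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = ceil_mode ? (H + 1) / 2 : H / 2;
  const int Wo = ceil_mode ? (W + 1) / 2 : W / 2;
  cube y(Ho, Wo, C);
  Rcpp::IntegerVector idx((R_xlen_t)Ho * Wo * C);  // 0-based linear index into x
  R_xlen_t k = 0;
  for (int c = 0; c < C; ++c) {
    const mat& sl = x.slice(c);
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        const int i1 = std::min(2 * i + 1, H - 1);
        const int j1 = std::min(2 * j + 1, W - 1);
        double best = -datum::inf;
        uword bi = 0, bj = 0;
        for (int jj = 2 * j; jj <= j1; ++jj)
          for (int ii = 2 * i; ii <= i1; ++ii)
            if (sl(ii, jj) > best) { best = sl(ii, jj); bi = ii; bj = jj; }
        y(i, j, c) = best;
      }
    }
  }
  // second pass to fill idx in cube storage order (column-major by slice)
  k = 0;
  for (int c = 0; c < C; ++c) {
    const mat& sl = x.slice(c);
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        const int i1 = std::min(2 * i + 1, H - 1);
        const int j1 = std::min(2 * j + 1, W - 1);
        double best = -datum::inf;
        long bidx = 0;
        for (int jj = 2 * j; jj <= j1; ++jj)
          for (int ii = 2 * i; ii <= i1; ++ii)
            if (sl(ii, jj) > best) {
              best = sl(ii, jj);
              bidx = (long)c * H * W + (long)jj * H + ii;
            }
        idx[k++] = (int)bidx;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("out") = y, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export]]
arma::cube cpp_maxpool_bw(const arma::cube& dy, const Rcpp::IntegerVector& idx,
                          const int H, const int W) {
  const int C = dy.n_slices;
  cube dx(H, W, C, fill::zeros);
  const double* src = dy.memptr();
  double* dst = dx.memptr();
  const R_xlen_t n = dy.n_elem;
  for (R_xlen_t k = 0; k < n; ++k) dst[idx[k]] += src[k];
  return dx;
}
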