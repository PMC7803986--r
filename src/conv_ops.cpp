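#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// Stride-1 2-D convolution kernels for H x W x C arrays (sample-major layout
// used throughout the package). Weights are stored as a (kh*kw*cin) x cout
// matrix; row index ((ky*kw + kx)*cin + c) matches the im2col column order
// below. All heavy lifting is im2col + BLAS gemm.

static mat im2col(const cube& x, int kh, int kw, int pt, int pl,
                  int Ho, int Wo) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  mat out(static_cast<uword>(Ho) * Wo, static_cast<uword>(kh) * kw * C,
          fill::zeros);
  for (int ky = 0; ky < kh; ++ky) {
    // valid output rows i with 0 <= i - pt + ky < H
    const int i0 = std::max(0, pt - ky);
    const int i1 = std::min(Ho, H + pt - ky);
    if (i0 >= i1) continue;
    for (int kx = 0; kx < kw; ++kx) {
      for (int c = 0; c < C; ++c) {
        const uword col = (static_cast<uword>(ky) * kw + kx) * C + c;
        double* dst = out.colptr(col);
        for (int j = 0; j < Wo; ++j) {
          const int xj = j - pl + kx;
          if (xj < 0 || xj >= W) continue;
          const double* src = x.slice(c).colptr(xj) + (i0 - pt + ky);
          std::memcpy(dst + static_cast<uword>(j) * Ho + i0, src,
                      sizeof(double) * (i1 - i0));
        }
      }
    }
  }
  return out;
}

// Scatter-add counterpart of im2col.
static void col2im(const mat& cols, cube& dx, int kh, int kw, int pt, int pl,
                   int Ho, int Wo) {
  const int H = dx.n_rows, W = dx.n_cols, C = dx.n_slices;
  for (int ky = 0; ky < kh; ++ky) {
    const int i0 = std::max(0, pt - ky);
    const int i1 = std::min(Ho, H + pt - ky);
    if (i0 >= i1) continue;
    for (int kx = 0; kx < kw; ++kx) {
      for (int c = 0; c < C; ++c) {
        const uword col = (static_cast<uword>(ky) * kw + kx) * C + c;
        const double* src = cols.colptr(col);
        for (int j = 0; j < Wo; ++j) {
          const int xj = j - pl + kx;
          if (xj < 0 || xj >= W) continue;
          double* dst = dx.slice(c).colptr(xj) + (i0 - pt + ky);
          const double* s = src + static_cast<uword>(j) * Ho + i0;
          const int len = i1 - i0;
          for (int i = 0; i < len; ++i) dst[i] += s[i];
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2dForward")]]
arma::cube conv2dForward(const arma::cube& x, const arma::mat& w,
                         const arma::vec& b, int kh, int kw,
                         int pt, int pl) {
  const int Ho = x.n_rows + pt + (kh - 1 - pt) - kh + 1; // same-size output
  const int Wo = x.n_cols + pl + (kw - 1 - pl) - kw + 1;
  mat cols = im2col(x, kh, kw, pt, pl, Ho, Wo);
  mat y = cols * w;
  y.each_row() += b.t();
  cube out(Ho, Wo, w.n_cols);
  std::memcpy(out.memptr(), y.memptr(), sizeof(double) * y.n_elem);
  return out;
}

// [[Rcpp::export(name = ".conv2dBackward")]]
Rcpp::List conv2dBackward(const arma::cube& x, const arma::cube& dy,
                          const arma::mat& w, int kh, int kw,
                          int pt, int pl) {
  const int Ho = dy.n_rows, Wo = dy.n_cols;
  mat cols = im2col(x, kh, kw, pt, pl, Ho, Wo);
  mat dym(const_cast<double*>(dy.memptr()),
          static_cast<uword>(Ho) * Wo, dy.n_slices, false, true);
  mat dw = cols.t() * dym;
  vec db = sum(dym, 0).t();
  mat dcols = dym * w.t();
  cube dx(x.n_rows, x.n_cols, x.n_slices, fill::zeros);
  col2im(dcols, dx, kh, kw, pt, pl, Ho, Wo);
  return Rcpp::List::create(Rcpp::Named("dW") = dw,
                            Rcpp::Named("db") = db,
                            Rcpp::Named("dx") = dx);
}

// 2x2 stride-2 max pooling; idx records the winning linear offset (0..3)
// within each pooling window for exact gradient routing.
// [[Rcpp::export(name = ".maxpool2Forward")]]
Rcpp::List maxpool2Forward(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = H / 2, Wo = W / 2;
  cube y(Ho, Wo, C);
  icube idx(Ho, Wo, C);
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        double best = x(2 * i, 2 * j, c);
        int bi = 0;
        const double v1 = x(2 * i + 1, 2 * j, c);
        if (v1 > best) { best = v1; bi = 1; }
        const double v2 = x(2 * i, 2 * j + 1, c);
        if (v2 > best) { best = v2; bi = 2; }
        const double v3 = x(2 * i + 1, 2 * j + 1, c);
        if (v3 > best) { best = v3; bi = 3; }
        y(i, j, c) = best;
        idx(i, j, c) = bi;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("y") = y, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export(name = ".maxpool2Backward")]]
arma::cube maxpool2Backward(const arma::cube& dy, const arma::icube& idx,
                            int H, int W) {
  const int Ho = dy.n_rows, Wo = dy.n_cols, C = dy.n_slices;
  cube dx(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        const int k = idx(i, j, c);
        dx(2 * i + (k & 1), 2 * j + (k >> 1), c) += dy(i, j, c);
      }
    }
  }
  return dx;
}
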