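// Minimal conv-net kernels used by the dense-block classifier.
// Batch activations are arma::cube with dims (channels, H*W, batch),
// spatial index column-major (p = r + c*H, 0-based), matching how R
// arrays of dim (H, W, C, N) are permuted on entry.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static inline int out_side(int H, int k, int pad, int stride) {
  return (H + 2 * pad - k) / stride + 1;
}

// col((kc*k + kr)*Cin + ci, n*HoWo + ro + co*Ho) = X(ci, r + c*H, n) with
// r = ro*stride - pad + kr, c = co*stride - pad + kc (0 outside). The Cin
// block for a fixed kernel offset is a contiguous column copy.
static void im2col_batch(const cube& X, int H, int W, int k, int pad,
                         int stride, mat& col) {
  const int Cin = X.n_rows;
  const int N = X.n_slices;
  const int Ho = out_side(H, k, pad, stride);
  const int Wo = out_side(W, k, pad, stride);
  col.zeros(Cin * k * k, (size_t)N * Ho * Wo);
  for (int n = 0; n < N; ++n) {
    const double* xs = X.slice_memptr(n);
    for (int co = 0; co < Wo; ++co) {
      for (int ro = 0; ro < Ho; ++ro) {
        double* cp = col.colptr((size_t)n * Ho * Wo + ro + (size_t)co * Ho);
        for (int kc = 0; kc < k; ++kc) {
          const int c = co * stride - pad + kc;
          if (c < 0 || c >= W) continue;
          for (int kr = 0; kr < k; ++kr) {
            const int r = ro * stride - pad + kr;
            if (r < 0 || r >= H) continue;
            std::memcpy(cp + (size_t)(kc * k + kr) * Cin,
                        xs + (size_t)(r + c * H) * Cin,
                        Cin * sizeof(double));
          }
        }
      }
    }
  }
}

static void col2im_batch(const mat& col, int H, int W, int k, int pad,
                         int stride, cube& X) {
  const int Cin = X.n_rows;
  const int N = X.n_slices;
  const int Ho = out_side(H, k, pad, stride);
  const int Wo = out_side(W, k, pad, stride);
  for (int n = 0; n < N; ++n) {
    double* xs = X.slice_memptr(n);
    for (int co = 0; co < Wo; ++co) {
      for (int ro = 0; ro < Ho; ++ro) {
        const double* cp =
          col.colptr((size_t)n * Ho * Wo + ro + (size_t)co * Ho);
        for (int kc = 0; kc < k; ++kc) {
          const int c = co * stride - pad + kc;
          if (c < 0 || c >= W) continue;
          for (int kr = 0; kr < k; ++kr) {
            const int r = ro * stride - pad + kr;
            if (r < 0 || r >= H) continue;
            double* dst = xs + (size_t)(r + c * H) * Cin;
            const double* src = cp + (size_t)(kc * k + kr) * Cin;
            for (int ci = 0; ci < Cin; ++ci) dst[ci] += src[ci];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
arma::cube conv_fw(const arma::cube& X, const arma::mat& Wm,
                   const arma::vec& bias, int H, int W, int k, int pad,
                   int stride) {
  const int N = X.n_slices;
  const int Ho = out_side(H, k, pad, stride);
  const int Wo = out_side(W, k, pad, stride);
  mat col;
  im2col_batch(X, H, W, k, pad, stride, col);
  mat Yb = Wm * col;          // (Cout, N*HoWo), sample-major columns
  Yb.each_col() += bias;
  cube Y(Wm.n_rows, Ho * Wo, N);
  std::memcpy(Y.memptr(), Yb.memptr(), Yb.n_elem * sizeof(double));
  return Y;
}

// [[Rcpp::export]]
Rcpp::List conv_bw(const arma::cube& X, const arma::mat& Wm,
                   const arma::cube& dY, int H, int W, int k, int pad,
                   int stride) {
  const int N = X.n_slices;
  mat col;
  im2col_batch(X, H, W, k, pad, stride, col);
  const mat dYb((double*)dY.memptr(), dY.n_rows,
                (size_t)dY.n_cols * N, false, true);
  mat dW = dYb * col.t();
  vec db = sum(dYb, 1);
  mat dcol = Wm.t() * dYb;
  cube dX(X.n_rows, X.n_cols, N, fill::zeros);
  col2im_batch(dcol, H, W, k, pad, stride, dX);
  return Rcpp::List::create(Rcpp::Named("dX") = dX, Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}

// 2x2 average pooling, stride 2, floor semantics.
// [[Rcpp::export]]
arma::cube avgpool2_fw(const arma::cube& X, int H, int W) {
  const int Ho = H / 2, Wo = W / 2, C = X.n_rows, N = X.n_slices;
  cube Y(C, Ho * Wo, N, fill::zeros);
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Wo; ++co)
      for (int ro = 0; ro < Ho; ++ro) {
        const int po = ro + co * Ho;
        for (int dc = 0; dc < 2; ++dc)
          for (int dr = 0; dr < 2; ++dr) {
            const int pin = (2 * ro + dr) + (2 * co + dc) * H;
            for (int c = 0; c < C; ++c)
              Y(c, po, n) += 0.25 * X(c, pin, n);
          }
      }
  return Y;
}

// [[Rcpp::export]]
arma::cube avgpool2_bw(const arma::cube& dY, int H, int W) {
  const int Ho = H / 2, Wo = W / 2, C = dY.n_rows, N = dY.n_slices;
  cube dX(C, H * W, N, fill::zeros);
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Wo; ++co)
      for (int ro = 0; ro < Ho; ++ro) {
        const int po = ro + co * Ho;
        for (int dc = 0; dc < 2; ++dc)
          for (int dr = 0; dr < 2; ++dr) {
            const int pin = (2 * ro + dr) + (2 * co + dc) * H;
            for (int c = 0; c < C; ++c)
              dX(c, pin, n) += 0.25 * dY(c, po, n);
          }
      }
  return dX;
}

// Adaptive average pooling to an `out` x `out` grid (torch bin edges:
// start = floor(i*H/out), end = ceil((i+1)*H/out)); valid for out > H
// as well, where bins repeat pixels.
// [[Rcpp::export]]
arma::cube adaptive_avgpool_fw(const arma::cube& X, int H, int W, int out) {
  const int C = X.n_rows, N = X.n_slices;
  cube Y(C, out * out, N, fill::zeros);
  for (int co = 0; co < out; ++co) {
    const int c0 = (co * W) / out;
    const int c1 = ((co + 1) * W + out - 1) / out;
    for (int ro = 0; ro < out; ++ro) {
      const int r0 = (ro * H) / out;
      const int r1 = ((ro + 1) * H + out - 1) / out;
      const double inv = 1.0 / ((r1 - r0) * (c1 - c0));
      const int po = ro + co * out;
      for (int n = 0; n < N; ++n)
        for (int c = c0; c < c1; ++c)
          for (int r = r0; r < r1; ++r)
            for (int ch = 0; ch < C; ++ch)
              Y(ch, po, n) += inv * X(ch, r + c * H, n);
    }
  }
  return Y;
}

// [[Rcpp::export]]
arma::cube adaptive_avgpool_bw(const arma::cube& dY, int H, int W, int out) {
  const int C = dY.n_rows, N = dY.n_slices;
  cube dX(C, H * W, N, fill::zeros);
  for (int co = 0; co < out; ++co) {
    const int c0 = (co * W) / out;
    const int c1 = ((co + 1) * W + out - 1) / out;
    for (int ro = 0; ro < out; ++ro) {
      const int r0 = (ro * H) / out;
      const int r1 = ((ro + 1) * H + out - 1) / out;
      const double inv = 1.0 / ((r1 - r0) * (c1 - c0));
      const int po = ro + co * out;
      for (int n = 0; n < N; ++n)
        for (int c = c0; c < c1; ++c)
          for (int r = r0; r < r1; ++r)
            for (int ch = 0; ch < C; ++ch)
              dX(ch, r + c * H, n) += inv * dY(ch, po, n);
    }
  }
  return dX;
}
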