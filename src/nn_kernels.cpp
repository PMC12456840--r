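// im2col / col2im kernels backing the convolutional layers.
//
// Activations are stored as 4-D arrays with dimensions (C, H, W, N),
// column-major as R lays them out.  im2col unrolls k x k patches so a
// convolution becomes a single GEMM:
//   out (C_out x Ho*Wo*N) = W (C_out x C*k*k) * cols (C*k*k x Ho*Wo*N).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// [[Rcpp::export]]
arma::mat cpp_im2col(const arma::vec& x, int C, int H, int W, int N,
                     int k, int stride, int pad) {
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  arma::mat cols(C * k * k, (arma::uword)Ho * Wo * N, arma::fill::zeros);
  const double* xp = x.memptr();
  const long strideN = (long)C * H * W;

  for (int n = 0; n < N; ++n) {
    const double* xn = xp + (long)n * strideN;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        arma::uword colidx = (arma::uword)n * Ho * Wo + (arma::uword)wo * Ho + ho;
        double* cp = cols.colptr(colidx);
        int h0 = ho * stride - pad;
        int w0 = wo * stride - pad;
        for (int kw = 0; kw < k; ++kw) {
          int w_in = w0 + kw;
          for (int kh = 0; kh < k; ++kh) {
            int h_in = h0 + kh;
            double* dst = cp + ((long)kw * k + kh) * C;
            if (h_in >= 0 && h_in < H && w_in >= 0 && w_in < W) {
              const double* src = xn + ((long)w_in * H + h_in) * C;
              std::copy(src, src + C, dst);
            }
          }
        }
      }
    }
  }
  return cols;
}

// Adjoint of im2col: scatter-add patch columns back onto the input grid.
// [[Rcpp::export]]
arma::vec cpp_col2im(const arma::mat& cols, int C, int H, int W, int N,
                     int k, int stride, int pad) {
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  arma::vec x((arma::uword)C * H * W * N, arma::fill::zeros);
  double* xp = x.memptr();
  const long strideN = (long)C * H * W;

  for (int n = 0; n < N; ++n) {
    double* xn = xp + (long)n * strideN;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        arma::uword colidx = (arma::uword)n * Ho * Wo + (arma::uword)wo * Ho + ho;
        const double* cp = cols.colptr(colidx);
        int h0 = ho * stride - pad;
        int w0 = wo * stride - pad;
        for (int kw = 0; kw < k; ++kw) {
          int w_in = w0 + kw;
          for (int kh = 0; kh < k; ++kh) {
            int h_in = h0 + kh;
            const double* src = cp + ((long)kw * k + kh) * C;
            if (h_in >= 0 && h_in < H && w_in >= 0 && w_in < W) {
              double* dst = xn + ((long)w_in * H + h_in) * C;
              for (int c = 0; c < C; ++c) dst[c] += src[c];
            }
          }
        }
      }
    }
  }
  return x;
}
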