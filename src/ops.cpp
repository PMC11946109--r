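// Low-level tensor kernels for the layer engine.
//
// Feature maps are stored as R double matrices with one row per spatial
// location and one column per channel. Rows are ordered batch-major,
// then row-major within an image: row = b*H*W + i*W + j (0-based).

#include <Rcpp.h>
using namespace Rcpp;

// Unfold k x k patches (stride s, zero padding p) into a matrix with one
// row per output location and k*k*C columns ordered (ki, kj, c).
// [[Rcpp::export(name = ".im2col")]]
NumericMatrix im2col_cpp(const NumericMatrix& X, int B, int H, int W,
                         int k, int s, int p) {
  const int C = X.ncol();
  const int OH = (H + 2 * p - k) / s + 1;
  const int OW = (W + 2 * p - k) / s + 1;
  NumericMatrix out(B * OH * OW, k * k * C);
  const double* x = X.begin();
  double* o = out.begin();
  const int nrow_in = X.nrow();
  const int nrow_out = out.nrow();
  for (int ki = 0; ki < k; ++ki) {
    for (int kj = 0; kj < k; ++kj) {
      for (int c = 0; c < C; ++c) {
        const int col_out = (ki * k + kj) * C + c;
        double* oc = o + (size_t)col_out * nrow_out;
        const double* xc = x + (size_t)c * nrow_in;
        for (int b = 0; b < B; ++b) {
          for (int oi = 0; oi < OH; ++oi) {
            const int ii = oi * s - p + ki;
            const int rbase = b * OH * OW + oi * OW;
            if (ii < 0 || ii >= H) {
              for (int oj = 0; oj < OW; ++oj) oc[rbase + oj] = 0.0;
              continue;
            }
            const int ibase = b * H * W + ii * W;
            for (int oj = 0; oj < OW; ++oj) {
              const int jj = oj * s - p + kj;
              oc[rbase + oj] = (jj < 0 || jj >= W) ? 0.0 : xc[ibase + jj];
            }
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col: scatter-add patch gradients back onto the input map.
// [[Rcpp::export(name = ".col2im")]]
NumericMatrix col2im_cpp(const NumericMatrix& dcol, int B, int H, int W,
                         int C, int k, int s, int p) {
  const int OH = (H + 2 * p - k) / s + 1;
  const int OW = (W + 2 * p - k) / s + 1;
  NumericMatrix dX(B * H * W, C);
  const double* dc = dcol.begin();
  double* dx = dX.begin();
  const int nrow_in = dX.nrow();
  const int nrow_col = dcol.nrow();
  for (int ki = 0; ki < k; ++ki) {
    for (int kj = 0; kj < k; ++kj) {
      for (int c = 0; c < C; ++c) {
        const int col_out = (ki * k + kj) * C + c;
        const double* cc = dc + (size_t)col_out * nrow_col;
        double* xc = dx + (size_t)c * nrow_in;
        for (int b = 0; b < B; ++b) {
          for (int oi = 0; oi < OH; ++oi) {
            const int ii = oi * s - p + ki;
            if (ii < 0 || ii >= H) continue;
            const int rbase = b * OH * OW + oi * OW;
            const int ibase = b * H * W + ii * W;
            for (int oj = 0; oj < OW; ++oj) {
              const int jj = oj * s - p + kj;
              if (jj >= 0 && jj < W) xc[ibase + jj] += cc[rbase + oj];
            }
          }
        }
      }
    }
  }
  return dX;
}

// k x k max pooling, stride 1, zero padding p (only used with k odd,
// p = k/2, the SPPF setting). Returns the pooled map and 1-based argmax
// row indices for the backward pass.
// [[Rcpp::export(name = ".maxpool")]]
List maxpool_cpp(const NumericMatrix& X, int B, int H, int W, int k, int p) {
  const int C = X.ncol();
  NumericMatrix out(B * H * W, C);
  IntegerMatrix arg(B * H * W, C);
  const double* x = X.begin();
  const int nrow = X.nrow();
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * nrow;
    double* oc = out.begin() + (size_t)c * nrow;
    int* ac = arg.begin() + (size_t)c * nrow;
    for (int b = 0; b < B; ++b) {
      for (int i = 0; i < H; ++i) {
        for (int j = 0; j < W; ++j) {
          double best = R_NegInf; int bestr = -1;
          for (int ki = 0; ki < k; ++ki) {
            const int ii = i - p + ki;
            if (ii < 0 || ii >= H) continue;
            for (int kj = 0; kj < k; ++kj) {
              const int jj = j - p + kj;
              if (jj < 0 || jj >= W) continue;
              const int r = b * H * W + ii * W + jj;
              if (xc[r] > best) { best = xc[r]; bestr = r; }
            }
          }
          const int ro = b * H * W + i * W + j;
          oc[ro] = best;
          ac[ro] = bestr + 1;
        }
      }
    }
  }
  return List::create(_["out"] = out, _["arg"] = arg);
}

// Scatter pooled-output gradients back to the argmax source locations.
// [[Rcpp::export(name = ".maxpool_bwd")]]
NumericMatrix maxpool_bwd_cpp(const NumericMatrix& dY, const IntegerMatrix& arg,
                              int nrow_in) {
  const int C = dY.ncol();
  NumericMatrix dX(nrow_in, C);
  for (int c = 0; c < C; ++c) {
    const double* dyc = dY.begin() + (size_t)c * dY.nrow();
    const int* ac = arg.begin() + (size_t)c * arg.nrow();
    double* dxc = dX.begin() + (size_t)c * (size_t)nrow_in;
    for (int r = 0; r < dY.nrow(); ++r) dxc[ac[r] - 1] += dyc[r];
  }
  return dX;
}

// Nearest-neighbour 2x upsampling.
// [[Rcpp::export(name = ".upsample2")]]
NumericMatrix upsample2_cpp(const NumericMatrix& X, int B, int H, int W) {
  const int C = X.ncol();
  const int H2 = 2 * H, W2 = 2 * W;
  NumericMatrix out(B * H2 * W2, C);
  for (int c = 0; c < C; ++c) {
    const double* xc = X.begin() + (size_t)c * X.nrow();
    double* oc = out.begin() + (size_t)c * out.nrow();
    for (int b = 0; b < B; ++b)
      for (int i = 0; i < H2; ++i)
        for (int j = 0; j < W2; ++j)
          oc[b * H2 * W2 + i * W2 + j] = xc[b * H * W + (i / 2) * W + j / 2];
  }
  return out;
}

// Adjoint of 2x nearest upsampling: sum each 2x2 block.
// [[Rcpp::export(name = ".upsample2_bwd")]]
NumericMatrix upsample2_bwd_cpp(const NumericMatrix& dY, int B, int H, int W) {
  // H, W are the *input* (coarse) dimensions
  const int C = dY.ncol();
  const int H2 = 2 * H, W2 = 2 * W;
  NumericMatrix dX(B * H * W, C);
  for (int c = 0; c < C; ++c) {
    const double* dyc = dY.begin() + (size_t)c * dY.nrow();
    double* dxc = dX.begin() + (size_t)c * dX.nrow();
    for (int b = 0; b < B; ++b)
      for (int i = 0; i < H2; ++i)
        for (int j = 0; j < W2; ++j)
          dxc[b * H * W + (i / 2) * W + j / 2] += dyc[b * H2 * W2 + i * W2 + j];
  }
  return dX;
}
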