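#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Reflect an out-of-range index back into [0, n) without repeating the
// edge sample ("reflect" padding, the adjoint of which folds border
// gradients onto their mirror source). Requires n >= 2 for any k > 1.
static inline int reflect_idx(int i, int n) {
  if (i < 0) return -i;
  if (i >= n) return 2 * n - 2 - i;
  return i;
}

// Unroll k x k neighbourhoods of an H x W x C cube into an (H*W) x (k*k*C)
// matrix under reflective padding, stride 1. Row index follows the
// column-major pixel order (i + H*j) so columns of the result reshape back
// to H x W maps; column index is di + k*dj + k*k*c, matching the
// column-major flattening of an R weight array [k, k, Cin, Cout].
static arma::mat im2col_reflect(const arma::cube& x, int k) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices, p = (k - 1) / 2;
  arma::mat col(H * W, k * k * C);
  for (int c = 0; c < C; ++c) {
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const int q = di + k * dj + k * k * c;
        double* dst = col.colptr(q);
        for (int j = 0; j < W; ++j) {
          const int sj = reflect_idx(j + dj - p, W);
          const double* src = x.slice_colptr(c, sj);
          for (int i = 0; i < H; ++i) {
            dst[i + H * j] = src[reflect_idx(i + di - p, H)];
          }
        }
      }
    }
  }
  return col;
}

// Same-size 2-D convolution (cross-correlation) with reflective padding.
// x: H x W x Cin; w: (k*k*Cin) x Cout; b: length Cout.
// [[Rcpp::export]]
arma::cube cpp_conv2d_same(const arma::cube& x, const arma::mat& w,
                           const arma::vec& b, int k) {
  const int H = x.n_rows, W = x.n_cols;
  const int Cout = w.n_cols;
  arma::mat y = im2col_reflect(x, k) * w;
  y.each_row() += b.t();
  arma::cube out(H, W, Cout);
  for (int co = 0; co < Cout; ++co)
    out.slice(co) = arma::reshape(y.col(co), H, W);
  return out;
}

// Gradients of cpp_conv2d_same wrt input, weights and bias, given the
// gradient gy of the loss wrt the output. The input gradient scatters
// through the reflective padding so border contributions fold back onto
// their mirror sources (exact adjoint of the forward pass).
// [[Rcpp::export]]
List cpp_conv2d_same_backward(const arma::cube& x, const arma::mat& w,
                              const arma::cube& gy, int k) {
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  const int Cout = gy.n_slices, p = (k - 1) / 2;

  arma::mat gym(H * W, Cout);
  for (int co = 0; co < Cout; ++co)
    gym.col(co) = arma::vectorise(gy.slice(co));

  arma::mat col = im2col_reflect(x, k);
  arma::mat gw = col.t() * gym;
  arma::vec gb = arma::sum(gym, 0).t();

  arma::mat gcol = gym * w.t();
  arma::cube gx(H, W, Cin, arma::fill::zeros);
  for (int c = 0; c < Cin; ++c) {
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const int q = di + k * dj + k * k * c;
        const double* src = gcol.colptr(q);
        for (int j = 0; j < W; ++j) {
          const int sj = reflect_idx(j + dj - p, W);
          double* dst = gx.slice_colptr(c, sj);
          for (int i = 0; i < H; ++i) {
            dst[reflect_idx(i + di - p, H)] += src[i + H * j];
          }
        }
      }
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}
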