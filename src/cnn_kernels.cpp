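// Compiled kernels for the patch classifier's hot layers.
//
// Activations are (H, W, batch, channel) column-major arrays, so the
// (H, W, batch) block of one channel is contiguous. Convolutions are 3x3,
// stride 1, zero same-padding, expressed as im2col + GEMM; the im2col matrix
// has rows indexed by (h, w, b) and columns ordered offset-major
// (dx, dy in -1..1, channel fastest within an offset), matching the
// (9 * C_in) x F weight layout used on the R side.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static void im2col_3x3(const double* a, int H, int Wd, int B, int C,
                       arma::mat& X) {
  int col = 0;
  for (int dx = -1; dx <= 1; ++dx) {
    for (int dy = -1; dy <= 1; ++dy) {
      for (int c = 0; c < C; ++c) {
        double* xcol = X.colptr(col++);
        for (int bb = 0; bb < B; ++bb) {
          const double* ac = a + ((size_t)c * B + bb) * (size_t)H * Wd;
          double* xo = xcol + (size_t)bb * H * Wd;
          for (int w = 0; w < Wd; ++w) {
            int sw = w + dx;
            double* dst = xo + (size_t)w * H;
            if (sw < 0 || sw >= Wd) {
              std::fill(dst, dst + H, 0.0);
              continue;
            }
            const double* src = ac + (size_t)sw * H;
            int r0 = std::max(0, -dy), r1 = std::min(H, H - dy);
            for (int r = 0; r < r0; ++r) dst[r] = 0.0;
            for (int r = r0; r < r1; ++r) dst[r] = src[r + dy];
            for (int r = r1; r < H; ++r) dst[r] = 0.0;
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
List cpp_conv_forward(NumericVector A, IntegerVector dims,
                      const arma::mat& W, const arma::vec& b) {
  int H = dims[0], Wd = dims[1], B = dims[2], C = dims[3];
  size_t n = (size_t)H * Wd * B;
  arma::mat X(n, 9 * (size_t)C);
  im2col_3x3(A.begin(), H, Wd, B, C, X);
  arma::mat Y = X * W;
  Y.each_row() += b.t();
  NumericVector out(Y.begin(), Y.end());
  out.attr("dim") = IntegerVector::create(H, Wd, B, (int)W.n_cols);
  return List::create(_["out"] = out, _["X"] = X);
}

// [[Rcpp::export]]
List cpp_conv_backward(const arma::mat& dY_mat, const arma::mat& X,
                       const arma::mat& W, IntegerVector dims) {
  int H = dims[0], Wd = dims[1], B = dims[2], C = dims[3];
  arma::mat dW = X.t() * dY_mat;
  arma::vec db = arma::sum(dY_mat, 0).t();
  arma::mat dX = dY_mat * W.t(); // (H*W*B) x 9C
  NumericVector dA((size_t)H * Wd * B * C);
  double* da = dA.begin();
  int col = 0;
  for (int dx = -1; dx <= 1; ++dx) {
    for (int dy = -1; dy <= 1; ++dy) {
      for (int c = 0; c < C; ++c) {
        const double* xcol = dX.colptr(col++);
        for (int bb = 0; bb < B; ++bb) {
          double* ac = da + ((size_t)c * B + bb) * (size_t)H * Wd;
          const double* xo = xcol + (size_t)bb * H * Wd;
          for (int w = 0; w < Wd; ++w) {
            int sw = w + dx;
            if (sw < 0 || sw >= Wd) continue;
            double* dst = ac + (size_t)sw * H;
            const double* src = xo + (size_t)w * H;
            int r0 = std::max(0, -dy), r1 = std::min(H, H - dy);
            for (int r = r0; r < r1; ++r) dst[r + dy] += src[r];
          }
        }
      }
    }
  }
  dA.attr("dim") = IntegerVector::create(H, Wd, B, C);
  return List::create(_["dA"] = dA, _["dW"] = dW, _["db"] = db);
}

// 2x2 max pooling, stride 2, floor on odd sides. `which` records the winning
// in-window position (0: +0,+0; 1: +1,+0; 2: +0,+1; 3: +1,+1; first maximum
// wins ties) for exact gradient routing.
// [[Rcpp::export]]
List cpp_maxpool_forward(NumericVector A, IntegerVector dims) {
  int H = dims[0], Wd = dims[1], B = dims[2], C = dims[3];
  int Ho = H / 2, Wo = Wd / 2;
  size_t n_out = (size_t)Ho * Wo * B * C;
  NumericVector out(n_out);
  IntegerVector which(n_out);
  const double* a = A.begin();
  double* o = out.begin();
  int* wh = which.begin();
  size_t idx = 0;
  long planes = (long)B * C;
  for (long q = 0; q < planes; ++q) {
    const double* ap = a + (size_t)q * H * Wd;
    for (int w = 0; w < Wo; ++w) {
      for (int r = 0; r < Ho; ++r) {
        const double* base = ap + (size_t)(2 * w) * H + 2 * r;
        double v = base[0];
        int k = 0;
        if (base[1] > v) { v = base[1]; k = 1; }
        if (base[H] > v) { v = base[H]; k = 2; }
        if (base[H + 1] > v) { v = base[H + 1]; k = 3; }
        o[idx] = v;
        wh[idx] = k;
        ++idx;
      }
    }
  }
  out.attr("dim") = IntegerVector::create(Ho, Wo, B, C);
  return List::create(_["out"] = out, _["which"] = which);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_backward(NumericVector dY, IntegerVector which,
                                   IntegerVector in_dims) {
  int H = in_dims[0], Wd = in_dims[1], B = in_dims[2], C = in_dims[3];
  int Ho = H / 2, Wo = Wd / 2;
  NumericVector dA((size_t)H * Wd * B * C);
  double* da = dA.begin();
  const double* g = dY.begin();
  const int* wh = which.begin();
  size_t idx = 0;
  long planes = (long)B * C;
  const int off_r[4] = {0, 1, 0, 1};
  const int off_w[4] = {0, 0, 1, 1};
  for (long q = 0; q < planes; ++q) {
    double* ap = da + (size_t)q * H * Wd;
    for (int w = 0; w < Wo; ++w) {
      for (int r = 0; r < Ho; ++r) {
        int k = wh[idx];
        ap[(size_t)(2 * w + off_w[k]) * H + 2 * r + off_r[k]] = g[idx];
        ++idx;
      }
    }
  }
  dA.attr("dim") = IntegerVector::create(H, Wd, B, C);
  return dA;
}
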