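// Low-level layer arithmetic for the autoencoders.
//
// Images and feature maps are H x W x C arma::cube (column-major, matching
// R arrays indexed [h, w, c]). Convolutions are stride-1 "same" with zero
// padding; weights are stored as a (K*K*Cin) x Cout matrix whose rows run
// kh fastest, then kw, then input channel, so im2col and the weight matrix
// agree by construction.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::mat im2col_same(const arma::cube& X, const int K) {
  const int H = X.n_rows, W = X.n_cols, C = X.n_slices;
  const int P = K / 2;
  arma::mat out(H * W, K * K * C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int kw = 0; kw < K; ++kw) {
      for (int kh = 0; kh < K; ++kh) {
        const int col = c * K * K + kw * K + kh;
        for (int w = 0; w < W; ++w) {
          const int sw = w + kw - P;
          if (sw < 0 || sw >= W) continue;
          for (int h = 0; h < H; ++h) {
            const int sh = h + kh - P;
            if (sh < 0 || sh >= H) continue;
            out(w * H + h, col) = X(sh, sw, c);
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
arma::cube conv2d_fw(const arma::cube& X, const arma::mat& W,
                     const arma::vec& b, const int K) {
  const int H = X.n_rows, Wd = X.n_cols;
  const int Cout = W.n_cols;
  arma::mat cols = im2col_same(X, K);
  arma::mat Y = cols * W;
  Y.each_row() += b.t();
  arma::cube out(H, Wd, Cout);
  std::memcpy(out.memptr(), Y.memptr(), sizeof(double) * Y.n_elem);
  return out;
}

// [[Rcpp::export]]
List conv2d_bw(const arma::cube& X, const arma::mat& W,
               const arma::cube& dY, const int K) {
  const int H = X.n_rows, Wd = X.n_cols, Cin = X.n_slices;
  const int Cout = dY.n_slices;
  const int P = K / 2;
  arma::mat dYm(const_cast<double*>(dY.memptr()), H * Wd, Cout, false, true);
  arma::mat cols = im2col_same(X, K);
  arma::mat dW = cols.t() * dYm;
  arma::vec db = arma::sum(dYm, 0).t();
  // scatter d(cols) = dYm * W' back onto the input grid
  arma::mat dcols = dYm * W.t();
  arma::cube dX(H, Wd, Cin, arma::fill::zeros);
  for (int c = 0; c < Cin; ++c) {
    for (int kw = 0; kw < K; ++kw) {
      for (int kh = 0; kh < K; ++kh) {
        const int col = c * K * K + kw * K + kh;
        for (int w = 0; w < Wd; ++w) {
          const int sw = w + kw - P;
          if (sw < 0 || sw >= Wd) continue;
          for (int h = 0; h < H; ++h) {
            const int sh = h + kh - P;
            if (sh < 0 || sh >= H) continue;
            dX(sh, sw, c) += dcols(w * H + h, col);
          }
        }
      }
    }
  }
  return List::create(_["dX"] = dX, _["dW"] = dW, _["db"] = db);
}

// 2x2 max pooling, stride 2. Returns pooled map and the linear index
// (0-based, within the input cube) of each selected element for backprop.
// [[Rcpp::export]]
List maxpool2_fw(const arma::cube& X) {
  const int H = X.n_rows, W = X.n_cols, C = X.n_slices;
  const int Ho = H / 2, Wo = W / 2;
  arma::cube Y(Ho, Wo, C);
  arma::ucube idx(Ho, Wo, C);
  for (int c = 0; c < C; ++c) {
    for (int w = 0; w < Wo; ++w) {
      for (int h = 0; h < Ho; ++h) {
        double best = -arma::datum::inf;
        arma::uword bi = 0;
        for (int dw = 0; dw < 2; ++dw) {
          for (int dh = 0; dh < 2; ++dh) {
            const int sh = 2 * h + dh, sw = 2 * w + dw;
            const double v = X(sh, sw, c);
            if (v > best) {
              best = v;
              bi = (arma::uword)c * H * W + (arma::uword)sw * H + sh;
            }
          }
        }
        Y(h, w, c) = best;
        idx(h, w, c) = bi;
      }
    }
  }
  return List::create(_["Y"] = Y, _["idx"] = idx);
}

// [[Rcpp::export]]
arma::cube maxpool2_bw(const arma::ucube& idx, const arma::cube& dY,
                       const int H, const int W) {
  const int C = dY.n_slices;
  arma::cube dX(H, W, C, arma::fill::zeros);
  for (arma::uword i = 0; i < idx.n_elem; ++i) {
    dX(idx(i)) += dY(i);
  }
  return dX;
}

// 2x2 nearest-neighbour up-sampling.
// [[Rcpp::export]]
arma::cube upsample2_fw(const arma::cube& X) {
  const int H = X.n_rows, W = X.n_cols, C = X.n_slices;
  arma::cube Y(2 * H, 2 * W, C);
  for (int c = 0; c < C; ++c)
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h) {
        const double v = X(h, w, c);
        Y(2 * h, 2 * w, c) = v;
        Y(2 * h + 1, 2 * w, c) = v;
        Y(2 * h, 2 * w + 1, c) = v;
        Y(2 * h + 1, 2 * w + 1, c) = v;
      }
  return Y;
}

// [[Rcpp::export]]
arma::cube upsample2_bw(const arma::cube& dY) {
  const int H = dY.n_rows / 2, W = dY.n_cols / 2, C = dY.n_slices;
  arma::cube dX(H, W, C);
  for (int c = 0; c < C; ++c)
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h)
        dX(h, w, c) = dY(2 * h, 2 * w, c) + dY(2 * h + 1, 2 * w, c) +
                      dY(2 * h, 2 * w + 1, c) + dY(2 * h + 1, 2 * w + 1, c);
  return dX;
}
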