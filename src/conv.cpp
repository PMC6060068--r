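// Minimal convolutional primitives for the twin-image removal network.
// Tensors are arma::cube with dimensions (H, W, C); convolution kernels are
// stored as an F x (K*K*C) matrix so that forward and backward passes reduce
// to GEMM calls on an im2col buffer.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// im2col for 3x3 same (zero) padding: returns (9*C) x (H*W)
static arma::mat im2col3(const arma::cube &x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::mat col(9 * C, (size_t)H * W, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const arma::mat &xc = x.slice(c);
    for (int dj = -1; dj <= 1; ++dj) {
      for (int di = -1; di <= 1; ++di) {
        const int krow = c * 9 + (dj + 1) * 3 + (di + 1);
        for (int j = 0; j < W; ++j) {
          const int js = j + dj;
          if (js < 0 || js >= W) continue;
          const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
          for (int i = i0; i < i1; ++i)
            col(krow, (size_t)j * H + i) = xc(i + di, js);
        }
      }
    }
  }
  return col;
}

// scatter-add the columns back to an image cube (adjoint of im2col3)
static arma::cube col2im3(const arma::mat &col, int H, int W, int C) {
  arma::cube x(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    arma::mat &xc = x.slice(c);
    for (int dj = -1; dj <= 1; ++dj) {
      for (int di = -1; di <= 1; ++di) {
        const int krow = c * 9 + (dj + 1) * 3 + (di + 1);
        for (int j = 0; j < W; ++j) {
          const int js = j + dj;
          if (js < 0 || js >= W) continue;
          const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
          for (int i = i0; i < i1; ++i)
            xc(i + di, js) += col(krow, (size_t)j * H + i);
        }
      }
    }
  }
  return x;
}

// [[Rcpp::export(name = ".conv3_forward")]]
arma::cube conv3_forward(const arma::cube &x, const arma::mat &w,
                         const arma::vec &b) {
  const int H = x.n_rows, W = x.n_cols;
  const int F = w.n_rows;
  if ((int)w.n_cols != 9 * (int)x.n_slices)
    stop("kernel/channel mismatch");
  arma::mat col = im2col3(x);
  arma::mat y = w * col;           // F x (H*W)
  y.each_col() += b;
  arma::cube out(H, W, F);
  for (int f = 0; f < F; ++f)
    out.slice(f) = arma::reshape(y.row(f), H, W);
  return out;
}

// [[Rcpp::export(name = ".conv3_backward")]]
List conv3_backward(const arma::cube &x, const arma::mat &w,
                    const arma::cube &dy) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int F = w.n_rows;
  arma::mat dym(F, (size_t)H * W);
  for (int f = 0; f < F; ++f)
    dym.row(f) = arma::vectorise(dy.slice(f)).t();
  arma::mat col = im2col3(x);
  arma::mat dw = dym * col.t();            // F x 9C
  arma::vec db = arma::sum(dym, 1);
  arma::mat dcol = w.t() * dym;            // 9C x HW
  arma::cube dx = col2im3(dcol, H, W, C);
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export(name = ".avgpool2_forward")]]
arma::cube avgpool2_forward(const arma::cube &x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  if (H % 2 || W % 2) stop("avgpool2 needs even dimensions");
  arma::cube y(H / 2, W / 2, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W / 2; ++j)
      for (int i = 0; i < H / 2; ++i)
        y(i, j, c) = 0.25 * (x(2 * i, 2 * j, c) + x(2 * i + 1, 2 * j, c) +
                             x(2 * i, 2 * j + 1, c) + x(2 * i + 1, 2 * j + 1, c));
  return y;
}

// [[Rcpp::export(name = ".avgpool2_backward")]]
arma::cube avgpool2_backward(const arma::cube &dy) {
  const int h = dy.n_rows, w = dy.n_cols, C = dy.n_slices;
  arma::cube dx(2 * h, 2 * w, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < w; ++j)
      for (int i = 0; i < h; ++i) {
        const double g = 0.25 * dy(i, j, c);
        dx(2 * i, 2 * j, c) = g;
        dx(2 * i + 1, 2 * j, c) = g;
        dx(2 * i, 2 * j + 1, c) = g;
        dx(2 * i + 1, 2 * j + 1, c) = g;
      }
  return dx;
}

// [[Rcpp::export(name = ".upsample2_forward")]]
arma::cube upsample2_forward(const arma::cube &x) {
  const int h = x.n_rows, w = x.n_cols, C = x.n_slices;
  arma::cube y(2 * h, 2 * w, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < w; ++j)
      for (int i = 0; i < h; ++i) {
        const double v = x(i, j, c);
        y(2 * i, 2 * j, c) = v;
        y(2 * i + 1, 2 * j, c) = v;
        y(2 * i, 2 * j + 1, c) = v;
        y(2 * i + 1, 2 * j + 1, c) = v;
      }
  return y;
}

// [[Rcpp::export(name = ".upsample2_backward")]]
arma::cube upsample2_backward(const arma::cube &dy) {
  const int H = dy.n_rows, W = dy.n_cols, C = dy.n_slices;
  if (H % 2 || W % 2) stop("upsample2 backward needs even dimensions");
  arma::cube dx(H / 2, W / 2, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W / 2; ++j)
      for (int i = 0; i < H / 2; ++i)
        dx(i, j, c) = dy(2 * i, 2 * j, c) + dy(2 * i + 1, 2 * j, c) +
                      dy(2 * i, 2 * j + 1, c) + dy(2 * i + 1, 2 * j + 1, c);
  return dx;
}
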