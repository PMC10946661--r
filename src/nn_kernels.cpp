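// Minimal dense CNN kernels: 2-D convolution, 2x2 max-pool and nearest
// upsample, each with a hand-derived backward pass.  Tensors are H x W x C
// cubes (matching R arrays dim c(H, W, C)); convolution weights are
// (k*k*Cin) x Cout matrices with row index c*k*k + ky*k + kx.  The im2col
// column index is ox*Hout + oy so that reshaping one output row column-major
// recovers the Hout x Wout grid.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static mat im2col(const cube& x, int k, int pad, int stride,
                  int Hout, int Wout) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  mat col(k * k * C, Hout * Wout);
  for (int ox = 0; ox < Wout; ++ox) {
    for (int oy = 0; oy < Hout; ++oy) {
      const int n = ox * Hout + oy;
      double* dst = col.colptr(n);
      for (int c = 0; c < C; ++c) {
        for (int ky = 0; ky < k; ++ky) {
          for (int kx = 0; kx < k; ++kx) {
            const int iy = oy * stride + ky - pad;
            const int ix = ox * stride + kx - pad;
            dst[c * k * k + ky * k + kx] =
              (iy >= 0 && iy < H && ix >= 0 && ix < W) ? x(iy, ix, c) : 0.0;
          }
        }
      }
    }
  }
  return col;
}

static cube col2im(const mat& col, int H, int W, int C, int k, int pad,
                   int stride, int Hout, int Wout) {
  cube x(H, W, C, fill::zeros);
  for (int ox = 0; ox < Wout; ++ox) {
    for (int oy = 0; oy < Hout; ++oy) {
      const int n = ox * Hout + oy;
      const double* src = col.colptr(n);
      for (int c = 0; c < C; ++c) {
        for (int ky = 0; ky < k; ++ky) {
          for (int kx = 0; kx < k; ++kx) {
            const int iy = oy * stride + ky - pad;
            const int ix = ox * stride + kx - pad;
            if (iy >= 0 && iy < H && ix >= 0 && ix < W)
              x(iy, ix, c) += src[c * k * k + ky * k + kx];
          }
        }
      }
    }
  }
  return x;
}

// [[Rcpp::export]]
arma::cube nn_conv2d(const arma::cube& x, const arma::mat& w,
                     const arma::vec& b, int k, int pad, int stride) {
  const int H = x.n_rows, W = x.n_cols;
  const int Hout = (H + 2 * pad - k) / stride + 1;
  const int Wout = (W + 2 * pad - k) / stride + 1;
  const int K = w.n_cols;
  mat col = im2col(x, k, pad, stride, Hout, Wout);
  mat y = w.t() * col;           // K x N
  y.each_col() += b;
  cube out(Hout, Wout, K);
  for (int kk = 0; kk < K; ++kk)
    out.slice(kk) = reshape(y.row(kk), Hout, Wout);
  return out;
}

// [[Rcpp::export]]
Rcpp::List nn_conv2d_bw(const arma::cube& x, const arma::mat& w,
                        const arma::cube& dy, int k, int pad, int stride) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Hout = dy.n_rows, Wout = dy.n_cols, K = dy.n_slices;
  mat dyMat(K, Hout * Wout);
  for (int kk = 0; kk < K; ++kk)
    dyMat.row(kk) = vectorise(dy.slice(kk)).t();
  mat col = im2col(x, k, pad, stride, Hout, Wout);
  mat dw = col * dyMat.t();                       // (k*k*C) x K
  vec db = sum(dyMat, 1);
  mat dcol = w * dyMat;                           // (k*k*C) x N
  cube dx = col2im(dcol, H, W, C, k, pad, stride, Hout, Wout);
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dw") = dw,
                            Rcpp::Named("db") = db);
}

// forward that also hands back the im2col matrix as an external pointer
// (kept on the C++ heap; reused by the backward pass without copying)
// [[Rcpp::export]]
Rcpp::List nn_conv2d_fw(const arma::cube& x, const arma::mat& w,
                        const arma::vec& b, int k, int pad, int stride) {
  const int H = x.n_rows, W = x.n_cols;
  const int Hout = (H + 2 * pad - k) / stride + 1;
  const int Wout = (W + 2 * pad - k) / stride + 1;
  const int K = w.n_cols;
  mat* col = new mat(im2col(x, k, pad, stride, Hout, Wout));
  mat y = w.t() * (*col);
  y.each_col() += b;
  cube out(Hout, Wout, K);
  for (int kk = 0; kk < K; ++kk)
    out.slice(kk) = reshape(y.row(kk), Hout, Wout);
  Rcpp::XPtr<mat> colp(col, true);
  return Rcpp::List::create(Rcpp::Named("y") = out,
                            Rcpp::Named("col") = colp);
}

// [[Rcpp::export]]
Rcpp::List nn_conv2d_bw_col(SEXP colp, const arma::mat& w,
                            const arma::cube& dy, int H, int W, int C,
                            int k, int pad, int stride) {
  Rcpp::XPtr<mat> col(colp);
  const int Hout = dy.n_rows, Wout = dy.n_cols, K = dy.n_slices;
  mat dyMat(K, Hout * Wout);
  for (int kk = 0; kk < K; ++kk)
    dyMat.row(kk) = vectorise(dy.slice(kk)).t();
  mat dw = (*col) * dyMat.t();
  vec db = sum(dyMat, 1);
  mat dcol = w * dyMat;
  cube dx = col2im(dcol, H, W, C, k, pad, stride, Hout, Wout);
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dw") = dw,
                            Rcpp::Named("db") = db);
}

// [[Rcpp::export]]
Rcpp::List nn_maxpool2(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = H / 2, Wo = W / 2;
  cube y(Ho, Wo, C);
  ucube idx(Ho, Wo, C);     // linear index iy + ix*H within the input slice
  for (int c = 0; c < C; ++c) {
    for (int ox = 0; ox < Wo; ++ox) {
      for (int oy = 0; oy < Ho; ++oy) {
        double best = -datum::inf;
        int bi = 0;
        for (int dx2 = 0; dx2 < 2; ++dx2) {
          for (int dy2 = 0; dy2 < 2; ++dy2) {
            const int iy = 2 * oy + dy2, ix = 2 * ox + dx2;
            const double v = x(iy, ix, c);
            if (v > best) { best = v; bi = iy + ix * H; }
          }
        }
        y(oy, ox, c) = best;
        idx(oy, ox, c) = bi;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("y") = y, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export]]
arma::cube nn_maxpool2_bw(const arma::cube& dy, const arma::ucube& idx,
                          int H, int W) {
  const int Ho = dy.n_rows, Wo = dy.n_cols, C = dy.n_slices;
  cube dx(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    double* slice = dx.slice_memptr(c);
    for (int ox = 0; ox < Wo; ++ox)
      for (int oy = 0; oy < Ho; ++oy)
        slice[idx(oy, ox, c)] += dy(oy, ox, c);
  }
  return dx;
}

// [[Rcpp::export]]
arma::cube nn_upsample2(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  cube y(2 * H, 2 * W, C);
  for (int c = 0; c < C; ++c)
    for (int ix = 0; ix < W; ++ix)
      for (int iy = 0; iy < H; ++iy) {
        const double v = x(iy, ix, c);
        y(2 * iy, 2 * ix, c) = v;
        y(2 * iy + 1, 2 * ix, c) = v;
        y(2 * iy, 2 * ix + 1, c) = v;
        y(2 * iy + 1, 2 * ix + 1, c) = v;
      }
  return y;
}

// [[Rcpp::export]]
arma::cube nn_upsample2_bw(const arma::cube& dy) {
  const int Ho = dy.n_rows / 2, Wo = dy.n_cols / 2, C = dy.n_slices;
  cube dx(Ho, Wo, C);
  for (int c = 0; c < C; ++c)
    for (int ix = 0; ix < Wo; ++ix)
      for (int iy = 0; iy < Ho; ++iy)
        dx(iy, ix, c) = dy(2 * iy, 2 * ix, c) + dy(2 * iy + 1, 2 * ix, c) +
                        dy(2 * iy, 2 * ix + 1, c) +
                        dy(2 * iy + 1, 2 * ix + 1, c);
  return dx;
}

// per-pixel across-channel normalization + leaky ReLU, fused.
// channel-sequential passes keep memory access contiguous.
// [[Rcpp::export]]
Rcpp::List nn_cnorm_leaky(const arma::cube& z, double eps, double slope) {
  const int np = z.n_rows * z.n_cols, C = z.n_slices;
  const double* zp = z.memptr();
  cube n(z.n_rows, z.n_cols, C), y(z.n_rows, z.n_cols, C);
  vec m(np, fill::zeros), sdv(np, fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double* zc = zp + (size_t)c * np;
    for (int i = 0; i < np; ++i) {
      m[i] += zc[i];
      sdv[i] += zc[i] * zc[i];
    }
  }
  for (int i = 0; i < np; ++i) {
    m[i] /= C;
    sdv[i] = std::sqrt(sdv[i] / C - m[i] * m[i] + eps);
  }
  for (int c = 0; c < C; ++c) {
    const double* zc = zp + (size_t)c * np;
    double* nc = n.memptr() + (size_t)c * np;
    double* yc = y.memptr() + (size_t)c * np;
    for (int i = 0; i < np; ++i) {
      const double nv = (zc[i] - m[i]) / sdv[i];
      nc[i] = nv;
      yc[i] = nv > 0 ? nv : slope * nv;
    }
  }
  return Rcpp::List::create(Rcpp::Named("y") = y, Rcpp::Named("n") = n,
                            Rcpp::Named("sdv") = sdv);
}

// [[Rcpp::export]]
arma::cube nn_cnorm_leaky_bw(const arma::cube& n, const arma::vec& sdv,
                             const arma::cube& dy, double slope) {
  const int np = n.n_rows * n.n_cols, C = n.n_slices;
  cube dz(n.n_rows, n.n_cols, C);
  const double* npr = n.memptr();
  const double* dyp = dy.memptr();
  vec mdn(np, fill::zeros), mdnn(np, fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double* nc = npr + (size_t)c * np;
    const double* dc = dyp + (size_t)c * np;
    for (int i = 0; i < np; ++i) {
      const double d = dc[i] * (nc[i] > 0 ? 1.0 : slope);
      mdn[i] += d;
      mdnn[i] += d * nc[i];
    }
  }
  for (int i = 0; i < np; ++i) { mdn[i] /= C; mdnn[i] /= C; }
  for (int c = 0; c < C; ++c) {
    const double* nc = npr + (size_t)c * np;
    const double* dc = dyp + (size_t)c * np;
    double* zc = dz.memptr() + (size_t)c * np;
    for (int i = 0; i < np; ++i) {
      const double d = dc[i] * (nc[i] > 0 ? 1.0 : slope);
      zc[i] = (d - mdn[i] - nc[i] * mdnn[i]) / sdv[i];
    }
  }
  return dz;
}
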