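// Low-level numerical kernels: stride-1 same-padding 2D convolution with
// explicit backward passes (im2col + BLAS gemm), 2x2 max pooling, 2x nearest
// upsampling, and an even-odd scanline polygon rasterizer.
//
// Tensor layout: arma::cube with (rows = H, cols = W, slices = channels).
// Kernel matrix layout: [K, C*kh*kw], patch index = c*kh*kw + dj*kh + di,
// which matches as.vector() of an R array with dim (kh, kw, C) per output
// channel.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Patch matrix in transposed layout: (H*W) x (C*kh*kw). Column r of the
// result holds input values at offset (di - pad, dj - pad) of channel c,
// for every output pixel; the inner i-loop copies contiguous memory.
static arma::mat im2col_t(const arma::cube& x, int kh, int kw, int pad) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::mat cols(H * W, C * kh * kw, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double* xc = x.slice_memptr(c);
    for (int dj = 0; dj < kw; ++dj) {
      for (int di = 0; di < kh; ++di) {
        const int r = c * kh * kw + dj * kh + di;
        double* dst0 = cols.colptr(r);
        const int i0 = std::max(0, pad - di);
        const int i1 = std::min(H - 1, H - 1 + pad - di);
        if (i1 < i0) continue;
        for (int j = 0; j < W; ++j) {
          const int sj = j + dj - pad;
          if (sj < 0 || sj >= W) continue;
          std::memcpy(dst0 + i0 + j * H,
                      xc + (i0 + di - pad) + sj * H,
                      (i1 - i0 + 1) * sizeof(double));
        }
      }
    }
  }
  return cols;
}

// [[Rcpp::export]]
arma::cube conv2d_fw_cpp(const arma::cube& x, const arma::mat& w,
                         const arma::vec& b, int kh, int kw, int pad) {
  const int H = x.n_rows, W = x.n_cols;
  const int K = w.n_rows;
  arma::mat cols = im2col_t(x, kh, kw, pad);
  arma::mat out = cols * w.t();      // (H*W) x K
  out.each_row() += b.t();
  return arma::cube(out.memptr(), H, W, K);
}

// [[Rcpp::export]]
List conv2d_bw_cpp(const arma::cube& x, const arma::mat& w,
                   const arma::cube& dout, int kh, int kw, int pad) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int K = w.n_rows;
  const arma::mat dout_t(const_cast<double*>(dout.memptr()), H * W, K,
                         false, true);
  arma::mat cols = im2col_t(x, kh, kw, pad);
  arma::mat dw = dout_t.t() * cols;            // K x (C*kh*kw)
  arma::vec db = arma::sum(dout_t, 0).t();
  arma::mat dcols = dout_t * w;                // (H*W) x (C*kh*kw)
  arma::cube dx(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    double* dxc = dx.slice_memptr(c);
    for (int dj = 0; dj < kw; ++dj) {
      for (int di = 0; di < kh; ++di) {
        const int r = c * kh * kw + dj * kh + di;
        const double* src0 = dcols.colptr(r);
        const int i0 = std::max(0, pad - di);
        const int i1 = std::min(H - 1, H - 1 + pad - di);
        if (i1 < i0) continue;
        for (int j = 0; j < W; ++j) {
          const int sj = j + dj - pad;
          if (sj < 0 || sj >= W) continue;
          double* d = dxc + (i0 + di - pad) + sj * H;
          const double* s = src0 + i0 + j * H;
          for (int i = 0; i <= i1 - i0; ++i) d[i] += s[i];
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export]]
List maxpool2_fw_cpp(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = H / 2, Wo = W / 2;
  arma::cube y(Ho, Wo, C);
  arma::ucube idx(Ho, Wo, C);        // linear index into the input slice
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        double best = -arma::datum::inf;
        unsigned int bi = 0;
        for (int dj = 0; dj < 2; ++dj) {
          for (int di = 0; di < 2; ++di) {
            const int si = 2 * i + di, sj = 2 * j + dj;
            const double v = x(si, sj, c);
            if (v > best) { best = v; bi = si + sj * H; }
          }
        }
        y(i, j, c) = best;
        idx(i, j, c) = bi;
      }
    }
  }
  return List::create(_["out"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
arma::cube maxpool2_bw_cpp(const arma::cube& dout, const arma::ucube& idx,
                           int H, int W) {
  const int C = dout.n_slices;
  arma::cube dx(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const arma::mat& dm = dout.slice(c);
    const arma::umat& im = idx.slice(c);
    arma::mat& dxc = dx.slice(c);
    for (arma::uword p = 0; p < dm.n_elem; ++p)
      dxc(im(p)) += dm(p);
  }
  return dx;
}

// [[Rcpp::export]]
arma::cube up2_fw_cpp(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::cube y(2 * H, 2 * W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        const double v = x(i, j, c);
        y(2 * i, 2 * j, c) = v;
        y(2 * i + 1, 2 * j, c) = v;
        y(2 * i, 2 * j + 1, c) = v;
        y(2 * i + 1, 2 * j + 1, c) = v;
      }
  return y;
}

// [[Rcpp::export]]
arma::cube up2_bw_cpp(const arma::cube& dout) {
  const int H = dout.n_rows / 2, W = dout.n_cols / 2, C = dout.n_slices;
  arma::cube dx(H, W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i)
        dx(i, j, c) = dout(2 * i, 2 * j, c) + dout(2 * i + 1, 2 * j, c) +
                      dout(2 * i, 2 * j + 1, c) + dout(2 * i + 1, 2 * j + 1, c);
  return dx;
}

// Even-odd scanline fill of a closed polygon. Vertices are (x = column,
// y = row) in pixel-center coordinates (1-based); pixel (r, c) is filled
// when its center lies inside the polygon.
// [[Rcpp::export]]
IntegerMatrix fill_polygon_cpp(NumericVector px, NumericVector py,
                               int nrow, int ncol) {
  const int n = px.size();
  IntegerMatrix out(nrow, ncol);
  std::vector<double> xs;
  for (int r = 1; r <= nrow; ++r) {
    xs.clear();
    const double y = r;
    for (int e = 0; e < n; ++e) {
      const int e2 = (e + 1) % n;
      double y1 = py[e], y2 = py[e2], x1 = px[e], x2 = px[e2];
      if (y1 == y2) continue;
      // half-open rule: edge covers [min(y1,y2), max(y1,y2))
      if ((y >= y1 && y < y2) || (y >= y2 && y < y1))
        xs.push_back(x1 + (y - y1) * (x2 - x1) / (y2 - y1));
    }
    if (xs.empty()) continue;
    std::sort(xs.begin(), xs.end());
    for (size_t p = 0; p + 1 < xs.size(); p += 2) {
      int c0 = (int)std::ceil(xs[p] - 1e-9);
      int c1 = (int)std::floor(xs[p + 1] + 1e-9);
      if (c0 < 1) c0 = 1;
      if (c1 > ncol) c1 = ncol;
      for (int c = c0; c <= c1; ++c) out(r - 1, c - 1) = 1;
    }
  }
  return out;
}
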