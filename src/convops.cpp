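// Convolution kernels for the 3D U-net and small image utilities.
//
// Volumes are channel-major matrices: column v holds the channel vector at
// spatial linear index v = ix + nx*(iy + ny*iz). Convolutions gather a
// cache-sized chunk of output rows at a time into a reused im2col buffer
// (k^3*Cin x ox*ych), so the working set stays cache-resident and the
// heavy lifting is a sequence of mid-sized GEMMs. Transposed convolutions
// reuse the same gather/scatter with input and output roles swapped.
//
// im2col row order is offset-major with channel fastest:
//   r = (kx + k*(ky + k*kz))*C + c
// and conv weights are Cout x (k^3*Cin) in that column order; transposed
// conv weights are (k^3*Cout) x Cin.

#include <RcppArmadillo.h>
#include <queue>
#include <algorithm>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_extent(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

// rows of the output plane processed per GEMM: keep the gather buffer
// around 2 MB so it stays cache-resident while the GEMMs remain mid-sized
static inline int row_chunk(int buf_rows, int ox, int oy) {
  double per_row = (double)buf_rows * ox * 8.0;
  int ych = (int)(2.0 * 1024 * 1024 / per_row);
  if (ych < 1) ych = 1;
  if (ych > oy) ych = oy;
  return ych;
}

// gather the im2col block for output row (oy, oz): buf is (C*k^3) x ox
static void gather_row(const arma::mat& x, arma::mat& buf,
                       int nx, int ny, int nz, int ox,
                       int oy, int oz, int k, int stride, int pad,
                       int col0) {
  const int C = x.n_rows;
  for (int kz = 0; kz < k; ++kz) {
    const int iz = oz * stride + kz - pad;
    for (int ky = 0; ky < k; ++ky) {
      const int iy = oy * stride + ky - pad;
      const bool yz_ok = iz >= 0 && iz < nz && iy >= 0 && iy < ny;
      for (int kx = 0; kx < k; ++kx) {
        const int r0 = (kx + k * (ky + k * kz)) * C;
        for (int o = 0; o < ox; ++o) {
          const int ix = o * stride + kx - pad;
          double* dst = buf.colptr(col0 + o) + r0;
          if (!yz_ok || ix < 0 || ix >= nx) {
            std::fill(dst, dst + C, 0.0);
          } else {
            const double* src = x.colptr(ix + nx * (iy + ny * iz));
            std::copy(src, src + C, dst);
          }
        }
      }
    }
  }
}

// scatter-add the transpose operation of gather_row
static void scatter_row(arma::mat& x, const arma::mat& buf,
                        int nx, int ny, int nz, int ox,
                        int oy, int oz, int k, int stride, int pad,
                        int col0) {
  const int C = x.n_rows;
  for (int kz = 0; kz < k; ++kz) {
    const int iz = oz * stride + kz - pad;
    if (iz < 0 || iz >= nz) continue;
    for (int ky = 0; ky < k; ++ky) {
      const int iy = oy * stride + ky - pad;
      if (iy < 0 || iy >= ny) continue;
      for (int kx = 0; kx < k; ++kx) {
        const int r0 = (kx + k * (ky + k * kz)) * C;
        for (int o = 0; o < ox; ++o) {
          const int ix = o * stride + kx - pad;
          if (ix < 0 || ix >= nx) continue;
          const double* src = buf.colptr(col0 + o) + r0;
          double* dst = x.colptr(ix + nx * (iy + ny * iz));
          for (int c = 0; c < C; ++c) dst[c] += src[c];
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv3_fwd")]]
arma::mat conv3_fwd(const arma::mat& x, const arma::mat& w,
                    const arma::vec& bias, const IntegerVector& dims,
                    int k, int stride, int pad) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int ox = out_extent(nx, k, stride, pad);
  const int oy = out_extent(ny, k, stride, pad);
  const int oz = out_extent(nz, k, stride, pad);
  const int C = x.n_rows;
  arma::mat y(w.n_rows, (size_t)ox * oy * oz);
  const int ych = row_chunk(C * k * k * k, ox, oy);
  arma::mat buf(C * k * k * k, (size_t)ox * ych);
  for (int z = 0; z < oz; ++z) {
    for (int y0 = 0; y0 < oy; y0 += ych) {
      const int m = std::min(ych, oy - y0);
      for (int yy = 0; yy < m; ++yy)
        gather_row(x, buf, nx, ny, nz, ox, y0 + yy, z, k, stride, pad, yy * ox);
      const size_t c0 = (size_t)ox * (y0 + (size_t)oy * z);
      y.cols(c0, c0 + (size_t)ox * m - 1) = w * buf.cols(0, (size_t)ox * m - 1);
    }
  }
  y.each_col() += bias;
  return y;
}

// gradient wrt input: dx = scatter(W^T dY)
// [[Rcpp::export(name = ".conv3_bwd_input")]]
arma::mat conv3_bwd_input(const arma::mat& dy, const arma::mat& w,
                          const IntegerVector& dims_in,
                          int k, int stride, int pad) {
  const int nx = dims_in[0], ny = dims_in[1], nz = dims_in[2];
  const int ox = out_extent(nx, k, stride, pad);
  const int oy = out_extent(ny, k, stride, pad);
  const int oz = out_extent(nz, k, stride, pad);
  const int C = w.n_cols / (k * k * k);
  arma::mat dx(C, (size_t)nx * ny * nz, arma::fill::zeros);
  const int ych = row_chunk(C * k * k * k, ox, oy);
  arma::mat buf;
  for (int z = 0; z < oz; ++z) {
    for (int y0 = 0; y0 < oy; y0 += ych) {
      const int m = std::min(ych, oy - y0);
      const size_t c0 = (size_t)ox * (y0 + (size_t)oy * z);
      buf = w.t() * dy.cols(c0, c0 + (size_t)ox * m - 1);
      for (int yy = 0; yy < m; ++yy)
        scatter_row(dx, buf, nx, ny, nz, ox, y0 + yy, z, k, stride, pad, yy * ox);
    }
  }
  return dx;
}

// gradient wrt weights: dW = dY gather(X)^T
// [[Rcpp::export(name = ".conv3_bwd_weight")]]
arma::mat conv3_bwd_weight(const arma::mat& x, const arma::mat& dy,
                           const IntegerVector& dims,
                           int k, int stride, int pad) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int ox = out_extent(nx, k, stride, pad);
  const int oy = out_extent(ny, k, stride, pad);
  const int oz = out_extent(nz, k, stride, pad);
  const int C = x.n_rows;
  arma::mat dw(dy.n_rows, C * k * k * k, arma::fill::zeros);
  const int ych = row_chunk(C * k * k * k, ox, oy);
  arma::mat buf(C * k * k * k, (size_t)ox * ych);
  for (int z = 0; z < oz; ++z) {
    for (int y0 = 0; y0 < oy; y0 += ych) {
      const int m = std::min(ych, oy - y0);
      for (int yy = 0; yy < m; ++yy)
        gather_row(x, buf, nx, ny, nz, ox, y0 + yy, z, k, stride, pad, yy * ox);
      const size_t c0 = (size_t)ox * (y0 + (size_t)oy * z);
      dw += dy.cols(c0, c0 + (size_t)ox * m - 1) * buf.cols(0, (size_t)ox * m - 1).t();
    }
  }
  return dw;
}

// transposed conv forward (geometry of a conv big -> small, run backward):
// y_big = scatter(Wt x_small) + bias
// [[Rcpp::export(name = ".tconv3_fwd")]]
arma::mat tconv3_fwd(const arma::mat& x, const arma::mat& wt,
                     const arma::vec& bias, const IntegerVector& dims_out,
                     int k, int stride, int pad) {
  const int nx = dims_out[0], ny = dims_out[1], nz = dims_out[2];
  const int ox = out_extent(nx, k, stride, pad);
  const int oy = out_extent(ny, k, stride, pad);
  const int oz = out_extent(nz, k, stride, pad);
  const int C = wt.n_rows / (k * k * k);
  arma::mat y(C, (size_t)nx * ny * nz, arma::fill::zeros);
  const int ych = row_chunk((int)wt.n_rows, ox, oy);
  arma::mat buf;
  for (int z = 0; z < oz; ++z) {
    for (int y0 = 0; y0 < oy; y0 += ych) {
      const int m = std::min(ych, oy - y0);
      const size_t c0 = (size_t)ox * (y0 + (size_t)oy * z);
      buf = wt * x.cols(c0, c0 + (size_t)ox * m - 1);
      for (int yy = 0; yy < m; ++yy)
        scatter_row(y, buf, nx, ny, nz, ox, y0 + yy, z, k, stride, pad, yy * ox);
    }
  }
  y.each_col() += bias;
  return y;
}

// transposed conv gradient wrt input: dx_small = Wt^T gather(dy_big)
// [[Rcpp::export(name = ".tconv3_bwd_input")]]
arma::mat tconv3_bwd_input(const arma::mat& dy, const arma::mat& wt,
                           const IntegerVector& dims_out,
                           int k, int stride, int pad) {
  const int nx = dims_out[0], ny = dims_out[1], nz = dims_out[2];
  const int ox = out_extent(nx, k, stride, pad);
  const int oy = out_extent(ny, k, stride, pad);
  const int oz = out_extent(nz, k, stride, pad);
  const int C = dy.n_rows;
  arma::mat dx(wt.n_cols, (size_t)ox * oy * oz);
  const int ych = row_chunk(C * k * k * k, ox, oy);
  arma::mat buf(C * k * k * k, (size_t)ox * ych);
  for (int z = 0; z < oz; ++z) {
    for (int y0 = 0; y0 < oy; y0 += ych) {
      const int m = std::min(ych, oy - y0);
      for (int yy = 0; yy < m; ++yy)
        gather_row(dy, buf, nx, ny, nz, ox, y0 + yy, z, k, stride, pad, yy * ox);
      const size_t c0 = (size_t)ox * (y0 + (size_t)oy * z);
      dx.cols(c0, c0 + (size_t)ox * m - 1) = wt.t() * buf.cols(0, (size_t)ox * m - 1);
    }
  }
  return dx;
}

// transposed conv gradient wrt weights: dWt = gather(dy_big) x_small^T
// [[Rcpp::export(name = ".tconv3_bwd_weight")]]
arma::mat tconv3_bwd_weight(const arma::mat& x, const arma::mat& dy,
                            const IntegerVector& dims_out,
                            int k, int stride, int pad) {
  const int nx = dims_out[0], ny = dims_out[1], nz = dims_out[2];
  const int ox = out_extent(nx, k, stride, pad);
  const int oy = out_extent(ny, k, stride, pad);
  const int oz = out_extent(nz, k, stride, pad);
  const int C = dy.n_rows;
  arma::mat dwt(C * k * k * k, x.n_rows, arma::fill::zeros);
  const int ych = row_chunk(C * k * k * k, ox, oy);
  arma::mat buf(C * k * k * k, (size_t)ox * ych);
  for (int z = 0; z < oz; ++z) {
    for (int y0 = 0; y0 < oy; y0 += ych) {
      const int m = std::min(ych, oy - y0);
      for (int yy = 0; yy < m; ++yy)
        gather_row(dy, buf, nx, ny, nz, ox, y0 + yy, z, k, stride, pad, yy * ox);
      const size_t c0 = (size_t)ox * (y0 + (size_t)oy * z);
      dwt += buf.cols(0, (size_t)ox * m - 1) * x.cols(c0, c0 + (size_t)ox * m - 1).t();
    }
  }
  return dwt;
}

// Separable 1D convolution along one axis of a 3D volume with replicate
// (nearest) edge padding; kernel length must be odd.
// [[Rcpp::export(name = ".sepconv_axis")]]
NumericVector sepconv_axis(const NumericVector& x, const IntegerVector& dims,
                           const NumericVector& kernel, int axis) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int klen = kernel.size();
  const int half = klen / 2;
  NumericVector out(x.size());
  const int n_ax = dims[axis];
  int stride_arr[3] = {1, nx, nx * ny};
  const int stride = stride_arr[axis];
  for (int iz = 0; iz < nz; ++iz) {
    for (int iy = 0; iy < ny; ++iy) {
      for (int ix = 0; ix < nx; ++ix) {
        const int idx = ix + nx * (iy + ny * iz);
        int pos_arr[3] = {ix, iy, iz};
        const int pos = pos_arr[axis];
        double acc = 0.0;
        for (int t = -half; t <= half; ++t) {
          int p = pos + t;
          if (p < 0) p = 0;
          if (p >= n_ax) p = n_ax - 1;
          acc += kernel[t + half] * x[idx + (p - pos) * stride];
        }
        out[idx] = acc;
      }
    }
  }
  return out;
}

// 6-connected components of a binary 3D volume; returns integer labels
// (0 = background), labels ordered by first-encountered voxel.
// [[Rcpp::export(name = ".label_components6")]]
IntegerVector label_components6(const LogicalVector& mask, const IntegerVector& dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  IntegerVector lab(n, 0);
  int next_label = 0;
  std::queue<int> q;
  for (int s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next_label;
    lab[s] = next_label;
    q.push(s);
    while (!q.empty()) {
      int v = q.front(); q.pop();
      int ix = v % nx, iy = (v / nx) % ny, iz = v / (nx * ny);
      const int nb[6][3] = {{ix - 1, iy, iz}, {ix + 1, iy, iz}, {ix, iy - 1, iz},
                            {ix, iy + 1, iz}, {ix, iy, iz - 1}, {ix, iy, iz + 1}};
      for (int j = 0; j < 6; ++j) {
        int jx = nb[j][0], jy = nb[j][1], jz = nb[j][2];
        if (jx < 0 || jx >= nx || jy < 0 || jy >= ny || jz < 0 || jz >= nz) continue;
        int w = jx + nx * (jy + ny * jz);
        if (mask[w] && lab[w] == 0) { lab[w] = next_label; q.push(w); }
      }
    }
  }
  lab.attr("n_labels") = next_label;
  return lab;
}
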