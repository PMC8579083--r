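// Low-level numerical kernels: convolution (im2col + single-precision GEMM),
// max-pooling, nearest-neighbour upsampling, affine resampling, 26-connected
// component labelling and slice-wise hole filling.
//
// Feature maps are stored as N x C matrices (one column per channel, voxels in
// column-major x-fastest order).  Convolution weights are K x Cout matrices
// with K = Cin*kx*ky*kz and kernel-tap index
//   k = ((c*kz + oz)*ky + oy)*kx + ox.

#include <RcppArmadillo.h>
#include <functional>
#include <unordered_map>
#include <vector>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int idx3(int x, int y, int z, int nx, int ny) {
  return (z * ny + y) * nx + x;
}

// Fill (or scatter from) the im2col matrix for a z-slab [z0, z1).
// colT is Mc x K with Mc = nx*ny*(z1-z0).  When scatter is false, colT is
// filled from X; when true, colT is accumulated back into X (col2im).
static void im2col_slab(arma::fmat& colT, arma::fmat& X,
                        int nx, int ny, int nz,
                        int kx, int ky, int kz,
                        int z0, int z1, bool scatter) {
  const int cx = kx / 2, cy = ky / 2, cz = kz / 2;
  const int Cin = X.n_cols;
  for (int c = 0; c < Cin; ++c) {
    float* src = X.colptr(c);
    for (int oz = 0; oz < kz; ++oz)
      for (int oy = 0; oy < ky; ++oy)
        for (int ox = 0; ox < kx; ++ox) {
          const int k = ((c * kz + oz) * ky + oy) * kx + ox;
          float* dst = colT.colptr(k);
          const int oxo = ox - cx;
          const int xlo = std::max(0, -oxo), xhi = std::min(nx, nx - oxo);
          for (int z = z0; z < z1; ++z) {
            const int iz = z + oz - cz;
            const bool zok = (iz >= 0 && iz < nz);
            for (int y = 0; y < ny; ++y) {
              const int iy = y + oy - cy;
              const int m0 = ((z - z0) * ny + y) * nx;
              if (!zok || iy < 0 || iy >= ny) {
                if (!scatter) std::fill(dst + m0, dst + m0 + nx, 0.0f);
                continue;
              }
              const int in0 = (iz * ny + iy) * nx + oxo;
              if (!scatter) {
                std::fill(dst + m0, dst + m0 + xlo, 0.0f);
                if (xhi > xlo)
                  std::copy(src + in0 + xlo, src + in0 + xhi, dst + m0 + xlo);
                std::fill(dst + m0 + xhi, dst + m0 + nx, 0.0f);
              } else {
                for (int x = xlo; x < xhi; ++x) src[in0 + x] += dst[m0 + x];
              }
            }
          }
        }
  }
}

static int slab_height(int nx, int ny, int K) {
  // cap the im2col slab at ~48 MB of floats
  double per_slice = (double)nx * ny * K * 4.0;
  int h = (int)std::floor(48.0 * 1024 * 1024 / std::max(per_slice, 1.0));
  return std::max(1, h);
}

// [[Rcpp::export(rng = false)]]
NumericMatrix cpp_conv_fw(const arma::mat& X, const arma::mat& W,
                          const arma::vec& b, const IntegerVector& dims,
                          const IntegerVector& ksz) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int kx = ksz[0], ky = ksz[1], kz = ksz[2];
  const int K = W.n_rows, Cout = W.n_cols;
  const int N = nx * ny * nz;
  if ((int)X.n_rows != N) stop("conv_fw: X rows do not match dims");
  if ((int)X.n_cols * kx * ky * kz != K) stop("conv_fw: W rows mismatch");
  arma::fmat Xf = arma::conv_to<arma::fmat>::from(X);
  arma::fmat Wf = arma::conv_to<arma::fmat>::from(W);
  arma::frowvec bf = arma::conv_to<arma::frowvec>::from(b.t());
  arma::fmat Yf(N, Cout);
  const int hz = slab_height(nx, ny, K);
  arma::fmat colT(nx * ny * std::min(hz, nz), K);
  for (int z0 = 0; z0 < nz; z0 += hz) {
    const int z1 = std::min(nz, z0 + hz);
    const int Mc = nx * ny * (z1 - z0);
    if ((int)colT.n_rows != Mc) colT.set_size(Mc, K);
    im2col_slab(colT, Xf, nx, ny, nz, kx, ky, kz, z0, z1, false);
    Yf.rows(z0 * nx * ny, z1 * nx * ny - 1) = colT * Wf;
  }
  Yf.each_row() += bf;
  return wrap(arma::conv_to<arma::mat>::from(Yf));
}

// [[Rcpp::export(rng = false)]]
List cpp_conv_bw(const arma::mat& X, const arma::mat& W, const arma::mat& dY,
                 const IntegerVector& dims, const IntegerVector& ksz) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int kx = ksz[0], ky = ksz[1], kz = ksz[2];
  const int K = W.n_rows, Cout = W.n_cols;
  const int N = nx * ny * nz;
  arma::fmat Xf = arma::conv_to<arma::fmat>::from(X);
  arma::fmat Wf = arma::conv_to<arma::fmat>::from(W);
  arma::fmat dYf = arma::conv_to<arma::fmat>::from(dY);
  arma::fmat dWf(K, Cout, arma::fill::zeros);
  arma::fmat dXf(N, Xf.n_cols, arma::fill::zeros);
  const int hz = slab_height(nx, ny, K);
  arma::fmat colT;
  for (int z0 = 0; z0 < nz; z0 += hz) {
    const int z1 = std::min(nz, z0 + hz);
    const int Mc = nx * ny * (z1 - z0);
    colT.set_size(Mc, K);
    im2col_slab(colT, Xf, nx, ny, nz, kx, ky, kz, z0, z1, false);
    arma::fmat dYc = dYf.rows(z0 * nx * ny, z1 * nx * ny - 1);
    dWf += colT.t() * dYc;
    colT = dYc * Wf.t();  // Mc x K -> scatter back
    im2col_slab(colT, dXf, nx, ny, nz, kx, ky, kz, z0, z1, true);
  }
  arma::frowvec dbf = arma::sum(dYf, 0);
  return List::create(
      _["dX"] = wrap(arma::conv_to<arma::mat>::from(dXf)),
      _["dW"] = wrap(arma::conv_to<arma::mat>::from(dWf)),
      _["db"] = wrap(arma::conv_to<arma::vec>::from(dbf.t())));
}

// [[Rcpp::export(rng = false)]]
List cpp_maxpool_fw(const arma::mat& X, const IntegerVector& dims,
                    const IntegerVector& f) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int fx = f[0], fy = f[1], fz = f[2];
  const int ox = (nx + fx - 1) / fx, oy = (ny + fy - 1) / fy,
            oz = (nz + fz - 1) / fz;
  const int C = X.n_cols, No = ox * oy * oz;
  NumericMatrix Y(No, C);
  IntegerMatrix idx(No, C);
  for (int c = 0; c < C; ++c) {
    const double* src = X.colptr(c);
    for (int z = 0; z < oz; ++z)
      for (int y = 0; y < oy; ++y)
        for (int x = 0; x < ox; ++x) {
          double best = -std::numeric_limits<double>::infinity();
          int bi = -1;
          for (int dz = 0; dz < fz && z * fz + dz < nz; ++dz)
            for (int dy = 0; dy < fy && y * fy + dy < ny; ++dy)
              for (int dx = 0; dx < fx && x * fx + dx < nx; ++dx) {
                const int i = idx3(x * fx + dx, y * fy + dy, z * fz + dz, nx, ny);
                if (src[i] > best) { best = src[i]; bi = i; }
              }
          const int m = idx3(x, y, z, ox, oy);
          Y(m, c) = best;
          idx(m, c) = bi;
        }
  }
  return List::create(_["Y"] = Y, _["idx"] = idx,
                      _["dims_out"] = IntegerVector::create(ox, oy, oz));
}

// [[Rcpp::export(rng = false)]]
NumericMatrix cpp_maxpool_bw(const arma::mat& dY, const IntegerMatrix& idx,
                             int Nin) {
  const int C = dY.n_cols, No = dY.n_rows;
  NumericMatrix dX(Nin, C);
  for (int c = 0; c < C; ++c)
    for (int m = 0; m < No; ++m) dX(idx(m, c), c) += dY(m, c);
  return dX;
}

// [[Rcpp::export(rng = false)]]
NumericMatrix cpp_upsample_fw(const arma::mat& X, const IntegerVector& dims_in,
                              const IntegerVector& f,
                              const IntegerVector& dims_out) {
  const int nxi = dims_in[0], nyi = dims_in[1];
  const int nxo = dims_out[0], nyo = dims_out[1], nzo = dims_out[2];
  const int C = X.n_cols;
  NumericMatrix Y(nxo * nyo * nzo, C);
  for (int c = 0; c < C; ++c) {
    const double* src = X.colptr(c);
    for (int z = 0; z < nzo; ++z)
      for (int y = 0; y < nyo; ++y)
        for (int x = 0; x < nxo; ++x)
          Y(idx3(x, y, z, nxo, nyo), c) =
              src[idx3(x / f[0], y / f[1], z / f[2], nxi, nyi)];
  }
  return Y;
}

// [[Rcpp::export(rng = false)]]
NumericMatrix cpp_upsample_bw(const arma::mat& dY, const IntegerVector& dims_in,
                              const IntegerVector& f,
                              const IntegerVector& dims_out) {
  const int nxi = dims_in[0], nyi = dims_in[1], nzi = dims_in[2];
  const int nxo = dims_out[0], nyo = dims_out[1], nzo = dims_out[2];
  const int C = dY.n_cols;
  NumericMatrix dX(nxi * nyi * nzi, C);
  for (int c = 0; c < C; ++c) {
    const double* src = dY.colptr(c);
    for (int z = 0; z < nzo; ++z)
      for (int y = 0; y < nyo; ++y)
        for (int x = 0; x < nxo; ++x)
          dX(idx3(x / f[0], y / f[1], z / f[2], nxi, nyi), c) +=
              src[idx3(x, y, z, nxo, nyo)];
  }
  return dX;
}

// Resample a volume through an affine voxel-to-voxel map.  A is 3x4 and maps
// 0-based output voxel indices (x,y,z,1) to 0-based input voxel coordinates.
// Voxels mapping outside the input grid get `fill`.
// [[Rcpp::export(rng = false)]]
NumericVector cpp_resample_affine(const NumericVector& vol,
                                  const IntegerVector& dims_in,
                                  const NumericMatrix& A,
                                  const IntegerVector& dims_out,
                                  bool nearest, double fill) {
  const int nxi = dims_in[0], nyi = dims_in[1], nzi = dims_in[2];
  const int nxo = dims_out[0], nyo = dims_out[1], nzo = dims_out[2];
  NumericVector out((R_xlen_t)nxo * nyo * nzo);
  const double* v = vol.begin();
  double* o = out.begin();
  for (int z = 0; z < nzo; ++z)
    for (int y = 0; y < nyo; ++y)
      for (int x = 0; x < nxo; ++x) {
        const double xi = A(0, 0) * x + A(0, 1) * y + A(0, 2) * z + A(0, 3);
        const double yi = A(1, 0) * x + A(1, 1) * y + A(1, 2) * z + A(1, 3);
        const double zi = A(2, 0) * x + A(2, 1) * y + A(2, 2) * z + A(2, 3);
        const int m = idx3(x, y, z, nxo, nyo);
        if (nearest) {
          const int ix = (int)std::lround(xi), iy = (int)std::lround(yi),
                    iz = (int)std::lround(zi);
          o[m] = (ix >= 0 && ix < nxi && iy >= 0 && iy < nyi && iz >= 0 &&
                  iz < nzi)
                     ? v[idx3(ix, iy, iz, nxi, nyi)]
                     : fill;
        } else {
          const int x0 = (int)std::floor(xi), y0 = (int)std::floor(yi),
                    z0 = (int)std::floor(zi);
          if (x0 < -1 || x0 > nxi - 1 || y0 < -1 || y0 > nyi - 1 || z0 < -1 ||
              z0 > nzi - 1) {
            o[m] = fill;
            continue;
          }
          const double fxr = xi - x0, fyr = yi - y0, fzr = zi - z0;
          double acc = 0.0;
          for (int dz = 0; dz <= 1; ++dz)
            for (int dy = 0; dy <= 1; ++dy)
              for (int dx = 0; dx <= 1; ++dx) {
                const int xx = x0 + dx, yy = y0 + dy, zz = z0 + dz;
                const double w = (dx ? fxr : 1 - fxr) * (dy ? fyr : 1 - fyr) *
                                 (dz ? fzr : 1 - fzr);
                const double val =
                    (xx >= 0 && xx < nxi && yy >= 0 && yy < nyi && zz >= 0 &&
                     zz < nzi)
                        ? v[idx3(xx, yy, zz, nxi, nyi)]
                        : fill;
                acc += w * val;
              }
          o[m] = acc;
        }
      }
  return out;
}

// 26-connected component labelling by union-find; labels are contiguous
// positive integers in scan order of each component's first voxel.
// [[Rcpp::export(rng = false)]]
IntegerVector cpp_label_components(const IntegerVector& mask,
                                   const IntegerVector& dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int N = nx * ny * nz;
  std::vector<int> parent(N, -1);
  std::function<int(int)> find = [&](int i) {
    while (parent[i] != i) {
      parent[i] = parent[parent[i]];
      i = parent[i];
    }
    return i;
  };
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        const int i = idx3(x, y, z, nx, ny);
        if (mask[i] == 0) continue;
        parent[i] = i;
        // half-neighbourhood: already-visited neighbours in scan order
        for (int dz = -1; dz <= 0; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (dz == 0 && (dy > 0 || (dy == 0 && dx >= 0))) continue;
              const int xx = x + dx, yy = y + dy, zz = z + dz;
              if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0) continue;
              const int j = idx3(xx, yy, zz, nx, ny);
              if (mask[j] == 0) continue;
              const int ri = find(i), rj = find(j);
              if (ri != rj) parent[std::max(ri, rj)] = std::min(ri, rj);
            }
      }
  IntegerVector labels(N, 0);
  std::unordered_map<int, int> remap;
  int next = 0;
  for (int i = 0; i < N; ++i) {
    if (parent[i] < 0) continue;
    const int r = find(i);
    auto it = remap.find(r);
    if (it == remap.end()) it = remap.emplace(r, ++next).first;
    labels[i] = it->second;
  }
  return labels;
}

// Fill holes of a binary mask slice by slice (axial planes): background
// voxels not reachable from the slice border become foreground.
// [[Rcpp::export(rng = false)]]
IntegerVector cpp_fill_holes_slicewise(const IntegerVector& mask,
                                       const IntegerVector& dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  IntegerVector out(clone(mask));
  std::vector<char> outside(nx * ny);
  std::vector<int> stack;
  for (int z = 0; z < nz; ++z) {
    const int off = z * nx * ny;
    std::fill(outside.begin(), outside.end(), 0);
    stack.clear();
    for (int x = 0; x < nx; ++x) {
      for (int yb : {0, ny - 1})
        if (mask[off + yb * nx + x] == 0) stack.push_back(yb * nx + x);
    }
    for (int y = 0; y < ny; ++y) {
      for (int xb : {0, nx - 1})
        if (mask[off + y * nx + xb] == 0) stack.push_back(y * nx + xb);
    }
    for (int s : stack) outside[s] = 1;
    while (!stack.empty()) {
      const int s = stack.back();
      stack.pop_back();
      const int x = s % nx, y = s / nx;
      const int nbr[4][2] = {{x - 1, y}, {x + 1, y}, {x, y - 1}, {x, y + 1}};
      for (auto& nb : nbr) {
        if (nb[0] < 0 || nb[0] >= nx || nb[1] < 0 || nb[1] >= ny) continue;
        const int t = nb[1] * nx + nb[0];
        if (!outside[t] && mask[off + t] == 0) {
          outside[t] = 1;
          stack.push_back(t);
        }
      }
    }
    for (int t = 0; t < nx * ny; ++t)
      if (mask[off + t] == 0 && !outside[t]) out[off + t] = 1;
  }
  return out;
}
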