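// Compiled numeric kernels for the 3D U-Net engine and surface metrics.
//
// Feature maps are (B * nx*ny*nz) x C matrices: rows are voxels in
// column-major (x fastest) order, samples stacked along rows, one column
// per channel.  All voxel indices here are 0-based.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace Rcpp;
using namespace arma;

// ---------------------------------------------------------------------------
// im2col / col2im for a 3x3x3 stride-1 zero-padded convolution.
// Column layout: col = c*27 + (kx+1) + 3*(ky+1) + 9*(kz+1).
// Work proceeds in z-slabs so whole-volume inference stays within memory.
// ---------------------------------------------------------------------------

static void im2col_slab(const mat& X, int nx, int ny, int nz,
                        uword s_off, int z0, int z1, mat& P) {
  const int Cin = (int) X.n_cols;
  P.zeros((uword)(z1 - z0) * nx * ny, (uword) Cin * 27);
  for (int c = 0; c < Cin; ++c) {
    const double* Xc = X.colptr(c) + s_off;
    for (int kz = -1; kz <= 1; ++kz)
      for (int ky = -1; ky <= 1; ++ky)
        for (int kx = -1; kx <= 1; ++kx) {
          const int col = c * 27 + (kx + 1) + 3 * (ky + 1) + 9 * (kz + 1);
          double* Pc = P.colptr(col);
          for (int z = z0; z < z1; ++z) {
            const int zz = z + kz;
            if (zz < 0 || zz >= nz) continue;
            for (int y = 0; y < ny; ++y) {
              const int yy = y + ky;
              if (yy < 0 || yy >= ny) continue;
              const int xlo = (kx < 0) ? 1 : 0;
              const int xhi = (kx > 0) ? nx - 1 : nx;
              const double* src = Xc + (uword) nx * (yy + (uword) ny * zz) + kx;
              double* dst = Pc + (uword)(z - z0) * nx * ny + (uword) y * nx;
              for (int x = xlo; x < xhi; ++x) dst[x] = src[x];
            }
          }
        }
  }
}

static void col2im_add(const mat& G, int nx, int ny, int nz,
                       uword s_off, int z0, int z1, mat& dX) {
  const int Cin = (int) dX.n_cols;
  for (int c = 0; c < Cin; ++c) {
    double* Xc = dX.colptr(c) + s_off;
    for (int kz = -1; kz <= 1; ++kz)
      for (int ky = -1; ky <= 1; ++ky)
        for (int kx = -1; kx <= 1; ++kx) {
          const int col = c * 27 + (kx + 1) + 3 * (ky + 1) + 9 * (kz + 1);
          const double* Gc = G.colptr(col);
          for (int z = z0; z < z1; ++z) {
            const int zz = z + kz;
            if (zz < 0 || zz >= nz) continue;
            for (int y = 0; y < ny; ++y) {
              const int yy = y + ky;
              if (yy < 0 || yy >= ny) continue;
              const int xlo = (kx < 0) ? 1 : 0;
              const int xhi = (kx > 0) ? nx - 1 : nx;
              double* dst = Xc + (uword) nx * (yy + (uword) ny * zz) + kx;
              const double* src = Gc + (uword)(z - z0) * nx * ny + (uword) y * nx;
              for (int x = xlo; x < xhi; ++x) dst[x] += src[x];
            }
          }
        }
  }
}

// weights W: (Cin*27) x Cout
// [[Rcpp::export]]
arma::mat conv3_fwd(const arma::mat& X, int nx, int ny, int nz, int B,
                    const arma::mat& W, const arma::rowvec& bias,
                    int slab = 8) {
  const uword nvox = (uword) nx * ny * nz;
  mat Y(X.n_rows, W.n_cols);
  mat P;
  for (int s = 0; s < B; ++s) {
    for (int z0 = 0; z0 < nz; z0 += slab) {
      const int z1 = std::min(nz, z0 + slab);
      im2col_slab(X, nx, ny, nz, (uword) s * nvox, z0, z1, P);
      Y.rows((uword) s * nvox + (uword) z0 * nx * ny,
             (uword) s * nvox + (uword) z1 * nx * ny - 1) = P * W;
    }
  }
  Y.each_row() += bias;
  return Y;
}

// [[Rcpp::export]]
Rcpp::List conv3_bwd(const arma::mat& X, const arma::mat& dY,
                     int nx, int ny, int nz, int B,
                     const arma::mat& W, int slab = 8) {
  const uword nvox = (uword) nx * ny * nz;
  mat dW(W.n_rows, W.n_cols, fill::zeros);
  mat dX(X.n_rows, X.n_cols, fill::zeros);
  mat P, G;
  for (int s = 0; s < B; ++s) {
    for (int z0 = 0; z0 < nz; z0 += slab) {
      const int z1 = std::min(nz, z0 + slab);
      im2col_slab(X, nx, ny, nz, (uword) s * nvox, z0, z1, P);
      const mat dYs = dY.rows((uword) s * nvox + (uword) z0 * nx * ny,
                              (uword) s * nvox + (uword) z1 * nx * ny - 1);
      dW += P.t() * dYs;
      G = dYs * W.t();
      col2im_add(G, nx, ny, nz, (uword) s * nvox, z0, z1, dX);
    }
  }
  rowvec db = sum(dY, 0);
  return List::create(_["dx"] = dX, _["dw"] = dW, _["db"] = db);
}

// ---------------------------------------------------------------------------
// 2x2x2 max pooling, stride 2
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
Rcpp::List pool3_fwd(const arma::mat& X, int nx, int ny, int nz, int B) {
  const int C = (int) X.n_cols;
  const int mx = nx / 2, my = ny / 2, mz = nz / 2;
  const uword nvox = (uword) nx * ny * nz, mvox = (uword) mx * my * mz;
  mat Y((uword) B * mvox, C);
  umat idx((uword) B * mvox, C);
  for (int s = 0; s < B; ++s)
    for (int c = 0; c < C; ++c) {
      const double* Xc = X.colptr(c) + (uword) s * nvox;
      double* Yc = Y.colptr(c) + (uword) s * mvox;
      uword* Ic = idx.colptr(c) + (uword) s * mvox;
      for (int z = 0; z < mz; ++z)
        for (int y = 0; y < my; ++y)
          for (int x = 0; x < mx; ++x) {
            double best = -datum::inf;
            uword bi = 0;
            for (int dz = 0; dz < 2; ++dz)
              for (int dy = 0; dy < 2; ++dy)
                for (int dx = 0; dx < 2; ++dx) {
                  const uword r = (uword)(2 * x + dx) +
                                  (uword) nx * ((2 * y + dy) + (uword) ny * (2 * z + dz));
                  if (Xc[r] > best) { best = Xc[r]; bi = r; }
                }
            const uword o = (uword) x + (uword) mx * (y + (uword) my * z);
            Yc[o] = best;
            Ic[o] = (uword) s * nvox + bi;  // global 0-based row in X
          }
    }
  return List::create(_["y"] = Y, _["idx"] = idx);
}

// [[Rcpp::export]]
arma::mat pool3_bwd(const arma::mat& dY, const arma::umat& idx, int nrow_x) {
  mat dX((uword) nrow_x, dY.n_cols, fill::zeros);
  for (uword c = 0; c < dY.n_cols; ++c) {
    const double* g = dY.colptr(c);
    const uword* I = idx.colptr(c);
    double* o = dX.colptr(c);
    for (uword r = 0; r < dY.n_rows; ++r) o[I[r]] += g[r];
  }
  return dX;
}

// ---------------------------------------------------------------------------
// Transposed convolution, 2x2x2 kernel, stride 2 (non-overlapping upsample).
// W: Cin x (8*Cout); kernel offset o = dx + 2*dy + 4*dz owns columns
// [o*Cout, (o+1)*Cout).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
arma::mat upconv3_fwd(const arma::mat& X, int nx, int ny, int nz, int B,
                      const arma::mat& W, const arma::rowvec& bias) {
  const int Cout = (int)(W.n_cols / 8);
  const int ox = 2 * nx, oy = 2 * ny, oz = 2 * nz;
  const uword nvox = (uword) nx * ny * nz, ovox = (uword) ox * oy * oz;
  mat T = X * W;  // (B*nvox) x 8Cout
  mat Y((uword) B * ovox, Cout);
  for (int s = 0; s < B; ++s)
    for (int c = 0; c < Cout; ++c) {
      double* Yc = Y.colptr(c) + (uword) s * ovox;
      for (int o = 0; o < 8; ++o) {
        const int dx = o & 1, dy = (o >> 1) & 1, dz = (o >> 2) & 1;
        const double* Tc = T.colptr(o * Cout + c) + (uword) s * nvox;
        for (int z = 0; z < nz; ++z)
          for (int y = 0; y < ny; ++y) {
            double* dst = Yc + (uword)(2 * z + dz) * ox * oy +
                          (uword)(2 * y + dy) * ox + dx;
            const double* src = Tc + (uword) z * nx * ny + (uword) y * nx;
            for (int x = 0; x < nx; ++x) dst[2 * x] = src[x];
          }
      }
    }
  Y.each_row() += bias;
  return Y;
}

// [[Rcpp::export]]
Rcpp::List upconv3_bwd(const arma::mat& X, const arma::mat& dY,
                       int nx, int ny, int nz, int B, const arma::mat& W) {
  const int Cout = (int)(W.n_cols / 8);
  const int ox = 2 * nx, oy = 2 * ny;
  const uword nvox = (uword) nx * ny * nz;
  const uword ovox = (uword) ox * oy * 2 * nz;
  mat Tg((uword) B * nvox, (uword) 8 * Cout);
  for (int s = 0; s < B; ++s)
    for (int c = 0; c < Cout; ++c) {
      const double* Gc = dY.colptr(c) + (uword) s * ovox;
      for (int o = 0; o < 8; ++o) {
        const int dx = o & 1, dy = (o >> 1) & 1, dz = (o >> 2) & 1;
        double* Tc = Tg.colptr(o * Cout + c) + (uword) s * nvox;
        for (int z = 0; z < nz; ++z)
          for (int y = 0; y < ny; ++y) {
            const double* src = Gc + (uword)(2 * z + dz) * ox * oy +
                                (uword)(2 * y + dy) * ox + dx;
            double* dst = Tc + (uword) z * nx * ny + (uword) y * nx;
            for (int x = 0; x < nx; ++x) dst[x] = src[2 * x];
          }
      }
    }
  mat dW = X.t() * Tg;
  mat dX = Tg * W.t();
  rowvec db = sum(dY, 0);
  return List::create(_["dx"] = dX, _["dw"] = dW, _["db"] = db);
}

// ---------------------------------------------------------------------------
// Affine resampling of one sample (nvox x C).  Output voxel p receives the
// input value at q = M * (p - ctr) + ctr; out-of-grid reads are zero.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
arma::mat affine_warp_cpp(const arma::mat& X, int nx, int ny, int nz,
                          const arma::mat& M, const arma::vec& ctr,
                          bool nearest) {
  const int C = (int) X.n_cols;
  mat Y(X.n_rows, C, fill::zeros);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        const double px = x - ctr(0), py = y - ctr(1), pz = z - ctr(2);
        const double qx = M(0,0)*px + M(0,1)*py + M(0,2)*pz + ctr(0);
        const double qy = M(1,0)*px + M(1,1)*py + M(1,2)*pz + ctr(1);
        const double qz = M(2,0)*px + M(2,1)*py + M(2,2)*pz + ctr(2);
        const uword out = (uword) x + (uword) nx * (y + (uword) ny * z);
        if (nearest) {
          const int ix = (int) std::floor(qx + 0.5);
          const int iy = (int) std::floor(qy + 0.5);
          const int iz = (int) std::floor(qz + 0.5);
          if (ix < 0 || ix >= nx || iy < 0 || iy >= ny || iz < 0 || iz >= nz)
            continue;
          const uword in = (uword) ix + (uword) nx * (iy + (uword) ny * iz);
          for (int c = 0; c < C; ++c) Y(out, c) = X(in, c);
        } else {
          const int x0 = (int) std::floor(qx), y0 = (int) std::floor(qy),
                    z0 = (int) std::floor(qz);
          const double fx = qx - x0, fy = qy - y0, fz = qz - z0;
          for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy)
              for (int dx = 0; dx < 2; ++dx) {
                const int ix = x0 + dx, iy = y0 + dy, iz = z0 + dz;
                if (ix < 0 || ix >= nx || iy < 0 || iy >= ny ||
                    iz < 0 || iz >= nz)
                  continue;
                const double w = (dx ? fx : 1 - fx) * (dy ? fy : 1 - fy) *
                                 (dz ? fz : 1 - fz);
                if (w == 0) continue;
                const uword in = (uword) ix + (uword) nx * (iy + (uword) ny * iz);
                for (int c = 0; c < C; ++c) Y(out, c) += w * X(in, c);
              }
        }
      }
  return Y;
}

// ---------------------------------------------------------------------------
// Surface extraction (6-connectivity; out-of-grid counts as background) and
// directed nearest-neighbour surface distances for Hausdorff95.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
arma::imat surface_voxels_cpp(const Rcpp::IntegerVector& mask,
                              int nx, int ny, int nz) {
  const int* m = INTEGER(mask);
  std::vector<int> xs, ys, zs;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        const uword v = (uword) x + (uword) nx * (y + (uword) ny * z);
        if (!m[v]) continue;
        bool surf = false;
        const int nb[6][3] = {{-1,0,0},{1,0,0},{0,-1,0},{0,1,0},{0,0,-1},{0,0,1}};
        for (int k = 0; k < 6 && !surf; ++k) {
          const int ix = x + nb[k][0], iy = y + nb[k][1], iz = z + nb[k][2];
          if (ix < 0 || ix >= nx || iy < 0 || iy >= ny || iz < 0 || iz >= nz)
            surf = true;
          else if (!m[(uword) ix + (uword) nx * (iy + (uword) ny * iz)])
            surf = true;
        }
        if (surf) { xs.push_back(x); ys.push_back(y); zs.push_back(z); }
      }
  imat out(xs.size(), 3);
  for (size_t i = 0; i < xs.size(); ++i) {
    out(i, 0) = xs[i]; out(i, 1) = ys[i]; out(i, 2) = zs[i];
  }
  return out;
}

// For each point (row) of A, the distance in mm to the nearest point of B.
// [[Rcpp::export]]
arma::vec nn_dist_cpp(const arma::imat& A, const arma::imat& B,
                      const arma::vec& spacing) {
  const uword nA = A.n_rows, nB = B.n_rows;
  const double sx = spacing(0), sy = spacing(1), sz = spacing(2);
  vec out(nA);
  for (uword i = 0; i < nA; ++i) {
    const double ax = A(i,0) * sx, ay = A(i,1) * sy, az = A(i,2) * sz;
    double best = datum::inf;
    for (uword j = 0; j < nB; ++j) {
      const double dx = ax - B(j,0) * sx;
      const double dy = ay - B(j,1) * sy;
      const double dz = az - B(j,2) * sz;
      const double d2 = dx*dx + dy*dy + dz*dz;
      if (d2 < best) best = d2;
    }
    out(i) = std::sqrt(best);
  }
  return out;
}
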