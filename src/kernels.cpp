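#include <Rcpp.h>
using namespace Rcpp;

// 3-D tensors are R arrays in column-major order with dim (nx, ny, nz, C).
// All coordinates exchanged with R are 1-based voxel-centre positions;
// sampling clamps to the volume border (replicate policy).

static inline int idx4(int i, int j, int l, int c, int nx, int ny, int nz) {
  return i + nx * (j + ny * (l + (R_xlen_t)nz * c));
}

// Unfold k^3 patches (stride, zero padding) into an nOut x (k^3*C) matrix
// (one row per output voxel). Column order matches R's column-major
// flattening of a (k,k,k,C) block, so a transposed weight matrix Wt of dim
// (k^3*C, Cout) applies as P %*% Wt with no transposes anywhere.
// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericVector x, IntegerVector dims, int k,
                         int stride, int pad) {
  const int nx = dims[0], ny = dims[1], nz = dims[2], C = dims[3];
  const int onx = (nx + 2 * pad - k) / stride + 1;
  const int ony = (ny + 2 * pad - k) / stride + 1;
  const int onz = (nz + 2 * pad - k) / stride + 1;
  const R_xlen_t nout = (R_xlen_t)onx * ony * onz;
  const int krows = k * k * k * C;
  NumericMatrix cols(nout, krows);
  const double *xp = x.begin();
  double *cp = cols.begin();
  int r = 0;
  for (int c = 0; c < C; ++c)
    for (int kz = 0; kz < k; ++kz)
      for (int ky = 0; ky < k; ++ky)
        for (int kx = 0; kx < k; ++kx, ++r) {
          double *dst = cp + (R_xlen_t)r * nout;
          R_xlen_t o = 0;
          for (int ol = 0; ol < onz; ++ol) {
            const int il = ol * stride - pad + kz;
            for (int oj = 0; oj < ony; ++oj) {
              const int ij = oj * stride - pad + ky;
              const bool okjl = ij >= 0 && ij < ny && il >= 0 && il < nz;
              const double *row =
                  xp + (R_xlen_t)nx * (ij + (R_xlen_t)ny * (il + (R_xlen_t)nz * c));
              for (int oi = 0; oi < onx; ++oi, ++o) {
                const int ii = oi * stride - pad + kx;
                dst[o] = (okjl && ii >= 0 && ii < nx) ? row[ii] : 0.0;
              }
            }
          }
        }
  return cols;
}

// Adjoint of cpp_im2col: scatter-add patch rows back onto the input grid.
// [[Rcpp::export]]
NumericVector cpp_col2im(NumericMatrix cols, IntegerVector dims, int k,
                         int stride, int pad) {
  const int nx = dims[0], ny = dims[1], nz = dims[2], C = dims[3];
  const int onx = (nx + 2 * pad - k) / stride + 1;
  const int ony = (ny + 2 * pad - k) / stride + 1;
  const int onz = (nz + 2 * pad - k) / stride + 1;
  const R_xlen_t nout = (R_xlen_t)onx * ony * onz;
  NumericVector out((R_xlen_t)nx * ny * nz * C);
  double *op = out.begin();
  const double *cp = cols.begin();
  int r = 0;
  for (int c = 0; c < C; ++c)
    for (int kz = 0; kz < k; ++kz)
      for (int ky = 0; ky < k; ++ky)
        for (int kx = 0; kx < k; ++kx, ++r) {
          const double *src = cp + (R_xlen_t)r * nout;
          R_xlen_t o = 0;
          for (int ol = 0; ol < onz; ++ol) {
            const int il = ol * stride - pad + kz;
            for (int oj = 0; oj < ony; ++oj) {
              const int ij = oj * stride - pad + ky;
              const bool okjl = ij >= 0 && ij < ny && il >= 0 && il < nz;
              double *row =
                  op + (R_xlen_t)nx * (ij + (R_xlen_t)ny * (il + (R_xlen_t)nz * c));
              for (int oi = 0; oi < onx; ++oi, ++o) {
                const int ii = oi * stride - pad + kx;
                if (okjl && ii >= 0 && ii < nx) row[ii] += src[o];
              }
            }
          }
        }
  out.attr("dim") = dims;
  return out;
}

static inline double clampd(double v, double lo, double hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Trilinear sampling of a (nx,ny,nz,C) tensor at m 1-based positions.
// Returns an m x C matrix. Out-of-domain positions are clamped (replicate).
// [[Rcpp::export]]
NumericMatrix cpp_trilinear_gather(NumericVector img, IntegerVector dims,
                                   NumericMatrix coords) {
  const int nx = dims[0], ny = dims[1], nz = dims[2], C = dims[3];
  const R_xlen_t m = coords.nrow();
  NumericMatrix out(m, C);
  const double *ip = img.begin();
  for (R_xlen_t p = 0; p < m; ++p) {
    double x = clampd(coords(p, 0), 1.0, (double)nx) - 1.0;
    double y = clampd(coords(p, 1), 1.0, (double)ny) - 1.0;
    double z = clampd(coords(p, 2), 1.0, (double)nz) - 1.0;
    int x0 = (int)std::floor(x), y0 = (int)std::floor(y),
        z0 = (int)std::floor(z);
    if (x0 > nx - 2) x0 = nx - 2;
    if (y0 > ny - 2) y0 = ny - 2;
    if (z0 > nz - 2) z0 = nz - 2;
    if (x0 < 0) x0 = 0;
    if (y0 < 0) y0 = 0;
    if (z0 < 0) z0 = 0;
    const double fx = x - x0, fy = y - y0, fz = z - z0;
    for (int c = 0; c < C; ++c) {
      const double v000 = ip[idx4(x0, y0, z0, c, nx, ny, nz)];
      const double v100 = ip[idx4(x0 + 1, y0, z0, c, nx, ny, nz)];
      const double v010 = ip[idx4(x0, y0 + 1, z0, c, nx, ny, nz)];
      const double v110 = ip[idx4(x0 + 1, y0 + 1, z0, c, nx, ny, nz)];
      const double v001 = ip[idx4(x0, y0, z0 + 1, c, nx, ny, nz)];
      const double v101 = ip[idx4(x0 + 1, y0, z0 + 1, c, nx, ny, nz)];
      const double v011 = ip[idx4(x0, y0 + 1, z0 + 1, c, nx, ny, nz)];
      const double v111 = ip[idx4(x0 + 1, y0 + 1, z0 + 1, c, nx, ny, nz)];
      const double c00 = v000 * (1 - fx) + v100 * fx;
      const double c10 = v010 * (1 - fx) + v110 * fx;
      const double c01 = v001 * (1 - fx) + v101 * fx;
      const double c11 = v011 * (1 - fx) + v111 * fx;
      out(p, c) = (c00 * (1 - fy) + c10 * fy) * (1 - fz) +
                  (c01 * (1 - fy) + c11 * fy) * fz;
    }
  }
  return out;
}

// Reverse-mode companion of cpp_trilinear_gather. Given upstream gradients
// dOut (m x C) it returns d(coords) (m x 3, zero where a coordinate was
// clamped) and the scatter-added d(img) tensor.
// [[Rcpp::export]]
List cpp_trilinear_gather_grad(NumericVector img, IntegerVector dims,
                               NumericMatrix coords, NumericMatrix dOut,
                               bool want_dimg, bool want_dcoords) {
  const int nx = dims[0], ny = dims[1], nz = dims[2], C = dims[3];
  const R_xlen_t m = coords.nrow();
  NumericMatrix dcoords(want_dcoords ? m : 0, 3);
  NumericVector dimg(want_dimg ? (R_xlen_t)nx * ny * nz * C : 0);
  const double *ip = img.begin();
  double *dip = dimg.begin();
  for (R_xlen_t p = 0; p < m; ++p) {
    const double rx = coords(p, 0), ry = coords(p, 1), rz = coords(p, 2);
    double x = clampd(rx, 1.0, (double)nx) - 1.0;
    double y = clampd(ry, 1.0, (double)ny) - 1.0;
    double z = clampd(rz, 1.0, (double)nz) - 1.0;
    int x0 = (int)std::floor(x), y0 = (int)std::floor(y),
        z0 = (int)std::floor(z);
    if (x0 > nx - 2) x0 = nx - 2;
    if (y0 > ny - 2) y0 = ny - 2;
    if (z0 > nz - 2) z0 = nz - 2;
    if (x0 < 0) x0 = 0;
    if (y0 < 0) y0 = 0;
    if (z0 < 0) z0 = 0;
    const double fx = x - x0, fy = y - y0, fz = z - z0;
    double gx = 0.0, gy = 0.0, gz = 0.0;
    for (int c = 0; c < C; ++c) {
      const double g = dOut(p, c);
      if (g == 0.0) continue;
      const double w000 = (1 - fx) * (1 - fy) * (1 - fz);
      const double w100 = fx * (1 - fy) * (1 - fz);
      const double w010 = (1 - fx) * fy * (1 - fz);
      const double w110 = fx * fy * (1 - fz);
      const double w001 = (1 - fx) * (1 - fy) * fz;
      const double w101 = fx * (1 - fy) * fz;
      const double w011 = (1 - fx) * fy * fz;
      const double w111 = fx * fy * fz;
      const int i000 = idx4(x0, y0, z0, c, nx, ny, nz);
      const int i100 = idx4(x0 + 1, y0, z0, c, nx, ny, nz);
      const int i010 = idx4(x0, y0 + 1, z0, c, nx, ny, nz);
      const int i110 = idx4(x0 + 1, y0 + 1, z0, c, nx, ny, nz);
      const int i001 = idx4(x0, y0, z0 + 1, c, nx, ny, nz);
      const int i101 = idx4(x0 + 1, y0, z0 + 1, c, nx, ny, nz);
      const int i011 = idx4(x0, y0 + 1, z0 + 1, c, nx, ny, nz);
      const int i111 = idx4(x0 + 1, y0 + 1, z0 + 1, c, nx, ny, nz);
      if (want_dimg) {
        dip[i000] += g * w000;
        dip[i100] += g * w100;
        dip[i010] += g * w010;
        dip[i110] += g * w110;
        dip[i001] += g * w001;
        dip[i101] += g * w101;
        dip[i011] += g * w011;
        dip[i111] += g * w111;
      }
      if (want_dcoords) {
        const double v000 = ip[i000], v100 = ip[i100], v010 = ip[i010],
                     v110 = ip[i110], v001 = ip[i001], v101 = ip[i101],
                     v011 = ip[i011], v111 = ip[i111];
        gx += g * ((v100 - v000) * (1 - fy) * (1 - fz) +
                   (v110 - v010) * fy * (1 - fz) +
                   (v101 - v001) * (1 - fy) * fz + (v111 - v011) * fy * fz);
        gy += g * ((v010 - v000) * (1 - fx) * (1 - fz) +
                   (v110 - v100) * fx * (1 - fz) +
                   (v011 - v001) * (1 - fx) * fz + (v111 - v101) * fx * fz);
        gz += g * ((v001 - v000) * (1 - fx) * (1 - fy) +
                   (v101 - v100) * fx * (1 - fy) +
                   (v011 - v010) * (1 - fx) * fy + (v111 - v110) * fx * fy);
      }
    }
    if (want_dcoords) {
      // a clamped coordinate has zero derivative
      dcoords(p, 0) = (rx < 1.0 || rx > (double)nx) ? 0.0 : gx;
      dcoords(p, 1) = (ry < 1.0 || ry > (double)ny) ? 0.0 : gy;
      dcoords(p, 2) = (rz < 1.0 || rz > (double)nz) ? 0.0 : gz;
    }
  }
  List res = List::create(Named("dcoords") = dcoords);
  if (want_dimg) {
    dimg.attr("dim") = dims;
    res["dimg"] = dimg;
  }
  return res;
}

// Nearest-neighbour sampling (ties round half away from the lower index via
// std::round). Used for label propagation.
// [[Rcpp::export]]
NumericMatrix cpp_nearest_gather(NumericVector img, IntegerVector dims,
                                 NumericMatrix coords) {
  const int nx = dims[0], ny = dims[1], nz = dims[2], C = dims[3];
  const R_xlen_t m = coords.nrow();
  NumericMatrix out(m, C);
  const double *ip = img.begin();
  for (R_xlen_t p = 0; p < m; ++p) {
    int i = (int)std::lround(clampd(coords(p, 0), 1.0, (double)nx)) - 1;
    int j = (int)std::lround(clampd(coords(p, 1), 1.0, (double)ny)) - 1;
    int l = (int)std::lround(clampd(coords(p, 2), 1.0, (double)nz)) - 1;
    for (int c = 0; c < C; ++c) out(p, c) = ip[idx4(i, j, l, c, nx, ny, nz)];
  }
  return out;
}

// Centered moving box sum of edge d (odd) with zero padding, via a 3-D
// integral image. Shared by the local-NCC loss and local weighted voting.
// [[Rcpp::export]]
NumericVector cpp_boxsum3d(NumericVector x, IntegerVector dims, int d) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int r = (d - 1) / 2;
  const int sx = nx + 1, sy = ny + 1, sz = nz + 1;
  std::vector<double> S((R_xlen_t)sx * sy * sz, 0.0);
  const double *xp = x.begin();
  // integral image: S[i,j,l] = sum of x over [0,i) x [0,j) x [0,l)
  for (int l = 1; l < sz; ++l)
    for (int j = 1; j < sy; ++j) {
      const R_xlen_t b = (R_xlen_t)sx * (j + (R_xlen_t)sy * l);
      const R_xlen_t bj = (R_xlen_t)sx * ((j - 1) + (R_xlen_t)sy * l);
      const R_xlen_t bl = (R_xlen_t)sx * (j + (R_xlen_t)sy * (l - 1));
      const R_xlen_t bjl = (R_xlen_t)sx * ((j - 1) + (R_xlen_t)sy * (l - 1));
      const double *row = xp + (R_xlen_t)nx * ((j - 1) + (R_xlen_t)ny * (l - 1));
      double run = 0.0;
      for (int i = 1; i < sx; ++i) {
        run += row[i - 1];
        S[b + i] = run + S[bj + i] + S[bl + i] - S[bjl + i];
      }
    }
  NumericVector out((R_xlen_t)nx * ny * nz);
  double *op = out.begin();
  for (int l = 0; l < nz; ++l) {
    const int l0 = std::max(0, l - r), l1 = std::min(nz, l + r + 1);
    for (int j = 0; j < ny; ++j) {
      const int j0 = std::max(0, j - r), j1 = std::min(ny, j + r + 1);
      for (int i = 0; i < nx; ++i) {
        const int i0 = std::max(0, i - r), i1 = std::min(nx, i + r + 1);
        const double v =
            S[i1 + (R_xlen_t)sx * (j1 + (R_xlen_t)sy * l1)] -
            S[i0 + (R_xlen_t)sx * (j1 + (R_xlen_t)sy * l1)] -
            S[i1 + (R_xlen_t)sx * (j0 + (R_xlen_t)sy * l1)] -
            S[i1 + (R_xlen_t)sx * (j1 + (R_xlen_t)sy * l0)] +
            S[i0 + (R_xlen_t)sx * (j0 + (R_xlen_t)sy * l1)] +
            S[i0 + (R_xlen_t)sx * (j1 + (R_xlen_t)sy * l0)] +
            S[i1 + (R_xlen_t)sx * (j0 + (R_xlen_t)sy * l0)] -
            S[i0 + (R_xlen_t)sx * (j0 + (R_xlen_t)sy * l0)];
        op[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * l)] = v;
      }
    }
  }
  out.attr("dim") = IntegerVector::create(nx, ny, nz);
  return out;
}

// Smoothness energy of a displacement field: each of the nine forward-
// difference partials is mean-squared over its own support, so an affine
// field phi_c = a*x_c scores exactly 3*a^2. Optionally also the gradient.
// [[Rcpp::export]]
List cpp_smoothness(NumericVector phi, IntegerVector dims, bool grad) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t vol = (R_xlen_t)nx * ny * nz;
  NumericVector g(grad ? vol * 3 : 0);
  const double *pp = phi.begin();
  double *gp = g.begin();
  double loss = 0.0;
  for (int c = 0; c < 3; ++c) {
    const double *a = pp + c * vol;
    double *ga = gp + c * vol;
    // axis 0
    {
      const double m = (double)(nx - 1) * ny * nz;
      double ss = 0.0;
      for (int l = 0; l < nz; ++l)
        for (int j = 0; j < ny; ++j) {
          const R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * l);
          for (int i = 0; i < nx - 1; ++i) {
            const double d = a[base + i + 1] - a[base + i];
            ss += d * d;
            if (grad) {
              ga[base + i + 1] += 2.0 * d / m;
              ga[base + i] -= 2.0 * d / m;
            }
          }
        }
      loss += ss / m;
    }
    // axis 1
    {
      const double m = (double)nx * (ny - 1) * nz;
      double ss = 0.0;
      for (int l = 0; l < nz; ++l)
        for (int j = 0; j < ny - 1; ++j) {
          const R_xlen_t b0 = (R_xlen_t)nx * (j + (R_xlen_t)ny * l);
          const R_xlen_t b1 = (R_xlen_t)nx * ((j + 1) + (R_xlen_t)ny * l);
          for (int i = 0; i < nx; ++i) {
            const double d = a[b1 + i] - a[b0 + i];
            ss += d * d;
            if (grad) {
              ga[b1 + i] += 2.0 * d / m;
              ga[b0 + i] -= 2.0 * d / m;
            }
          }
        }
      loss += ss / m;
    }
    // axis 2
    {
      const double m = (double)nx * ny * (nz - 1);
      double ss = 0.0;
      for (int l = 0; l < nz - 1; ++l)
        for (int j = 0; j < ny; ++j) {
          const R_xlen_t b0 = (R_xlen_t)nx * (j + (R_xlen_t)ny * l);
          const R_xlen_t b1 = (R_xlen_t)nx * (j + (R_xlen_t)ny * (l + 1));
          for (int i = 0; i < nx; ++i) {
            const double d = a[b1 + i] - a[b0 + i];
            ss += d * d;
            if (grad) {
              ga[b1 + i] += 2.0 * d / m;
              ga[b0 + i] -= 2.0 * d / m;
            }
          }
        }
      loss += ss / m;
    }
  }
  List res = List::create(Named("loss") = loss);
  if (grad) {
    g.attr("dim") = IntegerVector::create(nx, ny, nz, 3);
    res["grad"] = g;
  }
  return res;
}
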