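// Voxel-level kernels for freehand 3D ultrasound reconstruction.
//
// All positions handed to these routines are in continuous voxel units
// (already shifted by the grid origin and divided by the voxel spacing),
// so voxel centres sit at integer coordinates. Volume arrays use R's
// column-major layout: linear index = ix + nx*(iy + ny*iz), 0-based.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// round-half-toward-lower-index: deterministic nearest-voxel snapping
static inline int tie_round(double x) {
  return (int)std::ceil(x - 0.5);
}

static inline R_xlen_t lin(int ix, int iy, int iz, int nx, int ny) {
  return (R_xlen_t)ix + (R_xlen_t)nx * ((R_xlen_t)iy + (R_xlen_t)ny * iz);
}

// ---------------------------------------------------------------------------
// Bin-filling: distribute every in-bounds pixel into its nearest voxel
// (running average) and emit the continuous-position sample cloud.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_distribute(List images, List poses, NumericVector spacings,
                    IntegerVector frame_ids, NumericVector origin,
                    NumericVector gspacing, IntegerVector dims) {
  const int nframes = images.size();
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;

  R_xlen_t npix_total = 0;
  for (int f = 0; f < nframes; ++f) {
    NumericMatrix img = images[f];
    npix_total += (R_xlen_t)img.nrow() * img.ncol();
  }

  NumericVector sums(nvox, 0.0);
  IntegerVector counts(nvox, 0);
  NumericMatrix pos(npix_total, 3);
  NumericVector intens(npix_total);
  IntegerVector fid(npix_total);

  R_xlen_t n = 0, nskip = 0;
  for (int f = 0; f < nframes; ++f) {
    NumericMatrix img = images[f];
    NumericMatrix M = poses[f];
    const double s = spacings[f];
    const int nr = img.nrow(), nc = img.ncol();
    const double m00 = M(0,0), m01 = M(0,1), m03 = M(0,3);
    const double m10 = M(1,0), m11 = M(1,1), m13 = M(1,3);
    const double m20 = M(2,0), m21 = M(2,1), m23 = M(2,3);
    for (int u = 0; u < nc; ++u) {
      const double xu = u * s;
      for (int v = 0; v < nr; ++v) {
        const double yv = v * s;
        // physical position of pixel (u, v): pose applied to (u*s, v*s, 0)
        const double px = m00*xu + m01*yv + m03;
        const double py = m10*xu + m11*yv + m13;
        const double pz = m20*xu + m21*yv + m23;
        const double cx = (px - origin[0]) / gspacing[0];
        const double cy = (py - origin[1]) / gspacing[1];
        const double cz = (pz - origin[2]) / gspacing[2];
        const int ix = tie_round(cx), iy = tie_round(cy), iz = tie_round(cz);
        if (ix < 0 || ix >= nx || iy < 0 || iy >= ny || iz < 0 || iz >= nz) {
          ++nskip;
          continue;
        }
        sums[lin(ix, iy, iz, nx, ny)] += img(v, u);
        counts[lin(ix, iy, iz, nx, ny)] += 1;
        pos(n, 0) = cx; pos(n, 1) = cy; pos(n, 2) = cz;
        intens[n] = img(v, u);
        fid[n] = frame_ids[f];
        ++n;
      }
    }
  }

  NumericVector values(nvox, 0.0);
  LogicalVector filled(nvox);
  for (R_xlen_t i = 0; i < nvox; ++i) {
    filled[i] = counts[i] > 0;
    if (counts[i] > 0) values[i] = sums[i] / counts[i];
  }

  return List::create(_["values"] = values, _["counts"] = counts,
                      _["filled"] = filled,
                      _["positions"] = pos, _["intensities"] = intens,
                      _["frame_ids"] = fid,
                      _["n_samples"] = (double)n,
                      _["n_skipped"] = (double)nskip);
}

// ---------------------------------------------------------------------------
// Spatial index: samples binned by nearest voxel cell, CSR layout.
// ---------------------------------------------------------------------------

struct CellIndex {
  int nx, ny, nz;
  std::vector<R_xlen_t> start;  // nvox+1 offsets
  std::vector<R_xlen_t> order;  // sample indices, grouped by cell,
                                // input order preserved within a cell
};

static CellIndex build_index(const NumericMatrix& pos, const IntegerVector& dims) {
  CellIndex ci;
  ci.nx = dims[0]; ci.ny = dims[1]; ci.nz = dims[2];
  const R_xlen_t nvox = (R_xlen_t)ci.nx * ci.ny * ci.nz;
  const R_xlen_t n = pos.nrow();
  std::vector<R_xlen_t> cell(n);
  ci.start.assign(nvox + 1, 0);
  for (R_xlen_t i = 0; i < n; ++i) {
    int ix = std::min(std::max(tie_round(pos(i, 0)), 0), ci.nx - 1);
    int iy = std::min(std::max(tie_round(pos(i, 1)), 0), ci.ny - 1);
    int iz = std::min(std::max(tie_round(pos(i, 2)), 0), ci.nz - 1);
    cell[i] = lin(ix, iy, iz, ci.nx, ci.ny);
    ci.start[cell[i] + 1]++;
  }
  for (R_xlen_t c = 0; c < nvox; ++c) ci.start[c + 1] += ci.start[c];
  ci.order.assign(n, 0);
  std::vector<R_xlen_t> cursor(ci.start.begin(), ci.start.end() - 1);
  for (R_xlen_t i = 0; i < n; ++i) ci.order[cursor[cell[i]]++] = i;
  return ci;
}

// ---------------------------------------------------------------------------
// Kernel regression reconstruction.
// ---------------------------------------------------------------------------

static inline int basis_len(int order) {
  return order == 0 ? 1 : (order == 1 ? 4 : 10);
}

static inline void fill_basis(double* phi, int order,
                              double d1, double d2, double d3) {
  phi[0] = 1.0;
  if (order >= 1) { phi[1] = d1; phi[2] = d2; phi[3] = d3; }
  if (order >= 2) {
    phi[4] = d1*d1; phi[5] = d2*d2; phi[6] = d3*d3;
    phi[7] = d1*d2; phi[8] = d1*d3; phi[9] = d2*d3;
  }
}

// status codes: 0 = ok, 1 = fell back to order-0 weighted mean, 2 = empty

// [[Rcpp::export]]
List cpp_kr_reconstruct(NumericMatrix positions, NumericVector intens,
                        IntegerVector dims, int order, int halfw, double h,
                        int min_samples, double cond_limit, int leave_empty,
                        LogicalVector preserve, NumericVector base_values) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  const int p = basis_len(order);
  const double inv2h2 = 1.0 / (2.0 * h * h);
  const double rcond_min = 1.0 / cond_limit;
  const bool use_preserve = preserve.size() == nvox;

  CellIndex ci = build_index(positions, dims);

  NumericVector values(nvox, 0.0);
  LogicalVector filled(nvox);
  R_xlen_t n_ok = 0, n_fallback = 0, n_empty = 0;

  std::vector<R_xlen_t> nb;
  std::vector<double> d2s;
  arma::mat A(p, p);
  arma::vec b(p), beta(p);
  double phi[10];

  for (int tz = 0; tz < nz; ++tz)
  for (int ty = 0; ty < ny; ++ty)
  for (int tx = 0; tx < nx; ++tx) {
    const R_xlen_t vi = lin(tx, ty, tz, nx, ny);
    if (use_preserve && preserve[vi]) {
      values[vi] = base_values[vi];
      filled[vi] = true;
      ++n_ok;
      continue;
    }

    // gather samples with Chebyshev distance <= halfw of the target;
    // their nearest-voxel cells lie within halfw+1 of it
    nb.clear(); d2s.clear();
    double d2min = R_PosInf;
    const int zlo = std::max(tz - halfw - 1, 0), zhi = std::min(tz + halfw + 1, nz - 1);
    const int ylo = std::max(ty - halfw - 1, 0), yhi = std::min(ty + halfw + 1, ny - 1);
    const int xlo = std::max(tx - halfw - 1, 0), xhi = std::min(tx + halfw + 1, nx - 1);
    for (int cz = zlo; cz <= zhi; ++cz)
    for (int cy = ylo; cy <= yhi; ++cy)
    for (int cx = xlo; cx <= xhi; ++cx) {
      const R_xlen_t c = lin(cx, cy, cz, nx, ny);
      for (R_xlen_t k = ci.start[c]; k < ci.start[c + 1]; ++k) {
        const R_xlen_t i = ci.order[k];
        const double d1 = positions(i, 0) - tx;
        const double d2 = positions(i, 1) - ty;
        const double d3 = positions(i, 2) - tz;
        if (std::fabs(d1) > halfw + 1e-12 || std::fabs(d2) > halfw + 1e-12 ||
            std::fabs(d3) > halfw + 1e-12) continue;
        const double dd = d1*d1 + d2*d2 + d3*d3;
        nb.push_back(i);
        d2s.push_back(dd);
        if (dd < d2min) d2min = dd;
      }
    }

    const R_xlen_t m = (R_xlen_t)nb.size();
    if (m == 0) {
      ++n_empty;
      continue;  // value 0, unfilled
    }

    // weights rescaled by exp(d2min/(2h^2)); a constant factor cancels in
    // the WLS solution and this keeps the largest weight at 1 even for
    // very small bandwidths
    bool solved = false;
    if (m >= min_samples && order > 0) {
      A.zeros(); b.zeros();
      for (R_xlen_t k = 0; k < m; ++k) {
        const R_xlen_t i = nb[k];
        const double w = std::exp(-(d2s[k] - d2min) * inv2h2);
        if (w <= 0.0) continue;
        fill_basis(phi, order, positions(i, 0) - tx, positions(i, 1) - ty,
                   positions(i, 2) - tz);
        const double wy = w * intens[i];
        for (int a2 = 0; a2 < p; ++a2) {
          b[a2] += wy * phi[a2];
          for (int b2 = a2; b2 < p; ++b2) A(a2, b2) += w * phi[a2] * phi[b2];
        }
      }
      A = arma::symmatu(A);
      const double rc = arma::rcond(A);
      if (std::isfinite(rc) && rc > rcond_min && arma::solve(beta, A, b)) {
        values[vi] = beta[0];
        filled[vi] = true;
        ++n_ok;
        solved = true;
      }
    } else if (m >= min_samples && order == 0) {
      double sw = 0.0, swy = 0.0;
      for (R_xlen_t k = 0; k < m; ++k) {
        const double w = std::exp(-(d2s[k] - d2min) * inv2h2);
        sw += w; swy += w * intens[nb[k]];
      }
      values[vi] = swy / sw;
      filled[vi] = true;
      ++n_ok;
      solved = true;
    }

    if (!solved) {
      if (leave_empty) {
        ++n_empty;
      } else {
        // order-zero fallback: Nadaraya-Watson weighted mean
        double sw = 0.0, swy = 0.0;
        for (R_xlen_t k = 0; k < m; ++k) {
          const double w = std::exp(-(d2s[k] - d2min) * inv2h2);
          sw += w; swy += w * intens[nb[k]];
        }
        values[vi] = swy / sw;
        filled[vi] = true;
        ++n_fallback;
      }
    }
  }

  return List::create(_["values"] = values, _["filled"] = filled,
                      _["n_ok"] = (double)n_ok,
                      _["n_fallback"] = (double)n_fallback,
                      _["n_empty"] = (double)n_empty);
}

// ---------------------------------------------------------------------------
// Voxel nearest neighbour: expanding Chebyshev shells over the cell index.
// Ties in exact Euclidean distance break by lowest frame_id, then input
// order.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_vnn(NumericMatrix positions, NumericVector intens,
                      IntegerVector frame_ids, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  CellIndex ci = build_index(positions, dims);
  NumericVector values(nvox, 0.0);
  const int rmax = std::max(nx, std::max(ny, nz));

  for (int tz = 0; tz < nz; ++tz)
  for (int ty = 0; ty < ny; ++ty)
  for (int tx = 0; tx < nx; ++tx) {
    double best_d2 = R_PosInf;
    int best_fid = INT_MAX;
    R_xlen_t best_i = -1;
    for (int r = 0; r <= rmax; ++r) {
      // a sample in a cell at Chebyshev radius r is at Euclidean distance
      // >= r - 0.5 from the target; once that exceeds the best distance no
      // farther shell can improve on it
      if (best_i >= 0 && (double)r - 0.5 > std::sqrt(best_d2)) break;
      const int zlo = std::max(tz - r, 0), zhi = std::min(tz + r, nz - 1);
      const int ylo = std::max(ty - r, 0), yhi = std::min(ty + r, ny - 1);
      const int xlo = std::max(tx - r, 0), xhi = std::min(tx + r, nx - 1);
      for (int cz = zlo; cz <= zhi; ++cz)
      for (int cy = ylo; cy <= yhi; ++cy)
      for (int cx = xlo; cx <= xhi; ++cx) {
        // only the shell surface (cells at exactly radius r)
        if (std::max(std::abs(cx - tx),
                     std::max(std::abs(cy - ty), std::abs(cz - tz))) != r)
          continue;
        const R_xlen_t c = lin(cx, cy, cz, nx, ny);
        for (R_xlen_t k = ci.start[c]; k < ci.start[c + 1]; ++k) {
          const R_xlen_t i = ci.order[k];
          const double d1 = positions(i, 0) - tx;
          const double d2 = positions(i, 1) - ty;
          const double d3 = positions(i, 2) - tz;
          const double dd = d1*d1 + d2*d2 + d3*d3;
          if (dd < best_d2 ||
              (dd == best_d2 && (frame_ids[i] < best_fid ||
                                 (frame_ids[i] == best_fid && i < best_i)))) {
            best_d2 = dd; best_fid = frame_ids[i]; best_i = i;
          }
        }
      }
    }
    values[lin(tx, ty, tz, nx, ny)] = intens[best_i];
  }
  return values;
}

// ---------------------------------------------------------------------------
// Inverse-distance weighting within a fixed Euclidean radius.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_dw(NumericMatrix positions, NumericVector intens,
            IntegerVector frame_ids, IntegerVector dims, double radius) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  CellIndex ci = build_index(positions, dims);
  NumericVector values(nvox, 0.0);
  LogicalVector filled(nvox);
  const int rc = (int)std::ceil(radius + 0.5);

  for (int tz = 0; tz < nz; ++tz)
  for (int ty = 0; ty < ny; ++ty)
  for (int tx = 0; tx < nx; ++tx) {
    double sw = 0.0, swy = 0.0;
    R_xlen_t nin = 0;
    double zero_d2 = R_PosInf; int zero_fid = INT_MAX;
    R_xlen_t zero_i = -1;
    const int zlo = std::max(tz - rc, 0), zhi = std::min(tz + rc, nz - 1);
    const int ylo = std::max(ty - rc, 0), yhi = std::min(ty + rc, ny - 1);
    const int xlo = std::max(tx - rc, 0), xhi = std::min(tx + rc, nx - 1);
    for (int cz = zlo; cz <= zhi; ++cz)
    for (int cy = ylo; cy <= yhi; ++cy)
    for (int cx = xlo; cx <= xhi; ++cx) {
      const R_xlen_t c = lin(cx, cy, cz, nx, ny);
      for (R_xlen_t k = ci.start[c]; k < ci.start[c + 1]; ++k) {
        const R_xlen_t i = ci.order[k];
        const double d1 = positions(i, 0) - tx;
        const double d2 = positions(i, 1) - ty;
        const double d3 = positions(i, 2) - tz;
        const double d = std::sqrt(d1*d1 + d2*d2 + d3*d3);
        if (d > radius) continue;
        ++nin;
        if (d < 1e-9) {
          // coincident sample: exact assignment, nearest such wins
          const double dd = d * d;
          if (dd < zero_d2 ||
              (dd == zero_d2 && (frame_ids[i] < zero_fid ||
                                 (frame_ids[i] == zero_fid && i < zero_i)))) {
            zero_d2 = dd; zero_fid = frame_ids[i]; zero_i = i;
          }
        } else {
          sw += 1.0 / d; swy += intens[i] / d;
        }
      }
    }
    const R_xlen_t vi = lin(tx, ty, tz, nx, ny);
    if (zero_i >= 0) {
      values[vi] = intens[zero_i]; filled[vi] = true;
    } else if (nin > 0) {
      values[vi] = swy / sw; filled[vi] = true;
    }
  }
  return List::create(_["values"] = values, _["filled"] = filled);
}

// ---------------------------------------------------------------------------
// PNN hole-filling: each pass fills every empty voxel with the unweighted
// mean of voxels that were filled at the start of the pass, window growing
// by 2 between passes.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_pnn_fill(NumericVector values_in, LogicalVector filled_in,
                  IntegerVector dims, int window) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  NumericVector values = clone(values_in);
  LogicalVector filled = clone(filled_in);
  const int maxdim = std::max(nx, std::max(ny, nz));

  R_xlen_t n_empty = 0;
  for (R_xlen_t i = 0; i < nvox; ++i) if (!filled[i]) ++n_empty;

  int w = window;
  while (n_empty > 0 && w <= maxdim) {
    const int hw = (w - 1) / 2;
    NumericVector snap_v = clone(values);
    LogicalVector snap_f = clone(filled);
    for (int tz = 0; tz < nz; ++tz)
    for (int ty = 0; ty < ny; ++ty)
    for (int tx = 0; tx < nx; ++tx) {
      const R_xlen_t vi = lin(tx, ty, tz, nx, ny);
      if (snap_f[vi]) continue;
      double s = 0.0; R_xlen_t cnt = 0;
      const int zlo = std::max(tz - hw, 0), zhi = std::min(tz + hw, nz - 1);
      const int ylo = std::max(ty - hw, 0), yhi = std::min(ty + hw, ny - 1);
      const int xlo = std::max(tx - hw, 0), xhi = std::min(tx + hw, nx - 1);
      for (int cz = zlo; cz <= zhi; ++cz)
      for (int cy = ylo; cy <= yhi; ++cy)
      for (int cx = xlo; cx <= xhi; ++cx) {
        const R_xlen_t c = lin(cx, cy, cz, nx, ny);
        if (snap_f[c]) { s += snap_v[c]; ++cnt; }
      }
      if (cnt > 0) {
        values[vi] = s / cnt;
        filled[vi] = true;
        --n_empty;
      }
    }
    w += 2;
  }
  return List::create(_["values"] = values, _["filled"] = filled,
                      _["n_empty"] = (double)n_empty);
}

// ---------------------------------------------------------------------------
// Reslice: trilinear interpolation of the volume on an oriented plane.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_reslice(NumericVector values, IntegerVector dims,
                 NumericVector origin, NumericVector gspacing,
                 NumericMatrix pose, int nrow, int ncol, double pspacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericMatrix img(nrow, ncol);
  LogicalMatrix valid(nrow, ncol);
  const double m00 = pose(0,0), m01 = pose(0,1), m03 = pose(0,3);
  const double m10 = pose(1,0), m11 = pose(1,1), m13 = pose(1,3);
  const double m20 = pose(2,0), m21 = pose(2,1), m23 = pose(2,3);

  for (int u = 0; u < ncol; ++u) {
    const double xu = u * pspacing;
    for (int v = 0; v < nrow; ++v) {
      const double yv = v * pspacing;
      const double px = m00*xu + m01*yv + m03;
      const double py = m10*xu + m11*yv + m13;
      const double pz = m20*xu + m21*yv + m23;
      const double cx = (px - origin[0]) / gspacing[0];
      const double cy = (py - origin[1]) / gspacing[1];
      const double cz = (pz - origin[2]) / gspacing[2];
      if (cx < 0 || cx > nx - 1 || cy < 0 || cy > ny - 1 ||
          cz < 0 || cz > nz - 1) {
        valid(v, u) = false;
        continue;
      }
      int i0 = std::min((int)std::floor(cx), nx - 2); if (nx == 1) i0 = 0;
      int j0 = std::min((int)std::floor(cy), ny - 2); if (ny == 1) j0 = 0;
      int k0 = std::min((int)std::floor(cz), nz - 2); if (nz == 1) k0 = 0;
      const double fx = cx - i0, fy = cy - j0, fz = cz - k0;
      const int i1 = nx == 1 ? i0 : i0 + 1;
      const int j1 = ny == 1 ? j0 : j0 + 1;
      const int k1 = nz == 1 ? k0 : k0 + 1;
      const double c000 = values[lin(i0, j0, k0, nx, ny)];
      const double c100 = values[lin(i1, j0, k0, nx, ny)];
      const double c010 = values[lin(i0, j1, k0, nx, ny)];
      const double c110 = values[lin(i1, j1, k0, nx, ny)];
      const double c001 = values[lin(i0, j0, k1, nx, ny)];
      const double c101 = values[lin(i1, j0, k1, nx, ny)];
      const double c011 = values[lin(i0, j1, k1, nx, ny)];
      const double c111 = values[lin(i1, j1, k1, nx, ny)];
      const double c00 = c000 * (1 - fx) + c100 * fx;
      const double c10 = c010 * (1 - fx) + c110 * fx;
      const double c01 = c001 * (1 - fx) + c101 * fx;
      const double c11 = c011 * (1 - fx) + c111 * fx;
      const double c0 = c00 * (1 - fy) + c10 * fy;
      const double c1 = c01 * (1 - fy) + c11 * fy;
      img(v, u) = c0 * (1 - fz) + c1 * fz;
      valid(v, u) = true;
    }
  }
  return List::create(_["image"] = img, _["valid"] = valid);
}
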