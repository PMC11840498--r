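#include <Rcpp.h>
#include <vector>
#include <limits>

using namespace Rcpp;

// Border voxels of a 3D occupancy grid: foreground voxels with at least one
// face-adjacent (6-connectivity) background neighbour; outside the grid
// counts as background, so voxels on the grid boundary are border voxels.
// [[Rcpp::export(name = ".border_voxels")]]
LogicalVector border_voxels(LogicalVector grid, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (grid.size() != n) stop("grid length does not match dims");
  LogicalVector out(n);
  const int* g = LOGICAL(grid);
  int* o = LOGICAL(out);
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      R_xlen_t base = ((R_xlen_t)k * ny + j) * nx;
      for (int i = 0; i < nx; ++i) {
        R_xlen_t idx = base + i;
        if (!g[idx]) { o[idx] = FALSE; continue; }
        bool border =
          (i == 0      || !g[idx - 1]) ||
          (i == nx - 1 || !g[idx + 1]) ||
          (j == 0      || !g[idx - nx]) ||
          (j == ny - 1 || !g[idx + nx]) ||
          (k == 0      || !g[idx - (R_xlen_t)nx * ny]) ||
          (k == nz - 1 || !g[idx + (R_xlen_t)nx * ny]);
        o[idx] = border;
      }
    }
  }
  return out;
}

// One-dimensional squared distance transform (lower envelope of parabolas,
// Felzenszwalb & Huttenlocher 2012), on integer sample positions scaled by
// the squared physical spacing w2. f holds input squared distances, d the
// output; v/z are scratch of length n and n+1.
static void dt1d(const double* f, int n, double w2, double* d,
                 int* v, double* z) {
  const double INF = std::numeric_limits<double>::infinity();
  int q0 = 0;
  while (q0 < n && f[q0] == INF) ++q0;
  if (q0 == n) {
    for (int q = 0; q < n; ++q) d[q] = INF;
    return;
  }
  int k = 0;
  v[0] = q0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = q0 + 1; q < n; ++q) {
    if (f[q] == INF) continue;
    int p = v[k];
    double s = ((f[q] + (double)q * q * w2) - (f[p] + (double)p * p * w2)) /
               (2.0 * w2 * (q - p));
    while (s <= z[k]) {
      --k;
      p = v[k];
      s = ((f[q] + (double)q * q * w2) - (f[p] + (double)p * p * w2)) /
          (2.0 * w2 * (q - p));
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = (double)(q - v[k]);
    d[q] = dq * dq * w2 + f[v[k]];
  }
}

// Squared Euclidean distance (mm^2) from every voxel centre to the nearest
// seed voxel centre, honouring anisotropic spacing. Returns +Inf everywhere
// when there are no seeds.
// [[Rcpp::export(name = ".sq_distance_transform")]]
NumericVector sq_distance_transform(LogicalVector seeds, IntegerVector dims,
                                    NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (seeds.size() != n) stop("seeds length does not match dims");
  const double INF = std::numeric_limits<double>::infinity();
  NumericVector out(n);
  double* d = REAL(out);
  const int* s = LOGICAL(seeds);
  for (R_xlen_t i = 0; i < n; ++i) d[i] = s[i] ? 0.0 : INF;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), dd(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  const double wx2 = spacing[0] * spacing[0];
  const double wy2 = spacing[1] * spacing[1];
  const double wz2 = spacing[2] * spacing[2];

  // pass along x (stride 1)
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      R_xlen_t base = ((R_xlen_t)k * ny + j) * nx;
      bool any = false;
      for (int i = 0; i < nx; ++i) { f[i] = d[base + i]; if (f[i] < INF) any = true; }
      if (!any) continue;
      dt1d(f.data(), nx, wx2, dd.data(), v.data(), z.data());
      for (int i = 0; i < nx; ++i) d[base + i] = dd[i];
    }
  // pass along y (stride nx)
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = (R_xlen_t)k * ny * nx + i;
      bool any = false;
      for (int j = 0; j < ny; ++j) { f[j] = d[base + (R_xlen_t)j * nx]; if (f[j] < INF) any = true; }
      if (!any) continue;
      dt1d(f.data(), ny, wy2, dd.data(), v.data(), z.data());
      for (int j = 0; j < ny; ++j) d[base + (R_xlen_t)j * nx] = dd[j];
    }
  // pass along z (stride nx*ny)
  const R_xlen_t sz = (R_xlen_t)nx * ny;
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = (R_xlen_t)j * nx + i;
      bool any = false;
      for (int k = 0; k < nz; ++k) { f[k] = d[base + (R_xlen_t)k * sz]; if (f[k] < INF) any = true; }
      if (!any) continue;
      dt1d(f.data(), nz, wz2, dd.data(), v.data(), z.data());
      for (int k = 0; k < nz; ++k) d[base + (R_xlen_t)k * sz] = dd[k];
    }
  return out;
}
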