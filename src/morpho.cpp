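#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
#include <algorithm>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Exact Euclidean distance transform, squared (Felzenszwalb & Huttenlocher),
// separable over the three axes.  Input: logical feature mask; output:
// squared distance (voxel units) from every voxel to the nearest TRUE voxel.
// ---------------------------------------------------------------------------

static const double DT_INF = std::numeric_limits<double>::infinity();

// 1D squared distance transform of a sampled function f (in place result d)
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -DT_INF;
  z[1] = DT_INF;
  for (int q = 1; q < n; ++q) {
    if (f[q] == DT_INF) continue;
    if (f[v[0]] == DT_INF) { k = 0; v[0] = q; z[0] = -DT_INF; z[1] = DT_INF; continue; }
    double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (k > 0 && s <= z[k]) {
      --k;
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = DT_INF;
  }
  if (f[v[0]] == DT_INF) {          // no finite sample on this line
    for (int q = 0; q < n; ++q) d[q] = DT_INF;
    return;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = (double)q - v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// [[Rcpp::export(name = ".edt3d_sq")]]
NumericVector edt3d_sq(LogicalVector feat, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = feat[i] ? 0.0 : DT_INF;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax);

  // x axis
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      R_xlen_t base = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx;
      for (int x = 0; x < nx; ++x) f[x] = out[base + x];
      dt1d(f, d, nx);
      for (int x = 0; x < nx; ++x) out[base + x] = d[x];
    }
  // y axis
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = (R_xlen_t)z * nx * ny + x;
      for (int y = 0; y < ny; ++y) f[y] = out[base + (R_xlen_t)y * nx];
      dt1d(f, d, ny);
      for (int y = 0; y < ny; ++y) out[base + (R_xlen_t)y * nx] = d[y];
    }
  // z axis
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = (R_xlen_t)y * nx + x;
      for (int z = 0; z < nz; ++z) f[z] = out[base + (R_xlen_t)z * nx * ny];
      dt1d(f, d, nz);
      for (int z = 0; z < nz; ++z) out[base + (R_xlen_t)z * nx * ny] = d[z];
    }
  return out;
}

// ---------------------------------------------------------------------------
// Local thickness (Hildebrand-Ruegsegger): thickness(p) = 2 * max radius of a
// sphere fully inside the mask containing p.  radii_sq holds, per voxel, the
// squared distance to the nearest background voxel (with the volume border
// treated as background); a sphere of radius r(c) = sqrt(radii_sq[c]) centred
// at c covers exactly the voxels q with |q - c| < r(c), all of which are
// guaranteed foreground.  Painting spheres in decreasing radius order yields
// the thickness map in voxel units.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".local_thickness")]]
NumericVector local_thickness(LogicalVector mask, IntegerVector dim,
                              NumericVector radii_sq) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);

  std::vector<R_xlen_t> idx;
  idx.reserve(1024);
  for (R_xlen_t i = 0; i < n; ++i) if (mask[i]) idx.push_back(i);
  std::sort(idx.begin(), idx.end(), [&](R_xlen_t a, R_xlen_t b) {
    return radii_sq[a] > radii_sq[b];
  });

  for (size_t m = 0; m < idx.size(); ++m) {
    R_xlen_t c = idx[m];
    double r2 = radii_sq[c];
    if (!R_finite(r2) || r2 <= 0) continue;
    double r = std::sqrt(r2);
    double diam = 2.0 * r;
    int cz = (int)(c / ((R_xlen_t)nx * ny));
    int rem = (int)(c % ((R_xlen_t)nx * ny));
    int cy = rem / nx;
    int cx = rem % nx;
    int rr = (int)std::ceil(r) - 1;  // |q-c| < r strictly
    if ((double)(rr + 1) * (rr + 1) < r2) rr = rr + 1;
    int x0 = std::max(0, cx - rr), x1 = std::min(nx - 1, cx + rr);
    int y0 = std::max(0, cy - rr), y1 = std::min(ny - 1, cy + rr);
    int z0 = std::max(0, cz - rr), z1 = std::min(nz - 1, cz + rr);
    for (int z = z0; z <= z1; ++z) {
      double dz = (double)(z - cz);
      for (int y = y0; y <= y1; ++y) {
        double dy = (double)(y - cy);
        double dzy = dz * dz + dy * dy;
        if (dzy >= r2) continue;
        R_xlen_t base = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx;
        for (int x = x0; x <= x1; ++x) {
          double dx = (double)(x - cx);
          if (dzy + dx * dx < r2) {
            R_xlen_t q = base + x;
            if (out[q] < diam) out[q] = diam;
          }
        }
      }
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// 3D connected-component labelling (26-connectivity), iterative flood fill.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".label3d")]]
IntegerVector label3d(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> stack;
  int current = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || lab[i] != 0) continue;
    ++current;
    stack.push_back(i);
    lab[i] = current;
    while (!stack.empty()) {
      R_xlen_t v = stack.back();
      stack.pop_back();
      int vz = (int)(v / ((R_xlen_t)nx * ny));
      int rem = (int)(v % ((R_xlen_t)nx * ny));
      int vy = rem / nx;
      int vx = rem % nx;
      for (int dz = -1; dz <= 1; ++dz) {
        int z = vz + dz;
        if (z < 0 || z >= nz) continue;
        for (int dy = -1; dy <= 1; ++dy) {
          int y = vy + dy;
          if (y < 0 || y >= ny) continue;
          for (int dx = -1; dx <= 1; ++dx) {
            int x = vx + dx;
            if (x < 0 || x >= nx) continue;
            R_xlen_t q = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx + x;
            if (mask[q] && lab[q] == 0) {
              lab[q] = current;
              stack.push_back(q);
            }
          }
        }
      }
    }
  }
  return lab;
}
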