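#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Separable 1D convolution of a 3D volume along one axis with a centred
// odd-length kernel; boundaries handled by edge replication.
// axis: 0 = x (fastest varying), 1 = y, 2 = z.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".conv1d_axis")]]
NumericVector conv1d_axis(NumericVector vol, IntegerVector dim,
                          NumericVector kernel, int axis) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const int klen = kernel.size();
  const int kr = klen / 2;
  NumericVector out(n);

  int len, nlines_a, nlines_b;
  R_xlen_t stride, stride_a, stride_b;
  if (axis == 0) {
    len = nx; stride = 1;
    nlines_a = ny; stride_a = nx;
    nlines_b = nz; stride_b = (R_xlen_t)nx * ny;
  } else if (axis == 1) {
    len = ny; stride = nx;
    nlines_a = nx; stride_a = 1;
    nlines_b = nz; stride_b = (R_xlen_t)nx * ny;
  } else {
    len = nz; stride = (R_xlen_t)nx * ny;
    nlines_a = nx; stride_a = 1;
    nlines_b = ny; stride_b = nx;
  }

  std::vector<double> line(len);
  for (int b = 0; b < nlines_b; ++b) {
    for (int a = 0; a < nlines_a; ++a) {
      R_xlen_t base = (R_xlen_t)b * stride_b + (R_xlen_t)a * stride_a;
      for (int i = 0; i < len; ++i) line[i] = vol[base + (R_xlen_t)i * stride];
      for (int i = 0; i < len; ++i) {
        double acc = 0.0;
        for (int k = -kr; k <= kr; ++k) {
          int j = i + k;
          if (j < 0) j = 0;
          else if (j >= len) j = len - 1;
          acc += line[j] * kernel[kr + k];
        }
        out[base + (R_xlen_t)i * stride] = acc;
      }
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Eigenvalues of symmetric 3x3 matrices, vectorised over voxels; analytic
// trigonometric solution, values returned sorted by increasing magnitude
// (the ordering used by tubularity measures).
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".eig3_sym")]]
NumericMatrix eig3_sym(NumericVector xx, NumericVector yy, NumericVector zz,
                       NumericVector xy, NumericVector xz, NumericVector yz) {
  const R_xlen_t n = xx.size();
  NumericMatrix out(n, 3);
  const double two_pi_3 = 2.0943951023931953;  // 2*pi/3
  for (R_xlen_t i = 0; i < n; ++i) {
    double a11 = xx[i], a22 = yy[i], a33 = zz[i];
    double a12 = xy[i], a13 = xz[i], a23 = yz[i];
    double p1 = a12 * a12 + a13 * a13 + a23 * a23;
    double e1, e2, e3;
    if (p1 == 0.0) {
      e1 = a11; e2 = a22; e3 = a33;
    } else {
      double q = (a11 + a22 + a33) / 3.0;
      double b11 = a11 - q, b22 = a22 - q, b33 = a33 - q;
      double p2 = b11 * b11 + b22 * b22 + b33 * b33 + 2.0 * p1;
      double p = std::sqrt(p2 / 6.0);
      // det(B)/2 with B = (A - qI)/p
      double c11 = b11 / p, c22 = b22 / p, c33 = b33 / p;
      double c12 = a12 / p, c13 = a13 / p, c23 = a23 / p;
      double detB = c11 * (c22 * c33 - c23 * c23)
                  - c12 * (c12 * c33 - c23 * c13)
                  + c13 * (c12 * c23 - c22 * c13);
      double r = detB / 2.0;
      if (r < -1.0) r = -1.0;
      if (r > 1.0) r = 1.0;
      double phi = std::acos(r) / 3.0;
      e1 = q + 2.0 * p * std::cos(phi);
      e3 = q + 2.0 * p * std::cos(phi + two_pi_3 * 2.0);
      e2 = 3.0 * q - e1 - e3;
    }
    // sort by |e| ascending
    double v[3] = { e1, e2, e3 };
    std::sort(v, v + 3, [](double a, double b) {
      return std::fabs(a) < std::fabs(b);
    });
    out(i, 0) = v[0];
    out(i, 1) = v[1];
    out(i, 2) = v[2];
  }
  return out;
}
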