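#include <Rcpp.h>
#include <vector>
#include <cmath>

// Anisotropic squared Euclidean distance transform, separable
// lower-envelope-of-parabolas algorithm, one 1-D pass per axis.
// Sources are voxels where src is TRUE; h is the physical sample step
// of the axis. INF stands in for "no source on this line yet"; kept
// finite so parabola intersections stay well defined.

static const double BIG = 1e30;   // "no source" marker, kept finite
static const double ZINF = 1e300; // envelope sentinel, below/above any intersection

static void dt1d(const std::vector<double> &f, double h, int n,
                 std::vector<double> &d, std::vector<int> &v,
                 std::vector<double> &z) {
  int k = 0;
  v[0] = 0;
  z[0] = -ZINF;
  z[1] = ZINF;
  const double h2 = h * h;
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + h2 * q * q) - (f[v[k]] + h2 * v[k] * v[k])) /
               (2.0 * h2 * (q - v[k]));
    while (s <= z[k]) {
      --k;
      s = ((f[q] + h2 * q * q) - (f[v[k]] + h2 * v[k] * v[k])) /
          (2.0 * h2 * (q - v[k]));
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = ZINF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < (double)q) ++k;
    double dq = h * (q - v[k]);
    d[q] = dq * dq + f[v[k]];
  }
}

// [[Rcpp::export(name = ".edt3d")]]
Rcpp::NumericVector edt3d(Rcpp::LogicalVector src, Rcpp::IntegerVector dims,
                          Rcpp::NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  Rcpp::NumericVector out(n);
  std::vector<double> g(n);
  for (R_xlen_t i = 0; i < n; ++i) g[i] = src[i] ? 0.0 : BIG;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x (fastest-varying index)
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
      for (int i = 0; i < nx; ++i) f[i] = g[base + i];
      dt1d(f, spacing[0], nx, d, v, z);
      for (int i = 0; i < nx; ++i) g[base + i] = d[i];
    }
  // pass along y
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = i + (R_xlen_t)nx * ny * k;
      for (int j = 0; j < ny; ++j) f[j] = g[base + (R_xlen_t)nx * j];
      dt1d(f, spacing[1], ny, d, v, z);
      for (int j = 0; j < ny; ++j) g[base + (R_xlen_t)nx * j] = d[j];
    }
  // pass along z
  const R_xlen_t stride = (R_xlen_t)nx * ny;
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = i + (R_xlen_t)nx * j;
      for (int k = 0; k < nz; ++k) f[k] = g[base + stride * k];
      dt1d(f, spacing[2], nz, d, v, z);
      for (int k = 0; k < nz; ++k) g[base + stride * k] = d[k];
    }

  for (R_xlen_t i = 0; i < n; ++i) out[i] = std::sqrt(g[i]);
  return out;
}
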