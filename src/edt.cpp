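#include <Rcpp.h>
#include <vector>
#include <limits>

using namespace Rcpp;

// 1-D squared Euclidean distance transform (Felzenszwalb & Huttenlocher,
// lower envelope of parabolas). f and d have length n; v/z are scratch.
static void dt1d(const double *f, double *d, int n,
                 std::vector<int> &v, std::vector<double> &z) {
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Exact squared Euclidean distance (in voxel units) from every voxel centre
// to the nearest occupied voxel centre. `solid` is a logical 3-D array.
// [[Rcpp::export]]
NumericVector edt3d_sq(LogicalVector solid, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double INF = 1e30;
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = solid[i] ? 0.0 : INF;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      R_xlen_t base = (R_xlen_t)j * nx + (R_xlen_t)k * nx * ny;
      for (int i = 0; i < nx; ++i) f[i] = out[base + i];
      dt1d(f.data(), d.data(), nx, v, z);
      for (int i = 0; i < nx; ++i) out[base + i] = d[i];
    }
  // pass along y
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = i + (R_xlen_t)k * nx * ny;
      for (int j = 0; j < ny; ++j) f[j] = out[base + (R_xlen_t)j * nx];
      dt1d(f.data(), d.data(), ny, v, z);
      for (int j = 0; j < ny; ++j) out[base + (R_xlen_t)j * nx] = d[j];
    }
  // pass along z
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = i + (R_xlen_t)j * nx;
      for (int k = 0; k < nz; ++k) f[k] = out[base + (R_xlen_t)k * nx * ny];
      dt1d(f.data(), d.data(), nz, v, z);
      for (int k = 0; k < nz; ++k) out[base + (R_xlen_t)k * nx * ny] = d[k];
    }
  out.attr("dim") = dims;
  return out;
}
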