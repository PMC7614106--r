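#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

static const double DINF = std::numeric_limits<double>::infinity();

// Felzenszwalb & Huttenlocher lower-envelope 1D squared-distance transform
// along a line of n samples with physical spacing h.  Entries with f == INF
// (no source anywhere on the line yet) are skipped when building the envelope.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z, int n, double h) {
  int k = -1;
  for (int q = 0; q < n; ++q) {
    if (f[q] == DINF) continue;
    double qh = q * h;
    if (k < 0) {
      k = 0; v[0] = q; z[0] = -DINF; z[1] = DINF;
      continue;
    }
    double s = 0.0;
    while (k >= 0) {
      double vh = v[k] * h;
      s = ((f[q] + qh * qh) - (f[v[k]] + vh * vh)) / (2.0 * qh - 2.0 * vh);
      if (s <= z[k]) --k; else break;
    }
    if (k < 0) {
      k = 0; v[0] = q; z[0] = -DINF; z[1] = DINF;
    } else {
      ++k; v[k] = q; z[k] = s; z[k + 1] = DINF;
    }
  }
  if (k < 0) {  // whole line is object: stays INF
    for (int q = 0; q < n; ++q) d[q] = DINF;
    return;
  }
  int j = 0;
  for (int q = 0; q < n; ++q) {
    double qh = q * h;
    while (z[j + 1] < qh) ++j;
    double vh = v[j] * h;
    d[q] = (qh - vh) * (qh - vh) + f[v[j]];
  }
}

// Exact anisotropic Euclidean distance transform.
// mask: object voxels (column-major array, dims = c(n1,n2,n3) = (z,y,x));
// spacing: physical step per axis in the same order.  Returns, for every
// object voxel, the distance in physical units to the nearest background
// voxel centre (0 for background).  The grid is not padded: voxels outside
// the array are treated as object, matching scipy's distance_transform_edt.
// [[Rcpp::export]]
NumericVector cpp_edt(LogicalVector mask, IntegerVector dims, NumericVector spacing) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const R_xlen_t ntot = (R_xlen_t)n1 * n2 * n3;
  std::vector<double> g(ntot);
  for (R_xlen_t i = 0; i < ntot; ++i) g[i] = mask[i] ? DINF : 0.0;

  int nmax = std::max(n1, std::max(n2, n3));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // axis 1 (stride 1)
  for (int i3 = 0; i3 < n3; ++i3)
    for (int i2 = 0; i2 < n2; ++i2) {
      R_xlen_t base = (R_xlen_t)n1 * (i2 + (R_xlen_t)n2 * i3);
      for (int q = 0; q < n1; ++q) f[q] = g[base + q];
      dt1d(f, d, v, z, n1, spacing[0]);
      for (int q = 0; q < n1; ++q) g[base + q] = d[q];
    }
  // axis 2 (stride n1)
  for (int i3 = 0; i3 < n3; ++i3)
    for (int i1 = 0; i1 < n1; ++i1) {
      R_xlen_t base = i1 + (R_xlen_t)n1 * n2 * i3;
      for (int q = 0; q < n2; ++q) f[q] = g[base + (R_xlen_t)n1 * q];
      dt1d(f, d, v, z, n2, spacing[1]);
      for (int q = 0; q < n2; ++q) g[base + (R_xlen_t)n1 * q] = d[q];
    }
  // axis 3 (stride n1*n2)
  const R_xlen_t s3 = (R_xlen_t)n1 * n2;
  for (int i2 = 0; i2 < n2; ++i2)
    for (int i1 = 0; i1 < n1; ++i1) {
      R_xlen_t base = i1 + (R_xlen_t)n1 * i2;
      for (int q = 0; q < n3; ++q) f[q] = g[base + s3 * q];
      dt1d(f, d, v, z, n3, spacing[2]);
      for (int q = 0; q < n3; ++q) g[base + s3 * q] = d[q];
    }

  NumericVector out(ntot);
  for (R_xlen_t i = 0; i < ntot; ++i)
    out[i] = (g[i] == DINF) ? R_PosInf : std::sqrt(g[i]);
  return out;
}
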