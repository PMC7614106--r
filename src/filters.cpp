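#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// mirror (symmetric, edge-repeating) index reflection
static inline int reflect(int i, int n) {
  while (i < 0 || i >= n) {
    if (i < 0) i = -1 - i;
    if (i >= n) i = 2 * n - 1 - i;
  }
  return i;
}

// Separable Gaussian on a (n1,n2,n3) column-major grid; sigma in voxels per
// axis, kernel truncated at 4 sigma and renormalised so that convolution of
// a constant returns the constant and interior mass is conserved.
// [[Rcpp::export]]
NumericVector cpp_gaussian3d(NumericVector vol, IntegerVector dims, NumericVector sigma) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const R_xlen_t ntot = (R_xlen_t)n1 * n2 * n3;
  std::vector<double> a(vol.begin(), vol.end()), b(ntot);

  const int nax[3] = {n1, n2, n3};
  const R_xlen_t stride[3] = {1, (R_xlen_t)n1, (R_xlen_t)n1 * n2};

  for (int ax = 0; ax < 3; ++ax) {
    double s = sigma[ax];
    if (s <= 0) continue;
    int r = (int)std::ceil(4.0 * s);
    if (r < 1) r = 1;
    std::vector<double> k(2 * r + 1);
    double tot = 0.0;
    for (int o = -r; o <= r; ++o) {
      k[o + r] = std::exp(-0.5 * (o * o) / (s * s));
      tot += k[o + r];
    }
    for (double& w : k) w /= tot;

    const int n = nax[ax];
    const R_xlen_t st = stride[ax];
    // iterate over all lines along 'ax'
    const int m1 = (ax == 0) ? n2 : n1;
    const int m2 = (ax == 2) ? n2 : n3;
    const R_xlen_t st1 = (ax == 0) ? (R_xlen_t)n1 : 1;
    const R_xlen_t st2 = (ax == 2) ? (R_xlen_t)n1 : (R_xlen_t)n1 * n2;
    for (int j2 = 0; j2 < m2; ++j2)
      for (int j1 = 0; j1 < m1; ++j1) {
        R_xlen_t base = st1 * j1 + st2 * j2;
        for (int q = 0; q < n; ++q) {
          double acc = 0.0;
          for (int o = -r; o <= r; ++o)
            acc += k[o + r] * a[base + st * reflect(q + o, n)];
          b[base + st * q] = acc;
        }
        for (int q = 0; q < n; ++q) a[base + st * q] = b[base + st * q];
      }
  }
  return NumericVector(a.begin(), a.end());
}

// 26-connected component labelling; labels assigned 1..K in first-voxel scan
// order (deterministic).
// [[Rcpp::export]]
IntegerVector cpp_label26(LogicalVector mask, IntegerVector dims) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const R_xlen_t ntot = (R_xlen_t)n1 * n2 * n3;
  IntegerVector lab(ntot, 0);
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t i = 0; i < ntot; ++i) {
    if (!mask[i] || lab[i]) continue;
    ++next;
    lab[i] = next;
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t c = stack.back(); stack.pop_back();
      int i1 = (int)(c % n1);
      int i2 = (int)((c / n1) % n2);
      int i3 = (int)(c / ((R_xlen_t)n1 * n2));
      for (int d3 = -1; d3 <= 1; ++d3)
        for (int d2 = -1; d2 <= 1; ++d2)
          for (int d1 = -1; d1 <= 1; ++d1) {
            if (!d1 && !d2 && !d3) continue;
            int j1 = i1 + d1, j2 = i2 + d2, j3 = i3 + d3;
            if (j1 < 0 || j1 >= n1 || j2 < 0 || j2 >= n2 || j3 < 0 || j3 >= n3) continue;
            R_xlen_t j = j1 + (R_xlen_t)n1 * (j2 + (R_xlen_t)n2 * j3);
            if (mask[j] && !lab[j]) { lab[j] = next; stack.push_back(j); }
          }
    }
  }
  return lab;
}

// Fill internal cavities: background is flood-filled with 6-connectivity from
// the volume border; anything not reached and not object is a cavity.
// [[Rcpp::export]]
LogicalVector cpp_fill_holes(LogicalVector mask, IntegerVector dims) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const R_xlen_t ntot = (R_xlen_t)n1 * n2 * n3;
  std::vector<char> outside(ntot, 0);
  std::vector<R_xlen_t> stack;
  // seed all border background voxels
  for (int i3 = 0; i3 < n3; ++i3)
    for (int i2 = 0; i2 < n2; ++i2)
      for (int i1 = 0; i1 < n1; ++i1) {
        if (i1 != 0 && i1 != n1 - 1 && i2 != 0 && i2 != n2 - 1 &&
            i3 != 0 && i3 != n3 - 1) continue;
        R_xlen_t i = i1 + (R_xlen_t)n1 * (i2 + (R_xlen_t)n2 * i3);
        if (!mask[i] && !outside[i]) { outside[i] = 1; stack.push_back(i); }
      }
  const int d1s[6] = {-1, 1, 0, 0, 0, 0};
  const int d2s[6] = {0, 0, -1, 1, 0, 0};
  const int d3s[6] = {0, 0, 0, 0, -1, 1};
  while (!stack.empty()) {
    R_xlen_t c = stack.back(); stack.pop_back();
    int i1 = (int)(c % n1);
    int i2 = (int)((c / n1) % n2);
    int i3 = (int)(c / ((R_xlen_t)n1 * n2));
    for (int t = 0; t < 6; ++t) {
      int j1 = i1 + d1s[t], j2 = i2 + d2s[t], j3 = i3 + d3s[t];
      if (j1 < 0 || j1 >= n1 || j2 < 0 || j2 >= n2 || j3 < 0 || j3 >= n3) continue;
      R_xlen_t j = j1 + (R_xlen_t)n1 * (j2 + (R_xlen_t)n2 * j3);
      if (!mask[j] && !outside[j]) { outside[j] = 1; stack.push_back(j); }
    }
  }
  LogicalVector out(ntot);
  for (R_xlen_t i = 0; i < ntot; ++i) out[i] = mask[i] || !outside[i];
  return out;
}
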