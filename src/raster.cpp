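#include <Rcpp.h>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Rasterise a union of capsules (sphere swept along a line segment).
// dims/spacing in (z,y,x) order; segs columns: x1,y1,z1,x2,y2,z2,r in the
// same physical units as spacing.  Voxel (i1,i2,i3), 0-based, has its centre
// at z=(i1+0.5)*hz, y=(i2+0.5)*hy, x=(i3+0.5)*hx.  A voxel is inside when its
// centre lies within distance r of the capsule axis.
// [[Rcpp::export]]
LogicalVector cpp_rasterize_capsules(IntegerVector dims, NumericVector spacing,
                                     NumericMatrix segs) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const double hz = spacing[0], hy = spacing[1], hx = spacing[2];
  const R_xlen_t ntot = (R_xlen_t)n1 * n2 * n3;
  LogicalVector out(ntot);

  for (int s = 0; s < segs.nrow(); ++s) {
    double x1 = segs(s, 0), y1 = segs(s, 1), z1 = segs(s, 2);
    double x2 = segs(s, 3), y2 = segs(s, 4), z2 = segs(s, 5);
    double r = segs(s, 6), r2 = r * r;
    double ax = x2 - x1, ay = y2 - y1, az = z2 - z1;
    double len2 = ax * ax + ay * ay + az * az;

    int lo1 = std::max(0, (int)std::floor((std::min(z1, z2) - r) / hz - 0.5));
    int hi1 = std::min(n1 - 1, (int)std::ceil((std::max(z1, z2) + r) / hz - 0.5));
    int lo2 = std::max(0, (int)std::floor((std::min(y1, y2) - r) / hy - 0.5));
    int hi2 = std::min(n2 - 1, (int)std::ceil((std::max(y1, y2) + r) / hy - 0.5));
    int lo3 = std::max(0, (int)std::floor((std::min(x1, x2) - r) / hx - 0.5));
    int hi3 = std::min(n3 - 1, (int)std::ceil((std::max(x1, x2) + r) / hx - 0.5));

    for (int i3 = lo3; i3 <= hi3; ++i3) {
      double x = (i3 + 0.5) * hx;
      for (int i2 = lo2; i2 <= hi2; ++i2) {
        double y = (i2 + 0.5) * hy;
        for (int i1 = lo1; i1 <= hi1; ++i1) {
          double z = (i1 + 0.5) * hz;
          double t = 0.0;
          if (len2 > 0) {
            t = ((x - x1) * ax + (y - y1) * ay + (z - z1) * az) / len2;
            if (t < 0) t = 0; else if (t > 1) t = 1;
          }
          double dx = x - (x1 + t * ax), dy = y - (y1 + t * ay), dz = z - (z1 + t * az);
          if (dx * dx + dy * dy + dz * dz <= r2)
            out[i1 + (R_xlen_t)n1 * (i2 + (R_xlen_t)n2 * i3)] = true;
        }
      }
    }
  }
  return out;
}

// Solid ellipsoid: centre and semi-axes given as (x,y,z) physical units.
// [[Rcpp::export]]
LogicalVector cpp_ellipsoid_mask(IntegerVector dims, NumericVector spacing,
                                 NumericVector centre, NumericVector semi) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const double hz = spacing[0], hy = spacing[1], hx = spacing[2];
  LogicalVector out((R_xlen_t)n1 * n2 * n3);
  for (int i3 = 0; i3 < n3; ++i3) {
    double x = ((i3 + 0.5) * hx - centre[0]) / semi[0];
    for (int i2 = 0; i2 < n2; ++i2) {
      double y = ((i2 + 0.5) * hy - centre[1]) / semi[1];
      for (int i1 = 0; i1 < n1; ++i1) {
        double z = ((i1 + 0.5) * hz - centre[2]) / semi[2];
        if (x * x + y * y + z * z <= 1.0)
          out[i1 + (R_xlen_t)n1 * (i2 + (R_xlen_t)n2 * i3)] = true;
      }
    }
  }
  return out;
}
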