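#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Quickhull in 3D, used to rasterise the convex envelope of a vessel mask.
// Points are physical (x,y,z) coordinates of voxel centres.  Returns the
// hull as a logical voxel mask; a zero-length vector signals degenerate
// (rank < 3) input so the caller can fall back.

namespace {

struct Face {
  int a, b, c;
  double nx, ny, nz, off;   // outward plane: dot(n, p) <= off inside
  bool alive;
  std::vector<int> outside;
};

struct Hull {
  const std::vector<double>& X;
  const std::vector<double>& Y;
  const std::vector<double>& Z;
  double mx, my, mz;        // interior reference point
  double eps;
  std::vector<Face> faces;

  Hull(const std::vector<double>& x, const std::vector<double>& y,
       const std::vector<double>& z) : X(x), Y(y), Z(z) {}

  double dist(const Face& f, int p) const {
    return f.nx * X[p] + f.ny * Y[p] + f.nz * Z[p] - f.off;
  }

  void set_plane(Face& f) {
    double ux = X[f.b] - X[f.a], uy = Y[f.b] - Y[f.a], uz = Z[f.b] - Z[f.a];
    double vx = X[f.c] - X[f.a], vy = Y[f.c] - Y[f.a], vz = Z[f.c] - Z[f.a];
    f.nx = uy * vz - uz * vy;
    f.ny = uz * vx - ux * vz;
    f.nz = ux * vy - uy * vx;
    double nn = std::sqrt(f.nx * f.nx + f.ny * f.ny + f.nz * f.nz);
    if (nn > 0) { f.nx /= nn; f.ny /= nn; f.nz /= nn; }
    f.off = f.nx * X[f.a] + f.ny * Y[f.a] + f.nz * Z[f.a];
    // orient away from interior point
    if (f.nx * mx + f.ny * my + f.nz * mz - f.off > 0) {
      f.nx = -f.nx; f.ny = -f.ny; f.nz = -f.nz; f.off = -f.off;
      std::swap(f.b, f.c);
    }
    f.alive = true;
  }
};

}  // namespace

// [[Rcpp::export]]
LogicalVector cpp_convex_mask(NumericMatrix pts, IntegerVector dims, NumericVector spacing) {
  const int n = pts.nrow();
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const R_xlen_t ntot = (R_xlen_t)n1 * n2 * n3;
  if (n < 4) return LogicalVector(0);

  std::vector<double> X(n), Y(n), Z(n);
  for (int i = 0; i < n; ++i) { X[i] = pts(i, 0); Y[i] = pts(i, 1); Z[i] = pts(i, 2); }

  // bounding box and tolerance
  double xmin = X[0], xmax = X[0], ymin = Y[0], ymax = Y[0], zmin = Z[0], zmax = Z[0];
  for (int i = 1; i < n; ++i) {
    xmin = std::min(xmin, X[i]); xmax = std::max(xmax, X[i]);
    ymin = std::min(ymin, Y[i]); ymax = std::max(ymax, Y[i]);
    zmin = std::min(zmin, Z[i]); zmax = std::max(zmax, Z[i]);
  }
  double diag = std::sqrt((xmax - xmin) * (xmax - xmin) +
                          (ymax - ymin) * (ymax - ymin) +
                          (zmax - zmin) * (zmax - zmin));
  if (diag <= 0) return LogicalVector(0);
  double eps = 1e-9 * diag + 1e-12;

  // initial simplex: farthest pair among axis extremes, then line, then plane
  int ext[6] = {0, 0, 0, 0, 0, 0};
  for (int i = 0; i < n; ++i) {
    if (X[i] < X[ext[0]]) ext[0] = i;
    if (X[i] > X[ext[1]]) ext[1] = i;
    if (Y[i] < Y[ext[2]]) ext[2] = i;
    if (Y[i] > Y[ext[3]]) ext[3] = i;
    if (Z[i] < Z[ext[4]]) ext[4] = i;
    if (Z[i] > Z[ext[5]]) ext[5] = i;
  }
  int p0 = ext[0], p1 = ext[1];
  double best = -1;
  for (int a = 0; a < 6; ++a)
    for (int b = a + 1; b < 6; ++b) {
      double d = (X[ext[a]] - X[ext[b]]) * (X[ext[a]] - X[ext[b]]) +
                 (Y[ext[a]] - Y[ext[b]]) * (Y[ext[a]] - Y[ext[b]]) +
                 (Z[ext[a]] - Z[ext[b]]) * (Z[ext[a]] - Z[ext[b]]);
      if (d > best) { best = d; p0 = ext[a]; p1 = ext[b]; }
    }
  if (best <= eps * eps) return LogicalVector(0);

  double ax = X[p1] - X[p0], ay = Y[p1] - Y[p0], az = Z[p1] - Z[p0];
  double al2 = ax * ax + ay * ay + az * az;
  int p2 = -1; best = eps * eps;
  for (int i = 0; i < n; ++i) {
    double wx = X[i] - X[p0], wy = Y[i] - Y[p0], wz = Z[i] - Z[p0];
    double t = (wx * ax + wy * ay + wz * az) / al2;
    double dx = wx - t * ax, dy = wy - t * ay, dz = wz - t * az;
    double d = dx * dx + dy * dy + dz * dz;
    if (d > best) { best = d; p2 = i; }
  }
  if (p2 < 0) return LogicalVector(0);

  double ux = X[p2] - X[p0], uy = Y[p2] - Y[p0], uz = Z[p2] - Z[p0];
  double nx0 = ay * uz - az * uy, ny0 = az * ux - ax * uz, nz0 = ax * uy - ay * ux;
  double nn0 = std::sqrt(nx0 * nx0 + ny0 * ny0 + nz0 * nz0);
  nx0 /= nn0; ny0 /= nn0; nz0 /= nn0;
  double off0 = nx0 * X[p0] + ny0 * Y[p0] + nz0 * Z[p0];
  int p3 = -1; best = eps;
  for (int i = 0; i < n; ++i) {
    double d = std::fabs(nx0 * X[i] + ny0 * Y[i] + nz0 * Z[i] - off0);
    if (d > best) { best = d; p3 = i; }
  }
  if (p3 < 0) return LogicalVector(0);

  Hull H(X, Y, Z);
  H.eps = eps;
  H.mx = (X[p0] + X[p1] + X[p2] + X[p3]) / 4.0;
  H.my = (Y[p0] + Y[p1] + Y[p2] + Y[p3]) / 4.0;
  H.mz = (Z[p0] + Z[p1] + Z[p2] + Z[p3]) / 4.0;

  int tet[4][3] = {{p0, p1, p2}, {p0, p1, p3}, {p0, p2, p3}, {p1, p2, p3}};
  for (int f = 0; f < 4; ++f) {
    Face fc; fc.a = tet[f][0]; fc.b = tet[f][1]; fc.c = tet[f][2];
    H.set_plane(fc);
    H.faces.push_back(fc);
  }
  for (int i = 0; i < n; ++i) {
    if (i == p0 || i == p1 || i == p2 || i == p3) continue;
    for (size_t f = 0; f < H.faces.size(); ++f)
      if (H.dist(H.faces[f], i) > eps) { H.faces[f].outside.push_back(i); break; }
  }

  // refinement loop
  while (true) {
    int fi = -1;
    for (size_t f = 0; f < H.faces.size(); ++f)
      if (H.faces[f].alive && !H.faces[f].outside.empty()) { fi = (int)f; break; }
    if (fi < 0) break;
    Face& fref = H.faces[fi];
    int apex = fref.outside[0];
    double bd = H.dist(fref, apex);
    for (size_t q = 1; q < fref.outside.size(); ++q) {
      double d = H.dist(fref, fref.outside[q]);
      if (d > bd) { bd = d; apex = fref.outside[q]; }
    }
    // visible faces and orphaned points
    std::vector<int> visible;
    std::vector<int> orphans;
    for (size_t f = 0; f < H.faces.size(); ++f) {
      if (!H.faces[f].alive) continue;
      if (H.dist(H.faces[f], apex) > eps) {
        visible.push_back((int)f);
        orphans.insert(orphans.end(), H.faces[f].outside.begin(), H.faces[f].outside.end());
        H.faces[f].outside.clear();
      }
    }
    // horizon: undirected edges used exactly once among visible faces
    std::vector<std::pair<int, int> > edges;
    for (size_t v = 0; v < visible.size(); ++v) {
      const Face& fc = H.faces[visible[v]];
      int e[3][2] = {{fc.a, fc.b}, {fc.b, fc.c}, {fc.c, fc.a}};
      for (int t = 0; t < 3; ++t) {
        int lo = std::min(e[t][0], e[t][1]), hi = std::max(e[t][0], e[t][1]);
        bool dup = false;
        for (size_t w = 0; w < edges.size(); ++w)
          if (edges[w].first == lo && edges[w].second == hi) {
            edges.erase(edges.begin() + w); dup = true; break;
          }
        if (!dup) edges.push_back(std::make_pair(lo, hi));
      }
    }
    for (size_t v = 0; v < visible.size(); ++v) H.faces[visible[v]].alive = false;
    std::vector<int> fresh;
    for (size_t e = 0; e < edges.size(); ++e) {
      Face fc; fc.a = apex; fc.b = edges[e].first; fc.c = edges[e].second;
      H.set_plane(fc);
      fresh.push_back((int)H.faces.size());
      H.faces.push_back(fc);
    }
    for (size_t q = 0; q < orphans.size(); ++q) {
      int p = orphans[q];
      if (p == apex) continue;
      for (size_t f = 0; f < fresh.size(); ++f)
        if (H.dist(H.faces[fresh[f]], p) > eps) {
          H.faces[fresh[f]].outside.push_back(p); break;
        }
    }
  }

  // rasterise: voxel centre inside all half-spaces
  std::vector<const Face*> live;
  for (size_t f = 0; f < H.faces.size(); ++f)
    if (H.faces[f].alive) live.push_back(&H.faces[f]);

  const double hz = spacing[0], hy = spacing[1], hx = spacing[2];
  double tol = 1e-7 * diag;
  LogicalVector out(ntot);
  int lo1 = std::max(0, (int)std::floor(zmin / hz - 1.5));
  int hi1 = std::min(n1 - 1, (int)std::ceil(zmax / hz + 0.5));
  int lo2 = std::max(0, (int)std::floor(ymin / hy - 1.5));
  int hi2 = std::min(n2 - 1, (int)std::ceil(ymax / hy + 0.5));
  int lo3 = std::max(0, (int)std::floor(xmin / hx - 1.5));
  int hi3 = std::min(n3 - 1, (int)std::ceil(xmax / hx + 0.5));
  for (int i3 = lo3; i3 <= hi3; ++i3) {
    double x = (i3 + 0.5) * hx;
    for (int i2 = lo2; i2 <= hi2; ++i2) {
      double y = (i2 + 0.5) * hy;
      for (int i1 = lo1; i1 <= hi1; ++i1) {
        double z = (i1 + 0.5) * hz;
        bool inside = true;
        for (size_t f = 0; f < live.size(); ++f) {
          const Face* fc = live[f];
          if (fc->nx * x + fc->ny * y + fc->nz * z - fc->off > tol) { inside = false; break; }
        }
        if (inside) out[i1 + (R_xlen_t)n1 * (i2 + (R_xlen_t)n2 * i3)] = true;
      }
    }
  }
  return out;
}
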