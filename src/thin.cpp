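#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <utility>
using namespace Rcpp;

// Sequential directional homotopic thinning.
//
// A voxel is deleted only while it is a *simple point* of the current object
// (Bertrand/Malandain characterisation for the (26, 6) connectivity pair):
//   (a) the object voxels of its 26-neighbourhood minus the point form exactly
//       one 26-connected component, and
//   (b) the background voxels of its 18-neighbourhood form exactly one
//       6-connected component that is 6-adjacent to the point.
// Deleting a simple point preserves both the component count and all
// independent cycles (first Betti number) of the object.  Each sweep visits
// the six face directions in turn: candidates are the voxels whose face
// neighbour in that direction is background *at collection time*, ordered by
// (distance transform, linear index), and are re-checked sequentially before
// deletion.  Collecting per direction erodes at most one voxel layer per
// sweep from every side, so free tube ends recede by roughly one radius in
// total instead of being consumed along their axis; the distance ordering
// keeps the surviving curve medial.  Voxels with at most one object
// neighbour are curve endpoints and are never removed.

// offsets within the 3x3x3 block, p = (d1+1) + 3*(d2+1) + 9*(d3+1), centre 13
static inline int pd1(int p) { return p % 3 - 1; }
static inline int pd2(int p) { return (p / 3) % 3 - 1; }
static inline int pd3(int p) { return p / 9 - 1; }

static bool is_simple(const bool nb[27]) {
  // (a) one 26-component of object among the 26 neighbours
  bool seen[27] = {false};
  int comps = 0;
  int stack[27], top;
  for (int p = 0; p < 27; ++p) {
    if (p == 13 || !nb[p] || seen[p]) continue;
    ++comps;
    if (comps > 1) return false;
    top = 0; stack[top++] = p; seen[p] = true;
    while (top) {
      int c = stack[--top];
      for (int q = 0; q < 27; ++q) {
        if (q == 13 || q == c || !nb[q] || seen[q]) continue;
        int a = pd1(c) - pd1(q), b = pd2(c) - pd2(q), d = pd3(c) - pd3(q);
        if (a >= -1 && a <= 1 && b >= -1 && b <= 1 && d >= -1 && d <= 1) {
          seen[q] = true; stack[top++] = q;
        }
      }
    }
  }
  if (comps != 1) return false;

  // (b) one 6-component of background in the 18-neighbourhood touching centre
  bool inN18[27], bg[27];
  for (int p = 0; p < 27; ++p) {
    int m = (pd1(p) ? 1 : 0) + (pd2(p) ? 1 : 0) + (pd3(p) ? 1 : 0);
    inN18[p] = (p != 13) && (m <= 2);
    bg[p] = inN18[p] && !nb[p];
  }
  bool seen2[27] = {false};
  int comps2 = 0;
  for (int p = 0; p < 27; ++p) {
    if (!bg[p] || seen2[p]) continue;
    // only count components containing a face neighbour of the centre
    // (grow first, test membership after)
    bool touches = false;
    top = 0; stack[top++] = p; seen2[p] = true;
    while (top) {
      int c = stack[--top];
      int mc = (pd1(c) ? 1 : 0) + (pd2(c) ? 1 : 0) + (pd3(c) ? 1 : 0);
      if (mc == 1) touches = true;
      for (int q = 0; q < 27; ++q) {
        if (!bg[q] || seen2[q]) continue;
        int a = pd1(c) - pd1(q), b = pd2(c) - pd2(q), d = pd3(c) - pd3(q);
        if (std::abs(a) + std::abs(b) + std::abs(d) == 1) {
          seen2[q] = true; stack[top++] = q;
        }
      }
    }
    if (touches) ++comps2;
    if (comps2 > 1) return false;
  }
  return comps2 == 1;
}

// [[Rcpp::export]]
LogicalVector cpp_thin(LogicalVector mask, IntegerVector dims, NumericVector priority) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const R_xlen_t ntot = (R_xlen_t)n1 * n2 * n3;
  std::vector<char> obj(ntot);
  std::vector<R_xlen_t> active;
  for (R_xlen_t i = 0; i < ntot; ++i) {
    obj[i] = mask[i] ? 1 : 0;
    if (obj[i]) active.push_back(i);
  }

  const int d1s[6] = {-1, 1, 0, 0, 0, 0};
  const int d2s[6] = {0, 0, -1, 1, 0, 0};
  const int d3s[6] = {0, 0, 0, 0, -1, 1};

  auto coords = [&](R_xlen_t i, int& i1, int& i2, int& i3) {
    i1 = (int)(i % n1);
    i2 = (int)((i / n1) % n2);
    i3 = (int)(i / ((R_xlen_t)n1 * n2));
  };
  auto bg_in_dir = [&](int i1, int i2, int i3, int t) {
    int j1 = i1 + d1s[t], j2 = i2 + d2s[t], j3 = i3 + d3s[t];
    if (j1 < 0 || j1 >= n1 || j2 < 0 || j2 >= n2 || j3 < 0 || j3 >= n3)
      return false;  // outside counts as object (no peeling into the frame)
    return obj[j1 + (R_xlen_t)n1 * (j2 + (R_xlen_t)n2 * j3)] == 0;
  };
  auto fetch_nb = [&](int i1, int i2, int i3, bool nb[27], int& cnt) {
    cnt = 0;
    for (int p = 0; p < 27; ++p) {
      int j1 = i1 + pd1(p), j2 = i2 + pd2(p), j3 = i3 + pd3(p);
      bool v = false;
      if (j1 >= 0 && j1 < n1 && j2 >= 0 && j2 < n2 && j3 >= 0 && j3 < n3)
        v = obj[j1 + (R_xlen_t)n1 * (j2 + (R_xlen_t)n2 * j3)] != 0;
      nb[p] = v;
      if (p != 13 && v) ++cnt;
    }
  };

  // Candidates are processed in 8 parity subfields (no two voxels of one
  // subfield are 26-adjacent), which stops a deletion from cascading along a
  // one-voxel-thick ribbon within a single subiteration; inside a subfield
  // the distance transform orders deletions medially.
  struct Item {
    int field; double prio; R_xlen_t idx;
    bool operator<(const Item& o) const {
      if (field != o.field) return field < o.field;
      if (prio != o.prio) return prio < o.prio;
      return idx < o.idx;
    }
  };
  bool nb[27];
  int cnt;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int t = 0; t < 6; ++t) {
      std::vector<Item> cand;
      for (size_t a = 0; a < active.size(); ++a) {
        R_xlen_t i = active[a];
        if (!obj[i]) continue;
        int i1, i2, i3; coords(i, i1, i2, i3);
        if (bg_in_dir(i1, i2, i3, t)) {
          Item it;
          it.field = (i1 & 1) + 2 * (i2 & 1) + 4 * (i3 & 1);
          it.prio = priority[i];
          it.idx = i;
          cand.push_back(it);
        }
      }
      std::sort(cand.begin(), cand.end());
      for (size_t c = 0; c < cand.size(); ++c) {
        R_xlen_t i = cand[c].idx;
        if (!obj[i]) continue;
        int i1, i2, i3; coords(i, i1, i2, i3);
        if (!bg_in_dir(i1, i2, i3, t)) continue;    // re-check after deletions
        fetch_nb(i1, i2, i3, nb, cnt);
        if (cnt <= 1) continue;                      // curve endpoint: keep
        if (!is_simple(nb)) continue;
        obj[i] = 0;
        changed = true;
      }
    }
    // compact the active list
    size_t w = 0;
    for (size_t a = 0; a < active.size(); ++a)
      if (obj[active[a]]) active[w++] = active[a];
    active.resize(w);
  }

  LogicalVector out(ntot);
  for (R_xlen_t i = 0; i < ntot; ++i) out[i] = obj[i] != 0;
  return out;
}
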