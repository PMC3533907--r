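// Incremental 3-D Delaunay tetrahedralization (Bowyer-Watson).
//
// Used to realize Voronoi facet-sharing adjacency: in general position the
// residue pairs whose Voronoi cells share a facet are exactly the Delaunay
// edges of the joint point set (residues + solvent shell [+ other chain]).
// Callers are expected to pre-jitter the coordinates to break the exact
// co-sphericity of grid-based shells.
//
// The implementation favours robustness at the scale this package needs
// (a few thousand points) over asymptotic speed: the cavity of each
// inserted point is found by scanning all live tetrahedra with cached
// circumspheres, so insertion is O(T) and the whole build O(n T).

#include <Rcpp.h>
#include <vector>
#include <map>
#include <array>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

namespace {

struct Tet {
  int v[4];
  double cx, cy, cz;   // circumcenter
  double r2;           // squared circumradius
  bool alive;
};

// Solve for the circumsphere of 4 points; returns false when (nearly) flat.
bool circumsphere(const std::vector<double> &px, const std::vector<double> &py,
                  const std::vector<double> &pz, const int v[4],
                  double &cx, double &cy, double &cz, double &r2) {
  const double ax = px[v[0]], ay = py[v[0]], az = pz[v[0]];
  double A[3][3], b[3];
  for (int k = 0; k < 3; ++k) {
    const double dx = px[v[k + 1]] - ax;
    const double dy = py[v[k + 1]] - ay;
    const double dz = pz[v[k + 1]] - az;
    A[k][0] = dx; A[k][1] = dy; A[k][2] = dz;
    b[k] = 0.5 * (dx * dx + dy * dy + dz * dz);
  }
  const double det =
      A[0][0] * (A[1][1] * A[2][2] - A[1][2] * A[2][1]) -
      A[0][1] * (A[1][0] * A[2][2] - A[1][2] * A[2][0]) +
      A[0][2] * (A[1][0] * A[2][1] - A[1][1] * A[2][0]);
  if (std::fabs(det) < 1e-30) return false;
  const double ix = (b[0] * (A[1][1] * A[2][2] - A[1][2] * A[2][1]) -
                     A[0][1] * (b[1] * A[2][2] - A[1][2] * b[2]) +
                     A[0][2] * (b[1] * A[2][1] - A[1][1] * b[2])) / det;
  const double iy = (A[0][0] * (b[1] * A[2][2] - A[1][2] * b[2]) -
                     b[0] * (A[1][0] * A[2][2] - A[1][2] * A[2][0]) +
                     A[0][2] * (A[1][0] * b[2] - b[1] * A[2][0])) / det;
  const double iz = (A[0][0] * (A[1][1] * b[2] - b[1] * A[2][1]) -
                     A[0][1] * (A[1][0] * b[2] - b[1] * A[2][0]) +
                     b[0] * (A[1][0] * A[2][1] - A[1][1] * A[2][0])) / det;
  cx = ax + ix; cy = ay + iy; cz = az + iz;
  r2 = ix * ix + iy * iy + iz * iz;
  return true;
}

struct Facet {
  int a, b, c;  // sorted vertex ids
  bool operator<(const Facet &o) const {
    if (a != o.a) return a < o.a;
    if (b != o.b) return b < o.b;
    return c < o.c;
  }
};

Facet make_facet(int x, int y, int z) {
  int a = x, b = y, c = z, t;
  if (a > b) { t = a; a = b; b = t; }
  if (b > c) { t = b; b = c; c = t; }
  if (a > b) { t = a; a = b; b = t; }
  Facet f; f.a = a; f.b = b; f.c = c;
  return f;
}

}  // namespace

// [[Rcpp::export(name = ".delaunay_edges_cpp")]]
IntegerMatrix delaunay_edges_cpp(NumericMatrix pts) {
  const int n = pts.nrow();
  if (n < 5) stop("tessellation failed: need at least 5 points");

  std::vector<double> px(n + 4), py(n + 4), pz(n + 4);
  double lo[3] = {R_PosInf, R_PosInf, R_PosInf};
  double hi[3] = {R_NegInf, R_NegInf, R_NegInf};
  for (int i = 0; i < n; ++i) {
    px[i] = pts(i, 0); py[i] = pts(i, 1); pz[i] = pts(i, 2);
    if (!R_finite(px[i]) || !R_finite(py[i]) || !R_finite(pz[i]))
      stop("tessellation failed: non-finite coordinate");
    lo[0] = std::min(lo[0], px[i]); hi[0] = std::max(hi[0], px[i]);
    lo[1] = std::min(lo[1], py[i]); hi[1] = std::max(hi[1], py[i]);
    lo[2] = std::min(lo[2], pz[i]); hi[2] = std::max(hi[2], pz[i]);
  }
  const double cx = 0.5 * (lo[0] + hi[0]);
  const double cy = 0.5 * (lo[1] + hi[1]);
  const double cz = 0.5 * (lo[2] + hi[2]);
  double span = std::max(hi[0] - lo[0],
                         std::max(hi[1] - lo[1], hi[2] - lo[2]));
  if (span <= 0) span = 1.0;
  // Super-tetrahedron comfortably containing every circumsphere of interest.
  const double s = 60.0 * span;
  const int s0 = n, s1 = n + 1, s2 = n + 2, s3 = n + 3;
  px[s0] = cx - s;       py[s0] = cy - s;       pz[s0] = cz - s;
  px[s1] = cx + 3 * s;   py[s1] = cy - s;       pz[s1] = cz - s;
  px[s2] = cx;           py[s2] = cy + 3 * s;   pz[s2] = cz - s;
  px[s3] = cx;           py[s3] = cy;           pz[s3] = cz + 3 * s;

  std::vector<Tet> tets;
  tets.reserve(8 * n);
  {
    Tet t; t.v[0] = s0; t.v[1] = s1; t.v[2] = s2; t.v[3] = s3; t.alive = true;
    if (!circumsphere(px, py, pz, t.v, t.cx, t.cy, t.cz, t.r2))
      stop("tessellation failed: degenerate super-tetrahedron");
    tets.push_back(t);
  }

  std::vector<int> bad;
  std::map<Facet, int> facet_count;
  std::map<Facet, std::array<int, 3> > facet_verts;

  for (int p = 0; p < n; ++p) {
    bad.clear();
    const double x = px[p], y = py[p], z = pz[p];
    for (int t = 0; t < (int)tets.size(); ++t) {
      if (!tets[t].alive) continue;
      const double dx = x - tets[t].cx, dy = y - tets[t].cy,
                   dz = z - tets[t].cz;
      if (dx * dx + dy * dy + dz * dz < tets[t].r2) bad.push_back(t);
    }
    if (bad.empty())
      stop("tessellation failed: point outside all circumspheres");

    facet_count.clear();
    facet_verts.clear();
    for (size_t k = 0; k < bad.size(); ++k) {
      const Tet &t = tets[bad[k]];
      const int f[4][3] = {{t.v[0], t.v[1], t.v[2]}, {t.v[0], t.v[1], t.v[3]},
                           {t.v[0], t.v[2], t.v[3]}, {t.v[1], t.v[2], t.v[3]}};
      for (int j = 0; j < 4; ++j) {
        Facet fa = make_facet(f[j][0], f[j][1], f[j][2]);
        facet_count[fa] += 1;
        std::array<int, 3> vv = {{f[j][0], f[j][1], f[j][2]}};
        facet_verts[fa] = vv;
      }
      tets[bad[k]].alive = false;
    }
    for (std::map<Facet, int>::const_iterator it = facet_count.begin();
         it != facet_count.end(); ++it) {
      if (it->second != 1) continue;  // interior cavity facet
      const std::array<int, 3> &vv = facet_verts[it->first];
      Tet nt;
      nt.v[0] = vv[0]; nt.v[1] = vv[1]; nt.v[2] = vv[2]; nt.v[3] = p;
      nt.alive = true;
      if (!circumsphere(px, py, pz, nt.v, nt.cx, nt.cy, nt.cz, nt.r2)) {
        // Flat sliver after jitter: treat as having an unbounded
        // circumsphere so any later point will re-open it.
        nt.cx = x; nt.cy = y; nt.cz = z; nt.r2 = R_PosInf;
      }
      tets.push_back(nt);
    }
  }

  // Verification pass: with a finite super-tetrahedron, near-hull slivers
  // of real vertices can survive without being genuinely Delaunay. Only
  // tetrahedra whose circumsphere is empty of every input point contribute
  // edges.
  for (size_t t = 0; t < tets.size(); ++t) {
    if (!tets[t].alive) continue;
    const int *v = tets[t].v;
    if (v[0] >= n && v[1] >= n && v[2] >= n && v[3] >= n) continue;
    bool has_super = v[0] >= n || v[1] >= n || v[2] >= n || v[3] >= n;
    if (has_super) continue;  // never contributes edges; skip the check
    if (!R_finite(tets[t].r2)) { tets[t].alive = false; continue; }
    const double tol = 1e-9 * tets[t].r2;
    for (int p = 0; p < n; ++p) {
      if (p == v[0] || p == v[1] || p == v[2] || p == v[3]) continue;
      const double dx = px[p] - tets[t].cx, dy = py[p] - tets[t].cy,
                   dz = pz[p] - tets[t].cz;
      if (dx * dx + dy * dy + dz * dz < tets[t].r2 - tol) {
        tets[t].alive = false;
        break;
      }
    }
  }

  std::map<std::pair<int, int>, bool> edges;
  for (size_t t = 0; t < tets.size(); ++t) {
    if (!tets[t].alive) continue;
    const int *v = tets[t].v;
    for (int a = 0; a < 4; ++a) {
      if (v[a] >= n) continue;  // super vertex
      for (int b = a + 1; b < 4; ++b) {
        if (v[b] >= n) continue;
        const int lo_ = std::min(v[a], v[b]);
        const int hi_ = std::max(v[a], v[b]);
        edges[std::make_pair(lo_, hi_)] = true;
      }
    }
  }

  IntegerMatrix out(edges.size(), 2);
  int r = 0;
  for (std::map<std::pair<int, int>, bool>::const_iterator it = edges.begin();
       it != edges.end(); ++it, ++r) {
    out(r, 0) = it->first.first + 1;   // 1-based for R
    out(r, 1) = it->first.second + 1;
  }
  return out;
}
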