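// 3-D Delaunay triangulation by incremental Bowyer-Watson insertion.
// Used for cutoff-free "natural neighbor" contact detection between atoms:
// an atom pair is a candidate contact iff it is an edge of the triangulation,
// which also removes occluded pairs (an intervening atom breaks the empty
// circumsphere property).
//
// Predicates are evaluated in long double; exactly degenerate inputs
// (coplanar/cospherical beyond the guard) raise an error with the word
// "degenerate" so the R wrapper can retry after a deterministic jitter.
#include <Rcpp.h>
#include <array>
#include <cmath>
#include <map>
#include <vector>
using namespace Rcpp;

namespace {

typedef long double ld;

struct Tet {
  int v[4];
  ld c[3];   // circumcenter
  ld r2;     // squared circumradius
  bool alive;
};

typedef std::vector<std::array<ld, 3> > Points;

inline ld dist2(const ld a[3], const std::array<ld, 3>& b) {
  ld s = 0.0L;
  for (int k = 0; k < 3; ++k) {
    ld d = a[k] - b[k];
    s += d * d;
  }
  return s;
}

// Circumsphere of four points; false when (near-)coplanar.
bool circumsphere(const Points& P, int a, int b, int c, int d,
                  ld cen[3], ld& r2) {
  ld A[3][3], rhs[3];
  int idx[3] = {b, c, d};
  ld a2 = P[a][0] * P[a][0] + P[a][1] * P[a][1] + P[a][2] * P[a][2];
  for (int i = 0; i < 3; ++i) {
    ld n2 = 0.0L;
    for (int k = 0; k < 3; ++k) {
      A[i][k] = 2.0L * (P[idx[i]][k] - P[a][k]);
      n2 += P[idx[i]][k] * P[idx[i]][k];
    }
    rhs[i] = n2 - a2;
  }
  ld det =
      A[0][0] * (A[1][1] * A[2][2] - A[1][2] * A[2][1]) -
      A[0][1] * (A[1][0] * A[2][2] - A[1][2] * A[2][0]) +
      A[0][2] * (A[1][0] * A[2][1] - A[1][1] * A[2][0]);
  ld scale = 0.0L;
  for (int i = 0; i < 3; ++i)
    for (int k = 0; k < 3; ++k)
      scale = std::max(scale, (ld)std::fabs((double)A[i][k]));
  if (std::fabs((double)det) < 1e-13 * std::max(1.0, (double)(scale * scale * scale)))
    return false;
  ld inv[3][3];
  inv[0][0] = (A[1][1] * A[2][2] - A[1][2] * A[2][1]) / det;
  inv[0][1] = (A[0][2] * A[2][1] - A[0][1] * A[2][2]) / det;
  inv[0][2] = (A[0][1] * A[1][2] - A[0][2] * A[1][1]) / det;
  inv[1][0] = (A[1][2] * A[2][0] - A[1][0] * A[2][2]) / det;
  inv[1][1] = (A[0][0] * A[2][2] - A[0][2] * A[2][0]) / det;
  inv[1][2] = (A[0][2] * A[1][0] - A[0][0] * A[1][2]) / det;
  inv[2][0] = (A[1][0] * A[2][1] - A[1][1] * A[2][0]) / det;
  inv[2][1] = (A[0][1] * A[2][0] - A[0][0] * A[2][1]) / det;
  inv[2][2] = (A[0][0] * A[1][1] - A[0][1] * A[1][0]) / det;
  for (int i = 0; i < 3; ++i) {
    cen[i] = 0.0L;
    for (int k = 0; k < 3; ++k) cen[i] += inv[i][k] * rhs[k];
  }
  r2 = dist2(cen, P[a]);
  return true;
}

}  // namespace

// [[Rcpp::export(name = ".delaunay_edges_cpp")]]
IntegerMatrix delaunay_edges_cpp(NumericMatrix coords) {
  int n = coords.nrow();
  if (n < 4) stop("Delaunay triangulation requires at least 4 points");
  Points P(n + 4);
  ld lo[3], hi[3];
  for (int k = 0; k < 3; ++k) {
    lo[k] = 1e300L;
    hi[k] = -1e300L;
  }
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) {
      if (!std::isfinite(coords(i, k))) stop("non-finite coordinate");
      P[i][k] = (ld)coords(i, k);
      lo[k] = std::min(lo[k], P[i][k]);
      hi[k] = std::max(hi[k], P[i][k]);
    }
  ld ext = 1.0L, mid[3];
  for (int k = 0; k < 3; ++k) {
    ext = std::max(ext, hi[k] - lo[k]);
    mid[k] = 0.5L * (lo[k] + hi[k]);
  }
  ld big = 2.0e3L * ext;  // super-tetrahedron well outside all circumspheres
  ld sv[4][3] = {{0, 0, big * 3},
                 {big * -2.82843L, 0, -big},
                 {big * 1.41421L, big * 2.44949L, -big},
                 {big * 1.41421L, big * -2.44949L, -big}};
  for (int s = 0; s < 4; ++s)
    for (int k = 0; k < 3; ++k) P[n + s][k] = mid[k] + sv[s][k];

  std::vector<Tet> tets;
  {
    Tet t0;
    for (int s = 0; s < 4; ++s) t0.v[s] = n + s;
    if (!circumsphere(P, n, n + 1, n + 2, n + 3, t0.c, t0.r2))
      stop("degenerate super-tetrahedron");
    t0.alive = true;
    tets.push_back(t0);
  }

  typedef std::array<int, 3> Face;
  for (int p = 0; p < n; ++p) {
    std::vector<int> bad;
    for (size_t t = 0; t < tets.size(); ++t) {
      if (!tets[t].alive) continue;
      ld tol = 1e-12L * (1.0L + tets[t].r2);
      if (dist2(tets[t].c, P[p]) < tets[t].r2 - tol) bad.push_back((int)t);
    }
    if (bad.empty())
      stop("degenerate point configuration (point in no circumsphere)");
    std::map<Face, int> faces;
    for (size_t b = 0; b < bad.size(); ++b) {
      const int* v = tets[bad[b]].v;
      int combo[4][3] = {{0, 1, 2}, {0, 1, 3}, {0, 2, 3}, {1, 2, 3}};
      for (int f = 0; f < 4; ++f) {
        Face fc = {{v[combo[f][0]], v[combo[f][1]], v[combo[f][2]]}};
        std::sort(fc.begin(), fc.end());
        faces[fc] += 1;
      }
      tets[bad[b]].alive = false;
    }
    for (std::map<Face, int>::const_iterator it = faces.begin();
         it != faces.end(); ++it) {
      if (it->second != 1) continue;
      Tet nt;
      nt.v[0] = it->first[0];
      nt.v[1] = it->first[1];
      nt.v[2] = it->first[2];
      nt.v[3] = p;
      if (!circumsphere(P, nt.v[0], nt.v[1], nt.v[2], nt.v[3], nt.c, nt.r2))
        stop("degenerate point configuration (coplanar cavity face)");
      nt.alive = true;
      tets.push_back(nt);
    }
  }

  std::map<std::pair<int, int>, bool> edges;
  for (size_t t = 0; t < tets.size(); ++t) {
    if (!tets[t].alive) continue;
    const int* v = tets[t].v;
    bool super = false;
    for (int s = 0; s < 4; ++s)
      if (v[s] >= n) super = true;
    if (super) continue;
    for (int a = 0; a < 4; ++a)
      for (int b = a + 1; b < 4; ++b) {
        int i = std::min(v[a], v[b]), j = std::max(v[a], v[b]);
        edges[std::make_pair(i, j)] = true;
      }
  }
  IntegerMatrix out((int)edges.size(), 2);
  int r = 0;
  for (std::map<std::pair<int, int>, bool>::const_iterator it = edges.begin();
       it != edges.end(); ++it, ++r) {
    out(r, 0) = it->first.first + 1;   // 1-based for R
    out(r, 1) = it->first.second + 1;
  }
  return out;
}
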