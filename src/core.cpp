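#include <Rcpp.h>
#include <vector>
#include <array>
#include <algorithm>
#include <cmath>
#include <limits>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// 3D convex hull volume, incremental algorithm.
//
// Coordinates are collapsed to a 1e-12 grid before construction so that
// exactly-coplanar neighbourhoods (common on quantised trait rasters) are
// detected as degenerate instead of producing slivers of spurious volume.
// Degenerate inputs (S < 4, collinear, coplanar) yield volume 0.
// ---------------------------------------------------------------------------

namespace {

struct Vec3 {
  double x, y, z;
};

inline Vec3 sub(const Vec3 &a, const Vec3 &b) {
  return Vec3{a.x - b.x, a.y - b.y, a.z - b.z};
}
inline Vec3 cross(const Vec3 &a, const Vec3 &b) {
  return Vec3{a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z,
              a.x * b.y - a.y * b.x};
}
inline double dot(const Vec3 &a, const Vec3 &b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}
inline double norm(const Vec3 &a) { return std::sqrt(dot(a, a)); }

struct Face {
  int a, b, c;     // vertex indices, outward orientation
  Vec3 n;          // outward normal (not unit)
  double off;      // plane offset: dot(n, p) = off on the plane
  bool alive;
};

inline double snap12(double v) {
  // collapse to 1e-12 grid; stabilises coplanarity detection
  return std::nearbyint(v * 1e12) / 1e12;
}

Face make_face(int a, int b, int c, const std::vector<Vec3> &P,
               const Vec3 &interior) {
  Face f;
  f.a = a; f.b = b; f.c = c;
  f.n = cross(sub(P[b], P[a]), sub(P[c], P[a]));
  f.off = dot(f.n, P[a]);
  // orient outward relative to a point strictly inside the hull
  if (dot(f.n, interior) > f.off) {
    std::swap(f.b, f.c);
    f.n = Vec3{-f.n.x, -f.n.y, -f.n.z};
    f.off = -f.off;
  }
  f.alive = true;
  return f;
}

double hull_volume_impl(const std::vector<Vec3> &pts_in) {
  const double EPS = 1e-10;
  // dedupe snapped points
  std::vector<Vec3> P;
  P.reserve(pts_in.size());
  {
    std::vector<std::array<double, 3>> tmp;
    tmp.reserve(pts_in.size());
    for (const Vec3 &p : pts_in)
      tmp.push_back({snap12(p.x), snap12(p.y), snap12(p.z)});
    std::sort(tmp.begin(), tmp.end());
    tmp.erase(std::unique(tmp.begin(), tmp.end()), tmp.end());
    for (auto &t : tmp) P.push_back(Vec3{t[0], t[1], t[2]});
  }
  const int n = (int)P.size();
  if (n < 4) return 0.0;

  // initial simplex: spread-out extreme points
  int i1 = 1;
  double best = -1.0;
  for (int i = 1; i < n; ++i) {
    double d = norm(sub(P[i], P[0]));
    if (d > best) { best = d; i1 = i; }
  }
  if (best < EPS) return 0.0;
  int i2 = -1;
  best = -1.0;
  for (int i = 0; i < n; ++i) {
    if (i == 0 || i == i1) continue;
    double d = norm(cross(sub(P[i1], P[0]), sub(P[i], P[0])));
    if (d > best) { best = d; i2 = i; }
  }
  if (i2 < 0 || best < EPS) return 0.0;
  Vec3 nrm = cross(sub(P[i1], P[0]), sub(P[i2], P[0]));
  int i3 = -1;
  best = -1.0;
  for (int i = 0; i < n; ++i) {
    if (i == 0 || i == i1 || i == i2) continue;
    double d = std::fabs(dot(nrm, sub(P[i], P[0])));
    if (d > best) { best = d; i3 = i; }
  }
  if (i3 < 0 || best < EPS) return 0.0;  // all coplanar

  Vec3 interior{(P[0].x + P[i1].x + P[i2].x + P[i3].x) / 4.0,
                (P[0].y + P[i1].y + P[i2].y + P[i3].y) / 4.0,
                (P[0].z + P[i1].z + P[i2].z + P[i3].z) / 4.0};

  std::vector<Face> faces;
  faces.push_back(make_face(0, i1, i2, P, interior));
  faces.push_back(make_face(0, i1, i3, P, interior));
  faces.push_back(make_face(0, i2, i3, P, interior));
  faces.push_back(make_face(i1, i2, i3, P, interior));

  std::vector<bool> used(n, false);
  used[0] = used[i1] = used[i2] = used[i3] = true;

  for (int p = 0; p < n; ++p) {
    if (used[p]) continue;
    // visible faces
    std::vector<int> vis;
    for (int f = 0; f < (int)faces.size(); ++f) {
      if (!faces[f].alive) continue;
      if (dot(faces[f].n, P[p]) - faces[f].off >
          EPS * (1.0 + std::fabs(faces[f].off)))
        vis.push_back(f);
    }
    if (vis.empty()) continue;  // inside or on hull
    // horizon = edges appearing exactly once among visible faces
    std::vector<std::pair<int, int>> edges;
    for (int f : vis) {
      const Face &fc = faces[f];
      int e[3][2] = {{fc.a, fc.b}, {fc.b, fc.c}, {fc.c, fc.a}};
      for (auto &ed : e) {
        int lo = std::min(ed[0], ed[1]), hi = std::max(ed[0], ed[1]);
        edges.push_back({lo, hi});
      }
      faces[f].alive = false;
    }
    std::sort(edges.begin(), edges.end());
    for (size_t k = 0; k < edges.size();) {
      size_t j = k;
      while (j < edges.size() && edges[j] == edges[k]) ++j;
      if (j - k == 1)  // horizon edge
        faces.push_back(make_face(edges[k].first, edges[k].second, p, P,
                                  interior));
      k = j;
    }
  }

  // volume: fan of tetrahedra from the interior point over live faces
  double vol = 0.0;
  for (const Face &f : faces) {
    if (!f.alive) continue;
    Vec3 a = sub(P[f.a], interior), b = sub(P[f.b], interior),
         c = sub(P[f.c], interior);
    vol += dot(a, cross(b, c));
  }
  return std::fabs(vol) / 6.0;
}

double hull_volume_mat(const double *x, const double *y, const double *z,
                       int n) {
  std::vector<Vec3> pts(n);
  for (int i = 0; i < n; ++i) pts[i] = Vec3{x[i], y[i], z[i]};
  return hull_volume_impl(pts);
}

// ---------------------------------------------------------------------------
// Prim MST on a point set (Euclidean, dense). Deterministic tie rule: on
// equal candidate distances the edge with the lexicographically smaller
// (parent, vertex) index pair wins.
// ---------------------------------------------------------------------------

struct MstResult {
  std::vector<int> from, to;
  std::vector<double> len;
};

MstResult prim_mst(const double *x, const double *y, const double *z, int n) {
  MstResult res;
  if (n < 2) return res;
  std::vector<bool> inTree(n, false);
  std::vector<double> key(n, std::numeric_limits<double>::infinity());
  std::vector<int> parent(n, -1);
  key[0] = 0.0;
  for (int it = 0; it < n; ++it) {
    int u = -1;
    for (int v = 0; v < n; ++v) {
      if (inTree[v]) continue;
      if (u < 0 || key[v] < key[u]) { u = v; continue; }
      if (key[v] == key[u] &&
          std::make_pair(parent[v], v) < std::make_pair(parent[u], u))
        u = v;
    }
    inTree[u] = true;
    if (parent[u] >= 0) {
      res.from.push_back(parent[u]);
      res.to.push_back(u);
      res.len.push_back(key[u]);
    }
    for (int v = 0; v < n; ++v) {
      if (inTree[v]) continue;
      double dx = x[u] - x[v], dy = y[u] - y[v], dz = z[u] - z[v];
      double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (d < key[v] || (d == key[v] && std::make_pair(u, v) <
                                            std::make_pair(parent[v], v)))
        { key[v] = d; parent[v] = u; }
    }
  }
  return res;
}

// FDiv per Villeger-style centre-of-gravity geometry; NA if all points
// coincide (mean distance zero).
double fdiv_impl(const double *x, const double *y, const double *z, int n) {
  if (n < 2) return NA_REAL;
  double cx = 0, cy = 0, cz = 0;
  for (int i = 0; i < n; ++i) { cx += x[i]; cy += y[i]; cz += z[i]; }
  cx /= n; cy /= n; cz /= n;
  std::vector<double> d(n);
  double dbar = 0;
  for (int i = 0; i < n; ++i) {
    double dx = x[i] - cx, dy = y[i] - cy, dz = z[i] - cz;
    d[i] = std::sqrt(dx * dx + dy * dy + dz * dz);
    dbar += d[i];
  }
  dbar /= n;
  if (dbar <= 0) return NA_REAL;
  double dev = 0;
  for (int i = 0; i < n; ++i) dev += std::fabs(d[i] - dbar);
  dev /= n;
  return dbar / (dev + dbar);
}

// FEve from the MST branch-length distribution; NA for S < 3 or a
// zero-length tree (all points identical).
double feve_impl(const double *x, const double *y, const double *z, int n) {
  if (n < 3) return NA_REAL;
  MstResult mst = prim_mst(x, y, z, n);
  double tot = 0;
  for (double l : mst.len) tot += l;
  if (tot <= 0) return NA_REAL;
  const double thr = 1.0 / (n - 1);
  double s = 0;
  for (double l : mst.len) s += std::min(l / tot, thr);
  return (s - thr) / (1.0 - thr);
}

}  // namespace

// [[Rcpp::export]]
double cpp_hull_volume(NumericMatrix pts) {
  int n = pts.nrow();
  std::vector<double> x(n), y(n), z(n);
  for (int i = 0; i < n; ++i) {
    x[i] = pts(i, 0); y[i] = pts(i, 1); z[i] = pts(i, 2);
  }
  return hull_volume_mat(x.data(), y.data(), z.data(), n);
}

// [[Rcpp::export]]
List cpp_mst(NumericMatrix pts) {
  int n = pts.nrow();
  std::vector<double> x(n), y(n), z(n);
  for (int i = 0; i < n; ++i) {
    x[i] = pts(i, 0); y[i] = pts(i, 1); z[i] = pts(i, 2);
  }
  MstResult m = prim_mst(x.data(), y.data(), z.data(), n);
  return List::create(_["from"] = wrap(m.from), _["to"] = wrap(m.to),
                      _["length"] = wrap(m.len));
}

// [[Rcpp::export]]
double cpp_fdiv(NumericMatrix pts) {
  int n = pts.nrow();
  std::vector<double> x(n), y(n), z(n);
  for (int i = 0; i < n; ++i) {
    x[i] = pts(i, 0); y[i] = pts(i, 1); z[i] = pts(i, 2);
  }
  return fdiv_impl(x.data(), y.data(), z.data(), n);
}

// [[Rcpp::export]]
double cpp_feve(NumericMatrix pts) {
  int n = pts.nrow();
  std::vector<double> x(n), y(n), z(n);
  for (int i = 0; i < n; ++i) {
    x[i] = pts(i, 0); y[i] = pts(i, 1); z[i] = pts(i, 2);
  }
  return feve_impl(x.data(), y.data(), z.data(), n);
}

// ---------------------------------------------------------------------------
// Moving-window engine: one pass over the raster, computing a diversity
// index per masked pixel from its disc neighbourhood. Offsets are the
// precomputed (drow, dcol) pairs of the disc; traits t1..t3 are full
// matrices; mask is TRUE where the pixel carries a valid trait triplet.
// index: 1 = richness, 2 = divergence, 3 = evenness.
// min_points: samples smaller than this become NA (richness only).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix cpp_diversity_map(NumericMatrix t1, NumericMatrix t2,
                                NumericMatrix t3, LogicalMatrix mask,
                                IntegerMatrix offsets, int index,
                                int min_points) {
  const int nr = t1.nrow(), nc = t1.ncol(), K = offsets.nrow();
  NumericMatrix out(nr, nc);
  std::fill(out.begin(), out.end(), NA_REAL);
  std::vector<double> x, y, z;
  x.reserve(K); y.reserve(K); z.reserve(K);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c)) continue;
      x.clear(); y.clear(); z.clear();
      for (int k = 0; k < K; ++k) {
        int rr = r + offsets(k, 0), cc = c + offsets(k, 1);
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        if (!mask(rr, cc)) continue;
        x.push_back(t1(rr, cc));
        y.push_back(t2(rr, cc));
        z.push_back(t3(rr, cc));
      }
      const int S = (int)x.size();
      if (S == 0) continue;
      double v;
      switch (index) {
        case 1:
          if (S < min_points) { v = NA_REAL; break; }
          v = hull_volume_mat(x.data(), y.data(), z.data(), S);
          break;
        case 2: v = fdiv_impl(x.data(), y.data(), z.data(), S); break;
        default: v = feve_impl(x.data(), y.data(), z.data(), S); break;
      }
      out(r, c) = v;
    }
  }
  return out;
}

// Per-pixel neighbourhood size (count of masked pixels in the disc), used by
// the under-dispersion null model to match sample sizes.
// [[Rcpp::export]]
IntegerMatrix cpp_neighbourhood_size(LogicalMatrix mask,
                                     IntegerMatrix offsets) {
  const int nr = mask.nrow(), nc = mask.ncol(), K = offsets.nrow();
  IntegerMatrix out(nr, nc);
  std::fill(out.begin(), out.end(), NA_INTEGER);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c)) continue;
      int s = 0;
      for (int k = 0; k < K; ++k) {
        int rr = r + offsets(k, 0), cc = c + offsets(k, 1);
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        if (mask(rr, cc)) ++s;
      }
      out(r, c) = s;
    }
  return out;
}
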