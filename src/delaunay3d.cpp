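// Incremental (Bowyer-Watson) 3D Delaunay tetrahedralization.
// Coordinates are normalized to the unit box internally; Delaunayhood is
// invariant under uniform scaling + translation.  A tiny deterministic
// symbolic perturbation (LCG-driven, default 1e-9 of the bounding box) makes
// the triangulation unique on degenerate (gridded / cospherical) inputs; the
// perturbation never leaves the returned combinatorics' tolerance on generic
// inputs and output facets always reference the ORIGINAL point indices.
#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <map>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

namespace {

struct Tet {
  int v[4];
  int nb[4];      // nb[i] = tet sharing the face opposite v[i], -1 if none
  double cx, cy, cz, r2;  // circumsphere
  bool alive;
};

struct P3 { double x, y, z; };

inline double vol6(const P3 &a, const P3 &b, const P3 &c, const P3 &d) {
  double bx = b.x - a.x, by = b.y - a.y, bz = b.z - a.z;
  double cx = c.x - a.x, cy = c.y - a.y, cz = c.z - a.z;
  double dx = d.x - a.x, dy = d.y - a.y, dz = d.z - a.z;
  return bx * (cy * dz - cz * dy) - by * (cx * dz - cz * dx) +
         bz * (cx * dy - cy * dx);
}

inline double lcg01(uint64_t &s) {
  s = s * 6364136223846793005ULL + 1442695040888963407ULL;
  return double((s >> 11) & ((1ULL << 53) - 1)) / double(1ULL << 53);
}

class Delaunay3 {
public:
  std::vector<P3> pts;            // normalized (+ super vertices at end)
  std::vector<Tet> tets;
  int n;                          // number of real points
  int lastAlive = 0;
  double tolO = 1e-13;            // orientation tolerance (unit box)

  bool circumsphere(Tet &t) {
    const P3 &a = pts[t.v[0]], &b = pts[t.v[1]], &c = pts[t.v[2]],
             &d = pts[t.v[3]];
    double ax = b.x - a.x, ay = b.y - a.y, az = b.z - a.z;
    double bx = c.x - a.x, by = c.y - a.y, bz = c.z - a.z;
    double cx = d.x - a.x, cy = d.y - a.y, cz = d.z - a.z;
    double det = ax * (by * cz - bz * cy) - ay * (bx * cz - bz * cx) +
                 az * (bx * cy - by * cx);
    if (std::fabs(det) < 1e-300) return false;
    double ra = 0.5 * (ax * ax + ay * ay + az * az);
    double rb = 0.5 * (bx * bx + by * by + bz * bz);
    double rc = 0.5 * (cx * cx + cy * cy + cz * cz);
    double ux = (ra * (by * cz - bz * cy) - ay * (rb * cz - bz * rc) +
                 az * (rb * cy - by * rc)) / det;
    double uy = (ax * (rb * cz - bz * rc) - ra * (bx * cz - bz * cx) +
                 az * (bx * rc - rb * cx)) / det;
    double uz = (ax * (by * rc - rb * cy) - ay * (bx * rc - rb * cx) +
                 ra * (bx * cy - by * cx)) / det;
    t.cx = a.x + ux; t.cy = a.y + uy; t.cz = a.z + uz;
    t.r2 = ux * ux + uy * uy + uz * uz;
    return true;
  }

  // insphere by the 4x4 determinant in extended precision: for a positively
  // oriented tet the determinant is positive iff p lies strictly inside the
  // circumsphere.  Avoids the catastrophic cancellation of an explicit
  // circumcentre for flat tets.
  inline bool inSphere(const Tet &t, const P3 &p) const {
    long double m[4][4];
    for (int i = 0; i < 4; ++i) {
      const P3 &q = pts[t.v[i]];
      long double dx = (long double)q.x - p.x;
      long double dy = (long double)q.y - p.y;
      long double dz = (long double)q.z - p.z;
      m[i][0] = dx; m[i][1] = dy; m[i][2] = dz;
      m[i][3] = dx * dx + dy * dy + dz * dz;
    }
    long double det = 0;
    for (int i = 0; i < 4; ++i) {
      int r0 = (i + 1) % 4, r1 = (i + 2) % 4, r2i = (i + 3) % 4;
      long double c3 =
        m[r0][0] * (m[r1][1] * m[r2i][2] - m[r1][2] * m[r2i][1]) -
        m[r0][1] * (m[r1][0] * m[r2i][2] - m[r1][2] * m[r2i][0]) +
        m[r0][2] * (m[r1][0] * m[r2i][1] - m[r1][1] * m[r2i][0]);
      long double term = m[i][3] * c3;
      det += ((i % 2) == 0 ? term : -term);
    }
    // row-permutation parity: moving row i to the top flips sign by i
    // (handled by the alternating sign above); orientation of the stored
    // tet is positive, so det > 0 means inside
    return det > 0;
  }

  // conflict predicate: numeric insphere, plus a symbolic visibility catch
  // for tets with exactly one super vertex.  Their circumspheres are huge
  // and lose precision, which can leave thin hull wedges attached to the
  // super shell; p conflicts with such a tet whenever it lies on (or
  // numerically near) the outer side of the tet's real facet.
  bool conflicts(const Tet &t, const P3 &p) const {
    if (inSphere(t, p)) return true;
    int sup = -1, nsup = 0;
    for (int i = 0; i < 4; ++i)
      if (t.v[i] >= n) { sup = i; ++nsup; }
    if (nsup != 1) return false;
    // replace the super vertex by p: non-negative volume means p lies on or
    // beyond the tet's real (hull) facet, on the super side
    return faceTest(t, sup, p) >= -1e-12;
  }

  // signed volume with vertex i of tet replaced by p (order preserved)
  double faceTest(const Tet &t, int i, const P3 &p) const {
    P3 q[4] = {pts[t.v[0]], pts[t.v[1]], pts[t.v[2]], pts[t.v[3]]};
    q[i] = p;
    return vol6(q[0], q[1], q[2], q[3]);
  }

  int locate(const P3 &p) {
    int cur = lastAlive;
    if (cur >= (int)tets.size() || !tets[cur].alive) cur = -1;
    if (cur < 0) {
      for (int i = (int)tets.size() - 1; i >= 0; --i)
        if (tets[i].alive) { cur = i; break; }
    }
    int steps = 0, limit = (int)tets.size() + 64;
    while (cur >= 0 && steps++ < limit) {
      const Tet &t = tets[cur];
      double worst = -tolO;
      int wi = -1;
      for (int i = 0; i < 4; ++i) {
        double d = faceTest(t, i, p);
        if (d < worst) { worst = d; wi = i; }
      }
      if (wi < 0) return cur;          // inside (or on boundary)
      int nxt = t.nb[wi];
      if (nxt < 0 || !tets[nxt].alive) break;
      cur = nxt;
    }
    // fallback: linear scan for a tet whose circumsphere contains p
    for (int i = (int)tets.size() - 1; i >= 0; --i)
      if (tets[i].alive && inSphere(tets[i], p)) return i;
    return -1;
  }

  bool insert(int pi) {
    const P3 &p = pts[pi];
    int t0 = locate(p);
    if (t0 < 0) return false;
    // reject (near-)duplicate points
    for (int i = 0; i < 4; ++i) {
      const P3 &q = pts[tets[t0].v[i]];
      double dx = p.x - q.x, dy = p.y - q.y, dz = p.z - q.z;
      if (dx * dx + dy * dy + dz * dz < 1e-28) return false;
    }
    // cavity: BFS over tets whose circumsphere contains p
    std::vector<int> cavity;
    std::vector<char> inCav(tets.size(), 0);
    std::vector<int> stack;
    // p lies inside t0 (located), so carving t0 is always valid even when
    // the conflict predicate is numerically undecided for it
    stack.push_back(t0); inCav[t0] = 1;
    while (!stack.empty()) {
      int ti = stack.back(); stack.pop_back();
      cavity.push_back(ti);
      for (int i = 0; i < 4; ++i) {
        int nb = tets[ti].nb[i];
        if (nb >= 0 && tets[nb].alive && !inCav[nb] &&
            conflicts(tets[nb], p)) {
          inCav[nb] = 1; stack.push_back(nb);
        }
      }
    }
    // cavity repair: refilling assumes the cavity is star-shaped around p,
    // i.e. every boundary facet has p strictly on its interior side (the
    // facet then becomes the base of a positively oriented refill tet).
    // Marginal insphere decisions can violate this; expand the cavity
    // across any offending facet until it holds.
    {
      bool changed = true;
      while (changed) {
        changed = false;
        for (size_t ci = 0; ci < cavity.size(); ++ci) {
          int ti = cavity[ci];
          const Tet &t = tets[ti];
          for (int i = 0; i < 4; ++i) {
            int nb = t.nb[i];
            if (nb >= 0 && (inCav[nb] || !tets[nb].alive)) continue;
            // p must lie strictly on the interior side of this boundary
            // facet; the stored orientation makes faceTest the exact
            // parity-correct signed volume of the refill tet
            if (faceTest(t, i, p) < 1e-14 && nb >= 0) {
              inCav[nb] = 1;
              cavity.push_back(nb);
              changed = true;
            }
          }
        }
      }
    }
    // boundary facets of the cavity
    struct BFace { int a, b, c, outside, outFace; };
    std::vector<BFace> bnd;
    for (int ti : cavity) {
      const Tet &t = tets[ti];
      for (int i = 0; i < 4; ++i) {
        int nb = t.nb[i];
        if (nb >= 0 && inCav[nb]) continue;
        BFace f;
        int k = 0;
        int vv[3];
        for (int j = 0; j < 4; ++j) if (j != i) vv[k++] = t.v[j];
        f.a = vv[0]; f.b = vv[1]; f.c = vv[2];
        f.outside = nb;
        f.outFace = -1;
        if (nb >= 0) {
          for (int j = 0; j < 4; ++j) if (tets[nb].nb[j] == ti) f.outFace = j;
        }
        bnd.push_back(f);
      }
    }
    if (bnd.empty()) return false;
    // carve
    for (int ti : cavity) tets[ti].alive = false;
    // fill
    std::map<std::pair<int,int>, std::pair<int,int>> half; // edge -> (tet, face slot)
    std::vector<int> created;
    for (const BFace &f : bnd) {
      Tet nt;
      nt.v[0] = pi; nt.v[1] = f.a; nt.v[2] = f.b; nt.v[3] = f.c;
      double vol = vol6(pts[nt.v[0]], pts[nt.v[1]], pts[nt.v[2]], pts[nt.v[3]]);
      if (vol < 0) { std::swap(nt.v[2], nt.v[3]); }
      nt.nb[0] = f.outside;  // face opposite pi = the boundary facet
      nt.nb[1] = nt.nb[2] = nt.nb[3] = -1;
      nt.alive = true;
      if (!circumsphere(nt)) { nt.r2 = -1; }
      int id = (int)tets.size();
      tets.push_back(nt);
      created.push_back(id);
      if (f.outside >= 0 && f.outFace >= 0) tets[f.outside].nb[f.outFace] = id;
      // stitch internal faces: face opposite v[k] (k=1..3) contains pi and the
      // edge made of the other two non-pi vertices
      for (int k = 1; k < 4; ++k) {
        int e1 = -1, e2 = -1;
        for (int j = 1; j < 4; ++j) if (j != k) { (e1 < 0 ? e1 : e2) = tets[id].v[j]; }
        std::pair<int,int> key(std::min(e1, e2), std::max(e1, e2));
        auto it = half.find(key);
        if (it == half.end()) {
          half[key] = std::make_pair(id, k);
        } else {
          tets[id].nb[k] = it->second.first;
          tets[it->second.first].nb[it->second.second] = id;
          half.erase(it);
        }
      }
    }
    lastAlive = created.back();
    return true;
  }
};

} // namespace

// [[Rcpp::export(name = ".delaunay3d_cpp")]]
List delaunay3d_cpp(NumericMatrix points, double jitter = 1e-9,
                    int jitter_seed = 20260920) {
  int n = points.nrow();
  if (n < 4) stop("need at least 4 points for a 3D Delaunay tetrahedralization");
  Delaunay3 D;
  D.n = n;
  // normalize to unit box
  double mn[3], mx[3];
  for (int k = 0; k < 3; ++k) { mn[k] = R_PosInf; mx[k] = R_NegInf; }
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) {
      double v = points(i, k);
      if (!R_finite(v)) stop("non-finite coordinate at point %d", i + 1);
      if (v < mn[k]) mn[k] = v;
      if (v > mx[k]) mx[k] = v;
    }
  double scale = 0.0;
  for (int k = 0; k < 3; ++k) scale = std::max(scale, mx[k] - mn[k]);
  if (scale <= 0) stop("all points coincide");
  uint64_t rs = (uint64_t)jitter_seed * 2654435761ULL + 1ULL;
  D.pts.resize(n + 4);
  for (int i = 0; i < n; ++i) {
    P3 p;
    p.x = (points(i, 0) - mn[0]) / scale + jitter * (lcg01(rs) - 0.5);
    p.y = (points(i, 1) - mn[1]) / scale + jitter * (lcg01(rs) - 0.5);
    p.z = (points(i, 2) - mn[2]) / scale + jitter * (lcg01(rs) - 0.5);
    D.pts[i] = p;
  }
  // super tetrahedron enclosing the unit box.  It must be FAR away: a thin
  // hull sliver of depth d has circumradius ~ 1/d, and a super vertex inside
  // that circumsphere would (correctly, for the augmented point set) forbid
  // the sliver, denting the hull.  1e6 keeps slivers down to ~1e-6 depth.
  double K = 1e6;
  D.pts[n + 0] = {-K, -K, -K};
  D.pts[n + 1] = { 3 * K, -K, -K};
  D.pts[n + 2] = {-K, 3 * K, -K};
  D.pts[n + 3] = {-K, -K, 3 * K};
  Tet st;
  st.v[0] = n; st.v[1] = n + 1; st.v[2] = n + 2; st.v[3] = n + 3;
  if (vol6(D.pts[st.v[0]], D.pts[st.v[1]], D.pts[st.v[2]], D.pts[st.v[3]]) < 0)
    std::swap(st.v[2], st.v[3]);
  st.nb[0] = st.nb[1] = st.nb[2] = st.nb[3] = -1;
  st.alive = true;
  D.circumsphere(st);
  D.tets.push_back(st);
  // insertion order: deterministic shuffle (helps walk locality pathologies)
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  uint64_t ss = 0x9E3779B97F4A7C15ULL;
  for (int i = n - 1; i > 0; --i) {
    int j = (int)(lcg01(ss) * (i + 1));
    if (j > i) j = i;
    std::swap(order[i], order[j]);
  }
  int skipped = 0;
  for (int idx = 0; idx < n; ++idx) {
    if (!D.insert(order[idx])) ++skipped;
    if ((idx & 1023) == 0) Rcpp::checkUserInterrupt();
  }
  // collect real tets and unique facets
  std::vector<std::array<int,4>> tv;
  for (const Tet &t : D.tets) {
    if (!t.alive) continue;
    bool super = false;
    for (int i = 0; i < 4; ++i) if (t.v[i] >= n) { super = true; break; }
    if (!super) tv.push_back({t.v[0], t.v[1], t.v[2], t.v[3]});
  }
  if (tv.empty())
    stop("degenerate input: points are coplanar (no tetrahedron survives)");
  std::unordered_map<uint64_t, std::array<int,3>> fmap;
  fmap.reserve(tv.size() * 4);
  const int faceIdx[4][3] = {{1,2,3},{0,2,3},{0,1,3},{0,1,2}};
  uint64_t N = (uint64_t)n;
  for (const auto &t : tv) {
    for (int f = 0; f < 4; ++f) {
      int a = t[faceIdx[f][0]], b = t[faceIdx[f][1]], c = t[faceIdx[f][2]];
      if (a > b) std::swap(a, b);
      if (b > c) std::swap(b, c);
      if (a > b) std::swap(a, b);
      uint64_t key = ((uint64_t)a * N + (uint64_t)b) * N + (uint64_t)c;
      fmap.emplace(key, std::array<int,3>{a, b, c});
    }
  }
  IntegerMatrix facets((int)fmap.size(), 3);
  int r = 0;
  for (const auto &kv : fmap) {
    facets(r, 0) = kv.second[0] + 1;
    facets(r, 1) = kv.second[1] + 1;
    facets(r, 2) = kv.second[2] + 1;
    ++r;
  }
  IntegerMatrix tetm((int)tv.size(), 4);
  for (int i = 0; i < (int)tv.size(); ++i)
    for (int k = 0; k < 4; ++k) tetm(i, k) = tv[i][k] + 1;
  return List::create(_["facets"] = facets, _["tets"] = tetm,
                      _["skipped"] = skipped);
}
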