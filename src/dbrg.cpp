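// Delaunay-based region-growing (DBRG) surface extraction.
// Given the candidate triangle set T (all facets of the 3D Delaunay
// tetrahedralization of the combined crown+root vertex set), grow an accepted
// surface F from a start triangle (containing the globally max-z vertex, with
// minimum circumradius), repeatedly admitting the frontier triangle of
// largest local smooth degree (LSD = mean cosine between the consistently
// oriented normals of the candidate and its accepted neighbours across shared
// boundary edges) whose addition keeps the complex edge-manifold, orientable,
// and unpinched.  Candidates are ranked in three tiers — facets that coincide
// with an input-mesh face, facets whose circumradius matches the local
// sampling spacing, and the rest — because oversized facets skip over sample
// points and bury them.  When growth stalls with open boundary left, fronts
// are bridged under a relaxed vertex rule, and stuck frontiers are peeled
// back and regrown.
#include <Rcpp.h>
#include <vector>
#include <queue>
#include <unordered_map>
#include <unordered_set>
#include <cmath>
#include <cstdint>
#include <climits>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Cand {
  int tier;     // 2: input-mesh face, 1: locally fine circumradius, 0: other
  double lsd;
  int facet;
  bool operator<(const Cand &o) const {
    if (tier != o.tier) return tier < o.tier;
    if (lsd != o.lsd) return lsd < o.lsd;
    return facet > o.facet;
  }
};

struct Engine {
  int np = 0;
  const double *px = nullptr, *py = nullptr, *pz = nullptr;
  const double *localh = nullptr;
  double beta = 1.4;
  const double *vnorm = nullptr;
  double minAlign = 0.5;

  std::vector<std::array<int,3>> tri;          // candidates (0-based)
  std::vector<std::array<int64_t,3>> triEdge;
  std::unordered_map<int64_t, std::vector<int>> edgeFacets;
  std::vector<signed char> fineFlag;
  std::vector<char> preferred;

  // growth state
  std::vector<char> accepted;                  // per candidate facet
  std::vector<std::array<int,3>> orient;       // accepted oriented triples
  std::vector<int> facetOf;                    // accepted id -> candidate id
  std::vector<char> dead;                      // accepted id removed again
  std::vector<std::array<double,3>> faceNormal;
  std::unordered_map<int64_t, std::vector<int>> edgeInc;  // live accepted ids
  struct BInfo { int face; int from, to; };
  std::unordered_map<int64_t, BInfo> boundary;
  std::vector<std::vector<int>> vertFaces;     // live accepted ids per vertex
  std::vector<int> boundaryDeg;
  std::priority_queue<Cand> pq;
  long rejected = 0;

  int64_t ekey(int a, int b) const {
    if (a > b) std::swap(a, b);
    return (int64_t)a * np + b;
  }
  void normalOf(const std::array<int,3> &t, double *n) const {
    double ux = px[t[1]]-px[t[0]], uy = py[t[1]]-py[t[0]], uz = pz[t[1]]-pz[t[0]];
    double vx = px[t[2]]-px[t[0]], vy = py[t[2]]-py[t[0]], vz = pz[t[2]]-pz[t[0]];
    n[0] = uy*vz - uz*vy; n[1] = uz*vx - ux*vz; n[2] = ux*vy - uy*vx;
    double l = std::sqrt(n[0]*n[0] + n[1]*n[1] + n[2]*n[2]);
    if (l > 0) { n[0]/=l; n[1]/=l; n[2]/=l; }
  }
  int fine(int fi) {
    if (fineFlag[fi] >= 0) return fineFlag[fi];
    const std::array<int,3> &t = tri[fi];
    double e1 = 0, e2 = 0, e3 = 0;
    {
      double dx = px[t[1]]-px[t[0]], dy = py[t[1]]-py[t[0]], dz = pz[t[1]]-pz[t[0]];
      e1 = std::sqrt(dx*dx + dy*dy + dz*dz);
      dx = px[t[2]]-px[t[1]]; dy = py[t[2]]-py[t[1]]; dz = pz[t[2]]-pz[t[1]];
      e2 = std::sqrt(dx*dx + dy*dy + dz*dz);
      dx = px[t[0]]-px[t[2]]; dy = py[t[0]]-py[t[2]]; dz = pz[t[0]]-pz[t[2]];
      e3 = std::sqrt(dx*dx + dy*dy + dz*dz);
    }
    double s = 0.5 * (e1 + e2 + e3);
    double area2 = s * (s-e1) * (s-e2) * (s-e3);
    double r = area2 > 1e-300 ? (e1*e2*e3) / (4*std::sqrt(area2)) : R_PosInf;
    double h = std::max(localh[t[0]], std::max(localh[t[1]], localh[t[2]]));
    int g = (r <= beta * h) ? 1 : 0;
    fineFlag[fi] = (signed char)g;
    return g;
  }
  int tierOf(int fi) {
    if (!preferred.empty() && preferred[fi]) return 2;
    return fine(fi);
  }

  // admissibility + LSD.  Relaxed mode (front bridging): the per-vertex
  // shared-edge rule and the normal filter are dropped; a transient pinch at
  // an open boundary vertex is tolerated.
  bool eval(int fi, double &lsd, std::array<int,3> &otri,
            bool relaxed = false) {
    const std::array<int,3> &t = tri[fi];
    int nshared = 0;
    const BInfo *binfo[3] = {nullptr, nullptr, nullptr};
    for (int e = 0; e < 3; ++e) {
      auto itc = edgeInc.find(triEdge[fi][e]);
      if (itc != edgeInc.end() && (int)itc->second.size() >= 2) return false;
      auto itb = boundary.find(triEdge[fi][e]);
      if (itb != boundary.end()) { binfo[e] = &itb->second; ++nshared; }
    }
    if (nshared == 0) return false;
    int flip = -1;
    for (int e = 0; e < 3; ++e) {
      if (!binfo[e]) continue;
      int a = t[e], b = t[(e+1)%3];
      int need;
      if (binfo[e]->from == b && binfo[e]->to == a) need = 0;
      else if (binfo[e]->from == a && binfo[e]->to == b) need = 1;
      else return false;
      if (flip < 0) flip = need;
      else if (flip != need) return false;     // orientation conflict
    }
    otri = t;
    if (flip == 1) std::swap(otri[1], otri[2]);
    for (int c = 0; c < 3; ++c) {
      int vtx = t[c];
      if (vertFaces[vtx].empty()) continue;
      if (boundaryDeg[vtx] == 0) return false; // interior vertex: permanent pinch
      if (!relaxed) {
        int o1 = t[(c + 1) % 3], o2 = t[(c + 2) % 3];
        auto i1 = edgeInc.find(ekey(vtx, o1));
        auto i2 = edgeInc.find(ekey(vtx, o2));
        bool share = (i1 != edgeInc.end() && !i1->second.empty()) ||
                     (i2 != edgeInc.end() && !i2->second.empty());
        if (!share) return false;              // would create a pinch
      }
    }
    double nt[3];
    normalOf(otri, nt);
    if (vnorm && !relaxed) {
      double ax = 0, ay = 0, az = 0;
      for (int c = 0; c < 3; ++c) {
        ax += vnorm[3*t[c]]; ay += vnorm[3*t[c]+1]; az += vnorm[3*t[c]+2];
      }
      double l = std::sqrt(ax*ax + ay*ay + az*az);
      if (l > 1e-12) {
        double d = (nt[0]*ax + nt[1]*ay + nt[2]*az) / l;
        if (d < minAlign) return false;
      }
    }
    double s = 0; int k = 0;
    for (int e = 0; e < 3; ++e) {
      if (!binfo[e]) continue;
      const std::array<double,3> &nf = faceNormal[binfo[e]->face];
      s += nt[0]*nf[0] + nt[1]*nf[1] + nt[2]*nf[2];
      ++k;
    }
    lsd = s / k;
    return true;
  }

  void boundaryAdd(int64_t k, int id) {
    // traversal of edge k within orient[id]
    const std::array<int,3> &o = orient[id];
    for (int e = 0; e < 3; ++e) {
      int a = o[e], b = o[(e+1)%3];
      if (ekey(a, b) == k) {
        boundary[k] = {id, a, b};
        ++boundaryDeg[a]; ++boundaryDeg[b];
        return;
      }
    }
  }
  void boundaryRemove(int64_t k) {
    auto it = boundary.find(k);
    if (it == boundary.end()) return;
    int a = it->second.from, b = it->second.to;
    --boundaryDeg[a]; --boundaryDeg[b];
    boundary.erase(it);
  }

  void pushNeighbours(int64_t k) {
    auto it = edgeFacets.find(k);
    if (it == edgeFacets.end()) return;
    for (int g : it->second) {
      if (accepted[g]) continue;
      double lsd; std::array<int,3> ot;
      if (eval(g, lsd, ot)) pq.push({tierOf(g), lsd, g});
    }
  }

  void accept(int fi, const std::array<int,3> &otri) {
    accepted[fi] = 1;
    int id = (int)orient.size();
    orient.push_back(otri);
    facetOf.push_back(fi);
    dead.push_back(0);
    std::array<double,3> n;
    normalOf(otri, n.data());
    faceNormal.push_back(n);
    for (int c = 0; c < 3; ++c) vertFaces[otri[c]].push_back(id);
    std::vector<int64_t> newBoundary;
    for (int e = 0; e < 3; ++e) {
      int64_t k = ekey(otri[e], otri[(e+1)%3]);
      std::vector<int> &inc = edgeInc[k];
      inc.push_back(id);
      if (inc.size() == 1) {
        boundaryAdd(k, id);
        newBoundary.push_back(k);
      } else {
        boundaryRemove(k);
      }
    }
    for (int64_t k : newBoundary) pushNeighbours(k);
  }

  void removeFace(int id) {
    if (dead[id]) return;
    dead[id] = 1;
    accepted[facetOf[id]] = 0;
    const std::array<int,3> &o = orient[id];
    for (int c = 0; c < 3; ++c) {
      std::vector<int> &vf = vertFaces[o[c]];
      vf.erase(std::remove(vf.begin(), vf.end(), id), vf.end());
    }
    for (int e = 0; e < 3; ++e) {
      int64_t k = ekey(o[e], o[(e+1)%3]);
      auto it = edgeInc.find(k);
      if (it == edgeInc.end()) continue;
      std::vector<int> &inc = it->second;
      inc.erase(std::remove(inc.begin(), inc.end(), id), inc.end());
      if (inc.empty()) {
        boundaryRemove(k);
        edgeInc.erase(it);
      } else if (inc.size() == 1) {
        boundaryAdd(k, inc[0]);
      }
    }
  }

  // strict growth until the queue drains
  long drain() {
    long pops = 0;
    while (!pq.empty()) {
      Cand c = pq.top(); pq.pop();
      if (accepted[c.facet]) continue;
      double lsd; std::array<int,3> ot;
      if (!eval(c.facet, lsd, ot)) { ++rejected; continue; }
      if (lsd < c.lsd - 1e-12) { pq.push({c.tier, lsd, c.facet}); continue; }
      accept(c.facet, ot);
      if ((++pops & 2047) == 0) Rcpp::checkUserInterrupt();
    }
    return pops;
  }

  // one relaxed bridge: the smoothest frontier-adjacent candidate
  bool bridge() {
    int bestTier = -1; double bestLsd = -2.0; int bestF = -1;
    std::array<int,3> bestOt{};
    std::unordered_set<int> seen;
    for (const auto &kv : boundary) {
      auto it = edgeFacets.find(kv.first);
      if (it == edgeFacets.end()) continue;
      for (int g : it->second) {
        if (accepted[g] || seen.count(g)) continue;
        seen.insert(g);
        double lsd; std::array<int,3> ot;
        if (!eval(g, lsd, ot, true)) continue;
        int tr = tierOf(g);
        if (tr > bestTier || (tr == bestTier && lsd > bestLsd) ||
            (tr == bestTier && lsd == bestLsd && g < bestF)) {
          bestTier = tr; bestLsd = lsd; bestF = g; bestOt = ot;
        }
      }
    }
    if (bestF < 0) return false;
    accept(bestF, bestOt);
    return true;
  }

  void growToCompletion() {
    for (;;) {
      drain();
      if (boundary.empty()) break;
      if (!bridge()) break;
    }
  }
};

} // namespace

// [[Rcpp::export(name = ".dbrg_cpp")]]
List dbrg_cpp(NumericMatrix points, IntegerMatrix facets,
              NumericVector local_spacing, double beta = 1.4,
              int start_facet = 0,
              Nullable<NumericMatrix> vertex_normals = R_NilValue,
              double min_align = 0.5,
              Nullable<IntegerMatrix> input_faces = R_NilValue,
              int repair_rounds = 6) {
  Engine E;
  int np = points.nrow(), nf = facets.nrow();
  if (nf == 0) stop("empty candidate set");
  std::vector<double> X(np), Y(np), Z(np);
  for (int i = 0; i < np; ++i) { X[i]=points(i,0); Y[i]=points(i,1); Z[i]=points(i,2); }
  E.np = np; E.px = X.data(); E.py = Y.data(); E.pz = Z.data();
  std::vector<double> H(np, R_PosInf);
  if (local_spacing.size() == np)
    for (int i = 0; i < np; ++i) H[i] = local_spacing[i];
  E.localh = H.data();
  E.beta = beta;
  std::vector<double> VN;
  if (vertex_normals.isNotNull()) {
    NumericMatrix vn(vertex_normals);
    if (vn.nrow() == np && vn.ncol() == 3) {
      VN.resize(3 * (size_t)np);
      for (int i = 0; i < np; ++i) {
        VN[3*i] = vn(i,0); VN[3*i+1] = vn(i,1); VN[3*i+2] = vn(i,2);
      }
      E.vnorm = VN.data();
      E.minAlign = min_align;
    }
  }
  std::unordered_set<int64_t> inputSet;
  uint64_t NN = (uint64_t)np;
  if (input_faces.isNotNull()) {
    IntegerMatrix inf(input_faces);
    for (int i = 0; i < inf.nrow(); ++i) {
      int a = inf(i,0)-1, b = inf(i,1)-1, c = inf(i,2)-1;
      if (a > b) std::swap(a, b);
      if (b > c) std::swap(b, c);
      if (a > b) std::swap(a, b);
      inputSet.insert((int64_t)(((uint64_t)a * NN + b) * NN + c));
    }
  }
  E.fineFlag.assign(nf, -1);
  E.preferred.assign(nf, 0);
  E.tri.resize(nf); E.triEdge.resize(nf);
  E.accepted.assign(nf, 0);
  E.vertFaces.resize(np);
  E.boundaryDeg.assign(np, 0);
  for (int f = 0; f < nf; ++f) {
    E.tri[f] = {facets(f,0)-1, facets(f,1)-1, facets(f,2)-1};
    for (int e = 0; e < 3; ++e) {
      int64_t k = E.ekey(E.tri[f][e], E.tri[f][(e+1)%3]);
      E.triEdge[f][e] = k;
      E.edgeFacets[k].push_back(f);
    }
    if (!inputSet.empty()) {
      int a = E.tri[f][0], b = E.tri[f][1], c = E.tri[f][2];
      if (a > b) std::swap(a, b);
      if (b > c) std::swap(b, c);
      if (a > b) std::swap(a, b);
      if (inputSet.count((int64_t)(((uint64_t)a * NN + b) * NN + c)))
        E.preferred[f] = 1;
    }
  }
  // start triangle
  int sf = start_facet - 1;
  if (sf < 0) {
    int vmax = 0;
    for (int i = 1; i < np; ++i) if (Z[i] > Z[vmax]) vmax = i;
    double bestR = R_PosInf;
    std::array<int,3> bestKey = {INT_MAX, INT_MAX, INT_MAX};
    for (int f = 0; f < nf; ++f) {
      const auto &t = E.tri[f];
      if (t[0] != vmax && t[1] != vmax && t[2] != vmax) continue;
      double e1 = std::sqrt((X[t[1]]-X[t[0]])*(X[t[1]]-X[t[0]]) + (Y[t[1]]-Y[t[0]])*(Y[t[1]]-Y[t[0]]) + (Z[t[1]]-Z[t[0]])*(Z[t[1]]-Z[t[0]]));
      double e2 = std::sqrt((X[t[2]]-X[t[1]])*(X[t[2]]-X[t[1]]) + (Y[t[2]]-Y[t[1]])*(Y[t[2]]-Y[t[1]]) + (Z[t[2]]-Z[t[1]])*(Z[t[2]]-Z[t[1]]));
      double e3 = std::sqrt((X[t[0]]-X[t[2]])*(X[t[0]]-X[t[2]]) + (Y[t[0]]-Y[t[2]])*(Y[t[0]]-Y[t[2]]) + (Z[t[0]]-Z[t[2]])*(Z[t[0]]-Z[t[2]]));
      double s = 0.5 * (e1 + e2 + e3);
      double area2 = s * (s-e1) * (s-e2) * (s-e3);
      double area = area2 > 0 ? std::sqrt(area2) : 0;
      double R = area > 1e-300 ? (e1*e2*e3) / (4*area) : R_PosInf;
      std::array<int,3> key = t;
      std::sort(key.begin(), key.end());
      if (R < bestR - 1e-12 * (1 + bestR) ||
          (std::fabs(R - bestR) <= 1e-12 * (1 + bestR) && key < bestKey)) {
        bestR = R; bestKey = key; sf = f;
      }
    }
    if (sf < 0) stop("no facet contains the max-z vertex");
  }
  // orient the start triangle outward (vertex normals if given, else +z up)
  std::array<int,3> st = E.tri[sf];
  double n0[3];
  E.normalOf(st, n0);
  double refz = n0[2];
  if (E.vnorm) {
    double ax = 0, ay = 0, az = 0;
    for (int c = 0; c < 3; ++c) {
      ax += E.vnorm[3*st[c]]; ay += E.vnorm[3*st[c]+1]; az += E.vnorm[3*st[c]+2];
    }
    refz = n0[0]*ax + n0[1]*ay + n0[2]*az;
  }
  if (refz < 0) std::swap(st[1], st[2]);
  E.accept(sf, st);
  E.growToCompletion();
  // repair: peel the faces around stuck boundary and regrow
  for (int round = 0; round < repair_rounds && !E.boundary.empty(); ++round) {
    size_t before = E.boundary.size();
    std::unordered_set<int> peel;
    for (const auto &kv : E.boundary) peel.insert(kv.second.face);
    if (peel.empty()) break;
    for (int id : peel) E.removeFace(id);
    std::vector<int64_t> keys;
    for (const auto &kv : E.boundary) keys.push_back(kv.first);
    for (int64_t k : keys) E.pushNeighbours(k);
    E.growToCompletion();
    if (E.boundary.size() >= before) break;
    Rcpp::checkUserInterrupt();
  }
  // output live faces
  int na = 0;
  for (size_t i = 0; i < E.orient.size(); ++i) if (!E.dead[i]) ++na;
  IntegerMatrix out(na, 3);
  int r = 0;
  for (size_t i = 0; i < E.orient.size(); ++i) {
    if (E.dead[i]) continue;
    for (int k = 0; k < 3; ++k) out(r, k) = E.orient[i][k] + 1;
    ++r;
  }
  return List::create(_["faces"] = out,
                      _["start_facet"] = sf + 1,
                      _["rejected"] = (double)E.rejected,
                      _["boundary_edges"] = (double)E.boundary.size());
}
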