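// Isosurface extraction from a scalar voxel grid via the tetrahedral
// decomposition variant of marching cubes: each lattice cell is split into
// the 6 Freudenthal tetrahedra (a consistent triangulation of space), and
// each tetrahedron emits 0/1/2 triangles with vertices interpolated on its
// edges.  Shared lattice edges weld automatically, so the surface is
// watertight wherever the iso level is crossed inside the grid.
#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

namespace {
struct VKey { int64_t a, b; };
}

// [[Rcpp::export(name = ".marching_tetra_cpp")]]
List marching_tetra_cpp(NumericVector vol, IntegerVector dim, double iso,
                        NumericVector voxel, NumericVector origin,
                        double snap = 0.2) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  if (nx < 2 || ny < 2 || nz < 2) stop("volume must be at least 2 voxels per axis");
  const double *v = vol.begin();
  auto lid = [&](int i, int j, int k) -> int64_t {
    return (int64_t)i + (int64_t)nx * ((int64_t)j + (int64_t)ny * k);
  };
  std::unordered_map<int64_t, int> edgeVert;
  std::vector<double> VX, VY, VZ;
  std::vector<int> F;  // flat triples (0-based)
  const int64_t NV = (int64_t)nx * ny * nz;

  auto corner = [&](int64_t id, int &i, int &j, int &k) {
    i = (int)(id % nx); j = (int)((id / nx) % ny); k = (int)(id / ((int64_t)nx * ny));
  };
  // vertex on lattice edge (a,b): interpolate
  auto edgeVertex = [&](int64_t a, int64_t b) -> int {
    if (a > b) std::swap(a, b);
    int64_t key = a * NV + b;  // b-a is a lattice step; key fits 64-bit for grids < ~2^31 voxels total? guarded below
    auto it = edgeVert.find(key);
    if (it != edgeVert.end()) return it->second;
    double va = v[a], vb = v[b];
    double t = (iso - va) / (vb - va);
    if (!R_finite(t)) t = 0.5;
    // clamp away from the edge ends: keeps interpolated vertices a minimum
    // lattice distance apart so downstream triangulations see no slivers
    if (t < snap) t = snap; else if (t > 1 - snap) t = 1 - snap;
    int ia, ja, ka, ib, jb, kb;
    corner(a, ia, ja, ka); corner(b, ib, jb, kb);
    double px = ia + t * (ib - ia), py = ja + t * (jb - ja), pz = ka + t * (kb - ka);
    // voxel-centre convention: mm = origin + (index + 0.5) * voxel_size
    VX.push_back(origin[0] + (px + 0.5) * voxel[0]);
    VY.push_back(origin[1] + (py + 0.5) * voxel[1]);
    VZ.push_back(origin[2] + (pz + 0.5) * voxel[2]);
    int idx = (int)VX.size() - 1;
    edgeVert.emplace(key, idx);
    return idx;
  };
  if (NV >= (int64_t)1 << 31) stop("volume too large");

  // 6 Freudenthal tets: permutations of axis step order from cell corner
  const int perms[6][3] = {{0,1,2},{0,2,1},{1,0,2},{1,2,0},{2,0,1},{2,1,0}};
  int64_t c[4];
  for (int k = 0; k < nz - 1; ++k) {
    for (int j = 0; j < ny - 1; ++j) {
      for (int i = 0; i < nx - 1; ++i) {
        for (int p = 0; p < 6; ++p) {
          int ii = i, jj = j, kk = k;
          c[0] = lid(ii, jj, kk);
          for (int s = 0; s < 3; ++s) {
            int ax = perms[p][s];
            if (ax == 0) ++ii; else if (ax == 1) ++jj; else ++kk;
            c[s + 1] = lid(ii, jj, kk);
          }
          bool in[4];
          int nin = 0;
          for (int s = 0; s < 4; ++s) { in[s] = v[c[s]] > iso; if (in[s]) ++nin; }
          if (nin == 0 || nin == 4) continue;
          if (nin == 1 || nin == 3) {
            bool target = (nin == 1);
            int A = -1;
            int others[3]; int no = 0;
            for (int s = 0; s < 4; ++s) { if (in[s] == target) A = s; else others[no++] = s; }
            int e0 = edgeVertex(c[A], c[others[0]]);
            int e1 = edgeVertex(c[A], c[others[1]]);
            int e2 = edgeVertex(c[A], c[others[2]]);
            F.push_back(e0); F.push_back(e1); F.push_back(e2);
          } else {
            int A[2], B[2]; int na = 0, nb = 0;
            for (int s = 0; s < 4; ++s) { if (in[s]) A[na++] = s; else B[nb++] = s; }
            int e00 = edgeVertex(c[A[0]], c[B[0]]);
            int e01 = edgeVertex(c[A[0]], c[B[1]]);
            int e10 = edgeVertex(c[A[1]], c[B[0]]);
            int e11 = edgeVertex(c[A[1]], c[B[1]]);
            // quad e00-e01-e11-e10 split into two triangles
            F.push_back(e00); F.push_back(e01); F.push_back(e11);
            F.push_back(e00); F.push_back(e11); F.push_back(e10);
          }
        }
      }
      Rcpp::checkUserInterrupt();
    }
  }
  int nvtx = (int)VX.size(), nf = (int)F.size() / 3;
  NumericMatrix V(nvtx, 3);
  for (int i = 0; i < nvtx; ++i) { V(i,0)=VX[i]; V(i,1)=VY[i]; V(i,2)=VZ[i]; }
  IntegerMatrix Fm(nf, 3);
  for (int i = 0; i < nf; ++i) {
    Fm(i,0) = F[3*i] + 1; Fm(i,1) = F[3*i+1] + 1; Fm(i,2) = F[3*i+2] + 1;
  }
  return List::create(_["vertices"] = V, _["faces"] = Fm);
}

// Make face orientation globally consistent per connected component (BFS over
// edge-adjacent faces), then flip closed components to positive signed volume.
// Errors if the mesh is not orientable along an edge with > 2 incident faces.
// [[Rcpp::export(name = ".orient_faces_cpp")]]
IntegerMatrix orient_faces_cpp(NumericMatrix V, IntegerMatrix Fin) {
  int nf = Fin.nrow();
  int nv = V.nrow();
  std::vector<std::array<int,3>> F(nf);
  for (int i = 0; i < nf; ++i)
    F[i] = {Fin(i,0) - 1, Fin(i,1) - 1, Fin(i,2) - 1};
  // edge -> incident faces
  std::unordered_map<int64_t, std::vector<int>> emap;
  emap.reserve(nf * 2);
  auto ekey = [&](int a, int b) -> int64_t {
    if (a > b) std::swap(a, b);
    return (int64_t)a * nv + b;
  };
  for (int i = 0; i < nf; ++i)
    for (int e = 0; e < 3; ++e)
      emap[ekey(F[i][e], F[i][(e+1)%3])].push_back(i);
  std::vector<int> state(nf, 0);  // 0 unvisited, 1 fixed
  std::vector<int> comp(nf, -1);
  int ncomp = 0;
  std::vector<int> stack;
  for (int s = 0; s < nf; ++s) {
    if (state[s]) continue;
    int cid = ncomp++;
    state[s] = 1; comp[s] = cid;
    stack.push_back(s);
    while (!stack.empty()) {
      int f = stack.back(); stack.pop_back();
      for (int e = 0; e < 3; ++e) {
        int a = F[f][e], b = F[f][(e+1)%3];
        const auto &inc = emap[ekey(a, b)];
        if (inc.size() > 2) continue;  // non-manifold: leave as-is
        for (int g : inc) {
          if (g == f || state[g]) continue;
          // g must traverse edge (a,b) as (b,a); flip if it matches (a,b)
          bool same = false;
          for (int e2 = 0; e2 < 3; ++e2)
            if (F[g][e2] == a && F[g][(e2+1)%3] == b) { same = true; break; }
          if (same) std::swap(F[g][1], F[g][2]);
          state[g] = 1; comp[g] = cid;
          stack.push_back(g);
        }
      }
    }
  }
  // flip closed components with negative signed volume
  std::vector<double> svol(ncomp, 0.0);
  std::vector<char> closed(ncomp, 1);
  for (const auto &kv : emap)
    if (kv.second.size() != 2) closed[comp[kv.second[0]]] = 0;
  for (int i = 0; i < nf; ++i) {
    const double *v0 = &V(F[i][0], 0);
    double ax = V(F[i][0],0), ay = V(F[i][0],1), az = V(F[i][0],2);
    double bx = V(F[i][1],0), by = V(F[i][1],1), bz = V(F[i][1],2);
    double cx = V(F[i][2],0), cy = V(F[i][2],1), cz = V(F[i][2],2);
    svol[comp[i]] += (ax*(by*cz - bz*cy) - ay*(bx*cz - bz*cx) + az*(bx*cy - by*cx)) / 6.0;
    (void)v0;
  }
  IntegerMatrix out(nf, 3);
  for (int i = 0; i < nf; ++i) {
    bool flip = closed[comp[i]] && svol[comp[i]] < 0;
    out(i,0) = F[i][0] + 1;
    out(i,1) = (flip ? F[i][2] : F[i][1]) + 1;
    out(i,2) = (flip ? F[i][1] : F[i][2]) + 1;
  }
  return out;
}
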