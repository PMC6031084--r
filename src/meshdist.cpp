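// Point-to-surface distances: for each query point, the distance to the
// closest point on any triangle of the target mesh (true point-to-triangle
// minimization, accelerated by per-face bounding-sphere rejection).
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

namespace {
// Closest point on triangle (a,b,c) to p; Ericson, Real-Time Collision
// Detection, ch. 5.1.5.
inline void closestOnTri(const double *p, const double *a, const double *b,
                         const double *c, double *out) {
  double ab[3], ac[3], ap[3];
  for (int k = 0; k < 3; ++k) { ab[k] = b[k]-a[k]; ac[k] = c[k]-a[k]; ap[k] = p[k]-a[k]; }
  double d1 = ab[0]*ap[0]+ab[1]*ap[1]+ab[2]*ap[2];
  double d2 = ac[0]*ap[0]+ac[1]*ap[1]+ac[2]*ap[2];
  if (d1 <= 0 && d2 <= 0) { for (int k=0;k<3;++k) out[k]=a[k]; return; }
  double bp[3];
  for (int k = 0; k < 3; ++k) bp[k] = p[k]-b[k];
  double d3 = ab[0]*bp[0]+ab[1]*bp[1]+ab[2]*bp[2];
  double d4 = ac[0]*bp[0]+ac[1]*bp[1]+ac[2]*bp[2];
  if (d3 >= 0 && d4 <= d3) { for (int k=0;k<3;++k) out[k]=b[k]; return; }
  double vc = d1*d4 - d3*d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    double t = d1 / (d1 - d3);
    for (int k=0;k<3;++k) out[k] = a[k] + t*ab[k];
    return;
  }
  double cp[3];
  for (int k = 0; k < 3; ++k) cp[k] = p[k]-c[k];
  double d5 = ab[0]*cp[0]+ab[1]*cp[1]+ab[2]*cp[2];
  double d6 = ac[0]*cp[0]+ac[1]*cp[1]+ac[2]*cp[2];
  if (d6 >= 0 && d5 <= d6) { for (int k=0;k<3;++k) out[k]=c[k]; return; }
  double vb = d5*d2 - d1*d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    double t = d2 / (d2 - d6);
    for (int k=0;k<3;++k) out[k] = a[k] + t*ac[k];
    return;
  }
  double va = d3*d6 - d5*d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    double t = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int k=0;k<3;++k) out[k] = b[k] + t*(c[k]-b[k]);
    return;
  }
  double denom = 1.0 / (va + vb + vc);
  double vv = vb * denom, ww = vc * denom;
  for (int k=0;k<3;++k) out[k] = a[k] + ab[k]*vv + ac[k]*ww;
}
}

// [[Rcpp::export(name = ".point_mesh_distance_cpp")]]
List point_mesh_distance_cpp(NumericMatrix P, NumericMatrix V, IntegerMatrix F) {
  int np = P.nrow(), nf = F.nrow();
  if (nf == 0) stop("target mesh has no faces");
  std::vector<double> cx(nf), cy(nf), cz(nf), rad(nf);
  std::vector<std::array<double,9>> tri(nf);
  for (int f = 0; f < nf; ++f) {
    int a = F(f,0)-1, b = F(f,1)-1, c = F(f,2)-1;
    for (int k = 0; k < 3; ++k) {
      tri[f][k]   = V(a,k);
      tri[f][3+k] = V(b,k);
      tri[f][6+k] = V(c,k);
    }
    cx[f] = (tri[f][0]+tri[f][3]+tri[f][6]) / 3.0;
    cy[f] = (tri[f][1]+tri[f][4]+tri[f][7]) / 3.0;
    cz[f] = (tri[f][2]+tri[f][5]+tri[f][8]) / 3.0;
    double r2 = 0;
    for (int s = 0; s < 3; ++s) {
      double dx = tri[f][3*s]-cx[f], dy = tri[f][3*s+1]-cy[f], dz = tri[f][3*s+2]-cz[f];
      r2 = std::max(r2, dx*dx + dy*dy + dz*dz);
    }
    rad[f] = std::sqrt(r2);
  }
  NumericVector dist(np);
  NumericMatrix closest(np, 3);
  IntegerVector which(np);
  for (int i = 0; i < np; ++i) {
    double p[3] = {P(i,0), P(i,1), P(i,2)};
    // seed with the face of nearest centroid
    double bestc = R_PosInf; int seed = 0;
    for (int f = 0; f < nf; ++f) {
      double dx = p[0]-cx[f], dy = p[1]-cy[f], dz = p[2]-cz[f];
      double d2 = dx*dx + dy*dy + dz*dz;
      if (d2 < bestc) { bestc = d2; seed = f; }
    }
    double q[3];
    closestOnTri(p, &tri[seed][0], &tri[seed][3], &tri[seed][6], q);
    double best = std::sqrt((p[0]-q[0])*(p[0]-q[0]) + (p[1]-q[1])*(p[1]-q[1]) +
                            (p[2]-q[2])*(p[2]-q[2]));
    int bf = seed;
    double bq[3] = {q[0], q[1], q[2]};
    for (int f = 0; f < nf; ++f) {
      if (f == seed) continue;
      double dx = p[0]-cx[f], dy = p[1]-cy[f], dz = p[2]-cz[f];
      double dc = std::sqrt(dx*dx + dy*dy + dz*dz);
      if (dc - rad[f] >= best) continue;
      closestOnTri(p, &tri[f][0], &tri[f][3], &tri[f][6], q);
      double d = std::sqrt((p[0]-q[0])*(p[0]-q[0]) + (p[1]-q[1])*(p[1]-q[1]) +
                           (p[2]-q[2])*(p[2]-q[2]));
      if (d < best) { best = d; bf = f; bq[0]=q[0]; bq[1]=q[1]; bq[2]=q[2]; }
    }
    dist[i] = best;
    which[i] = bf + 1;
    closest(i,0) = bq[0]; closest(i,1) = bq[1]; closest(i,2) = bq[2];
    if ((i & 255) == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["distance"] = dist, _["closest"] = closest,
                      _["face"] = which);
}
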