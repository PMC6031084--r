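// Separable 3D Gaussian blur (reflected boundaries), sigma in voxels per axis.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export(name = ".gauss_blur3d_cpp")]]
NumericVector gauss_blur3d_cpp(NumericVector vol, IntegerVector dim,
                               NumericVector sigma) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<double> a(vol.begin(), vol.end()), b(a.size());
  int n[3] = {nx, ny, nz};
  long stride[3] = {1, (long)nx, (long)nx * ny};
  for (int ax = 0; ax < 3; ++ax) {
    double s = sigma[ax];
    if (s <= 0) continue;
    int r = (int)std::ceil(3.0 * s);
    std::vector<double> k(2 * r + 1);
    double sum = 0;
    for (int i = -r; i <= r; ++i) { k[i + r] = std::exp(-0.5 * i * i / (s * s)); sum += k[i + r]; }
    for (double &v : k) v /= sum;
    long len = n[ax], st = stride[ax];
    long nlines = (long)nx * ny * nz / len;
    // iterate all lines along axis ax
    int o1 = (ax + 1) % 3, o2 = (ax + 2) % 3;
    for (long j2 = 0; j2 < n[o2]; ++j2) {
      for (long j1 = 0; j1 < n[o1]; ++j1) {
        long base = j1 * stride[o1] + j2 * stride[o2];
        for (long i = 0; i < len; ++i) {
          double acc = 0;
          for (int t = -r; t <= r; ++t) {
            long ii = i + t;
            if (ii < 0) ii = -ii - 1;
            else if (ii >= len) ii = 2 * len - ii - 1;
            acc += k[t + r] * a[base + ii * st];
          }
          b[base + i * st] = acc;
        }
      }
      Rcpp::checkUserInterrupt();
    }
    std::swap(a, b);
    (void)nlines;
  }
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = dim;
  return out;
}
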