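// Marker-based priority flood on the dual graph of a triangle mesh.
// Faces are flooded from seed faces in ascending order of the crossing-edge
// barrier height H; an edge is admitted only while H < threshold and its
// admission value (the per-edge vector `admit` when given, H otherwise)
// stays below admit_threshold.  Ties are broken deterministically: lower H,
// then lower label, then lower face index.
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <tuple>
using namespace Rcpp;

// [[Rcpp::export(name = ".mesh_flood_cpp")]]
List mesh_flood_cpp(int n_faces, IntegerMatrix edge_faces, NumericVector H,
                    IntegerVector seed_faces, IntegerVector seed_labels,
                    double threshold, IntegerVector init_labels,
                    NumericVector admit, double admit_threshold) {
  int ne = edge_faces.nrow();
  bool useAdmit = admit.size() == ne;
  // adjacency carries (neighbor, priority H, admission value)
  struct Nb { int f; double h, adm; };
  std::vector<std::vector<Nb>> adj(n_faces);
  for (int e = 0; e < ne; ++e) {
    int a = edge_faces(e, 0) - 1, b = edge_faces(e, 1) - 1;
    if (a < 0 || b < 0) continue;  // boundary edge
    double ad = useAdmit ? admit[e] : H[e];
    adj[a].push_back({b, H[e], ad});
    adj[b].push_back({a, H[e], ad});
  }
  std::vector<int> label(n_faces, 0);
  std::vector<double> entry(n_faces, NA_REAL);
  // (H, insertion seq, label, face): equal-H fronts advance first-in
  // first-out, so competing basins race as fair wavefronts; remaining ties
  // resolve to the lower label then lower face index
  typedef std::tuple<double,long,int,int> QE;
  std::priority_queue<QE, std::vector<QE>, std::greater<QE>> pq;
  long seq = 0;
  if (init_labels.size() == n_faces) {
    for (int i = 0; i < n_faces; ++i)
      if (init_labels[i] > 0) { label[i] = init_labels[i]; entry[i] = 0.0; }
  }
  for (int s = 0; s < seed_faces.size(); ++s) {
    int f = seed_faces[s] - 1;
    label[f] = seed_labels[s];
    entry[f] = 0.0;
  }
  for (int f = 0; f < n_faces; ++f) {
    if (label[f] == 0) continue;
    for (const auto &nb : adj[f])
      if (label[nb.f] == 0 && nb.adm < admit_threshold)
        pq.push(std::make_tuple(nb.h, seq++, label[f], nb.f));
  }
  while (!pq.empty()) {
    QE top = pq.top(); pq.pop();
    double h = std::get<0>(top);
    int lab = std::get<2>(top), f = std::get<3>(top);
    if (label[f] != 0) continue;
    if (h >= threshold) continue;   // barrier too high: stays unlabeled
    label[f] = lab;
    entry[f] = h;
    for (const auto &nb : adj[f])
      if (label[nb.f] == 0 && nb.adm < admit_threshold)
        pq.push(std::make_tuple(nb.h, seq++, lab, nb.f));
  }
  return List::create(_["label"] = IntegerVector(label.begin(), label.end()),
                      _["entry_h"] = NumericVector(entry.begin(), entry.end()));
}
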