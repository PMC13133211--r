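// Exact 3D nearest-neighbour queries via a kd-tree; metric p = 1 or 2.
// Stateless API: the tree is rebuilt per call (cheap at the point counts
// used here) which keeps the R side free of external pointers.
#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

struct KDTree {
  const double *pts; // n x 3, column-major from R
  int n;
  std::vector<int> idx;
  int metric; // 1 or 2

  double coord(int i, int d) const { return pts[i + (size_t)d * n]; }

  double dist(int i, const double *q) const {
    double dx = std::fabs(coord(i, 0) - q[0]);
    double dy = std::fabs(coord(i, 1) - q[1]);
    double dz = std::fabs(coord(i, 2) - q[2]);
    if (metric == 1) return dx + dy + dz;
    return std::sqrt(dx * dx + dy * dy + dz * dz);
  }

  void build(int lo, int hi, int depth) {
    if (hi - lo <= 1) return;
    int d = depth % 3;
    int mid = (lo + hi) / 2;
    std::nth_element(idx.begin() + lo, idx.begin() + mid, idx.begin() + hi,
                     [&](int a, int b) { return coord(a, d) < coord(b, d); });
    build(lo, mid, depth + 1);
    build(mid + 1, hi, depth + 1);
  }

  void query(int lo, int hi, int depth, const double *q, double &best,
             int &bestIdx) const {
    if (hi <= lo) return;
    int d = depth % 3;
    int mid = (lo + hi) / 2;
    int i = idx[mid];
    double dd = dist(i, q);
    if (dd < best) { best = dd; bestIdx = i; }
    double diff = q[d] - coord(i, d);
    // |diff| lower-bounds the distance to the far half-space in both L1
    // and L2, so the same pruning rule is exact for either metric.
    if (diff < 0) {
      query(lo, mid, depth + 1, q, best, bestIdx);
      if (std::fabs(diff) < best) query(mid + 1, hi, depth + 1, q, best, bestIdx);
    } else {
      query(mid + 1, hi, depth + 1, q, best, bestIdx);
      if (std::fabs(diff) < best) query(lo, mid, depth + 1, q, best, bestIdx);
    }
  }
};

} // namespace

// Nearest neighbour in `ref` for each row of `query`; returns 1-based
// indices and distances under the requested metric.
// [[Rcpp::export]]
List cpp_nn(NumericMatrix ref, NumericMatrix query, int metric) {
  KDTree tree;
  tree.pts = ref.begin();
  tree.n = ref.nrow();
  tree.metric = metric;
  tree.idx.resize(tree.n);
  for (int i = 0; i < tree.n; ++i) tree.idx[i] = i;
  tree.build(0, tree.n, 0);

  int m = query.nrow();
  IntegerVector oi(m);
  NumericVector od(m);
  double q[3];
  for (int j = 0; j < m; ++j) {
    q[0] = query(j, 0); q[1] = query(j, 1); q[2] = query(j, 2);
    double best = R_PosInf;
    int bi = -1;
    tree.query(0, tree.n, 0, q, best, bi);
    oi[j] = bi + 1;
    od[j] = best;
  }
  return List::create(_["idx"] = oi, _["dist"] = od);
}
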