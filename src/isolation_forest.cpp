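#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Isolation forest over a small point cloud. Trees are grown on random
// subsamples with uniform splits on randomly chosen dimensions; the anomaly
// score of a point is 2^(-E[h]/c(m)) where E[h] is its average path length
// over the forest and c(m) the expected path length of an unsuccessful BST
// search among m points. Harmonic numbers are exact, so c(2) == 1.

static double harmonic(int k) {
  double h = 0.0;
  for (int i = 1; i <= k; ++i) h += 1.0 / i;
  return h;
}

// average unsuccessful-search path length among k points
static double c_factor(int k) {
  if (k <= 1) return 0.0;
  return 2.0 * harmonic(k - 1) - 2.0 * (k - 1.0) / k;
}

struct IsoNode {
  int dim;        // -1 for a leaf
  double split;
  int left, right;
  int size;       // leaf size
};

struct IsoTree {
  std::vector<IsoNode> nodes;

  int build(const NumericMatrix& X, std::vector<int>& idx, int lo, int hi,
            int depth, int max_depth) {
    int n = hi - lo;
    IsoNode node;
    node.dim = -1; node.split = 0.0; node.left = node.right = -1;
    node.size = n;
    int self = (int)nodes.size();
    nodes.push_back(node);
    if (n <= 1 || depth >= max_depth) return self;

    int d = X.ncol();
    // pick a dimension with spread, starting from a random one
    int start = (int)std::floor(unif_rand() * d);
    if (start >= d) start = d - 1;
    int dim = -1;
    double mn = 0.0, mx = 0.0;
    for (int t = 0; t < d; ++t) {
      int dd = (start + t) % d;
      double lmn = X(idx[lo], dd), lmx = lmn;
      for (int i = lo + 1; i < hi; ++i) {
        double v = X(idx[i], dd);
        if (v < lmn) lmn = v;
        if (v > lmx) lmx = v;
      }
      if (lmx > lmn) { dim = dd; mn = lmn; mx = lmx; break; }
    }
    if (dim < 0) return self;   // all points identical: leaf

    double split = mn + unif_rand() * (mx - mn);
    // partition idx[lo, hi) by x[dim] < split
    int mid = lo;
    for (int i = lo; i < hi; ++i) {
      if (X(idx[i], dim) < split) std::swap(idx[i], idx[mid++]);
    }
    if (mid == lo || mid == hi) {
      // degenerate split (split equals max); force one point left
      mid = lo + 1;
    }
    nodes[self].dim = dim;
    nodes[self].split = split;
    int l = build(X, idx, lo, mid, depth + 1, max_depth);
    int r = build(X, idx, mid, hi, depth + 1, max_depth);
    nodes[self].left = l;
    nodes[self].right = r;
    return self;
  }

  double path_length(const NumericMatrix& X, int row) const {
    int cur = 0;
    double depth = 0.0;
    while (nodes[cur].dim >= 0) {
      cur = (X(row, nodes[cur].dim) < nodes[cur].split) ? nodes[cur].left
                                                        : nodes[cur].right;
      depth += 1.0;
    }
    return depth + c_factor(nodes[cur].size);
  }
};

// [[Rcpp::export]]
NumericVector iso_forest_scores_cpp(NumericMatrix X, int n_trees,
                                    int subsample) {
  int n = X.nrow();
  if (n < 2) stop("isolation forest needs at least 2 points");
  if (subsample < 2) subsample = 2;
  if (subsample > n) subsample = n;
  int max_depth = (int)std::ceil(std::log2((double)subsample));
  if (max_depth < 1) max_depth = 1;
  double cm = c_factor(subsample);

  NumericVector avg(n);
  std::vector<int> pool(n), idx(subsample);
  for (int t = 0; t < n_trees; ++t) {
    // draw the subsample without replacement (partial Fisher-Yates on R RNG)
    for (int i = 0; i < n; ++i) pool[i] = i;
    for (int i = 0; i < subsample; ++i) {
      int j = i + (int)std::floor(unif_rand() * (n - i));
      if (j >= n) j = n - 1;
      std::swap(pool[i], pool[j]);
      idx[i] = pool[i];
    }
    IsoTree tree;
    std::vector<int> work(idx);
    tree.build(X, work, 0, subsample, 0, max_depth);
    for (int i = 0; i < n; ++i) avg[i] += tree.path_length(X, i);
  }
  NumericVector score(n);
  for (int i = 0; i < n; ++i) {
    double eh = avg[i] / n_trees;
    score[i] = std::pow(2.0, -eh / cm);
  }
  return score;
}

// [[Rcpp::export]]
double iso_path_norm_cpp(int m) {
  return c_factor(m);
}
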