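// From-scratch isolation forest: trees grown on psi-subsamples by uniform
// random feature choice and uniform random threshold, scored by average
// path length. Uses R's RNG stream (RNGScope via Rcpp attributes), so
// set.seed() on the R side makes fit and subsampling deterministic.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Exact harmonic number H(m) = sum_{k<=m} 1/k (H(1) = 1), via digamma.
static double harmonic(int m) {
  if (m <= 0) return 0.0;
  return R::digamma((double)m + 1.0) + 0.57721566490153286;
}

// Average unsuccessful-search path length of a BST with m points:
// c(m) = 2 H(m-1) - 2 (m-1)/m, c(1) = 0. With exact H, c(2) = 1.
// [[Rcpp::export(name = ".c_factor")]]
double c_factor(int m) {
  if (m <= 1) return 0.0;
  return 2.0 * harmonic(m - 1) - 2.0 * (double)(m - 1) / (double)m;
}

struct FlatTree {
  // node arrays; children index into the same arrays, -1 for none (leaf)
  std::vector<int> feature;      // split feature (0-based), -1 at leaves
  std::vector<double> threshold;
  std::vector<int> left, right;
  std::vector<int> size;         // training points reaching the node

  int add_node() {
    feature.push_back(-1); threshold.push_back(NA_REAL);
    left.push_back(-1); right.push_back(-1); size.push_back(0);
    return (int)feature.size() - 1;
  }
};

static int grow(FlatTree& tree, const NumericMatrix& X,
                std::vector<int>& idx, int begin, int end,
                int depth, int height_limit) {
  int node = tree.add_node();
  int m = end - begin;
  tree.size[node] = m;
  if (m <= 1 || depth >= height_limit) return node;

  int d = X.ncol();
  // candidate features: those with a spread inside this node's subset
  std::vector<int> usable;
  std::vector<double> lo(d), hi(d);
  for (int j = 0; j < d; ++j) {
    double mn = X(idx[begin], j), mx = mn;
    for (int i = begin + 1; i < end; ++i) {
      double v = X(idx[i], j);
      if (v < mn) mn = v;
      if (v > mx) mx = v;
    }
    lo[j] = mn; hi[j] = mx;
    if (mx > mn) usable.push_back(j);
  }
  if (usable.empty()) return node;  // duplicate points: leaf

  int j = usable[(int)(unif_rand() * usable.size()) % usable.size()];
  // threshold strictly inside (min, max) of the feature in this node; when
  // min and max are so close that no representable interior value is drawn
  // (adjacent floats happen with heavily duplicated traces), stop splitting
  double thr = lo[j];
  for (int attempt = 0; attempt < 16; ++attempt) {
    thr = lo[j] + unif_rand() * (hi[j] - lo[j]);
    if (thr > lo[j] && thr < hi[j]) break;
  }
  if (thr <= lo[j] || thr >= hi[j]) return node;  // degenerate: leaf

  // partition idx[begin, end) by the threshold
  int mid = begin;
  for (int i = begin; i < end; ++i)
    if (X(idx[i], j) < thr) std::swap(idx[i], idx[mid++]);

  tree.feature[node] = j;
  tree.threshold[node] = thr;
  tree.left[node] = grow(tree, X, idx, begin, mid, depth + 1, height_limit);
  tree.right[node] = grow(tree, X, idx, mid, end, depth + 1, height_limit);
  return node;
}

// [[Rcpp::export(name = ".iso_fit")]]
List iso_fit(NumericMatrix X, int n_trees, int psi, int height_limit) {
  int n = X.nrow();
  List trees(n_trees);
  std::vector<int> pool(n);
  for (int t = 0; t < n_trees; ++t) {
    for (int i = 0; i < n; ++i) pool[i] = i;
    // partial Fisher-Yates draw of psi indices without replacement
    std::vector<int> idx(psi);
    for (int i = 0; i < psi; ++i) {
      int k = i + (int)(unif_rand() * (n - i)) % (n - i);
      std::swap(pool[i], pool[k]);
      idx[i] = pool[i];
    }
    FlatTree tree;
    grow(tree, X, idx, 0, psi, 0, height_limit);
    trees[t] = List::create(
      _["feature"] = IntegerVector(tree.feature.begin(), tree.feature.end()),
      _["threshold"] = NumericVector(tree.threshold.begin(), tree.threshold.end()),
      _["left"] = IntegerVector(tree.left.begin(), tree.left.end()),
      _["right"] = IntegerVector(tree.right.begin(), tree.right.end()),
      _["size"] = IntegerVector(tree.size.begin(), tree.size.end()));
  }
  return trees;
}

// Mean over trees of (edges traversed + c(leaf size)) for each row of X.
// [[Rcpp::export(name = ".iso_path_lengths")]]
NumericVector iso_path_lengths(List trees, NumericMatrix X) {
  int n = X.nrow(), T = trees.size();
  NumericVector out(n);
  for (int t = 0; t < T; ++t) {
    List tr = trees[t];
    IntegerVector feature = tr["feature"];
    NumericVector threshold = tr["threshold"];
    IntegerVector left = tr["left"], right = tr["right"], size = tr["size"];
    for (int i = 0; i < n; ++i) {
      int node = 0, depth = 0;
      while (feature[node] >= 0) {
        node = (X(i, feature[node]) < threshold[node]) ? left[node]
                                                       : right[node];
        ++depth;
      }
      out[i] += depth + c_factor(size[node]);
    }
  }
  return out / (double)T;
}
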