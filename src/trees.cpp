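// Regression/classification trees over binary indicator features.
//
// Features are 0/1 indicators, so every split is "x == 0 vs x == 1" and the
// best split per node can be found with a single pass of count/sum
// accumulation. Variance reduction is the split criterion; on a 0/1
// response it is proportional to the Gini gain, so one routine serves both
// the bagged classification forest and the gradient-boosting base learner.
// All randomness is drawn from R's RNG so set.seed() governs determinism.

#include <Rcpp.h>
using namespace Rcpp;

struct Node {
  int feature;   // -1 for leaf
  int left, right;
  double value;  // mean response in node
};

static void grow(const IntegerMatrix& X, const NumericVector& y,
                 std::vector<int>& rows, int begin, int end,
                 int depth, int max_depth, int min_node, int mtry,
                 std::vector<Node>& nodes, int node_id,
                 std::vector<double>& importance) {
  const int n = end - begin;
  double sum = 0.0;
  for (int i = begin; i < end; ++i) sum += y[rows[i]];
  nodes[node_id].value = sum / n;
  nodes[node_id].feature = -1;
  if (depth >= max_depth || n < 2 * min_node) return;

  const int p = X.ncol();
  // candidate features: all, or a uniform draw of mtry without replacement
  std::vector<int> cand;
  if (mtry >= p) {
    cand.resize(p);
    for (int j = 0; j < p; ++j) cand[j] = j;
  } else {
    std::vector<int> pool(p);
    for (int j = 0; j < p; ++j) pool[j] = j;
    cand.resize(mtry);
    int remaining = p;
    for (int k = 0; k < mtry; ++k) {
      int idx = (int)(unif_rand() * remaining);
      if (idx >= remaining) idx = remaining - 1;
      cand[k] = pool[idx];
      pool[idx] = pool[--remaining];
    }
    std::sort(cand.begin(), cand.end()); // deterministic tie-breaking order
  }

  int best_j = -1;
  double best_gain = 1e-12;
  for (size_t c = 0; c < cand.size(); ++c) {
    const int j = cand[c];
    int n1 = 0;
    double s1 = 0.0;
    for (int i = begin; i < end; ++i) {
      const int r = rows[i];
      if (X(r, j) == 1) { ++n1; s1 += y[r]; }
    }
    const int n0 = n - n1;
    if (n1 < min_node || n0 < min_node) continue;
    const double s0 = sum - s1;
    const double gain = s1 * s1 / n1 + s0 * s0 / n0 - sum * sum / n;
    if (gain > best_gain) { best_gain = gain; best_j = j; }
  }
  if (best_j < 0) return;

  // partition rows[begin:end) in place: x==0 first, then x==1
  int mid = begin;
  for (int i = begin; i < end; ++i) {
    if (X(rows[i], best_j) == 0) std::swap(rows[i], rows[mid++]);
  }
  if (mid == begin || mid == end) return;

  importance[best_j] += best_gain;
  const int left_id = (int)nodes.size();
  nodes.push_back(Node());
  const int right_id = (int)nodes.size();
  nodes.push_back(Node());
  nodes[node_id].feature = best_j;
  nodes[node_id].left = left_id;
  nodes[node_id].right = right_id;
  grow(X, y, rows, begin, mid, depth + 1, max_depth, min_node, mtry,
       nodes, left_id, importance);
  grow(X, y, rows, mid, end, depth + 1, max_depth, min_node, mtry,
       nodes, right_id, importance);
}

static List pack_tree(const std::vector<Node>& nodes) {
  const int m = (int)nodes.size();
  IntegerVector feature(m), left(m), right(m);
  NumericVector value(m);
  for (int k = 0; k < m; ++k) {
    feature[k] = nodes[k].feature;
    left[k] = nodes[k].left;
    right[k] = nodes[k].right;
    value[k] = nodes[k].value;
  }
  return List::create(_["feature"] = feature, _["left"] = left,
                      _["right"] = right, _["value"] = value);
}

static void predict_tree(const List& tree, const IntegerMatrix& X,
                         NumericVector& out, double weight) {
  const IntegerVector feature = tree["feature"];
  const IntegerVector left = tree["left"];
  const IntegerVector right = tree["right"];
  const NumericVector value = tree["value"];
  const int n = X.nrow();
  for (int i = 0; i < n; ++i) {
    int k = 0;
    while (feature[k] >= 0) {
      k = (X(i, feature[k]) == 0) ? left[k] : right[k];
    }
    out[i] += weight * value[k];
  }
}

// [[Rcpp::export(rng = true)]]
List cpp_forest_fit(IntegerMatrix X, NumericVector y, int ntree, int mtry,
                    int max_depth, int min_node) {
  const int n = X.nrow(), p = X.ncol();
  std::vector<double> importance(p, 0.0);
  List trees(ntree);
  for (int t = 0; t < ntree; ++t) {
    std::vector<int> rows(n);
    for (int i = 0; i < n; ++i) {
      int idx = (int)(unif_rand() * n);
      if (idx >= n) idx = n - 1;
      rows[i] = idx; // bootstrap sample
    }
    std::vector<Node> nodes(1);
    grow(X, y, rows, 0, n, 0, max_depth, min_node, mtry, nodes, 0, importance);
    trees[t] = pack_tree(nodes);
  }
  return List::create(_["trees"] = trees,
                      _["importance"] = NumericVector(importance.begin(),
                                                      importance.end()));
}

// [[Rcpp::export(rng = false)]]
NumericVector cpp_forest_predict(List fit, IntegerMatrix X) {
  const List trees = fit["trees"];
  const int ntree = trees.size();
  NumericVector out(X.nrow());
  for (int t = 0; t < ntree; ++t) {
    predict_tree(trees[t], X, out, 1.0 / ntree);
  }
  for (int i = 0; i < out.size(); ++i) { // guard fp summation drift
    if (out[i] < 0.0) out[i] = 0.0;
    if (out[i] > 1.0) out[i] = 1.0;
  }
  return out;
}

// Gradient tree boosting with logistic loss: trees are fit to the
// residual y - p and leaves take a Newton step sum(r) / sum(p (1 - p)).
// [[Rcpp::export(rng = false)]]
List cpp_gbm_fit(IntegerMatrix X, NumericVector y, int ntree,
                 double shrinkage, int max_depth, int min_node) {
  const int n = X.nrow(), p = X.ncol();
  std::vector<double> importance(p, 0.0);

  double ybar = 0.0;
  for (int i = 0; i < n; ++i) ybar += y[i];
  ybar /= n;
  if (ybar < 1e-6) ybar = 1e-6;
  if (ybar > 1 - 1e-6) ybar = 1 - 1e-6;
  const double f0 = std::log(ybar / (1.0 - ybar));

  NumericVector F(n, f0), r(n), hess(n);
  List trees(ntree);
  int used = 0;
  for (int t = 0; t < ntree; ++t) {
    double abs_r = 0.0;
    for (int i = 0; i < n; ++i) {
      const double prob = 1.0 / (1.0 + std::exp(-F[i]));
      r[i] = y[i] - prob;
      hess[i] = prob * (1.0 - prob);
      abs_r += std::fabs(r[i]);
    }
    if (abs_r / n < 1e-2) break; // mean |gradient| negligible: converged
    std::vector<int> rows(n);
    for (int i = 0; i < n; ++i) rows[i] = i;
    std::vector<Node> nodes(1);
    grow(X, r, rows, 0, n, 0, max_depth, min_node, p, nodes, 0, importance);
    // replace leaf means of r by Newton-step values
    // (recompute membership by dropping rows down the tree)
    std::vector<double> num(nodes.size(), 0.0), den(nodes.size(), 0.0);
    for (int i = 0; i < n; ++i) {
      int k = 0;
      while (nodes[k].feature >= 0) {
        k = (X(i, nodes[k].feature) == 0) ? nodes[k].left : nodes[k].right;
      }
      num[k] += r[i];
      den[k] += hess[i];
    }
    for (size_t k = 0; k < nodes.size(); ++k) {
      if (nodes[k].feature < 0) {
        double v = (den[k] > 1e-12) ? num[k] / den[k] : 0.0;
        if (v > 4.0) v = 4.0;
        if (v < -4.0) v = -4.0;
        nodes[k].value = v;
      }
    }
    List tree = pack_tree(nodes);
    predict_tree(tree, X, F, shrinkage);
    trees[t] = tree;
    ++used;
  }
  List kept(used);
  for (int t = 0; t < used; ++t) kept[t] = trees[t];
  return List::create(_["trees"] = kept, _["f0"] = f0,
                      _["shrinkage"] = shrinkage,
                      _["importance"] = NumericVector(importance.begin(),
                                                      importance.end()));
}

// [[Rcpp::export(rng = false)]]
NumericVector cpp_gbm_predict(List fit, IntegerMatrix X) {
  const List trees = fit["trees"];
  const double f0 = fit["f0"];
  const double shrinkage = fit["shrinkage"];
  const int n = X.nrow();
  NumericVector F(n, f0);
  for (int t = 0; t < trees.size(); ++t) {
    predict_tree(trees[t], X, F, shrinkage);
  }
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = 1.0 / (1.0 + std::exp(-F[i]));
  return out;
}
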