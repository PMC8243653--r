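// Random forest (classification) with scikit-learn-compatible
// semantics for the configuration used by the pipeline:
//   - bootstrap = false: every tree is grown on the full training set,
//     randomness enters only through per-node feature subsampling;
//   - CART splits minimizing gini impurity, split at the midpoint
//     between consecutive distinct values, x <= threshold goes left;
//   - stopping: max_depth, min_samples_split, min_samples_leaf, purity;
//   - prediction: average of leaf class-proportion vectors;
//   - importance: impurity decrease weighted by node sample fraction,
//     normalized to sum 1 per tree, averaged over trees.
//
// Feature subsampling uses an explicit Fisher-Yates with raw mt19937
// draws (no std::uniform_int_distribution), so results are identical
// across standard-library implementations.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <random>
#include <vector>

using namespace Rcpp;

namespace {

struct Node {
  int feature = -1;  // -1 for leaf
  double threshold = 0.0;
  int left = -1, right = -1;
  std::vector<double> dist;  // class proportions (leaves only)
};

struct BuildCtx {
  const double* X;  // column-major n x p
  const int* y;
  int n, p, K;
  int mtry, min_split, min_leaf, max_depth;
  std::mt19937 rng;
  std::vector<Node> nodes;
  std::vector<double> importance;
  std::vector<int> feat_pool;
};

inline double gini(const std::vector<double>& counts, double n) {
  double g = 1.0;
  for (double c : counts) {
    double f = c / n;
    g -= f * f;
  }
  return g;
}

inline int bounded_draw(std::mt19937& rng, int bound) {
  // modulo bias is negligible for bound << 2^32 and keeps draws
  // implementation-independent
  return (int)(rng() % (uint32_t)bound);
}

int build_node(BuildCtx& ctx, std::vector<int>& idx, int depth) {
  const int n = (int)idx.size();
  std::vector<double> counts(ctx.K, 0.0);
  for (int i : idx) counts[ctx.y[i]] += 1.0;
  double imp = gini(counts, n);

  bool make_leaf = depth >= ctx.max_depth || n < ctx.min_split || imp <= 0.0;

  int best_feat = -1;
  double best_thr = 0.0, best_gain = 0.0;
  std::vector<int> left_idx, right_idx;

  if (!make_leaf) {
    // sample mtry distinct features
    for (int j = 0; j < ctx.mtry; ++j) {
      int k = j + bounded_draw(ctx.rng, ctx.p - j);
      std::swap(ctx.feat_pool[j], ctx.feat_pool[k]);
    }
    std::vector<std::pair<double, int>> vals(n);
    std::vector<double> lc(ctx.K);
    for (int j = 0; j < ctx.mtry; ++j) {
      int f = ctx.feat_pool[j];
      const double* col = ctx.X + (size_t)f * ctx.n;
      for (int i = 0; i < n; ++i) vals[i] = {col[idx[i]], ctx.y[idx[i]]};
      std::sort(vals.begin(), vals.end());
      std::fill(lc.begin(), lc.end(), 0.0);
      for (int i = 0; i < n - 1; ++i) {
        lc[vals[i].second] += 1.0;
        if (vals[i + 1].first <= vals[i].first) continue;  // no boundary
        int nl = i + 1, nr = n - nl;
        if (nl < ctx.min_leaf || nr < ctx.min_leaf) continue;
        double gl = 1.0, gr = 1.0;
        for (int c = 0; c < ctx.K; ++c) {
          double fl = lc[c] / nl, fr = (counts[c] - lc[c]) / nr;
          gl -= fl * fl;
          gr -= fr * fr;
        }
        double gain = imp - (nl * gl + nr * gr) / n;
        if (gain > best_gain + 1e-15) {
          best_gain = gain;
          best_feat = f;
          best_thr = 0.5 * (vals[i].first + vals[i + 1].first);
        }
      }
    }
    if (best_feat < 0) make_leaf = true;
  }

  int id = (int)ctx.nodes.size();
  ctx.nodes.emplace_back();
  if (make_leaf) {
    Node& nd = ctx.nodes[id];
    nd.dist.resize(ctx.K);
    for (int c = 0; c < ctx.K; ++c) nd.dist[c] = counts[c] / n;
    return id;
  }

  ctx.importance[best_feat] += (double)n * best_gain;
  const double* col = ctx.X + (size_t)best_feat * ctx.n;
  left_idx.reserve(n);
  right_idx.reserve(n);
  for (int i : idx) {
    (col[i] <= best_thr ? left_idx : right_idx).push_back(i);
  }
  idx.clear();
  idx.shrink_to_fit();
  int l = build_node(ctx, left_idx, depth + 1);
  int r = build_node(ctx, right_idx, depth + 1);
  ctx.nodes[id].feature = best_feat;
  ctx.nodes[id].threshold = best_thr;
  ctx.nodes[id].left = l;
  ctx.nodes[id].right = r;
  return id;
}

List tree_to_list(const BuildCtx& ctx) {
  int m = (int)ctx.nodes.size();
  IntegerVector feature(m), left(m), right(m);
  NumericVector threshold(m);
  NumericMatrix dist(m, ctx.K);
  for (int i = 0; i < m; ++i) {
    const Node& nd = ctx.nodes[i];
    feature[i] = nd.feature;
    threshold[i] = nd.threshold;
    left[i] = nd.left;
    right[i] = nd.right;
    if (nd.feature < 0) {
      for (int c = 0; c < ctx.K; ++c) dist(i, c) = nd.dist[c];
    }
  }
  return List::create(_["feature"] = feature, _["threshold"] = threshold,
                      _["left"] = left, _["right"] = right,
                      _["dist"] = dist);
}

}  // namespace

// [[Rcpp::export(name = ".rf_train_cpp")]]
List rf_train_cpp(NumericMatrix X, IntegerVector y, int n_classes,
                  int n_trees, int mtry, int min_split, int min_leaf,
                  int max_depth, IntegerVector seeds) {
  const int n = X.nrow(), p = X.ncol();
  if (y.size() != n) stop("rf_train: label length mismatch");
  if (seeds.size() != n_trees) stop("rf_train: one seed per tree required");
  if (mtry < 1 || mtry > p) stop("rf_train: invalid mtry");
  List trees(n_trees);
  NumericVector importance(p);
  for (int t = 0; t < n_trees; ++t) {
    BuildCtx ctx;
    ctx.X = REAL(X);
    ctx.y = INTEGER(y);
    ctx.n = n;
    ctx.p = p;
    ctx.K = n_classes;
    ctx.mtry = mtry;
    ctx.min_split = min_split;
    ctx.min_leaf = min_leaf;
    ctx.max_depth = max_depth;
    ctx.rng.seed((uint32_t)seeds[t]);
    ctx.importance.assign(p, 0.0);
    ctx.feat_pool.resize(p);
    for (int f = 0; f < p; ++f) ctx.feat_pool[f] = f;
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = i;
    build_node(ctx, idx, 0);
    trees[t] = tree_to_list(ctx);
    double tot = 0.0;
    for (double v : ctx.importance) tot += v;
    if (tot > 0) {
      for (int f = 0; f < p; ++f) importance[f] += ctx.importance[f] / tot;
    }
  }
  for (int f = 0; f < p; ++f) importance[f] /= n_trees;
  return List::create(_["trees"] = trees, _["importance"] = importance);
}

// [[Rcpp::export(name = ".rf_predict_cpp")]]
NumericMatrix rf_predict_cpp(List trees, NumericMatrix X, int n_classes) {
  const int n = X.nrow();
  const int nt = trees.size();
  NumericMatrix prob(n, n_classes);
  for (int t = 0; t < nt; ++t) {
    List tr = trees[t];
    IntegerVector feature = tr["feature"], left = tr["left"],
                  right = tr["right"];
    NumericVector threshold = tr["threshold"];
    NumericMatrix dist = tr["dist"];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (feature[node] >= 0) {
        node = (X(i, feature[node]) <= threshold[node]) ? left[node]
                                                        : right[node];
      }
      for (int c = 0; c < n_classes; ++c) prob(i, c) += dist(node, c);
    }
  }
  for (int i = 0; i < n; ++i) {
    for (int c = 0; c < n_classes; ++c) prob(i, c) /= nt;
  }
  return prob;
}
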