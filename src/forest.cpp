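// Regression random forest with Mean Decrease Impurity accounting.
//
// Node impurity is the (population) sum of squared deviations
// SSE(S) = #S * Var(S); the importance credited to a split is
// I(N) = SSE(S) - SSE(S_t) - SSE(S_f).  SSE is computed by a two-pass
// mean/deviation sum at every node and the child values are reused as
// the parent terms of the next level, so for a fully grown tree the
// per-feature importances telescope exactly to SSE(root).

#include <Rcpp.h>
#include <random>
#include <algorithm>
#include <vector>
#include <cstdint>

using namespace Rcpp;

namespace {

struct TreeBuf {
  std::vector<int> feature;      // split feature (0-based), -1 for leaf
  std::vector<double> threshold; // go left when x <= threshold
  std::vector<int> left, right;  // child node ids, -1 for leaf
  std::vector<double> value;     // node mean (prediction at leaves)
};

double node_sse(const std::vector<double> &y, const std::vector<int> &idx,
                double &mean_out) {
  double s = 0.0;
  for (int i : idx) s += y[i];
  const double m = s / idx.size();
  double sse = 0.0;
  for (int i : idx) {
    const double d = y[i] - m;
    sse += d * d;
  }
  mean_out = m;
  return sse;
}

// strictly-better comparison with a relative tolerance: mathematically
// tied splits (identical partitions reached through different features)
// must compare as ties even after floating-point jitter. Ties go to the
// feature encountered first in the per-node shuffle of the canonical
// (gene-name-ordered) feature pool, so the draw is random across nodes
// and trees yet invariant to column order and to rescaling the targets.
inline bool score_better(double a, double b) {
  return a > b + 1e-9 * std::max(std::abs(a), std::abs(b));
}

struct Builder {
  const NumericMatrix &x;
  const std::vector<double> &y;
  int q;
  int k_features;
  int min_split;
  std::mt19937_64 &rng;
  TreeBuf tree;
  std::vector<double> imp; // per-feature summed I over this tree
  std::vector<int> feat_pool;
  // scratch for split scanning
  std::vector<std::pair<double, double>> xy;

  Builder(const NumericMatrix &x_, const std::vector<double> &y_,
          const std::vector<int> &canonical_order, int k, int min_split_,
          std::mt19937_64 &rng_)
      : x(x_), y(y_), q(x_.ncol()), k_features(k),
        min_split(min_split_), rng(rng_), imp(q, 0.0),
        feat_pool(canonical_order) {}

  int new_node(double value) {
    tree.feature.push_back(-1);
    tree.threshold.push_back(NA_REAL);
    tree.left.push_back(-1);
    tree.right.push_back(-1);
    tree.value.push_back(value);
    return (int)tree.feature.size() - 1;
  }

  // returns node id; sse/mean precomputed for idx
  int build(std::vector<int> &idx, double sse, double mean) {
    const int n = (int)idx.size();
    const int node = new_node(mean);
    if (n < min_split || sse <= 0.0) return node;
    bool pure = true; // exact check: two-pass sse can be a few ulp for ties
    for (int i : idx) {
      if (y[i] != y[idx[0]]) { pure = false; break; }
    }
    if (pure) return node;

    // sample k features without replacement (partial Fisher-Yates)
    for (int i = 0; i < k_features; ++i) {
      std::uniform_int_distribution<int> d(i, q - 1);
      std::swap(feat_pool[i], feat_pool[d(rng)]);
    }

    int best_f = -1;
    double best_score = 0.0, best_thr = 0.0;
    for (int fi = 0; fi < k_features; ++fi) {
      const int f = feat_pool[fi];
      xy.clear();
      for (int i : idx) xy.emplace_back(x(i, f), y[i]);
      std::sort(xy.begin(), xy.end());
      if (xy.front().first == xy.back().first) continue; // constant feature
      double sl = 0.0;
      double st = 0.0;
      for (auto &p : xy) st += p.second;
      // best split of this feature; earliest position wins within-feature
      // ties. candidate split after position i (0-based): left = 0..i
      int have = 0;
      double fscore = 0.0, fthr = 0.0;
      for (int i = 0; i < n - 1; ++i) {
        sl += xy[i].second;
        if (xy[i].first == xy[i + 1].first) continue;
        const int nl = i + 1, nr = n - nl;
        const double sr = st - sl;
        // score = SSE(S) - SSE(L) - SSE(R) up to a constant:
        // maximize sl^2/nl + sr^2/nr
        const double score = sl * sl / nl + sr * sr / nr;
        if (!have || score_better(score, fscore)) {
          have = 1;
          fscore = score;
          fthr = xy[i].first + 0.5 * (xy[i + 1].first - xy[i].first);
        }
      }
      if (!have) continue;
      if (best_f < 0 || score_better(fscore, best_score)) {
        best_score = fscore;
        best_f = f;
        best_thr = fthr;
      }
    }
    if (best_f < 0) return node; // all sampled features constant

    std::vector<int> li, ri;
    for (int i : idx) {
      if (x(i, best_f) <= best_thr) li.push_back(i);
      else ri.push_back(i);
    }
    // degenerate partition cannot happen: threshold strictly separates values
    double lm, rm;
    const double lsse = node_sse(y, li, lm);
    const double rsse = node_sse(y, ri, rm);
    imp[best_f] += sse - lsse - rsse;

    tree.feature[node] = best_f;
    tree.threshold[node] = best_thr;
    const int lid = build(li, lsse, lm);
    const int rid = build(ri, rsse, rm);
    tree.left[node] = lid;
    tree.right[node] = rid;
    return node;
  }
};

double predict_one(const IntegerVector &feature, const NumericVector &threshold,
                   const IntegerVector &left, const IntegerVector &right,
                   const NumericVector &value, const NumericMatrix &x, int row) {
  int node = 0;
  while (feature[node] >= 0) {
    node = (x(row, feature[node]) <= threshold[node]) ? left[node] : right[node];
  }
  return value[node];
}

} // namespace

// [[Rcpp::export(name = ".rf_train")]]
List rf_train_cpp(NumericMatrix x, NumericVector y, IntegerVector tie_rank,
                  int n_trees, int k, bool bootstrap, int min_split,
                  double seed) {
  const int n = x.nrow(), q = x.ncol();
  if (k < 1 || k > q) stop("k must be in [1, ncol(x)]");
  if (tie_rank.size() != q) stop("tie_rank length mismatch");
  // canonical feature pool: positions sorted by tie rank (gene name),
  // re-shuffled at every node by the tree RNG
  std::vector<int> canon(q);
  for (int f = 0; f < q; ++f) canon[f] = f;
  std::vector<int> rank_vec(tie_rank.begin(), tie_rank.end());
  std::sort(canon.begin(), canon.end(),
            [&](int a, int b) { return rank_vec[a] < rank_vec[b]; });
  std::mt19937_64 rng((std::uint64_t)seed);
  std::uniform_int_distribution<int> row_draw(0, n - 1);

  List trees(n_trees);
  NumericMatrix tree_importance(q, n_trees);
  IntegerMatrix inbag(n, n_trees);

  std::vector<double> yb(n);
  for (int t = 0; t < n_trees; ++t) {
    std::vector<int> idx;
    idx.reserve(n);
    if (bootstrap) {
      for (int i = 0; i < n; ++i) {
        const int j = row_draw(rng);
        idx.push_back(j);
        inbag(j, t) += 1;
      }
    } else {
      for (int i = 0; i < n; ++i) {
        idx.push_back(i);
        inbag(i, t) = 1;
      }
    }
    for (int i = 0; i < n; ++i) yb[i] = y[i];
    Builder b(x, yb, canon, k, min_split, rng);
    double mean;
    const double sse = node_sse(yb, idx, mean);
    b.build(idx, sse, mean);
    for (int f = 0; f < q; ++f) tree_importance(f, t) = b.imp[f];
    trees[t] = List::create(
        _["feature"] = IntegerVector(b.tree.feature.begin(), b.tree.feature.end()),
        _["threshold"] = NumericVector(b.tree.threshold.begin(), b.tree.threshold.end()),
        _["left"] = IntegerVector(b.tree.left.begin(), b.tree.left.end()),
        _["right"] = IntegerVector(b.tree.right.begin(), b.tree.right.end()),
        _["value"] = NumericVector(b.tree.value.begin(), b.tree.value.end()));
  }
  return List::create(_["trees"] = trees,
                      _["tree_importance"] = tree_importance,
                      _["inbag"] = inbag);
}

// [[Rcpp::export(name = ".rf_predict")]]
NumericVector rf_predict_cpp(List trees, NumericMatrix x) {
  const int n = x.nrow(), T = trees.size();
  NumericVector out(n);
  for (int t = 0; t < T; ++t) {
    List tr = trees[t];
    IntegerVector feature = tr["feature"];
    NumericVector threshold = tr["threshold"];
    IntegerVector left = tr["left"];
    IntegerVector right = tr["right"];
    NumericVector value = tr["value"];
    for (int i = 0; i < n; ++i)
      out[i] += predict_one(feature, threshold, left, right, value, x, i);
  }
  for (int i = 0; i < n; ++i) out[i] /= T;
  return out;
}

// Mean prediction over the trees whose bootstrap left the row out.
// Rows in-bag for every tree get NA.
// [[Rcpp::export(name = ".rf_predict_oob")]]
NumericVector rf_predict_oob_cpp(List trees, IntegerMatrix inbag,
                                 NumericMatrix x) {
  const int n = x.nrow(), T = trees.size();
  if (inbag.nrow() != n) stop("inbag/x row mismatch");
  NumericVector out(n);
  IntegerVector cnt(n);
  for (int t = 0; t < T; ++t) {
    List tr = trees[t];
    IntegerVector feature = tr["feature"];
    NumericVector threshold = tr["threshold"];
    IntegerVector left = tr["left"];
    IntegerVector right = tr["right"];
    NumericVector value = tr["value"];
    for (int i = 0; i < n; ++i) {
      if (inbag(i, t) == 0) {
        out[i] += predict_one(feature, threshold, left, right, value, x, i);
        cnt[i] += 1;
      }
    }
  }
  for (int i = 0; i < n; ++i) {
    if (cnt[i] == 0) out[i] = NA_REAL;
    else out[i] /= cnt[i];
  }
  return out;
}
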