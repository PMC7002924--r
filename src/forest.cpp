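// Random-forest classifier: CART trees, Gini impurity, bootstrap sampling,
// per-node random feature subsets, and mean-decrease-impurity feature
// importance (fraction of samples reaching a node times the impurity
// decrease of its split, summed per feature, normalized per tree, averaged
// over the forest).
#include <Rcpp.h>
#include <random>
#include <algorithm>
#include <vector>
using namespace Rcpp;

namespace {

struct TreeNodes {
  std::vector<int> feature;      // -1 for leaf
  std::vector<double> threshold;
  std::vector<int> left, right, pred;
};

double gini_from_counts(const std::vector<double>& cnt, double n) {
  if (n <= 0) return 0.0;
  double g = 1.0;
  for (double c : cnt) { double p = c / n; g -= p * p; }
  return g;
}

struct Builder {
  const NumericMatrix& X;
  const IntegerVector& y;
  int n_classes, mtry, max_depth, min_samples_leaf;
  double n_total;
  std::mt19937 rng;
  TreeNodes nodes;
  std::vector<double> importance; // per feature, this tree

  Builder(const NumericMatrix& X_, const IntegerVector& y_, int n_classes_,
          int mtry_, int max_depth_, int min_leaf_, unsigned seed)
    : X(X_), y(y_), n_classes(n_classes_), mtry(mtry_),
      max_depth(max_depth_), min_samples_leaf(min_leaf_),
      n_total(0.0), rng(seed), importance(X_.ncol(), 0.0) {}

  int make_leaf(const std::vector<double>& cnt) {
    int best = 0;
    for (int c = 1; c < n_classes; ++c) if (cnt[c] > cnt[best]) best = c;
    nodes.feature.push_back(-1);
    nodes.threshold.push_back(0.0);
    nodes.left.push_back(-1);
    nodes.right.push_back(-1);
    nodes.pred.push_back(best);
    return (int)nodes.feature.size() - 1;
  }

  // idx: sample indices reaching this node (may repeat under bootstrap)
  int build(std::vector<int>& idx, int depth) {
    int n = (int)idx.size();
    std::vector<double> cnt(n_classes, 0.0);
    for (int s : idx) cnt[y[s]] += 1.0;
    double node_gini = gini_from_counts(cnt, n);
    bool pure = node_gini <= 0.0;
    if (pure || n < 2 * min_samples_leaf || n < 2 ||
        (max_depth > 0 && depth >= max_depth))
      return make_leaf(cnt);

    int p = X.ncol();
    std::vector<int> feats(p);
    for (int f = 0; f < p; ++f) feats[f] = f;
    std::shuffle(feats.begin(), feats.end(), rng);
    int n_try = std::min(mtry, p);

    int best_feat = -1;
    double best_thr = 0.0, best_gain = 1e-12;
    std::vector<std::pair<double,int> > vals(n);

    int tried = 0;
    for (int fi = 0; fi < p && tried < n_try; ++fi) {
      int f = feats[fi];
      for (int k = 0; k < n; ++k)
        vals[k] = std::make_pair(X(idx[k], f), y[idx[k]]);
      std::sort(vals.begin(), vals.end());
      if (vals.front().first == vals.back().first) continue; // constant here
      ++tried;
      std::vector<double> lc(n_classes, 0.0);
      int nl = 0;
      for (int k = 0; k < n - 1; ++k) {
        lc[vals[k].second] += 1.0; ++nl;
        if (vals[k].first == vals[k + 1].first) continue;
        int nr = n - nl;
        if (nl < min_samples_leaf || nr < min_samples_leaf) continue;
        double gl = 1.0, gr = 1.0;
        for (int c = 0; c < n_classes; ++c) {
          double pl = lc[c] / nl, pr = (cnt[c] - lc[c]) / nr;
          gl -= pl * pl; gr -= pr * pr;
        }
        double gain = node_gini -
          ((double)nl / n) * gl - ((double)nr / n) * gr;
        if (gain > best_gain) {
          best_gain = gain;
          best_feat = f;
          best_thr = 0.5 * (vals[k].first + vals[k + 1].first);
        }
      }
    }
    if (best_feat < 0) return make_leaf(cnt);

    importance[best_feat] += (n / n_total) * best_gain;

    std::vector<int> li, ri;
    li.reserve(n); ri.reserve(n);
    for (int s : idx) {
      if (X(s, best_feat) <= best_thr) li.push_back(s);
      else ri.push_back(s);
    }
    int me = make_leaf(cnt); // placeholder slot; converted to split below
    nodes.feature[me] = best_feat;
    nodes.threshold[me] = best_thr;
    int l = build(li, depth + 1);
    int r = build(ri, depth + 1);
    nodes.left[me] = l;
    nodes.right[me] = r;
    return me;
  }
};

int tree_predict_one(const List& tree, const NumericMatrix& X, int row) {
  IntegerVector feature = tree["feature"];
  NumericVector threshold = tree["threshold"];
  IntegerVector left = tree["left"], right = tree["right"],
    pred = tree["pred"];
  int node = 0;
  while (feature[node] >= 0) {
    node = (X(row, feature[node]) <= threshold[node]) ? left[node]
                                                      : right[node];
  }
  return pred[node];
}

} // namespace

// [[Rcpp::export(name = ".forest_fit")]]
List forest_fit(NumericMatrix X, IntegerVector y, int n_classes,
                int n_trees, int mtry, int max_depth, int min_samples_leaf,
                bool bootstrap, int seed) {
  int n = X.nrow(), p = X.ncol();
  if (mtry <= 0) mtry = std::max(1, (int)std::floor(std::sqrt((double)p)));
  NumericVector imp(p);
  List trees(n_trees);
  std::mt19937 seeder((unsigned)seed);
  for (int t = 0; t < n_trees; ++t) {
    unsigned tree_seed = seeder();
    Builder b(X, y, n_classes, mtry, max_depth, min_samples_leaf, tree_seed);
    std::vector<int> idx(n);
    if (bootstrap) {
      std::uniform_int_distribution<int> pick(0, n - 1);
      for (int k = 0; k < n; ++k) idx[k] = pick(b.rng);
    } else {
      for (int k = 0; k < n; ++k) idx[k] = k;
    }
    b.n_total = (double)n;
    b.build(idx, 0);
    // per-tree normalization to sum 1, then average over the forest
    double tot = 0.0;
    for (double v : b.importance) tot += v;
    if (tot > 0.0)
      for (int f = 0; f < p; ++f) imp[f] += b.importance[f] / tot / n_trees;
    trees[t] = List::create(
      _["feature"] = wrap(b.nodes.feature),
      _["threshold"] = wrap(b.nodes.threshold),
      _["left"] = wrap(b.nodes.left),
      _["right"] = wrap(b.nodes.right),
      _["pred"] = wrap(b.nodes.pred));
  }
  return List::create(_["importance"] = imp, _["trees"] = trees,
                      _["n_classes"] = n_classes);
}

// [[Rcpp::export(name = ".forest_predict")]]
IntegerVector forest_predict(List forest, NumericMatrix X) {
  List trees = forest["trees"];
  int n_classes = as<int>(forest["n_classes"]);
  int n = X.nrow(), n_trees = trees.size();
  IntegerVector out(n);
  std::vector<int> votes(n_classes);
  for (int i = 0; i < n; ++i) {
    std::fill(votes.begin(), votes.end(), 0);
    for (int t = 0; t < n_trees; ++t)
      votes[tree_predict_one(trees[t], X, i)]++;
    int best = 0;
    for (int c = 1; c < n_classes; ++c) if (votes[c] > votes[best]) best = c;
    out[i] = best;
  }
  return out;
}
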