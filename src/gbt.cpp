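// Gradient-boosted decision trees with second-order (Newton) leaf values,
// logistic loss, per-sample weights, and learned default directions for
// missing values. Deterministic: all randomness (folds, bootstraps) lives
// on the R side. Split search uses one global pre-sort per feature so each
// node costs O(n * p) regardless of node size.
#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Node {
  int feature;       // -1 for leaf
  double threshold;
  int default_left;  // 1: missing goes left
  int left, right;   // child node ids, -1 for leaf
  double value;      // leaf value (already scaled by learning rate)
  double gain;       // split gain, 0 for leaf
};

struct Builder {
  const NumericMatrix& X;
  const std::vector<std::vector<int> >& order; // per-feature indices, sorted by value, NA excluded
  const std::vector<double>& g;
  const std::vector<double>& h;
  double lambda, min_child_weight, eta;
  int max_depth;
  std::vector<Node> nodes;
  std::vector<char> in_node; // scratch membership mask

  Builder(const NumericMatrix& X_,
          const std::vector<std::vector<int> >& order_,
          const std::vector<double>& g_, const std::vector<double>& h_,
          double lambda_, double mcw_, double eta_, int max_depth_)
    : X(X_), order(order_), g(g_), h(h_), lambda(lambda_),
      min_child_weight(mcw_), eta(eta_), max_depth(max_depth_),
      in_node(X_.nrow(), 0) {}

  double leaf_value(double G, double H) const {
    return -eta * G / (H + lambda);
  }

  int build(std::vector<int>& idx, int depth) {
    double Gtot = 0.0, Htot = 0.0;
    for (size_t k = 0; k < idx.size(); ++k) { Gtot += g[idx[k]]; Htot += h[idx[k]]; }

    int id = (int) nodes.size();
    nodes.push_back(Node());
    Node& placeholder = nodes[id];
    placeholder.feature = -1; placeholder.threshold = 0.0;
    placeholder.default_left = 1; placeholder.left = -1; placeholder.right = -1;
    placeholder.value = leaf_value(Gtot, Htot); placeholder.gain = 0.0;

    if (depth >= max_depth || Htot < 2.0 * min_child_weight || idx.size() < 2)
      return id;

    const int p = X.ncol();
    double best_gain = 1e-12;
    int best_feat = -1, best_default_left = 1;
    double best_thr = 0.0;
    double parent_obj = (Gtot * Gtot) / (Htot + lambda);

    for (size_t k = 0; k < idx.size(); ++k) in_node[idx[k]] = 1;

    for (int j = 0; j < p; ++j) {
      // members of this node with non-missing feature j, in sorted order
      double Gmiss = Gtot, Hmiss = Htot; // start from totals, subtract observed
      double Gobs = 0.0, Hobs = 0.0;
      const std::vector<int>& ord = order[j];
      // first pass: observed totals
      std::vector<int> mem;
      mem.reserve(idx.size());
      for (size_t k = 0; k < ord.size(); ++k) {
        int i = ord[k];
        if (in_node[i]) {
          mem.push_back(i);
          Gobs += g[i]; Hobs += h[i];
        }
      }
      if (mem.size() < 2) continue;
      Gmiss -= Gobs; Hmiss -= Hobs;

      double GL = 0.0, HL = 0.0;
      for (size_t k = 0; k + 1 < mem.size(); ++k) {
        int i = mem[k];
        GL += g[i]; HL += h[i];
        double x_here = X(i, j), x_next = X(mem[k + 1], j);
        if (x_next <= x_here) continue; // not a boundary between distinct values
        double GR = Gobs - GL, HR = Hobs - HL;
        // missing right
        {
          double hl = HL, hr = HR + Hmiss;
          if (hl >= min_child_weight && hr >= min_child_weight) {
            double gl = GL, gr = GR + Gmiss;
            double gain = (gl * gl) / (hl + lambda) + (gr * gr) / (hr + lambda) - parent_obj;
            if (gain > best_gain) {
              best_gain = gain; best_feat = j;
              best_thr = 0.5 * (x_here + x_next);
              best_default_left = 0;
            }
          }
        }
        // missing left
        {
          double hl = HL + Hmiss, hr = HR;
          if (hl >= min_child_weight && hr >= min_child_weight) {
            double gl = GL + Gmiss, gr = GR;
            double gain = (gl * gl) / (hl + lambda) + (gr * gr) / (hr + lambda) - parent_obj;
            if (gain > best_gain) {
              best_gain = gain; best_feat = j;
              best_thr = 0.5 * (x_here + x_next);
              best_default_left = 1;
            }
          }
        }
      }
    }

    for (size_t k = 0; k < idx.size(); ++k) in_node[idx[k]] = 0;

    if (best_feat < 0) return id; // no useful split: stay a leaf

    std::vector<int> left_idx, right_idx;
    left_idx.reserve(idx.size()); right_idx.reserve(idx.size());
    for (size_t k = 0; k < idx.size(); ++k) {
      int i = idx[k];
      double x = X(i, best_feat);
      bool go_left = ISNAN(x) ? (best_default_left == 1) : (x < best_thr);
      if (go_left) left_idx.push_back(i); else right_idx.push_back(i);
    }
    if (left_idx.empty() || right_idx.empty()) return id; // numerical guard

    nodes[id].feature = best_feat;
    nodes[id].threshold = best_thr;
    nodes[id].default_left = best_default_left;
    nodes[id].gain = best_gain * 0.5;
    int lid = build(left_idx, depth + 1);
    int rid = build(right_idx, depth + 1);
    nodes[id].left = lid;
    nodes[id].right = rid;
    return id;
  }
};

double tree_score(const std::vector<Node>& nodes, const NumericMatrix& X, int i) {
  int cur = 0;
  while (nodes[cur].feature >= 0) {
    double x = X(i, nodes[cur].feature);
    bool go_left = ISNAN(x) ? (nodes[cur].default_left == 1)
                            : (x < nodes[cur].threshold);
    cur = go_left ? nodes[cur].left : nodes[cur].right;
  }
  return nodes[cur].value;
}

List pack_tree(const std::vector<Node>& nodes) {
  int m = (int) nodes.size();
  IntegerVector feature(m), default_left(m), left(m), right(m);
  NumericVector threshold(m), value(m), gain(m);
  for (int k = 0; k < m; ++k) {
    feature[k] = nodes[k].feature;
    threshold[k] = nodes[k].threshold;
    default_left[k] = nodes[k].default_left;
    left[k] = nodes[k].left;
    right[k] = nodes[k].right;
    value[k] = nodes[k].value;
    gain[k] = nodes[k].gain;
  }
  return List::create(_["feature"] = feature, _["threshold"] = threshold,
                      _["default_left"] = default_left, _["left"] = left,
                      _["right"] = right, _["value"] = value, _["gain"] = gain);
}

std::vector<Node> unpack_tree(List tr) {
  IntegerVector feature = tr["feature"], default_left = tr["default_left"],
                left = tr["left"], right = tr["right"];
  NumericVector threshold = tr["threshold"], value = tr["value"], gain = tr["gain"];
  int m = feature.size();
  std::vector<Node> nodes(m);
  for (int k = 0; k < m; ++k) {
    nodes[k].feature = feature[k]; nodes[k].threshold = threshold[k];
    nodes[k].default_left = default_left[k]; nodes[k].left = left[k];
    nodes[k].right = right[k]; nodes[k].value = value[k]; nodes[k].gain = gain[k];
  }
  return nodes;
}

} // namespace

// [[Rcpp::export]]
List gbt_fit_cpp(NumericMatrix X, NumericVector y, NumericVector w,
                 int n_trees, int max_depth, double eta, double lambda,
                 double min_child_weight, double base_margin) {
  const int n = X.nrow(), p = X.ncol();

  // global per-feature sort orders (stable; NA excluded)
  std::vector<std::vector<int> > order(p);
  for (int j = 0; j < p; ++j) {
    std::vector<int> idx;
    idx.reserve(n);
    for (int i = 0; i < n; ++i) if (!ISNAN(X(i, j))) idx.push_back(i);
    const NumericMatrix& Xr = X;
    std::stable_sort(idx.begin(), idx.end(),
                     [&Xr, j](int a, int b) { return Xr(a, j) < Xr(b, j); });
    order[j] = idx;
  }

  std::vector<double> F(n, base_margin), g(n), h(n);
  NumericVector feat_gain(p);
  List trees(n_trees);
  std::vector<int> all_idx(n);
  for (int i = 0; i < n; ++i) all_idx[i] = i;

  for (int t = 0; t < n_trees; ++t) {
    for (int i = 0; i < n; ++i) {
      double pi = 1.0 / (1.0 + std::exp(-F[i]));
      g[i] = w[i] * (pi - y[i]);
      h[i] = w[i] * pi * (1.0 - pi);
      if (h[i] < 1e-16) h[i] = 1e-16;
    }
    Builder b(X, order, g, h, lambda, min_child_weight, eta, max_depth);
    std::vector<int> idx = all_idx;
    b.build(idx, 0);
    for (int i = 0; i < n; ++i) F[i] += tree_score(b.nodes, X, i);
    for (size_t k = 0; k < b.nodes.size(); ++k)
      if (b.nodes[k].feature >= 0) feat_gain[b.nodes[k].feature] += b.nodes[k].gain;
    trees[t] = pack_tree(b.nodes);
  }

  return List::create(_["trees"] = trees, _["base_margin"] = base_margin,
                      _["feature_gain"] = feat_gain);
}

// [[Rcpp::export]]
NumericVector gbt_margin_cpp(List trees, NumericMatrix X, double base_margin) {
  const int n = X.nrow(), T = trees.size();
  NumericVector out(n, base_margin);
  for (int t = 0; t < T; ++t) {
    std::vector<Node> nodes = unpack_tree(trees[t]);
    for (int i = 0; i < n; ++i) out[i] += tree_score(nodes, X, i);
  }
  return out;
}
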