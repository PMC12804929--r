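// Histogram-based gradient boosting for squared loss with disjoint-group
// feature-interaction constraints: once a tree path has split on a feature
// from group g, descendants may only split on features from group g. With a
// single group this reduces to unconstrained boosting.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

struct Tree {
  std::vector<int> feature;   // -1 for leaf
  std::vector<int> threshold; // bin index: go left if bin <= threshold
  std::vector<int> left, right;
  std::vector<double> value;  // leaf value
};

struct BuildCtx {
  const IntegerMatrix& X;     // n x p, 0-based bin indices
  const std::vector<double>& grad; // residuals to fit
  const IntegerVector& groups;
  int n_bins, max_depth, min_child;
  double lambda;
};

static int build_node(BuildCtx& c, Tree& t, std::vector<int>& rows,
                      int depth, int grp) {
  int node = (int)t.feature.size();
  double sum = 0.0;
  for (int r : rows) sum += c.grad[r];
  double n_node = (double)rows.size();
  t.feature.push_back(-1);
  t.threshold.push_back(-1);
  t.left.push_back(-1);
  t.right.push_back(-1);
  t.value.push_back(sum / (n_node + c.lambda));
  if (depth >= c.max_depth || (int)rows.size() < 2 * c.min_child)
    return node;

  double base = sum * sum / (n_node + c.lambda);
  double best_gain = 1e-12;
  int best_f = -1, best_t = -1;
  std::vector<double> hsum(c.n_bins);
  std::vector<int> hcnt(c.n_bins);
  int p = c.X.ncol();
  for (int f = 0; f < p; ++f) {
    if (grp >= 0 && c.groups[f] != grp) continue;
    std::fill(hsum.begin(), hsum.end(), 0.0);
    std::fill(hcnt.begin(), hcnt.end(), 0);
    for (int r : rows) {
      int b = c.X(r, f);
      hsum[b] += c.grad[r];
      hcnt[b] += 1;
    }
    double ls = 0.0; int lc = 0;
    for (int b = 0; b < c.n_bins - 1; ++b) {
      ls += hsum[b]; lc += hcnt[b];
      int rc = (int)rows.size() - lc;
      if (lc < c.min_child || rc < c.min_child) continue;
      double rs = sum - ls;
      double gain = ls * ls / (lc + c.lambda) + rs * rs / (rc + c.lambda)
                    - base;
      if (gain > best_gain) { best_gain = gain; best_f = f; best_t = b; }
    }
  }
  if (best_f < 0) return node;

  std::vector<int> lrows, rrows;
  lrows.reserve(rows.size());
  for (int r : rows) {
    if (c.X(r, best_f) <= best_t) lrows.push_back(r);
    else rrows.push_back(r);
  }
  int child_grp = (grp >= 0) ? grp : c.groups[best_f];
  t.feature[node] = best_f;
  t.threshold[node] = best_t;
  t.left[node] = build_node(c, t, lrows, depth + 1, child_grp);
  t.right[node] = build_node(c, t, rrows, depth + 1, child_grp);
  return node;
}

static double tree_predict_row(const Tree& t, const IntegerMatrix& X, int r) {
  int node = 0;
  while (t.feature[node] >= 0) {
    node = (X(r, t.feature[node]) <= t.threshold[node]) ? t.left[node]
                                                        : t.right[node];
  }
  return t.value[node];
}

static List tree_to_list(const Tree& t) {
  return List::create(_["feature"] = wrap(t.feature),
                      _["threshold"] = wrap(t.threshold),
                      _["left"] = wrap(t.left),
                      _["right"] = wrap(t.right),
                      _["value"] = wrap(t.value));
}

static Tree tree_from_list(const List& l) {
  Tree t;
  t.feature = as<std::vector<int>>(l["feature"]);
  t.threshold = as<std::vector<int>>(l["threshold"]);
  t.left = as<std::vector<int>>(l["left"]);
  t.right = as<std::vector<int>>(l["right"]);
  t.value = as<std::vector<double>>(l["value"]);
  return t;
}

// [[Rcpp::export]]
List boost_fit_cpp(IntegerMatrix X, NumericVector y, IntegerMatrix Xval,
                   NumericVector yval, IntegerVector groups, int n_bins,
                   double eta, int max_depth, int n_rounds, double lambda,
                   int min_child, int patience) {
  int n = X.nrow(), nv = Xval.nrow();
  double base = mean(y);
  std::vector<double> pred(n, base), pred_val(nv, base);
  std::vector<double> grad(n);
  List trees(n_rounds);
  double best_loss = R_PosInf;
  int best_iter = 0, bad = 0, done = 0;
  for (int it = 0; it < n_rounds; ++it) {
    for (int i = 0; i < n; ++i) grad[i] = y[i] - pred[i];
    Tree t;
    BuildCtx c{X, grad, groups, n_bins, max_depth, min_child, lambda};
    std::vector<int> rows(n);
    for (int i = 0; i < n; ++i) rows[i] = i;
    build_node(c, t, rows, 0, -1);
    for (int i = 0; i < n; ++i) pred[i] += eta * tree_predict_row(t, X, i);
    double vloss = 0.0;
    for (int i = 0; i < nv; ++i) {
      pred_val[i] += eta * tree_predict_row(t, Xval, i);
      double d = yval[i] - pred_val[i];
      vloss += d * d;
    }
    vloss /= std::max(nv, 1);
    trees[it] = tree_to_list(t);
    done = it + 1;
    if (nv > 0) {
      if (vloss < best_loss - 1e-12) { best_loss = vloss; best_iter = done; bad = 0; }
      else if (++bad >= patience) break;
    } else {
      best_iter = done;
    }
  }
  List kept(done);
  for (int i = 0; i < done; ++i) kept[i] = trees[i];
  return List::create(_["base"] = base, _["trees"] = kept,
                      _["best_iter"] = best_iter,
                      _["val_loss"] = (nv > 0) ? best_loss : NA_REAL);
}

// [[Rcpp::export]]
NumericVector boost_predict_cpp(List model, IntegerMatrix X, int n_trees) {
  double base = as<double>(model["base"]);
  List trees = model["trees"];
  int use = std::min<int>(n_trees, trees.size());
  double eta = as<double>(model["eta"]);
  NumericVector out(X.nrow(), base);
  for (int k = 0; k < use; ++k) {
    Tree t = tree_from_list(trees[k]);
    for (int i = 0; i < X.nrow(); ++i)
      out[i] += eta * tree_predict_row(t, X, i);
  }
  return out;
}
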