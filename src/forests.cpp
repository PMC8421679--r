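// Tree-ensemble learners backing the cascade deep forest.
//
// Three forest flavours are provided:
//   * completely-random trees: every node splits on one uniformly chosen
//     feature at a uniform threshold, grown until leaves are class-pure;
//   * extremely-randomized trees: mtry candidate features, one random
//     threshold each, best Gini gain wins;
//   * gradient-boosted trees: depth-limited randomized regression trees fit
//     to logistic-loss gradients with Newton leaf values.
//
// All randomness flows through a private xorshift-free mt19937_64 stream
// seeded from R so results are bit-reproducible across platforms (the
// std::uniform_* distributions are implementation-defined and never used).
// Fitted trees are returned as plain R lists of flat vectors so models can
// be serialized without external pointers.

#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

static inline double runif01(std::mt19937_64 &rng) {
  // 53 random mantissa bits -> uniform on [0, 1)
  return (rng() >> 11) * (1.0 / 9007199254740992.0);
}

static inline int randbelow(std::mt19937_64 &rng, int n) {
  int v = (int)(runif01(rng) * n);
  return v >= n ? n - 1 : v;
}

struct TreeNodes {
  std::vector<int> feature;      // -1 for leaf
  std::vector<double> threshold; // x <= thr goes left
  std::vector<int> left, right;
  std::vector<double> value;     // leaves: K class probs (classif) or 1 value (regr)
  int k;                         // values per node

  int add_node() {
    feature.push_back(-1);
    threshold.push_back(0.0);
    left.push_back(-1);
    right.push_back(-1);
    for (int j = 0; j < k; ++j) value.push_back(0.0);
    return (int)feature.size() - 1;
  }

  List as_list() const {
    return List::create(
      _["feature"] = IntegerVector(feature.begin(), feature.end()),
      _["threshold"] = NumericVector(threshold.begin(), threshold.end()),
      _["left"] = IntegerVector(left.begin(), left.end()),
      _["right"] = IntegerVector(right.begin(), right.end()),
      _["value"] = NumericVector(value.begin(), value.end()),
      _["k"] = k);
  }
};

// node feature range over a row subset; returns false when constant
static bool feat_range(const NumericMatrix &X, const std::vector<int> &rows,
                       int j, double &lo, double &hi) {
  lo = R_PosInf;
  hi = R_NegInf;
  for (int r : rows) {
    double v = X(r, j);
    if (v < lo) lo = v;
    if (v > hi) hi = v;
  }
  return hi > lo;
}

static double gini(const std::vector<int> &counts, int n) {
  if (n == 0) return 0.0;
  double g = 1.0;
  for (int c : counts) {
    double p = (double)c / n;
    g -= p * p;
  }
  return g;
}

// ---------------------------------------------------------------------------
// classification trees (completely-random / extra-trees)
// ---------------------------------------------------------------------------

struct ClsCtx {
  const NumericMatrix &X;
  const IntegerVector &y; // 0..K-1
  int K;
  int mtry;          // 0 => completely-random (one feature, no criterion)
  int min_node;
  std::mt19937_64 rng;
};

static void cls_leaf(TreeNodes &T, int node, ClsCtx &ctx,
                     const std::vector<int> &rows) {
  std::vector<int> cnt(ctx.K, 0);
  for (int r : rows) cnt[ctx.y[r]]++;
  for (int j = 0; j < ctx.K; ++j)
    T.value[(size_t)node * ctx.K + j] = (double)cnt[j] / rows.size();
}

static void cls_grow(TreeNodes &T, int node, ClsCtx &ctx,
                     std::vector<int> &rows, int depth) {
  int n = (int)rows.size();
  std::vector<int> cnt(ctx.K, 0);
  for (int r : rows) cnt[ctx.y[r]]++;
  bool pure = false;
  for (int c : cnt) if (c == n) pure = true;
  if (pure || n < 2 * ctx.min_node || n < 2) {
    cls_leaf(T, node, ctx, rows);
    return;
  }

  int p = ctx.X.ncol();
  int best_f = -1;
  double best_thr = 0.0, best_score = R_PosInf;

  if (ctx.mtry <= 0) {
    // completely-random: scan features in random order, take the first
    // non-constant one with a uniform threshold -- no goodness criterion
    std::vector<int> order(p);
    for (int j = 0; j < p; ++j) order[j] = j;
    for (int j = p - 1; j > 0; --j)
      std::swap(order[j], order[randbelow(ctx.rng, j + 1)]);
    for (int j = 0; j < p; ++j) {
      double lo, hi;
      if (feat_range(ctx.X, rows, order[j], lo, hi)) {
        best_f = order[j];
        best_thr = lo + runif01(ctx.rng) * (hi - lo);
        break;
      }
    }
  } else {
    // extra-trees: mtry random candidates, random threshold each, Gini
    int tried = 0, seen = 0;
    std::vector<int> cl(ctx.K), cr(ctx.K);
    while (seen < ctx.mtry && tried < 4 * p) {
      ++tried;
      int f = randbelow(ctx.rng, p);
      double lo, hi;
      if (!feat_range(ctx.X, rows, f, lo, hi)) continue;
      ++seen;
      double thr = lo + runif01(ctx.rng) * (hi - lo);
      std::fill(cl.begin(), cl.end(), 0);
      std::fill(cr.begin(), cr.end(), 0);
      int nl = 0;
      for (int r : rows) {
        if (ctx.X(r, f) <= thr) { cl[ctx.y[r]]++; nl++; }
        else cr[ctx.y[r]]++;
      }
      int nr = n - nl;
      if (nl == 0 || nr == 0) continue;
      double score = (nl * gini(cl, nl) + nr * gini(cr, nr)) / n;
      if (score < best_score) {
        best_score = score;
        best_f = f;
        best_thr = thr;
      }
    }
  }

  if (best_f < 0) { // all candidate features constant
    cls_leaf(T, node, ctx, rows);
    return;
  }

  std::vector<int> lrows, rrows;
  for (int r : rows)
    (ctx.X(r, best_f) <= best_thr ? lrows : rrows).push_back(r);
  if (lrows.empty() || rrows.empty()) {
    cls_leaf(T, node, ctx, rows);
    return;
  }

  T.feature[node] = best_f;
  T.threshold[node] = best_thr;
  int L = T.add_node(), R = T.add_node();
  T.left[node] = L;
  T.right[node] = R;
  rows.clear();
  rows.shrink_to_fit();
  cls_grow(T, L, ctx, lrows, depth + 1);
  cls_grow(T, R, ctx, rrows, depth + 1);
}

// [[Rcpp::export(name = ".cpp_fit_cls_forest")]]
List cpp_fit_cls_forest(NumericMatrix X, IntegerVector y, int n_classes,
                        int n_trees, int mtry, int min_node, double seed) {
  ClsCtx ctx{X, y, n_classes, mtry, min_node,
             std::mt19937_64((uint64_t)seed)};
  List trees(n_trees);
  int n = X.nrow();
  for (int t = 0; t < n_trees; ++t) {
    TreeNodes T;
    T.k = n_classes;
    T.add_node();
    std::vector<int> rows(n);
    for (int r = 0; r < n; ++r) rows[r] = r;
    cls_grow(T, 0, ctx, rows, 0);
    trees[t] = T.as_list();
  }
  return trees;
}

static int descend(const IntegerVector &feature, const NumericVector &threshold,
                   const IntegerVector &left, const IntegerVector &right,
                   const NumericMatrix &X, int row) {
  int node = 0;
  while (feature[node] >= 0)
    node = X(row, feature[node]) <= threshold[node] ? left[node] : right[node];
  return node;
}

// [[Rcpp::export(name = ".cpp_predict_cls_forest")]]
NumericMatrix cpp_predict_cls_forest(List trees, NumericMatrix X,
                                     int n_classes) {
  int n = X.nrow(), nt = trees.size();
  NumericMatrix out(n, n_classes);
  for (int t = 0; t < nt; ++t) {
    List tr = trees[t];
    IntegerVector feature = tr["feature"], left = tr["left"],
                  right = tr["right"];
    NumericVector threshold = tr["threshold"], value = tr["value"];
    for (int i = 0; i < n; ++i) {
      int leaf = descend(feature, threshold, left, right, X, i);
      for (int j = 0; j < n_classes; ++j)
        out(i, j) += value[(size_t)leaf * n_classes + j];
    }
  }
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n_classes; ++j) out(i, j) /= nt;
  return out;
}

// ---------------------------------------------------------------------------
// gradient boosting (binary logistic, Newton leaves, randomized splits)
// ---------------------------------------------------------------------------

struct RegCtx {
  const NumericMatrix &X;
  const std::vector<double> &g; // gradient  (y - p)
  const std::vector<double> &h; // hessian   p(1-p)
  int mtry, max_depth, min_node;
  double lambda;
  std::mt19937_64 rng;
};

static void reg_leaf(TreeNodes &T, int node, RegCtx &ctx,
                     const std::vector<int> &rows) {
  double sg = 0.0, sh = 0.0;
  for (int r : rows) { sg += ctx.g[r]; sh += ctx.h[r]; }
  T.value[node] = sg / (sh + ctx.lambda);
}

static void reg_grow(TreeNodes &T, int node, RegCtx &ctx,
                     std::vector<int> &rows, int depth) {
  int n = (int)rows.size();
  if (depth >= ctx.max_depth || n < 2 * ctx.min_node) {
    reg_leaf(T, node, ctx, rows);
    return;
  }
  int p = ctx.X.ncol();
  int best_f = -1;
  double best_thr = 0.0, best_gain = 0.0;
  double SG = 0.0, SH = 0.0;
  for (int r : rows) { SG += ctx.g[r]; SH += ctx.h[r]; }
  double parent = SG * SG / (SH + ctx.lambda);

  int tried = 0, seen = 0;
  while (seen < ctx.mtry && tried < 4 * p) {
    ++tried;
    int f = randbelow(ctx.rng, p);
    double lo, hi;
    if (!feat_range(ctx.X, rows, f, lo, hi)) continue;
    ++seen;
    double thr = lo + runif01(ctx.rng) * (hi - lo);
    double gl = 0.0, hl = 0.0;
    int nl = 0;
    for (int r : rows)
      if (ctx.X(r, f) <= thr) { gl += ctx.g[r]; hl += ctx.h[r]; nl++; }
    int nr = n - nl;
    if (nl < ctx.min_node || nr < ctx.min_node) continue;
    double gr = SG - gl, hr = SH - hl;
    double gain = gl * gl / (hl + ctx.lambda) + gr * gr / (hr + ctx.lambda)
                  - parent;
    if (gain > best_gain) {
      best_gain = gain;
      best_f = f;
      best_thr = thr;
    }
  }

  if (best_f < 0) {
    reg_leaf(T, node, ctx, rows);
    return;
  }
  std::vector<int> lrows, rrows;
  for (int r : rows)
    (ctx.X(r, best_f) <= best_thr ? lrows : rrows).push_back(r);
  T.feature[node] = best_f;
  T.threshold[node] = best_thr;
  int L = T.add_node(), R = T.add_node();
  T.left[node] = L;
  T.right[node] = R;
  rows.clear();
  rows.shrink_to_fit();
  reg_grow(T, L, ctx, lrows, depth + 1);
  reg_grow(T, R, ctx, rrows, depth + 1);
}

// [[Rcpp::export(name = ".cpp_fit_gbm")]]
List cpp_fit_gbm(NumericMatrix X, IntegerVector y, int n_rounds,
                 double shrinkage, int max_depth, int mtry, int min_node,
                 double lambda, double seed) {
  int n = X.nrow();
  double pos = 0.0;
  for (int i = 0; i < n; ++i) pos += y[i];
  double pbar = std::min(std::max(pos / n, 1e-6), 1.0 - 1e-6);
  double F0 = std::log(pbar / (1.0 - pbar));

  std::vector<double> F(n, F0), g(n), h(n);
  std::mt19937_64 rng((uint64_t)seed);
  List trees(n_rounds);

  for (int t = 0; t < n_rounds; ++t) {
    for (int i = 0; i < n; ++i) {
      double pi = 1.0 / (1.0 + std::exp(-F[i]));
      g[i] = y[i] - pi;
      h[i] = std::max(pi * (1.0 - pi), 1e-12);
    }
    RegCtx ctx{X, g, h, mtry, max_depth, min_node, lambda, rng};
    TreeNodes T;
    T.k = 1;
    T.add_node();
    std::vector<int> rows(n);
    for (int r = 0; r < n; ++r) rows[r] = r;
    reg_grow(T, 0, ctx, rows, 0);
    rng = ctx.rng; // keep the stream advancing across rounds
    // update scores
    List tl = T.as_list();
    IntegerVector feature = tl["feature"], left = tl["left"],
                  right = tl["right"];
    NumericVector threshold = tl["threshold"], value = tl["value"];
    for (int i = 0; i < n; ++i) {
      int leaf = descend(feature, threshold, left, right, X, i);
      F[i] += shrinkage * value[leaf];
    }
    trees[t] = tl;
  }
  return List::create(_["intercept"] = F0, _["shrinkage"] = shrinkage,
                      _["trees"] = trees);
}

// [[Rcpp::export(name = ".cpp_predict_gbm")]]
NumericVector cpp_predict_gbm(List model, NumericMatrix X) {
  double F0 = as<double>(model["intercept"]);
  double shrink = as<double>(model["shrinkage"]);
  List trees = model["trees"];
  int n = X.nrow(), nt = trees.size();
  NumericVector F(n, F0);
  for (int t = 0; t < nt; ++t) {
    List tr = trees[t];
    IntegerVector feature = tr["feature"], left = tr["left"],
                  right = tr["right"];
    NumericVector threshold = tr["threshold"], value = tr["value"];
    for (int i = 0; i < n; ++i) {
      int leaf = descend(feature, threshold, left, right, X, i);
      F[i] += shrink * value[leaf];
    }
  }
  NumericVector p(n);
  for (int i = 0; i < n; ++i) p[i] = 1.0 / (1.0 + std::exp(-F[i]));
  return p;
}

// ---------------------------------------------------------------------------
// GIP kernel inner loop (the n^2 * p distance evaluation)
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".cpp_sq_dist")]]
NumericMatrix cpp_sq_dist(NumericMatrix P) {
  int n = P.nrow(), p = P.ncol();
  NumericMatrix D(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double d = 0.0;
      for (int c = 0; c < p; ++c) {
        double v = P(i, c) - P(j, c);
        d += v * v;
      }
      D(i, j) = d;
      D(j, i) = d;
    }
  }
  return D;
}
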