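// Conditional inference forest engine.
//
// Variable selection at each node uses the standardized linear permutation
// statistic T = sum_i x_i (y_i - ybar) with exact conditional moments
// (E[T] = 0, Var[T] = Sxx * Syy / (n - 1)) and a two-sided asymptotic
// normal p-value.  Splits maximize the standardized two-sample
// mean-difference statistic over admissible cutpoints.
//
// All randomness flows through a splitmix64-based counter RNG so that
// fits are bit-reproducible across platforms for a given integer seed.
// Streams are split hierarchically (forest seed -> tree seed -> per-node
// seeds, children keyed 1/2), so pruning one branch never perturbs the
// candidate draws of another.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

static inline uint64_t mix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

static inline uint64_t derive(uint64_t state, uint64_t key) {
  return mix64(state ^ (key * 0xD1342543DE82EF95ULL + 0x2545F4914F6CDD1DULL));
}

struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(mix64(seed ^ 0x5BF0363529C3A1E6ULL)) {}
  uint64_t next() { s = mix64(s); return s; }
  // uniform in [0, 1)
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  // uniform integer in [0, n), n >= 1
  int below(int n) {
    int k = (int)(unif() * n);
    return (k >= n) ? n - 1 : k;
  }
  // first m entries of a Fisher-Yates shuffle of 0..n-1
  void sample_idx(int n, int m, std::vector<int>& out) {
    std::vector<int> pool(n);
    for (int i = 0; i < n; ++i) pool[i] = i;
    out.resize(m);
    for (int i = 0; i < m; ++i) {
      int j = i + below(n - i);
      std::swap(pool[i], pool[j]);
      out[i] = pool[i];
    }
  }
  void shuffle(std::vector<int>& v) {
    int n = (int)v.size();
    for (int i = n - 1; i > 0; --i) {
      int j = below(i + 1);
      std::swap(v[i], v[j]);
    }
  }
};

static const double VAR_TOL = 1e-12;

// standardized linear association statistic and asymptotic two-sided p
static void assoc_stat(const double* x, const double* y, int n,
                       double& stat, double& pval) {
  double xbar = 0.0, ybar = 0.0;
  for (int i = 0; i < n; ++i) { xbar += x[i]; ybar += y[i]; }
  xbar /= n; ybar /= n;
  double T = 0.0, sxx = 0.0, syy = 0.0;
  for (int i = 0; i < n; ++i) {
    double dx = x[i] - xbar, dy = y[i] - ybar;
    T += dx * dy;
    sxx += dx * dx;
    syy += dy * dy;
  }
  if (sxx <= VAR_TOL || syy <= VAR_TOL) { stat = 0.0; pval = 1.0; return; }
  double v = sxx * syy / (double)(n - 1);
  stat = std::fabs(T) / std::sqrt(v);
  pval = 2.0 * R::pnorm(-stat, 0.0, 1.0, 1, 0);
  if (pval > 1.0) pval = 1.0;
}

// best binary split of y by x <= t, standardized two-sample statistic
static bool best_split(const std::vector<double>& x,
                       const std::vector<double>& y,
                       int min_bucket,
                       double& threshold, double& statistic) {
  int n = (int)x.size();
  if (n < 2 * min_bucket) return false;
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return x[a] < x[b]; });
  double ybar = 0.0;
  for (int i = 0; i < n; ++i) ybar += y[i];
  ybar /= n;
  double syy = 0.0;
  for (int i = 0; i < n; ++i) { double d = y[i] - ybar; syy += d * d; }
  if (syy <= VAR_TOL) return false;
  bool found = false;
  double best_z = -1.0, prefix = 0.0;
  for (int i = 0; i < n - 1; ++i) {
    prefix += y[ord[i]] - ybar;
    int nl = i + 1, nr = n - nl;
    if (x[ord[i]] >= x[ord[i + 1]]) continue;  // not a distinct-value gap
    if (nl < min_bucket || nr < min_bucket) continue;
    double v = ((double)nl * nr / n) * syy / (double)(n - 1);
    double z = std::fabs(prefix) / std::sqrt(v);
    if (z > best_z + 1e-12) {  // strict: ties keep the smallest threshold
      best_z = z;
      threshold = 0.5 * (x[ord[i]] + x[ord[i + 1]]);
      found = true;
    }
  }
  statistic = best_z;
  return found;
}

struct TreeParams {
  int mtry, min_split, min_bucket, max_depth;
  double alpha;
};

struct Tree {
  std::vector<int> var;       // 0-based split column, -1 = terminal
  std::vector<double> thr;
  std::vector<int> left, right;  // node indices, -1 for terminal
  std::vector<double> pred;   // node mean of training responses
  std::vector<int> nn;        // node size
  std::vector<char> used;     // per-column: split on anywhere in tree

  int add_node(double mean, int n) {
    var.push_back(-1); thr.push_back(NA_REAL);
    left.push_back(-1); right.push_back(-1);
    pred.push_back(mean); nn.push_back(n);
    return (int)var.size() - 1;
  }

  double predict_one(const double* xrow) const {
    int node = 0;
    while (var[node] >= 0)
      node = (xrow[var[node]] <= thr[node]) ? left[node] : right[node];
    return pred[node];
  }
};

struct Data {
  const double* X;  // column-major n x p
  const double* y;
  int n, p;
  double xval(int i, int j) const { return X[(size_t)j * n + i]; }
};

static int fit_node(const Data& d, Tree& tree, const TreeParams& par,
                    std::vector<int>& idx, int depth, uint64_t state) {
  int n = (int)idx.size();
  double mean = 0.0;
  for (int i : idx) mean += d.y[i];
  mean /= n;
  int node = tree.add_node(mean, n);
  if (n < par.min_split || depth >= par.max_depth) return node;

  double syy = 0.0;
  for (int i : idx) { double dv = d.y[i] - mean; syy += dv * dv; }
  if (syy <= VAR_TOL) return node;

  // draw mtry candidate columns
  int m = std::min(par.mtry, d.p);
  Rng rng(derive(state, 3));
  std::vector<int> cand;
  rng.sample_idx(d.p, m, cand);
  std::sort(cand.begin(), cand.end());  // index-order ties are deterministic

  std::vector<double> xbuf(n), ybuf(n);
  for (int i = 0; i < n; ++i) ybuf[i] = d.y[idx[i]];
  int chosen = -1;
  double pmin = 2.0;
  for (int j : cand) {
    for (int i = 0; i < n; ++i) xbuf[i] = d.xval(idx[i], j);
    double st, pv;
    assoc_stat(xbuf.data(), ybuf.data(), n, st, pv);
    if (pv < pmin - 1e-15) { pmin = pv; chosen = j; }
  }
  if (chosen < 0) return node;
  double p_adj = std::min(1.0, pmin * m);  // Bonferroni over candidates
  if (p_adj > par.alpha + 1e-12) return node;

  for (int i = 0; i < n; ++i) xbuf[i] = d.xval(idx[i], chosen);
  double threshold, stat;
  if (!best_split(xbuf, ybuf, par.min_bucket, threshold, stat)) return node;

  std::vector<int> li, ri;
  for (int i = 0; i < n; ++i) {
    if (xbuf[i] <= threshold) li.push_back(idx[i]); else ri.push_back(idx[i]);
  }
  tree.var[node] = chosen;
  tree.thr[node] = threshold;
  tree.used[chosen] = 1;
  int l = fit_node(d, tree, par, li, depth + 1, derive(state, 1));
  tree.left[node] = l;
  int r = fit_node(d, tree, par, ri, depth + 1, derive(state, 2));
  tree.right[node] = r;
  return node;
}

struct ForestFit {
  std::vector<Tree> trees;
  std::vector<std::vector<int> > inbag;   // sorted 0-based row indices
  std::vector<std::vector<char> > is_in;  // n flags per tree
};

static void fit_forest_core(const Data& d, int n_trees, const TreeParams& par,
                            double subsample_frac, uint64_t seed,
                            ForestFit& out) {
  int n = d.n;
  int k = (int)std::lround(subsample_frac * n);
  if (k < 1) k = 1;
  if (k > n) k = n;
  out.trees.resize(n_trees);
  out.inbag.resize(n_trees);
  out.is_in.assign(n_trees, std::vector<char>(n, 0));
  for (int t = 0; t < n_trees; ++t) {
    uint64_t ts = derive(seed, 1000 + (uint64_t)t);
    Rng rng(derive(ts, 7));
    std::vector<int> bag;
    rng.sample_idx(n, k, bag);
    std::sort(bag.begin(), bag.end());
    out.inbag[t] = bag;
    for (int i : bag) out.is_in[t][i] = 1;
    Tree& tr = out.trees[t];
    tr.used.assign(d.p, 0);
    std::vector<int> idx = bag;
    fit_node(d, tr, par, idx, 0, derive(ts, 11));
  }
}

// tree-level OOB MSE with one column's values replaced by a permutation
static double tree_oob_mse(const Data& d, const Tree& tr,
                           const std::vector<int>& oob,
                           int perm_col, const std::vector<double>* perm_vals) {
  double sse = 0.0;
  std::vector<double> row(d.p);
  for (size_t q = 0; q < oob.size(); ++q) {
    int i = oob[q];
    for (int j = 0; j < d.p; ++j) row[j] = d.xval(i, j);
    if (perm_col >= 0) row[perm_col] = (*perm_vals)[q];
    double e = d.y[i] - tr.predict_one(row.data());
    sse += e * e;
  }
  return sse / oob.size();
}

// per-tree MSE increases for the selected predictors: |sel| x n_trees
static void importance_core(const Data& d, const ForestFit& ff,
                            const std::vector<int>& sel, int n_perm,
                            uint64_t seed, std::vector<double>& out) {
  int T = (int)ff.trees.size(), ns = (int)sel.size();
  out.assign((size_t)ns * T, 0.0);
  for (int t = 0; t < T; ++t) {
    std::vector<int> oob;
    for (int i = 0; i < d.n; ++i) if (!ff.is_in[t][i]) oob.push_back(i);
    if (oob.empty()) continue;  // caller guards subsample_frac == 1
    double mse0 = tree_oob_mse(d, ff.trees[t], oob, -1, NULL);
    int m = (int)oob.size();
    std::vector<double> vals(m);
    std::vector<int> perm(m);
    for (int s = 0; s < ns; ++s) {
      int j = sel[s];
      if (!ff.trees[t].used[j]) continue;  // importance exactly 0
      double acc = 0.0;
      for (int r = 0; r < n_perm; ++r) {
        Rng rng(derive(seed, ((uint64_t)t << 40) ^ ((uint64_t)j << 20) ^ (uint64_t)r));
        for (int q = 0; q < m; ++q) perm[q] = q;
        rng.shuffle(perm);
        for (int q = 0; q < m; ++q) vals[q] = d.xval(oob[perm[q]], j);
        acc += tree_oob_mse(d, ff.trees[t], oob, j, &vals);
      }
      out[(size_t)s * T + t] = acc / n_perm - mse0;
    }
  }
}

static TreeParams make_params(int mtry, int min_split, int min_bucket,
                              double alpha, int max_depth) {
  TreeParams par;
  par.mtry = mtry; par.min_split = min_split; par.min_bucket = min_bucket;
  par.alpha = alpha; par.max_depth = max_depth;
  return par;
}

static List export_forest(const ForestFit& ff) {
  int T = (int)ff.trees.size();
  List trees(T), inbag(T);
  for (int t = 0; t < T; ++t) {
    const Tree& tr = ff.trees[t];
    int nn = (int)tr.var.size();
    IntegerVector var(nn), left(nn), right(nn), n_(nn);
    NumericVector thr(nn), pred(nn);
    for (int i = 0; i < nn; ++i) {
      var[i] = tr.var[i] >= 0 ? tr.var[i] + 1 : NA_INTEGER;
      thr[i] = tr.thr[i];
      left[i] = tr.left[i] >= 0 ? tr.left[i] + 1 : NA_INTEGER;
      right[i] = tr.right[i] >= 0 ? tr.right[i] + 1 : NA_INTEGER;
      pred[i] = tr.pred[i];
      n_[i] = tr.nn[i];
    }
    trees[t] = DataFrame::create(_["split_var"] = var, _["threshold"] = thr,
                                 _["left"] = left, _["right"] = right,
                                 _["prediction"] = pred, _["n"] = n_);
    IntegerVector bag((int)ff.inbag[t].size());
    for (int i = 0; i < bag.size(); ++i) bag[i] = ff.inbag[t][i] + 1;
    inbag[t] = bag;
  }
  return List::create(_["trees"] = trees, _["in_bag"] = inbag);
}

static void import_forest(List trees, List inbag, int n, int p, ForestFit& ff) {
  int T = trees.size();
  ff.trees.resize(T);
  ff.inbag.resize(T);
  ff.is_in.assign(T, std::vector<char>(n, 0));
  for (int t = 0; t < T; ++t) {
    DataFrame df = as<DataFrame>(trees[t]);
    IntegerVector var = df["split_var"], left = df["left"], right = df["right"],
                  n_ = df["n"];
    NumericVector thr = df["threshold"], pred = df["prediction"];
    Tree& tr = ff.trees[t];
    int nn = var.size();
    tr.var.resize(nn); tr.thr.resize(nn); tr.left.resize(nn);
    tr.right.resize(nn); tr.pred.resize(nn); tr.nn.resize(nn);
    tr.used.assign(p, 0);
    for (int i = 0; i < nn; ++i) {
      tr.var[i] = var[i] == NA_INTEGER ? -1 : var[i] - 1;
      tr.thr[i] = thr[i];
      tr.left[i] = left[i] == NA_INTEGER ? -1 : left[i] - 1;
      tr.right[i] = right[i] == NA_INTEGER ? -1 : right[i] - 1;
      tr.pred[i] = pred[i];
      tr.nn[i] = n_[i];
      if (tr.var[i] >= 0) tr.used[tr.var[i]] = 1;
    }
    IntegerVector bag = as<IntegerVector>(inbag[t]);
    ff.inbag[t].resize(bag.size());
    for (int i = 0; i < bag.size(); ++i) {
      ff.inbag[t][i] = bag[i] - 1;
      ff.is_in[t][bag[i] - 1] = 1;
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_assoc(NumericVector x, NumericVector y) {
  if (x.size() != y.size()) stop("x and y must have the same length");
  if (x.size() < 2) stop("need at least two observations");
  double st, pv;
  assoc_stat(x.begin(), y.begin(), x.size(), st, pv);
  return NumericVector::create(_["statistic"] = st, _["p_value"] = pv);
}

// [[Rcpp::export]]
List cpp_best_split(NumericVector x, NumericVector y, int min_bucket) {
  if (x.size() != y.size()) stop("x and y must have the same length");
  std::vector<double> xv(x.begin(), x.end()), yv(y.begin(), y.end());
  double thr = NA_REAL, st = NA_REAL;
  bool found = best_split(xv, yv, min_bucket, thr, st);
  return List::create(_["found"] = found, _["threshold"] = thr,
                      _["statistic"] = st);
}

// [[Rcpp::export]]
List cpp_fit_forest(NumericMatrix X, NumericVector y, int n_trees, int mtry,
                    int min_split, int min_bucket, double alpha, int max_depth,
                    double subsample_frac, double seed) {
  Data d; d.X = X.begin(); d.y = y.begin(); d.n = X.nrow(); d.p = X.ncol();
  TreeParams par = make_params(mtry, min_split, min_bucket, alpha, max_depth);
  ForestFit ff;
  fit_forest_core(d, n_trees, par, subsample_frac, (uint64_t)seed, ff);
  return export_forest(ff);
}

// [[Rcpp::export]]
NumericMatrix cpp_predict_trees(List trees, List inbag, NumericMatrix X, int p) {
  ForestFit ff;
  import_forest(trees, inbag, X.nrow(), p, ff);
  int T = (int)ff.trees.size(), n = X.nrow();
  NumericMatrix out(n, T);
  std::vector<double> row(p);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < p; ++j) row[j] = X(i, j);
    for (int t = 0; t < T; ++t) out(i, t) = ff.trees[t].predict_one(row.data());
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_importance(List trees, List inbag, NumericMatrix X,
                             NumericVector y, IntegerVector sel, int n_perm,
                             double seed) {
  Data d; d.X = X.begin(); d.y = y.begin(); d.n = X.nrow(); d.p = X.ncol();
  ForestFit ff;
  import_forest(trees, inbag, d.n, d.p, ff);
  std::vector<int> s(sel.size());
  for (int i = 0; i < sel.size(); ++i) s[i] = sel[i] - 1;
  std::vector<double> per_tree;
  importance_core(d, ff, s, n_perm, (uint64_t)seed, per_tree);
  int T = (int)ff.trees.size();
  NumericMatrix out(sel.size(), T);
  for (int i = 0; i < sel.size(); ++i)
    for (int t = 0; t < T; ++t) out(i, t) = per_tree[(size_t)i * T + t];
  return out;
}

// Re-randomization null: B forests fit to row-permuted responses; each row
// of the result is the importance profile (mean over trees) of one refit.
// [[Rcpp::export]]
NumericMatrix cpp_rerand_null(NumericMatrix X, NumericVector y,
                              IntegerVector sel, int B, int n_trees, int mtry,
                              int min_split, int min_bucket, double alpha,
                              int max_depth, double subsample_frac, int n_perm,
                              double seed) {
  Data d; d.X = X.begin(); d.n = X.nrow(); d.p = X.ncol();
  TreeParams par = make_params(mtry, min_split, min_bucket, alpha, max_depth);
  int ns = sel.size();
  std::vector<int> s(ns);
  for (int i = 0; i < ns; ++i) s[i] = sel[i] - 1;
  NumericMatrix out(B, ns);
  std::vector<double> yp(d.n);
  std::vector<int> perm(d.n);
  for (int b = 0; b < B; ++b) {
    uint64_t bs = derive((uint64_t)seed, 500000 + (uint64_t)b);
    Rng rng(derive(bs, 1));
    for (int i = 0; i < d.n; ++i) perm[i] = i;
    rng.shuffle(perm);
    for (int i = 0; i < d.n; ++i) yp[i] = y[perm[i]];
    d.y = yp.data();
    ForestFit ff;
    fit_forest_core(d, n_trees, par, subsample_frac, derive(bs, 2), ff);
    std::vector<double> per_tree;
    importance_core(d, ff, s, n_perm, derive(bs, 3), per_tree);
    for (int i = 0; i < ns; ++i) {
      double acc = 0.0;
      for (int t = 0; t < n_trees; ++t) acc += per_tree[(size_t)i * n_trees + t];
      out(b, i) = acc / n_trees;
    }
    if (b % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
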