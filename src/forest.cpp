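#include <Rcpp.h>
#include <random>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// A compact CART random-forest for binary classification: gini splits,
// bootstrap resampling, mtry feature subsampling, trees grown to purity
// (or until no split improves), out-of-bag permutation importance
// (mean decrease in OOB accuracy). Deterministic under a fixed seed.

struct Tree {
  std::vector<int> feature;      // -1 for a leaf
  std::vector<double> threshold; // go left if x <= threshold
  std::vector<int> left, right;
  std::vector<double> pred;      // fraction of positive training rows in node
};

static inline double gini_part(double pos, double n) {
  if (n <= 0) return 0.0;
  double p = pos / n;
  return 2.0 * p * (1.0 - p) * n; // weighted gini contribution
}

static int grow_node(Tree &tr, const NumericMatrix &X, const IntegerVector &y,
                     std::vector<int> &idx, int lo, int hi, int mtry,
                     std::mt19937 &rng, std::vector<int> &featbuf) {
  const int node = (int) tr.feature.size();
  tr.feature.push_back(-1);
  tr.threshold.push_back(0.0);
  tr.left.push_back(-1);
  tr.right.push_back(-1);

  const int n = hi - lo;
  int pos = 0;
  for (int i = lo; i < hi; ++i) pos += y[idx[i]];
  tr.pred.push_back(n > 0 ? (double) pos / n : 0.5);
  if (pos == 0 || pos == n || n < 2) return node;

  const int p = X.ncol();
  // sample mtry distinct features (partial Fisher-Yates over featbuf)
  for (int j = 0; j < p; ++j) featbuf[j] = j;
  int best_f = -1;
  double best_thr = 0.0, best_gain = 1e-12;
  const double parent = gini_part((double) pos, (double) n);

  std::vector<std::pair<double,int>> vals(n);
  for (int t = 0; t < mtry; ++t) {
    std::uniform_int_distribution<int> pick(t, p - 1);
    int k = pick(rng);
    std::swap(featbuf[t], featbuf[k]);
    int f = featbuf[t];
    for (int i = 0; i < n; ++i) {
      int r = idx[lo + i];
      vals[i] = std::make_pair(X(r, f), y[r]);
    }
    std::sort(vals.begin(), vals.end());
    double lpos = 0.0;
    for (int i = 0; i < n - 1; ++i) {
      lpos += vals[i].second;
      if (vals[i].first < vals[i + 1].first) {
        double nl = i + 1, nr = n - nl;
        double gain = parent - gini_part(lpos, nl) - gini_part(pos - lpos, nr);
        if (gain > best_gain) {
          best_gain = gain;
          best_f = f;
          best_thr = vals[i].first + 0.5 * (vals[i + 1].first - vals[i].first);
        }
      }
    }
  }
  if (best_f < 0) return node;

  // partition idx[lo..hi) in place
  int mid = lo;
  for (int i = lo; i < hi; ++i)
    if (X(idx[i], best_f) <= best_thr) std::swap(idx[i], idx[mid++]);
  if (mid == lo || mid == hi) return node; // numeric degeneracy guard

  tr.feature[node] = best_f;
  tr.threshold[node] = best_thr;
  int l = grow_node(tr, X, y, idx, lo, mid, mtry, rng, featbuf);
  int r = grow_node(tr, X, y, idx, mid, hi, mtry, rng, featbuf);
  tr.left[node] = l;
  tr.right[node] = r;
  return node;
}

// predict a single row, optionally overriding one feature's value
static inline double tree_pred(const Tree &tr, const NumericMatrix &X, int row,
                               int override_f = -1, double override_v = 0.0) {
  int node = 0;
  while (tr.feature[node] >= 0) {
    int f = tr.feature[node];
    double v = (f == override_f) ? override_v : X(row, f);
    node = (v <= tr.threshold[node]) ? tr.left[node] : tr.right[node];
  }
  return tr.pred[node];
}

static List tree_to_list(const Tree &tr) {
  return List::create(_["feature"] = wrap(tr.feature),
                      _["threshold"] = wrap(tr.threshold),
                      _["left"] = wrap(tr.left),
                      _["right"] = wrap(tr.right),
                      _["pred"] = wrap(tr.pred));
}

static Tree tree_from_list(List lst) {
  Tree tr;
  tr.feature = as<std::vector<int>>(lst["feature"]);
  tr.threshold = as<std::vector<double>>(lst["threshold"]);
  tr.left = as<std::vector<int>>(lst["left"]);
  tr.right = as<std::vector<int>>(lst["right"]);
  tr.pred = as<std::vector<double>>(lst["pred"]);
  return tr;
}

// [[Rcpp::export(name = ".rf_train_cpp")]]
List rf_train_cpp(NumericMatrix X, IntegerVector y, int ntree, int mtry,
                  int seed, bool importance) {
  const int n = X.nrow(), p = X.ncol();
  std::mt19937 rng((unsigned) seed);
  std::uniform_int_distribution<int> unif_n(0, n - 1);

  std::vector<Tree> forest(ntree);
  NumericVector imp(p);
  std::vector<double> oob_votes(n, 0.0);
  std::vector<int> oob_count(n, 0);
  std::vector<int> featbuf(p);

  for (int t = 0; t < ntree; ++t) {
    std::vector<int> inbag(n, 0), idx;
    idx.reserve(n);
    for (int i = 0; i < n; ++i) {
      int k = unif_n(rng);
      inbag[k]++;
      idx.push_back(k);
    }
    grow_node(forest[t], X, y, idx, 0, n, mtry, rng, featbuf);

    std::vector<int> oob;
    for (int i = 0; i < n; ++i)
      if (!inbag[i]) oob.push_back(i);
    const int m = (int) oob.size();
    if (m == 0) continue;
    int correct = 0;
    for (int i = 0; i < m; ++i) {
      double pr = tree_pred(forest[t], X, oob[i]);
      int vote = pr >= 0.5 ? 1 : 0;
      oob_votes[oob[i]] += vote;
      oob_count[oob[i]]++;
      if (vote == y[oob[i]]) correct++;
    }
    if (importance) {
      double acc0 = (double) correct / m;
      // permuting a feature the tree never splits on cannot change its
      // predictions; only used features need the permutation pass
      std::vector<char> used(p, 0);
      for (size_t k = 0; k < forest[t].feature.size(); ++k)
        if (forest[t].feature[k] >= 0) used[forest[t].feature[k]] = 1;
      std::vector<int> perm(m);
      for (int j = 0; j < p; ++j) {
        if (!used[j]) continue;
        for (int i = 0; i < m; ++i) perm[i] = i;
        for (int i = m - 1; i > 0; --i) {
          std::uniform_int_distribution<int> pick(0, i);
          std::swap(perm[i], perm[pick(rng)]);
        }
        int cj = 0;
        for (int i = 0; i < m; ++i) {
          double v = X(oob[perm[i]], j);
          double pr = tree_pred(forest[t], X, oob[i], j, v);
          if ((pr >= 0.5 ? 1 : 0) == y[oob[i]]) cj++;
        }
        imp[j] += acc0 - (double) cj / m;
      }
    }
  }
  if (importance) for (int j = 0; j < p; ++j) imp[j] /= ntree;

  int oob_wrong = 0, oob_n = 0;
  for (int i = 0; i < n; ++i)
    if (oob_count[i] > 0) {
      oob_n++;
      int vote = (oob_votes[i] / oob_count[i] >= 0.5) ? 1 : 0;
      if (vote != y[i]) oob_wrong++;
    }

  List trees(ntree);
  for (int t = 0; t < ntree; ++t) trees[t] = tree_to_list(forest[t]);
  return List::create(
      _["trees"] = trees, _["importance"] = imp,
      _["oob_error"] = oob_n > 0 ? (double) oob_wrong / oob_n : NA_REAL);
}

// Fraction of trees voting positive for each row.
// [[Rcpp::export(name = ".rf_predict_cpp")]]
NumericVector rf_predict_cpp(List trees, NumericMatrix X) {
  const int n = X.nrow(), ntree = trees.size();
  std::vector<Tree> forest(ntree);
  for (int t = 0; t < ntree; ++t) forest[t] = tree_from_list(trees[t]);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    int votes = 0;
    for (int t = 0; t < ntree; ++t)
      if (tree_pred(forest[t], X, i) >= 0.5) votes++;
    out[i] = (double) votes / ntree;
  }
  return out;
}
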