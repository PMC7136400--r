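// Compact random forest for binary classification on small expression panels.
// Bootstrap-aggregated CART trees, Gini splits over mtry random features,
// out-of-bag (OOB) vote aggregation and unscaled permutation importance.
// Self-contained mt19937 RNG so results are bit-reproducible across
// platforms given an integer seed.
#include <Rcpp.h>
#include <random>
#include <algorithm>
#include <vector>
#include <cstdint>
using namespace Rcpp;

namespace {

struct RNG {
  std::mt19937 eng;
  explicit RNG(uint32_t seed) : eng(seed) {}
  // bounded draw; modulo bias is negligible for our n and fully deterministic
  int below(int n) { return static_cast<int>(eng() % static_cast<uint32_t>(n)); }
};

// column-major view: n rows (samples) x p cols (features)
struct Mat {
  const double* v;
  int n, p;
  double at(int r, int c) const { return v[static_cast<size_t>(c) * n + r]; }
};

struct Node {
  int feature = -1;      // -1 => leaf
  double threshold = 0.0;
  int left = -1, right = -1;
  int klass = 0;         // leaf majority class
};

struct Tree {
  std::vector<Node> nodes;

  // predict row r of X; if perm_feature >= 0, feature perm_feature reads
  // from row perm_row instead (used for permutation importance)
  int predict(const Mat& X, int r, int perm_feature = -1,
              int perm_row = -1) const {
    int cur = 0;
    while (nodes[cur].feature >= 0) {
      const Node& nd = nodes[cur];
      double v = (nd.feature == perm_feature)
        ? X.at(perm_row, nd.feature) : X.at(r, nd.feature);
      cur = (v <= nd.threshold) ? nd.left : nd.right;
    }
    return nodes[cur].klass;
  }
};

struct Builder {
  const Mat& X;
  const int* y;
  int mtry;
  RNG& rng;
  std::vector<int> feat_pool;
  std::vector<std::pair<double,int>> vals;
  std::vector<int> lbuf, rbuf;

  Builder(const Mat& X_, const int* y_, int mtry_, RNG& rng_)
      : X(X_), y(y_), mtry(mtry_), rng(rng_), feat_pool(X_.p) {
    for (int f = 0; f < X.p; ++f) feat_pool[f] = f;
    vals.reserve(X.n);
    lbuf.reserve(X.n);
    rbuf.reserve(X.n);
  }

  int grow(Tree& tree, std::vector<int>& idx, int lo, int hi) {
    int n = hi - lo;
    int n1 = 0;
    for (int i = lo; i < hi; ++i) n1 += y[idx[i]];
    int node_id = static_cast<int>(tree.nodes.size());
    tree.nodes.push_back(Node());
    tree.nodes[node_id].klass = (2 * n1 > n) ? 1 : 0; // tie -> class 0
    if (n1 == 0 || n1 == n || n < 2) return node_id;

    // sample mtry features without replacement (partial Fisher-Yates)
    for (int i = 0; i < mtry; ++i) {
      int j = i + rng.below(X.p - i);
      std::swap(feat_pool[i], feat_pool[j]);
    }

    double best_score = -1.0; // Gini decrease
    int best_f = -1;
    double best_thr = 0.0;
    double parent_gini = 2.0 * (double)n1 / n * (1.0 - (double)n1 / n);

    vals.resize(n);
    for (int fi = 0; fi < mtry; ++fi) {
      int f = feat_pool[fi];
      for (int i = 0; i < n; ++i) {
        int r = idx[lo + i];
        vals[i] = { X.at(r, f), y[r] };
      }
      std::sort(vals.begin(), vals.end());
      int left1 = 0;
      for (int i = 0; i < n - 1; ++i) {
        left1 += vals[i].second;
        if (vals[i].first == vals[i + 1].first) continue;
        int nl = i + 1, nr = n - nl;
        int l1 = left1, r1 = n1 - left1;
        double gl = 2.0 * (double)l1 / nl * (1.0 - (double)l1 / nl);
        double gr = 2.0 * (double)r1 / nr * (1.0 - (double)r1 / nr);
        double score = parent_gini - ((double)nl / n * gl + (double)nr / n * gr);
        if (score > best_score + 1e-12) {
          best_score = score;
          best_f = f;
          best_thr = 0.5 * (vals[i].first + vals[i + 1].first);
        }
      }
    }
    if (best_f < 0 || best_score <= 1e-12) return node_id; // no useful split

    lbuf.clear(); rbuf.clear();
    for (int i = lo; i < hi; ++i) {
      if (X.at(idx[i], best_f) <= best_thr) lbuf.push_back(idx[i]);
      else rbuf.push_back(idx[i]);
    }
    std::copy(lbuf.begin(), lbuf.end(), idx.begin() + lo);
    std::copy(rbuf.begin(), rbuf.end(), idx.begin() + lo + lbuf.size());
    int mid = lo + static_cast<int>(lbuf.size());

    tree.nodes[node_id].feature = best_f;
    tree.nodes[node_id].threshold = best_thr;
    int left_id = grow(tree, idx, lo, mid);
    int right_id = grow(tree, idx, mid, hi);
    tree.nodes[node_id].left = left_id;
    tree.nodes[node_id].right = right_id;
    return node_id;
  }
};

Tree fit_tree(const Mat& X, const int* y, std::vector<int>& boot,
              int mtry, RNG& rng) {
  Tree tree;
  Builder b(X, y, mtry, rng);
  b.grow(tree, boot, 0, static_cast<int>(boot.size()));
  return tree;
}

} // namespace

// [[Rcpp::export(name = ".rf_oob_cpp")]]
List rf_oob_cpp(NumericMatrix X, IntegerVector y, int ntree, int mtry,
                int seed, bool importance) {
  int n = X.nrow(), p = X.ncol();
  std::vector<double> xv(X.begin(), X.end());
  Mat M{xv.data(), n, p};
  std::vector<int> yv(y.begin(), y.end());
  RNG rng(static_cast<uint32_t>(seed));
  std::vector<int> oob_pos(n, 0), oob_tot(n, 0);
  NumericVector imp(p, 0.0);
  std::vector<int> imp_trees(p, 0);
  std::vector<char> inbag(n);
  std::vector<int> boot(n), oob_rows, perm;

  for (int t = 0; t < ntree; ++t) {
    std::fill(inbag.begin(), inbag.end(), 0);
    for (int i = 0; i < n; ++i) {
      boot[i] = rng.below(n);
      inbag[boot[i]] = 1;
    }
    oob_rows.clear();
    for (int i = 0; i < n; ++i) if (!inbag[i]) oob_rows.push_back(i);
    Tree tree = fit_tree(M, yv.data(), boot, mtry, rng);
    if (oob_rows.empty()) continue;

    int base_correct = 0;
    for (int r : oob_rows) {
      int pred = tree.predict(M, r);
      if (pred == 1) oob_pos[r]++;
      oob_tot[r]++;
      if (pred == yv[r]) base_correct++;
    }

    if (importance) {
      int m = static_cast<int>(oob_rows.size());
      perm.resize(m);
      for (int f = 0; f < p; ++f) {
        // permute feature f's values among the OOB rows
        for (int i = 0; i < m; ++i) perm[i] = oob_rows[i];
        for (int i = m - 1; i > 0; --i) {
          int j = rng.below(i + 1);
          std::swap(perm[i], perm[j]);
        }
        int perm_correct = 0;
        for (int i = 0; i < m; ++i)
          if (tree.predict(M, oob_rows[i], f, perm[i]) == yv[oob_rows[i]])
            perm_correct++;
        imp[f] += (double)(base_correct - perm_correct) / m;
        imp_trees[f]++;
      }
    }
  }

  int used = 0, wrong = 0;
  NumericVector votes(n, NA_REAL);
  for (int i = 0; i < n; ++i) {
    if (oob_tot[i] == 0) continue;
    used++;
    votes[i] = (double)oob_pos[i] / oob_tot[i];
    int pred = (2 * oob_pos[i] > oob_tot[i]) ? 1 : 0;
    if (pred != yv[i]) wrong++;
  }
  if (importance)
    for (int f = 0; f < p; ++f)
      if (imp_trees[f] > 0) imp[f] /= imp_trees[f];

  return List::create(
    _["oob_error"] = used > 0 ? (double)wrong / used : NA_REAL,
    _["oob_votes"] = votes,
    _["importance"] = imp,
    _["n_oob_used"] = used);
}

// [[Rcpp::export(name = ".rf_predict_cpp")]]
NumericVector rf_predict_cpp(NumericMatrix Xtrain, IntegerVector ytrain,
                             NumericMatrix Xtest, int ntree, int mtry,
                             int seed) {
  int n = Xtrain.nrow(), m = Xtest.nrow();
  std::vector<double> xtr(Xtrain.begin(), Xtrain.end());
  std::vector<double> xte(Xtest.begin(), Xtest.end());
  Mat Mtr{xtr.data(), n, Xtrain.ncol()};
  Mat Mte{xte.data(), m, Xtest.ncol()};
  std::vector<int> yv(ytrain.begin(), ytrain.end());
  RNG rng(static_cast<uint32_t>(seed));
  std::vector<int> pos(m, 0);
  std::vector<int> boot(n);
  for (int t = 0; t < ntree; ++t) {
    for (int i = 0; i < n; ++i) boot[i] = rng.below(n);
    Tree tree = fit_tree(Mtr, yv.data(), boot, mtry, rng);
    for (int r = 0; r < m; ++r)
      if (tree.predict(Mte, r) == 1) pos[r]++;
  }
  NumericVector out(m);
  for (int r = 0; r < m; ++r) out[r] = (double)pos[r] / ntree;
  return out;
}
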