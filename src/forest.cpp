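#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cstdint>

using namespace Rcpp;

// Self-contained RNG (splitmix64 seeding an xorshift128+) so that forests are
// reproducible from an integer seed independently of R's RNG state.
struct Xoshiro {
  uint64_t s0, s1;
  explicit Xoshiro(uint64_t seed) {
    uint64_t z = seed + 0x9E3779B97F4A7C15ULL;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    s0 = z ^ (z >> 31);
    z = seed + 2 * 0x9E3779B97F4A7C15ULL;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    s1 = z ^ (z >> 31);
    if (s0 == 0 && s1 == 0) s1 = 1;
  }
  uint64_t next() {
    uint64_t x = s0, y = s1;
    s0 = y;
    x ^= x << 23;
    s1 = x ^ y ^ (x >> 17) ^ (y >> 26);
    return s1 + y;
  }
  // uniform integer in [0, n)
  int unif_int(int n) { return (int)(next() % (uint64_t)n); }
};

struct TreeBuilder {
  // flat tree arrays; children index 0 means "leaf"
  std::vector<int> feature, left, right, pred;
  std::vector<double> thr;
  const NumericMatrix& X;
  const IntegerVector& y; // 0-based class codes
  int K, p, mtry, min_node;
  Xoshiro& rng;

  TreeBuilder(const NumericMatrix& X_, const IntegerVector& y_, int K_,
              int mtry_, int min_node_, Xoshiro& rng_)
    : X(X_), y(y_), K(K_), p(X_.ncol()), mtry(mtry_), min_node(min_node_),
      rng(rng_) {}

  int new_node() {
    feature.push_back(-1); thr.push_back(0.0);
    left.push_back(0); right.push_back(0); pred.push_back(-1);
    return (int)feature.size() - 1;
  }

  int majority(const std::vector<int>& idx) {
    std::vector<int> cnt(K, 0);
    for (int i : idx) cnt[y[i]]++;
    int best = 0;
    for (int k = 1; k < K; ++k) if (cnt[k] > cnt[best]) best = k; // tie: lowest index
    return best;
  }

  static double gini(const std::vector<int>& cnt, int n) {
    if (n == 0) return 0.0;
    double s = 0.0;
    for (int c : cnt) { double f = (double)c / n; s += f * f; }
    return 1.0 - s;
  }

  int grow(std::vector<int>& idx) {
    int node = new_node();
    int n = (int)idx.size();
    std::vector<int> cnt(K, 0);
    for (int i : idx) cnt[y[i]]++;
    int nonzero = 0;
    for (int k = 0; k < K; ++k) if (cnt[k] > 0) nonzero++;
    if (nonzero <= 1 || n <= min_node) {
      pred[node] = majority(idx);
      return node;
    }
    double parent_gini = gini(cnt, n);

    // sample mtry distinct features (partial Fisher-Yates)
    std::vector<int> feats(p);
    for (int j = 0; j < p; ++j) feats[j] = j;
    int m = std::min(mtry, p);
    for (int j = 0; j < m; ++j) {
      int r = j + rng.unif_int(p - j);
      std::swap(feats[j], feats[r]);
    }

    double best_dec = 0.0, best_thr = 0.0;
    int best_feat = -1;
    std::vector<int> ord(idx);

    for (int j = 0; j < m; ++j) {
      int f = feats[j];
      std::sort(ord.begin(), ord.end(), [&](int a, int b) {
        double va = X(a, f), vb = X(b, f);
        if (va != vb) return va < vb;
        return a < b; // stable, deterministic
      });
      std::vector<int> lcnt(K, 0), rcnt(cnt);
      int nl = 0;
      for (int i = 0; i < n - 1; ++i) {
        int s = ord[i];
        lcnt[y[s]]++; rcnt[y[s]]--; nl++;
        double v0 = X(s, f), v1 = X(ord[i + 1], f);
        if (v0 == v1) continue;
        int nr = n - nl;
        double dec = parent_gini -
          ((double)nl / n) * gini(lcnt, nl) -
          ((double)nr / n) * gini(rcnt, nr);
        if (dec > best_dec + 1e-12) {
          best_dec = dec;
          best_feat = f;
          best_thr = v0 + (v1 - v0) / 2.0;
        }
      }
    }

    if (best_feat < 0) { // no impurity decrease possible
      pred[node] = majority(idx);
      return node;
    }

    std::vector<int> lidx, ridx;
    for (int i : idx) {
      if (X(i, best_feat) <= best_thr) lidx.push_back(i); else ridx.push_back(i);
    }
    if (lidx.empty() || ridx.empty()) {
      pred[node] = majority(idx);
      return node;
    }
    feature[node] = best_feat;
    thr[node] = best_thr;
    left[node] = grow(lidx);
    right[node] = grow(ridx);
    return node;
  }
};

// [[Rcpp::export(name = ".cpp_forest_fit")]]
List cpp_forest_fit(NumericMatrix X, IntegerVector y, int n_classes,
                    int n_trees, int mtry, int min_node, double seed) {
  int n = X.nrow();
  List trees(n_trees);
  for (int t = 0; t < n_trees; ++t) {
    // one RNG stream per tree: reproducible and order-independent
    Xoshiro rng((uint64_t)seed * 2654435761ULL + (uint64_t)(t + 1));
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = rng.unif_int(n); // bootstrap
    TreeBuilder tb(X, y, n_classes, mtry, min_node, rng);
    tb.grow(idx);
    int nn = (int)tb.feature.size();
    IntegerMatrix nodes(nn, 4);
    NumericVector thr(nn);
    for (int i = 0; i < nn; ++i) {
      nodes(i, 0) = tb.feature[i];
      nodes(i, 1) = tb.left[i];
      nodes(i, 2) = tb.right[i];
      nodes(i, 3) = tb.pred[i];
      thr[i] = tb.thr[i];
    }
    trees[t] = List::create(Named("nodes") = nodes, Named("thr") = thr);
  }
  return trees;
}

// [[Rcpp::export(name = ".cpp_forest_votes")]]
IntegerMatrix cpp_forest_votes(List trees, NumericMatrix X, int n_classes) {
  int n = X.nrow(), T = trees.size();
  IntegerMatrix votes(n, n_classes);
  for (int t = 0; t < T; ++t) {
    List tr = trees[t];
    IntegerMatrix nodes = tr["nodes"];
    NumericVector thr = tr["thr"];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (nodes(node, 0) >= 0) {
        node = (X(i, nodes(node, 0)) <= thr[node]) ? nodes(node, 1)
                                                   : nodes(node, 2);
      }
      votes(i, nodes(node, 3))++;
    }
  }
  return votes;
}

// Connected-component labelling of a binary mask (1 = target), 4- or
// 8-connectivity, labels assigned in row-major discovery order.
// [[Rcpp::export(name = ".cpp_label_components")]]
IntegerMatrix cpp_label_components(IntegerMatrix mask, int connectivity) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<std::pair<int, int>> stack;
  int next = 0;
  const int dr4[] = {-1, 1, 0, 0}, dc4[] = {0, 0, -1, 1};
  const int dr8[] = {-1, 1, 0, 0, -1, -1, 1, 1},
            dc8[] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int* dr = connectivity == 8 ? dr8 : dr4;
  const int* dc = connectivity == 8 ? dc8 : dc4;
  int nd = connectivity == 8 ? 8 : 4;
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      if (mask(r, c) != 1 || lab(r, c) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back({r, c});
      lab(r, c) = next;
      while (!stack.empty()) {
        auto rc = stack.back(); stack.pop_back();
        for (int d = 0; d < nd; ++d) {
          int rr = rc.first + dr[d], cc = rc.second + dc[d];
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          if (mask(rr, cc) == 1 && lab(rr, cc) == 0) {
            lab(rr, cc) = next;
            stack.push_back({rr, cc});
          }
        }
      }
    }
  }
  return lab;
}
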