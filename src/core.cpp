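#include <Rcpp.h>
#include <unordered_set>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Binary classification tree grown to purity (or until no impurity-reducing
// split exists), with exact midpoint thresholds and deterministic tie-breaks:
// among equal gains the lowest feature index wins, then the lowest threshold.
// Node-level statistics are returned so that mean-decrease-impurity can be
// assembled (and audited) on the R side.
// ---------------------------------------------------------------------------

namespace {

struct NodeRec {
  int id, depth, n, n_pos;
  double impurity;        // impurity of the node
  int feature;            // 0-based split feature, -1 for leaf
  double threshold;       // x <= threshold goes left
  double child_impurity;  // sample-weighted mean impurity of the two children
  int left, right;        // child ids, -1 for leaf
};

inline double impurity_of(int n_pos, int n, bool gini) {
  if (n == 0) return 0.0;
  double p1 = (double)n_pos / n, p0 = 1.0 - p1;
  if (gini) return p1 * (1.0 - p1) + p0 * (1.0 - p0);
  double s = 0.0;
  if (p1 > 0) s -= p1 * std::log(p1);
  if (p0 > 0) s -= p0 * std::log(p0);
  return s;
}

struct TreeBuilder {
  const NumericMatrix& X;
  const IntegerVector& y;
  bool gini;
  std::vector<NodeRec> nodes;

  TreeBuilder(const NumericMatrix& X_, const IntegerVector& y_, bool gini_)
    : X(X_), y(y_), gini(gini_) {}

  int build(std::vector<int>& idx, int depth) {
    int n = idx.size();
    int n_pos = 0;
    for (int i : idx) n_pos += y[i];
    double imp = impurity_of(n_pos, n, gini);

    NodeRec rec;
    rec.id = (int)nodes.size();
    rec.depth = depth; rec.n = n; rec.n_pos = n_pos;
    rec.impurity = imp;
    rec.feature = -1; rec.threshold = NA_REAL;
    rec.child_impurity = NA_REAL; rec.left = -1; rec.right = -1;
    nodes.push_back(rec);
    int my_id = rec.id;

    if (n_pos == 0 || n_pos == n) return my_id;  // pure leaf

    // exhaustive split search
    int best_f = -1;
    double best_thr = 0.0, best_gain = 0.0;
    int best_nl = 0, best_npl = 0;
    const double eps = 1e-12;
    int p = X.ncol();
    std::vector<std::pair<double,int>> vals(n);

    for (int f = 0; f < p; ++f) {
      for (int i = 0; i < n; ++i) vals[i] = {X(idx[i], f), y[idx[i]]};
      std::sort(vals.begin(), vals.end(),
                [](const std::pair<double,int>& a, const std::pair<double,int>& b) {
                  return a.first < b.first;
                });
      int nl = 0, npl = 0;
      for (int i = 0; i < n - 1; ++i) {
        nl++; npl += vals[i].second;
        if (vals[i].first == vals[i + 1].first) continue;
        double thr = vals[i].first + (vals[i + 1].first - vals[i].first) / 2.0;
        int nr = n - nl, npr = n_pos - npl;
        double g = imp - (nl * impurity_of(npl, nl, gini) +
                          nr * impurity_of(npr, nr, gini)) / n;
        if (g > best_gain + eps) {  // strict improvement keeps first (lowest f, thr)
          best_gain = g; best_f = f; best_thr = thr;
          best_nl = nl; best_npl = npl;
        }
      }
    }

    if (best_f < 0 || best_gain <= eps) return my_id;  // unsplittable (duplicates)

    std::vector<int> li, ri;
    li.reserve(best_nl); ri.reserve(n - best_nl);
    for (int i : idx) {
      if (X(i, best_f) <= best_thr) li.push_back(i); else ri.push_back(i);
    }
    int lid = build(li, depth + 1);
    int rid = build(ri, depth + 1);
    double ci = (nodes[lid].n * nodes[lid].impurity +
                 nodes[rid].n * nodes[rid].impurity) / n;
    nodes[my_id].feature = best_f;
    nodes[my_id].threshold = best_thr;
    nodes[my_id].child_impurity = ci;
    nodes[my_id].left = lid;
    nodes[my_id].right = rid;
    return my_id;
  }
};

}  // namespace

// [[Rcpp::export]]
List cpp_fit_tree(NumericMatrix X, IntegerVector y, bool gini) {
  int n = X.nrow();
  if (y.size() != n) stop("X and y have different lengths");
  if (n < 1) stop("at least one sample required");
  TreeBuilder tb(X, y, gini);
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  tb.build(idx, 0);

  int m = tb.nodes.size();
  IntegerVector id(m), depth(m), nn(m), n_pos(m), feature(m), left(m), right(m);
  NumericVector impurity(m), threshold(m), child_impurity(m);
  for (int i = 0; i < m; ++i) {
    const NodeRec& r = tb.nodes[i];
    id[i] = r.id + 1; depth[i] = r.depth; nn[i] = r.n; n_pos[i] = r.n_pos;
    impurity[i] = r.impurity;
    feature[i] = r.feature >= 0 ? r.feature + 1 : NA_INTEGER;
    threshold[i] = r.threshold;
    child_impurity[i] = r.child_impurity;
    left[i] = r.left >= 0 ? r.left + 1 : NA_INTEGER;
    right[i] = r.right >= 0 ? r.right + 1 : NA_INTEGER;
  }
  return List::create(
    _["node"] = id, _["depth"] = depth, _["n"] = nn, _["n_pos"] = n_pos,
    _["impurity"] = impurity, _["feature"] = feature,
    _["threshold"] = threshold, _["child_impurity"] = child_impurity,
    _["left"] = left, _["right"] = right);
}

// ---------------------------------------------------------------------------
// Switch randomization: n_steps *accepted* double-edge swaps
// (a->b, c->d) => (a->d, c->b), rejecting proposals that would create a
// self-loop or a duplicate edge. Degree sequences are preserved exactly.
// Uses R's RNG so results follow set.seed().
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_switch_randomize(IntegerVector src, IntegerVector dst, int n_nodes,
                          int n_steps, double max_attempts) {
  int m = src.size();
  if (dst.size() != m) stop("src/dst length mismatch");
  std::vector<int> s(src.begin(), src.end()), d(dst.begin(), dst.end());
  std::unordered_set<long long> edges;
  edges.reserve(m * 2);
  long long N = n_nodes;
  auto key = [N](int a, int b) { return (long long)(a - 1) * N + (b - 1); };
  for (int i = 0; i < m; ++i) edges.insert(key(s[i], d[i]));

  RNGScope scope;
  long long accepted = 0, attempts = 0;
  while (accepted < n_steps) {
    if (++attempts > max_attempts)
      return List::create(_["src"] = wrap(s), _["dst"] = wrap(d),
                          _["accepted"] = (double)accepted,
                          _["attempts"] = (double)attempts,
                          _["converged"] = false);
    int i = (int)(unif_rand() * m); if (i >= m) i = m - 1;
    int j = (int)(unif_rand() * m); if (j >= m) j = m - 1;
    if (i == j) continue;
    int a = s[i], b = d[i], c = s[j], e = d[j];
    if (a == e || c == b) continue;            // would create self-loop
    if (b == e || a == c) continue;            // no-op / duplicate by construction
    long long k1 = key(a, e), k2 = key(c, b);
    if (edges.count(k1) || edges.count(k2)) continue;  // duplicate edge
    edges.erase(key(a, b)); edges.erase(key(c, e));
    edges.insert(k1); edges.insert(k2);
    d[i] = e; d[j] = b;
    ++accepted;
  }
  return List::create(_["src"] = wrap(s), _["dst"] = wrap(d),
                      _["accepted"] = (double)accepted,
                      _["attempts"] = (double)attempts,
                      _["converged"] = true);
}
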