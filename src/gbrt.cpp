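// Gradient-boosted regression trees with squared-error loss.
//
// Deterministic by construction: no row/feature subsampling, exact greedy
// splits, ties broken by (feature index, threshold) order. Trees are grown
// level-wise; every feature's global sort order is computed once and each
// level is scanned in O(n) per feature, so 1000 shallow trees on a few
// thousand genes fit in seconds.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <limits>
using namespace Rcpp;

struct Node {
  int feature = -1;          // -1 for leaf
  double threshold = 0.0;
  int left = -1, right = -1; // child node ids (tree-local)
  double value = 0.0;        // leaf prediction (mean residual)
};

// [[Rcpp::export(name = ".gbrt_fit_cpp")]]
List gbrt_fit_cpp(NumericMatrix X, NumericVector y, int n_trees,
                  double learning_rate, int max_depth, int min_leaf) {
  const int n = X.nrow(), p = X.ncol();
  if (n < 2) stop("need at least 2 samples");
  if (max_depth < 1) stop("max_depth must be >= 1");

  // global sort order per feature (stable for determinism)
  std::vector<std::vector<int>> order(p, std::vector<int>(n));
  for (int j = 0; j < p; ++j) {
    std::vector<int>& o = order[j];
    for (int i = 0; i < n; ++i) o[i] = i;
    const double* col = &X(0, j);
    std::stable_sort(o.begin(), o.end(),
                     [col](int a, int b) { return col[a] < col[b]; });
  }

  double init = mean(y);
  std::vector<double> resid(n);
  for (int i = 0; i < n; ++i) resid[i] = y[i] - init;

  std::vector<double> importance(p, 0.0);

  // flattened forest
  std::vector<int> tree_offset(1, 0);
  std::vector<int> nf, nl, nr;
  std::vector<double> nt, nv;

  std::vector<int> node_of(n);      // current leaf id per sample
  std::vector<Node> nodes;

  struct Stat { double sum; int cnt; };
  struct Best {
    double gain = 0.0; int feature = -1; double threshold = 0.0;
  };

  for (int t = 0; t < n_trees; ++t) {
    nodes.clear();
    nodes.push_back(Node());
    std::fill(node_of.begin(), node_of.end(), 0);

    std::vector<int> active(1, 0);  // node ids open at current depth

    for (int depth = 0; depth < max_depth && !active.empty(); ++depth) {
      const int n_act = (int)nodes.size();
      // total stats per node
      std::vector<Stat> total(n_act, {0.0, 0});
      for (int i = 0; i < n; ++i) {
        int nd = node_of[i];
        total[nd].sum += resid[i];
        total[nd].cnt += 1;
      }
      std::vector<Best> best(n_act);
      std::vector<Stat> left(n_act);
      std::vector<double> last_val(n_act);

      for (int j = 0; j < p; ++j) {
        for (int a : active) {
          left[a] = {0.0, 0};
          last_val[a] = -std::numeric_limits<double>::infinity();
        }
        const double* col = &X(0, j);
        const std::vector<int>& o = order[j];
        for (int k = 0; k < n; ++k) {
          const int i = o[k];
          const int nd = node_of[i];
          const double v = col[i];
          Stat& L = left[nd];
          if (L.cnt > 0 && v > last_val[nd]) {
            const Stat& T = total[nd];
            const int nR = T.cnt - L.cnt;
            if (L.cnt >= min_leaf && nR >= min_leaf) {
              const double sR = T.sum - L.sum;
              const double gain = L.sum * L.sum / L.cnt +
                                  sR * sR / nR - T.sum * T.sum / T.cnt;
              if (gain > best[nd].gain + 1e-12) {
                best[nd].gain = gain;
                best[nd].feature = j;
                best[nd].threshold = 0.5 * (last_val[nd] + v);
              }
            }
          }
          L.sum += resid[i];
          L.cnt += 1;
          last_val[nd] = v;
        }
      }

      // apply splits
      std::vector<int> next_active;
      std::vector<char> is_active(n_act, 0);
      for (int a : active) is_active[a] = 1;
      for (int a : active) {
        if (best[a].feature >= 0 && best[a].gain > 1e-10) {
          nodes[a].feature = best[a].feature;
          nodes[a].threshold = best[a].threshold;
          nodes[a].left = (int)nodes.size();
          nodes.push_back(Node());
          nodes[a].right = (int)nodes.size();
          nodes.push_back(Node());
          importance[best[a].feature] += best[a].gain;
          next_active.push_back(nodes[a].left);
          next_active.push_back(nodes[a].right);
        }
      }
      if (next_active.empty()) break;
      // route samples to children
      for (int i = 0; i < n; ++i) {
        int nd = node_of[i];
        if (nd < n_act && is_active[nd] && nodes[nd].feature >= 0) {
          node_of[i] = (X(i, nodes[nd].feature) <= nodes[nd].threshold)
                           ? nodes[nd].left : nodes[nd].right;
        }
      }
      active = next_active;
    }

    // leaf values = mean residual of samples in leaf
    {
      std::vector<Stat> st(nodes.size(), {0.0, 0});
      for (int i = 0; i < n; ++i) {
        st[node_of[i]].sum += resid[i];
        st[node_of[i]].cnt += 1;
      }
      for (size_t u = 0; u < nodes.size(); ++u) {
        if (nodes[u].feature < 0 && st[u].cnt > 0) {
          nodes[u].value = st[u].sum / st[u].cnt;
        }
      }
      for (int i = 0; i < n; ++i) {
        resid[i] -= learning_rate * nodes[node_of[i]].value;
      }
    }

    for (const Node& nd : nodes) {
      nf.push_back(nd.feature);
      nt.push_back(nd.threshold);
      nl.push_back(nd.left);
      nr.push_back(nd.right);
      nv.push_back(nd.value);
    }
    tree_offset.push_back((int)nf.size());
  }

  return List::create(
    _["init"] = init,
    _["learning_rate"] = learning_rate,
    _["tree_offset"] = IntegerVector(tree_offset.begin(), tree_offset.end()),
    _["feature"] = IntegerVector(nf.begin(), nf.end()),
    _["threshold"] = NumericVector(nt.begin(), nt.end()),
    _["left"] = IntegerVector(nl.begin(), nl.end()),
    _["right"] = IntegerVector(nr.begin(), nr.end()),
    _["value"] = NumericVector(nv.begin(), nv.end()),
    _["gain"] = NumericVector(importance.begin(), importance.end()));
}

// [[Rcpp::export(name = ".gbrt_predict_cpp")]]
NumericVector gbrt_predict_cpp(List model, NumericMatrix X) {
  const int n = X.nrow();
  const double init = as<double>(model["init"]);
  const double lr = as<double>(model["learning_rate"]);
  IntegerVector off = model["tree_offset"];
  IntegerVector nf = model["feature"];
  NumericVector nt = model["threshold"];
  IntegerVector nl = model["left"];
  IntegerVector nr = model["right"];
  NumericVector nv = model["value"];
  const int n_trees = off.size() - 1;

  NumericVector out(n, init);
  for (int t = 0; t < n_trees; ++t) {
    const int base = off[t];
    for (int i = 0; i < n; ++i) {
      int u = 0;
      while (nf[base + u] >= 0) {
        u = (X(i, nf[base + u]) <= nt[base + u]) ? nl[base + u]
                                                 : nr[base + u];
      }
      out[i] += lr * nv[base + u];
    }
  }
  return out;
}
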