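// Minimal random survival forest: bootstrap trees, log-rank splitting with
// random candidate split values, Nelson-Aalen leaf cumulative hazards
// summed over the cohort event-time grid ("ensemble mortality").
// R-side code owns the protocol (repeats, OOB permutation importance,
// pruning); this file owns speed. Member index lists are kept sorted by
// time from the root down, so log-rank scans are single passes.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

namespace {

struct NodeRec {
  int feature;       // -1 for leaf
  double threshold;  // go left when x <= threshold
  int left, right;
  double mortality;
};

// Two-group log-rank statistic; members sorted by time. Group = x <= thr.
double logrank_stat(const std::vector<double>& t, const std::vector<int>& e,
                    const std::vector<double>& x, double thr) {
  const int m = (int)t.size();
  int rem_left = 0;
  for (int j = 0; j < m; ++j) rem_left += (x[j] <= thr);
  if (rem_left == 0 || rem_left == m) return -1.0;
  int rem_total = m;
  double o_minus_e = 0.0, v = 0.0;
  int j = 0;
  while (j < m) {
    int k = j, dt = 0, d1t = 0, left_block = 0;
    const double tj = t[j];
    while (k < m && t[k] == tj) {
      dt += e[k];
      const bool L = x[k] <= thr;
      d1t += e[k] && L;
      left_block += L;
      ++k;
    }
    if (dt > 0) {
      const double nt = rem_total, frac = (double)rem_left / nt;
      o_minus_e += d1t - dt * frac;
      if (nt > 1.0) v += dt * frac * (1.0 - frac) * (nt - dt) / (nt - 1.0);
    }
    rem_left -= left_block;
    rem_total -= (k - j);
    j = k;
  }
  if (v <= 0.0) return -1.0;
  return o_minus_e * o_minus_e / v;
}

// Nelson-Aalen CHF of node members (time-sorted) summed over the grid.
double leaf_mortality(const std::vector<double>& t, const std::vector<int>& e,
                      const std::vector<double>& grid) {
  const int m = (int)t.size();
  double mort = 0.0;
  int at_risk = m, j = 0;
  while (j < m) {
    int k = j, dt = 0;
    while (k < m && t[k] == t[j]) { dt += e[k]; ++k; }
    if (dt > 0) {
      const double jump = (double)dt / (double)at_risk;
      const int ge = (int)(grid.end() -
                           std::lower_bound(grid.begin(), grid.end(), t[j]));
      mort += jump * ge;
    }
    at_risk -= (k - j);
    j = k;
  }
  return mort;
}

int sample_int(int n) {  // uniform on 0..n-1 via R's RNG
  int v = (int)(unif_rand() * n);
  return v >= n ? n - 1 : v;
}

}  // namespace

// [[Rcpp::export(name = ".rsf_fit_cpp")]]
List rsf_fit_cpp(NumericMatrix X, NumericVector time, IntegerVector event,
                 int n_trees, int mtry, int nsplit, int min_node,
                 int max_depth) {
  const int n = X.nrow(), p = X.ncol();
  std::vector<double> grid;
  for (int i = 0; i < n; ++i) if (event[i] == 1) grid.push_back(time[i]);
  std::sort(grid.begin(), grid.end());
  grid.erase(std::unique(grid.begin(), grid.end()), grid.end());

  // cohort order by time; bootstrap samples stay time-sorted via this order
  std::vector<int> time_rank(n);
  {
    std::vector<int> ord(n);
    for (int i = 0; i < n; ++i) ord[i] = i;
    std::stable_sort(ord.begin(), ord.end(),
                     [&](int a, int b) { return time[a] < time[b]; });
    for (int r = 0; r < n; ++r) time_rank[ord[r]] = r;
  }

  List trees(n_trees);
  IntegerMatrix inbag(n, n_trees);
  std::vector<int> feat_pool(p);
  std::vector<double> t_buf, x_buf;
  std::vector<int> e_buf, cnt(n);

  for (int b = 0; b < n_trees; ++b) {
    std::fill(cnt.begin(), cnt.end(), 0);
    for (int i = 0; i < n; ++i) cnt[sample_int(n)] += 1;
    std::vector<int> boot;
    boot.reserve(n);
    // emit bootstrap members in time order
    {
      std::vector<std::pair<int, int>> tmp;  // (rank, id)
      tmp.reserve(n);
      for (int i = 0; i < n; ++i)
        if (cnt[i]) tmp.push_back({time_rank[i], i});
      std::sort(tmp.begin(), tmp.end());
      for (auto& pr : tmp) {
        inbag(pr.second, b) = cnt[pr.second];
        for (int c = 0; c < cnt[pr.second]; ++c) boot.push_back(pr.second);
      }
    }
    std::vector<NodeRec> nodes;
    struct Work { int id; std::vector<int> members; int depth; };
    std::vector<Work> stack;
    nodes.push_back({-1, 0.0, -1, -1, 0.0});
    stack.push_back({0, std::move(boot), 0});

    while (!stack.empty()) {
      Work w = std::move(stack.back());
      stack.pop_back();
      std::vector<int>& mem = w.members;  // time-sorted
      const int m = (int)mem.size();
      t_buf.resize(m); e_buf.resize(m);
      int n_events = 0;
      for (int j = 0; j < m; ++j) {
        t_buf[j] = time[mem[j]];
        e_buf[j] = event[mem[j]];
        n_events += e_buf[j];
      }
      bool make_leaf = (m <= min_node) || (n_events < 2) || (w.depth >= max_depth);
      int best_f = -1;
      double best_thr = 0.0, best_stat = 0.0;
      if (!make_leaf) {
        for (int q = 0; q < p; ++q) feat_pool[q] = q;
        const int n_try = std::min(mtry, p);
        x_buf.resize(m);
        for (int q = 0; q < n_try; ++q) {
          const int pick = q + sample_int(p - q);
          std::swap(feat_pool[q], feat_pool[pick]);
          const int f = feat_pool[q];
          double xmax = -1e300;
          for (int j = 0; j < m; ++j) {
            x_buf[j] = X(mem[j], f);
            if (x_buf[j] > xmax) xmax = x_buf[j];
          }
          for (int s = 0; s < nsplit; ++s) {
            const double thr = x_buf[sample_int(m)];
            if (thr >= xmax) continue;  // right side would be empty
            const double st = logrank_stat(t_buf, e_buf, x_buf, thr);
            if (st > best_stat) {
              best_stat = st;
              best_f = f;
              best_thr = thr;
            }
          }
        }
        if (best_f < 0) make_leaf = true;
      }
      if (make_leaf) {
        nodes[w.id].feature = -1;
        nodes[w.id].mortality = leaf_mortality(t_buf, e_buf, grid);
        continue;
      }
      std::vector<int> lmem, rmem;  // stable partition keeps time order
      lmem.reserve(m);
      rmem.reserve(m);
      for (int j = 0; j < m; ++j) {
        if (X(mem[j], best_f) <= best_thr) lmem.push_back(mem[j]);
        else rmem.push_back(mem[j]);
      }
      const int lid = (int)nodes.size();
      nodes.push_back({-1, 0.0, -1, -1, 0.0});
      const int rid = (int)nodes.size();
      nodes.push_back({-1, 0.0, -1, -1, 0.0});
      nodes[w.id].feature = best_f;
      nodes[w.id].threshold = best_thr;
      nodes[w.id].left = lid;
      nodes[w.id].right = rid;
      stack.push_back({lid, std::move(lmem), w.depth + 1});
      stack.push_back({rid, std::move(rmem), w.depth + 1});
    }
    NumericMatrix tm((int)nodes.size(), 5);
    for (size_t q = 0; q < nodes.size(); ++q) {
      tm(q, 0) = nodes[q].feature;
      tm(q, 1) = nodes[q].threshold;
      tm(q, 2) = nodes[q].left;
      tm(q, 3) = nodes[q].right;
      tm(q, 4) = nodes[q].mortality;
    }
    trees[b] = tm;
  }
  return List::create(_["trees"] = trees, _["inbag"] = inbag,
                      _["n_grid"] = (int)grid.size());
}

// Per-tree leaf mortality for each row of X, plus terminal node ids
// (used for proximity-based imputation).
// [[Rcpp::export(name = ".rsf_predict_cpp")]]
List rsf_predict_cpp(List trees, NumericMatrix X) {
  const int n = X.nrow(), B = trees.size();
  NumericMatrix mort(n, B);
  IntegerMatrix leaf(n, B);
  for (int b = 0; b < B; ++b) {
    NumericMatrix tm = trees[b];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while ((int)tm(node, 0) >= 0) {
        node = X(i, (int)tm(node, 0)) <= tm(node, 1) ? (int)tm(node, 2)
                                                     : (int)tm(node, 3);
      }
      mort(i, b) = tm(node, 4);
      leaf(i, b) = node;
    }
  }
  return List::create(_["mortality"] = mort, _["leaf"] = leaf);
}

// Harrell C over usable pairs (higher risk should fail earlier); risk ties
// count 0.5. Used in the permutation-importance hot loop.
// [[Rcpp::export(name = ".cindex_cpp")]]
double cindex_cpp(NumericVector time, IntegerVector event, NumericVector risk) {
  const int n = time.size();
  double conc = 0.0, usable = 0.0;
  for (int i = 0; i < n; ++i) {
    if (!event[i]) continue;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      const bool comparable =
          (time[i] < time[j]) || (time[i] == time[j] && !event[j]);
      if (!comparable) continue;
      usable += 1.0;
      if (risk[i] > risk[j]) conc += 1.0;
      else if (risk[i] == risk[j]) conc += 0.5;
    }
  }
  if (usable == 0.0) return NA_REAL;
  return conc / usable;
}
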