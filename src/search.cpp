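#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Cluster score for aggregated (event, baseline) sums.
// stat 0: Kulldorff Poisson log LR against the global-rate null.
// stat 1: expectation-based Poisson log LR, baseline = expected count.
static inline double cluster_score(double c, double b, int stat,
                                   double Ctot, double Btot) {
  if (stat == 1) {
    if (b <= 0.0 || c <= b) return 0.0;
    return c * std::log(c / b) + b - c;
  }
  if (Btot <= 0.0) return 0.0;
  double E = Ctot * b / Btot;
  if (E <= 0.0 || c <= E) return 0.0;
  double s = c * std::log(c / E);
  double rem = Ctot - c, remE = Ctot - E;
  if (rem > 0.0 && remE > 0.0) s += rem * std::log(rem / remE);
  return s;
}

// Connectivity of (mem \ {drop}) U {add} by DFS over the adjacency lists.
static bool connected_with(const std::vector<int>& mem, int drop, int add,
                           const std::vector<std::vector<int>>& adj,
                           std::vector<char>& flag, std::vector<char>& vis,
                           std::vector<int>& stack) {
  std::fill(flag.begin(), flag.end(), 0);
  std::fill(vis.begin(), vis.end(), 0);
  int cnt = 0, start = -1;
  for (int i : mem) if (i != drop) { flag[i] = 1; ++cnt; start = i; }
  if (add >= 0 && !flag[add]) { flag[add] = 1; ++cnt; start = add; }
  if (cnt <= 1) return cnt == 1;
  stack.clear();
  stack.push_back(start);
  vis[start] = 1;
  int seen = 1;
  while (!stack.empty()) {
    int u = stack.back();
    stack.pop_back();
    for (int w : adj[u]) {
      if (flag[w] && !vis[w]) { vis[w] = 1; ++seen; stack.push_back(w); }
    }
  }
  return seen == cnt;
}

static bool lex_less(const std::vector<int>& a, const std::vector<int>& b) {
  return std::lexicographical_compare(a.begin(), a.end(), b.begin(), b.end());
}

struct Candidate {
  std::vector<int> mem; // sorted
  double score;
};

// Best-improvement 1-swap local search: add a neighbor, drop a member, or
// swap, keeping the set connected and within max_size. Deterministic move
// ordering; stops at a fixed point.
static void local_search(std::vector<int>& mem, double& cur_s,
                         const std::vector<std::vector<int>>& adj,
                         const NumericVector& ev, const NumericVector& bl,
                         const std::vector<char>& active, int stat,
                         double Ctot, double Btot, int max_size,
                         int n, int max_iter) {
  std::vector<char> flag(n), vis(n), inset(n);
  std::vector<int> stack;
  double cc = 0.0, bb = 0.0;
  for (int i : mem) { cc += ev[i]; bb += bl[i]; }
  cur_s = cluster_score(cc, bb, stat, Ctot, Btot);

  for (int iter = 0; iter < max_iter; ++iter) {
    std::fill(inset.begin(), inset.end(), 0);
    for (int i : mem) inset[i] = 1;
    // sorted candidate neighbors of the set
    std::vector<int> cand;
    for (int i : mem) {
      for (int j : adj[i]) {
        if (!inset[j] && active[j]) cand.push_back(j);
      }
    }
    std::sort(cand.begin(), cand.end());
    cand.erase(std::unique(cand.begin(), cand.end()), cand.end());
    std::vector<int> msort(mem);
    std::sort(msort.begin(), msort.end());

    double best_s = cur_s;
    int best_drop = -2, best_add = -2; // -2 = no move; -1 = none in slot
    // adds
    if ((int)mem.size() < max_size) {
      for (int j : cand) {
        double s = cluster_score(cc + ev[j], bb + bl[j], stat, Ctot, Btot);
        if (s > best_s + 1e-12) { best_s = s; best_drop = -1; best_add = j; }
      }
    }
    // drops
    if (mem.size() > 1) {
      for (int i : msort) {
        double s = cluster_score(cc - ev[i], bb - bl[i], stat, Ctot, Btot);
        if (s > best_s + 1e-12 &&
            connected_with(mem, i, -1, adj, flag, vis, stack)) {
          best_s = s; best_drop = i; best_add = -1;
        }
      }
    }
    // swaps
    for (int i : msort) {
      for (int j : cand) {
        double s = cluster_score(cc - ev[i] + ev[j], bb - bl[i] + bl[j],
                                 stat, Ctot, Btot);
        if (s > best_s + 1e-12 &&
            connected_with(mem, i, j, adj, flag, vis, stack)) {
          best_s = s; best_drop = i; best_add = j;
        }
      }
    }
    if (best_drop == -2 && best_add == -2) break;
    if (best_drop >= 0) {
      mem.erase(std::find(mem.begin(), mem.end(), best_drop));
      cc -= ev[best_drop]; bb -= bl[best_drop];
    }
    if (best_add >= 0) {
      mem.push_back(best_add);
      cc += ev[best_add]; bb += bl[best_add];
    }
    cur_s = cluster_score(cc, bb, stat, Ctot, Btot);
  }
}

// Multi-seed greedy growth + local search over a masked node set.
// adj_r: 1-based adjacency lists; returns best member set (1-based sorted)
// and its score. Ties broken toward the lexicographically smallest sorted
// member list (node order = sorted county ids on the R side).
// [[Rcpp::export]]
List greedy_search_cpp(List adj_r, NumericVector ev, NumericVector bl,
                       LogicalVector active_r, int stat,
                       double Ctot, double Btot, int max_size,
                       int n_polish = 8, int max_ls_iter = 200) {
  int n = ev.size();
  std::vector<char> active(n, 0);
  for (int i = 0; i < n; ++i) active[i] = active_r[i] ? 1 : 0;
  std::vector<std::vector<int>> adj(n);
  for (int i = 0; i < n; ++i) {
    if (!active[i]) continue;
    IntegerVector nb = adj_r[i];
    for (int k = 0; k < nb.size(); ++k) {
      int j = nb[k] - 1;
      if (active[j]) adj[i].push_back(j);
    }
  }

  std::vector<Candidate> seeds_best;
  std::vector<char> in_set(n), in_front(n);

  for (int v = 0; v < n; ++v) {
    if (!active[v]) continue;
    std::fill(in_set.begin(), in_set.end(), 0);
    std::fill(in_front.begin(), in_front.end(), 0);
    std::vector<int> order;
    std::vector<int> frontier;
    double c = ev[v], b = bl[v];
    in_set[v] = 1;
    order.push_back(v);
    for (int j : adj[v]) { in_front[j] = 1; frontier.push_back(j); }
    double best_pref = cluster_score(c, b, stat, Ctot, Btot);
    int best_len = 1;
    while ((int)order.size() < max_size) {
      int bj = -1;
      double bs = 0.0;
      for (int j : frontier) {
        if (in_set[j]) continue;
        double s = cluster_score(c + ev[j], b + bl[j], stat, Ctot, Btot);
        if (bj < 0 || s > bs + 1e-12 || (s >= bs - 1e-12 && j < bj)) {
          bs = s; bj = j;
        }
      }
      if (bj < 0) break;
      in_set[bj] = 1;
      order.push_back(bj);
      c += ev[bj]; b += bl[bj];
      for (int j : adj[bj]) {
        if (!in_set[j] && !in_front[j]) { in_front[j] = 1; frontier.push_back(j); }
      }
      double s = cluster_score(c, b, stat, Ctot, Btot);
      if (s > best_pref + 1e-12) { best_pref = s; best_len = (int)order.size(); }
    }
    Candidate cnd;
    cnd.mem.assign(order.begin(), order.begin() + best_len);
    std::sort(cnd.mem.begin(), cnd.mem.end());
    cnd.score = best_pref;
    seeds_best.push_back(std::move(cnd));
  }

  if (seeds_best.empty()) {
    return List::create(_["members"] = IntegerVector(0), _["score"] = 0.0);
  }

  // polish the strongest seed candidates (deduplicated), keep global best
  std::sort(seeds_best.begin(), seeds_best.end(),
            [](const Candidate& a, const Candidate& b) {
              if (a.score != b.score) return a.score > b.score;
              return lex_less(a.mem, b.mem);
            });
  seeds_best.erase(std::unique(seeds_best.begin(), seeds_best.end(),
                               [](const Candidate& a, const Candidate& b) {
                                 return a.mem == b.mem;
                               }),
                   seeds_best.end());

  std::vector<int> best_mem = seeds_best[0].mem;
  double best_score = seeds_best[0].score;
  int n_pol = std::min<int>(n_polish, (int)seeds_best.size());
  for (int k = 0; k < n_pol; ++k) {
    std::vector<int> mem = seeds_best[k].mem;
    double s = seeds_best[k].score;
    local_search(mem, s, adj, ev, bl, active, stat, Ctot, Btot,
                 max_size, n, max_ls_iter);
    std::sort(mem.begin(), mem.end());
    if (s > best_score + 1e-9 ||
        (std::fabs(s - best_score) <= 1e-9 && lex_less(mem, best_mem))) {
      best_score = s;
      best_mem = mem;
    }
  }

  IntegerVector out(best_mem.size());
  for (size_t i = 0; i < best_mem.size(); ++i) out[i] = best_mem[i] + 1;
  return List::create(_["members"] = out, _["score"] = best_score);
}
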