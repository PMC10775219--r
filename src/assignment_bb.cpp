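// Exact capacitated single-assignment solver: the generalized-assignment
// subproblem of the hub-location model (each facility wholly assigned to
// one open site, sum of assigned demand within each site's capacity,
// minimize total assignment cost).
//
// Branch-and-bound with a Lagrangian-dual bound: capacity constraints are
// priced with multipliers v_j >= 0, so each facility independently picks
// its cheapest priced site and
//   L(v) = forced_cost + sum_i d_i * min_j (c_ij/d_i + v_j) - sum_j v_j r_j
// is a valid lower bound for ANY v (equal to the transportation-LP bound
// at the optimal v).  Multipliers are improved by a few subgradient steps
// per node, warm-started from the parent.  Branching is multiway: a
// facility assigned to the most overloaded site is forced onto each of
// its feasible sites in priced-cost order.  A greedy repair of the
// Lagrangian assignment provides integral incumbents throughout.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <queue>
#include <cmath>
#include <limits>

using namespace Rcpp;

static const double EPS = 1e-7;
static const double INF = std::numeric_limits<double>::infinity();

namespace {

struct Edge {
  int to;
  double cap;
  double cost;
  int rev;
};

// small min-cost-flow (successive shortest paths, Dijkstra on reduced
// costs); used once at the root to get the exact transportation-LP bound
// and its dual site prices
struct MCMF {
  int n_nodes;
  std::vector<std::vector<Edge>> g;
  std::vector<double> pot, dist;
  std::vector<int> pv, pe;

  explicit MCMF(int n) : n_nodes(n), g(n), pot(n, 0.0), dist(n), pv(n), pe(n) {}

  void add_edge(int from, int to, double cap, double cost) {
    g[from].push_back({to, cap, cost, (int)g[to].size()});
    g[to].push_back({from, 0.0, -cost, (int)g[from].size() - 1});
  }

  std::pair<double, double> run(int s, int t) {
    double flow = 0.0, cost = 0.0;
    for (;;) {
      std::fill(dist.begin(), dist.end(), INF);
      dist[s] = 0.0;
      using QI = std::pair<double, int>;
      std::priority_queue<QI, std::vector<QI>, std::greater<QI>> pq;
      pq.push({0.0, s});
      while (!pq.empty()) {
        auto [du, u] = pq.top();
        pq.pop();
        if (du > dist[u] + 1e-12) continue;
        for (int k = 0; k < (int)g[u].size(); ++k) {
          const Edge& e = g[u][k];
          if (e.cap <= EPS) continue;
          double nd = du + e.cost + pot[u] - pot[e.to];
          if (nd < dist[e.to] - 1e-12) {
            dist[e.to] = nd;
            pv[e.to] = u;
            pe[e.to] = k;
            pq.push({nd, e.to});
          }
        }
      }
      if (dist[t] == INF) break;
      for (int u = 0; u < n_nodes; ++u) {
        if (dist[u] < INF) pot[u] += dist[u];
      }
      double push = INF;
      for (int u = t; u != s; u = pv[u]) {
        push = std::min(push, g[pv[u]][pe[u]].cap);
      }
      for (int u = t; u != s; u = pv[u]) {
        Edge& e = g[pv[u]][pe[u]];
        e.cap -= push;
        g[u][e.rev].cap += push;
        cost += push * e.cost;
      }
      flow += push;
    }
    return {flow, cost};
  }
};

struct Problem {
  int n, m;
  const double* cost; // n x m, column-major (R layout)
  std::vector<double> d;
  std::vector<double> cu;  // per-unit cost, n x m column-major
  std::vector<double> caps;

  double C(int i, int j) const { return cost[j * n + i]; }
  double CU(int i, int j) const { return cu[j * n + i]; }
};

struct Search {
  const Problem& P;
  std::vector<int> forced;   // site per facility, -1 if free
  std::vector<double> resid;
  double forced_cost;
  double best_obj;
  std::vector<int> best_assign;
  long nodes;
  long max_nodes;
  bool aborted;
  double root_lb = -INF;

  // scratch
  std::vector<double> load;
  std::vector<int> assign_try;

  Search(const Problem& p, double upper, long mn)
      : P(p), forced(p.n, -1), resid(p.caps), forced_cost(0.0),
        best_obj(upper), nodes(0), max_nodes(mn), aborted(false),
        load(p.m), assign_try(p.n) {}

  // one Lagrangian evaluation at prices v: fills assign_try/load, returns
  // the bound; assign_try[i] = priced argmin for free facilities
  double evaluate(const std::vector<double>& v) {
    double L = forced_cost;
    std::fill(load.begin(), load.end(), 0.0);
    for (int i = 0; i < P.n; ++i) {
      if (forced[i] >= 0) continue;
      double bestc = INF;
      int bestj = -1;
      for (int j = 0; j < P.m; ++j) {
        if (resid[j] < P.d[i] - EPS) continue;
        double c = P.CU(i, j) + v[j];
        if (c < bestc - 1e-15 ||
            (c < bestc + 1e-15 && (bestj < 0 || j < bestj))) {
          bestc = c;
          bestj = j;
        }
      }
      if (bestj < 0) return INF; // facility cannot be placed at this node
      assign_try[i] = bestj;
      load[bestj] += P.d[i];
      L += P.d[i] * bestc;
    }
    for (int j = 0; j < P.m; ++j) L -= v[j] * std::max(resid[j], 0.0);
    return L;
  }

  // greedy repair of the current assign_try into an integral incumbent
  void repair() {
    std::vector<double> res2(resid);
    std::vector<int> asg(forced);
    double obj = forced_cost;
    std::vector<int> later;
    for (int i = 0; i < P.n; ++i) {
      if (forced[i] >= 0) continue;
      int j = assign_try[i];
      if (res2[j] >= P.d[i] - EPS) {
        asg[i] = j;
        res2[j] -= P.d[i];
        obj += P.C(i, j);
      } else {
        later.push_back(i);
      }
    }
    std::sort(later.begin(), later.end(), [&](int a, int b) {
      if (P.d[a] != P.d[b]) return P.d[a] > P.d[b];
      return a < b;
    });
    for (int i : later) {
      int jb = -1;
      double cb = INF;
      for (int j = 0; j < P.m; ++j) {
        if (res2[j] < P.d[i] - EPS) continue;
        if (P.C(i, j) < cb) { cb = P.C(i, j); jb = j; }
      }
      if (jb < 0) return;
      asg[i] = jb;
      res2[jb] -= P.d[i];
      obj += cb;
    }
    if (obj < best_obj * 1.005 + EPS) local_search(asg, res2, obj);
    if (obj < best_obj - EPS) {
      best_obj = obj;
      best_assign = asg;
    }
  }

  // first-improvement move/swap passes until a local optimum
  void local_search(std::vector<int>& asg, std::vector<double>& res2,
                    double& obj) {
    bool improved = true;
    int guard = 0;
    while (improved && ++guard < 60) {
      improved = false;
      // single-facility moves
      for (int i = 0; i < P.n; ++i) {
        if (forced[i] >= 0) continue;
        int j0 = asg[i];
        for (int j = 0; j < P.m; ++j) {
          if (j == j0 || res2[j] < P.d[i] - EPS) continue;
          if (P.C(i, j) < P.C(i, j0) - 1e-9) {
            res2[j0] += P.d[i];
            res2[j] -= P.d[i];
            obj += P.C(i, j) - P.C(i, j0);
            asg[i] = j;
            j0 = j;
            improved = true;
          }
        }
      }
      // pairwise swaps
      for (int a = 0; a < P.n; ++a) {
        if (forced[a] >= 0) continue;
        for (int b = a + 1; b < P.n; ++b) {
          if (forced[b] >= 0) continue;
          int ja = asg[a], jb = asg[b];
          if (ja == jb) continue;
          double delta = P.C(a, jb) + P.C(b, ja) - P.C(a, ja) - P.C(b, jb);
          if (delta >= -1e-9) continue;
          if (res2[jb] + P.d[b] < P.d[a] - EPS) continue;
          if (res2[ja] + P.d[a] < P.d[b] - EPS) continue;
          res2[ja] += P.d[a] - P.d[b];
          res2[jb] += P.d[b] - P.d[a];
          asg[a] = jb;
          asg[b] = ja;
          obj += delta;
          improved = true;
        }
      }
    }
  }

  void dfs(std::vector<double> v, int iters) {
    if (aborted) return;
    if (max_nodes > 0 && nodes >= max_nodes) { aborted = true; return; }
    ++nodes;

    bool any_free = false;
    for (int i = 0; i < P.n; ++i) {
      if (forced[i] < 0) { any_free = true; break; }
    }
    if (!any_free) {
      if (forced_cost < best_obj - EPS) {
        best_obj = forced_cost;
        best_assign = forced;
      }
      return;
    }

    // subgradient ascent on the capacity prices, keeping the best bound
    // and the first feasible (= integral) pricing met along the way
    double bound = -INF;
    std::vector<double> v_best(v);
    for (int t = 0; t < iters; ++t) {
      double L = evaluate(v);
      if (L == INF) return; // infeasible node
      if (L > bound) { bound = L; v_best = v; }
      if (bound >= best_obj - EPS) return;

      double gnorm2 = 0.0;
      bool feas = true;
      for (int j = 0; j < P.m; ++j) {
        double g = load[j] - std::max(resid[j], 0.0);
        if (g > EPS) feas = false;
        gnorm2 += g * g;
      }
      if (feas) { // priced assignment respects every capacity: integral
        double obj = forced_cost;
        for (int i = 0; i < P.n; ++i) {
          if (forced[i] < 0) obj += P.C(i, assign_try[i]);
        }
        if (obj < best_obj - EPS) {
          best_obj = obj;
          best_assign = forced;
          for (int i = 0; i < P.n; ++i) {
            if (forced[i] < 0) best_assign[i] = assign_try[i];
          }
        }
        if (bound >= best_obj - EPS) return;
      }
      if (gnorm2 < 1e-18) break;
      double target = best_obj < INF / 2 ? best_obj : bound + 1.0;
      double step = 0.7 * std::max(target - L, 1e-6) / gnorm2;
      for (int j = 0; j < P.m; ++j) {
        double g = load[j] - std::max(resid[j], 0.0);
        v[j] = std::max(0.0, v[j] + step * g);
      }
    }

    // final evaluation at the best prices to define branching
    double L = evaluate(v_best);
    if (L == INF || L >= best_obj - EPS) return;
    repair();
    if (L >= best_obj - EPS) return;

    // branch facility: among facilities priced onto overloaded sites,
    // pick the one whose second-best priced option costs most extra
    // (max regret) -- its children separate the bound fastest
    int bi = -1;
    double best_regret = -1.0;
    for (int i = 0; i < P.n; ++i) {
      if (forced[i] >= 0) continue;
      int j0 = assign_try[i];
      if (load[j0] <= std::max(resid[j0], 0.0) + EPS) continue;
      double c1 = INF, c2 = INF;
      for (int j = 0; j < P.m; ++j) {
        if (resid[j] < P.d[i] - EPS) continue;
        double c = P.CU(i, j) + v_best[j];
        if (c < c1) { c2 = c1; c1 = c; }
        else if (c < c2) { c2 = c; }
      }
      double regret = (c2 == INF ? 1e12 : P.d[i] * (c2 - c1));
      if (regret > best_regret) { best_regret = regret; bi = i; }
    }
    if (bi < 0) return; // priced assignment feasible: handled above

    // children: force bi onto each feasible site in priced-cost order,
    // pruning children by the reduced-cost bound
    // L_child(v) = L(v) + d_i (cu_ij + v_j - u_i)
    double u_i = INF;
    for (int j = 0; j < P.m; ++j) {
      if (resid[j] < P.d[bi] - EPS) continue;
      u_i = std::min(u_i, P.CU(bi, j) + v_best[j]);
    }
    std::vector<std::pair<double, int>> kids;
    for (int j = 0; j < P.m; ++j) {
      if (resid[j] < P.d[bi] - EPS) continue;
      kids.push_back({P.CU(bi, j) + v_best[j], j});
    }
    std::sort(kids.begin(), kids.end());
    for (auto& kv : kids) {
      int j = kv.second;
      double child_lb = L + P.d[bi] * (kv.first - u_i);
      if (child_lb >= best_obj - EPS) break; // kids sorted: rest are worse
      forced[bi] = j;
      resid[j] -= P.d[bi];
      forced_cost += P.C(bi, j);
      dfs(v_best, std::max(4, iters / 4));
      forced_cost -= P.C(bi, j);
      resid[j] += P.d[bi];
      forced[bi] = -1;
      if (aborted) return;
    }
  }
};

} // namespace

// [[Rcpp::export]]
List lp_bound_cpp(NumericMatrix cost, NumericVector d, NumericVector caps) {
  int n = cost.nrow(), m = cost.ncol();
  int S = 0, T = n + m + 1;
  MCMF net(n + m + 2);
  double supply = 0.0;
  for (int i = 0; i < n; ++i) {
    net.add_edge(S, 1 + i, d[i], 0.0);
    supply += d[i];
    bool any = false;
    for (int j = 0; j < m; ++j) {
      if (caps[j] < d[i] - EPS) continue;
      double cu = d[i] > 0 ? cost(i, j) / d[i] : 0.0;
      net.add_edge(1 + i, 1 + n + j, d[i], cu);
      any = true;
    }
    if (!any) return List::create(_["feasible"] = false);
  }
  for (int j = 0; j < m; ++j) net.add_edge(1 + n + j, T, caps[j], 0.0);
  auto [flow, lp_cost] = net.run(S, T);
  if (flow < supply - 1e-6) return List::create(_["feasible"] = false);
  NumericVector v(m);
  for (int j = 0; j < m; ++j) {
    v[j] = std::max(0.0, net.pot[T] - net.pot[1 + n + j]);
  }
  return List::create(_["feasible"] = true, _["bound"] = lp_cost,
                      _["duals"] = v);
}

// [[Rcpp::export]]
List bb_assign_cpp(NumericMatrix cost, NumericVector d, NumericVector caps,
                   double upper, long max_nodes = -1,
                   Nullable<NumericVector> v_init = R_NilValue,
                   int pre_iters = 25) {
  Problem P;
  P.n = cost.nrow();
  P.m = cost.ncol();
  P.cost = cost.begin();
  P.d.assign(d.begin(), d.end());
  P.caps.assign(caps.begin(), caps.end());
  P.cu.resize((size_t)P.n * P.m);
  for (int j = 0; j < P.m; ++j) {
    for (int i = 0; i < P.n; ++i) {
      P.cu[(size_t)j * P.n + i] = P.d[i] > 0 ? P.C(i, j) / P.d[i] : 0.0;
    }
  }

  Search search(P, upper, max_nodes);

  // cheap pre-phase: refine supplied dual prices by subgradient; if the
  // Lagrangian bound already clears `upper`, the subset is pruned without
  // paying for the exact LP
  std::vector<double> v0(P.m, 0.0);
  if (v_init.isNotNull() && upper < INF / 2) {
    NumericVector vi(v_init);
    std::vector<double> v(vi.begin(), vi.end());
    double bound = -INF;
    for (int t = 0; t < pre_iters; ++t) {
      double L = search.evaluate(v);
      if (L == INF) {
        return List::create(_["feasible"] = false, _["nodes"] = 0L,
                            _["proven"] = true, _["root_lb"] = R_PosInf);
      }
      bound = std::max(bound, L);
      if (bound >= upper - EPS) {
        return List::create(_["feasible"] = false, _["nodes"] = 0L,
                            _["proven"] = true, _["root_lb"] = bound);
      }
      double gnorm2 = 0.0;
      for (int j = 0; j < P.m; ++j) {
        double g = search.load[j] - std::max(P.caps[j], 0.0);
        gnorm2 += g * g;
      }
      if (gnorm2 < 1e-18) break;
      double step = 0.7 * std::max(upper - L, 1e-6) / gnorm2;
      for (int j = 0; j < P.m; ++j) {
        double g = search.load[j] - std::max(P.caps[j], 0.0);
        v[j] = std::max(0.0, v[j] + step * g);
      }
    }
  }

  // root transportation LP: exact bound, dual prices, repair incumbent
  {
    int S = 0, T = P.n + P.m + 1;
    MCMF net(P.n + P.m + 2);
    double supply = 0.0;
    bool ok = true;
    for (int i = 0; i < P.n; ++i) {
      net.add_edge(S, 1 + i, P.d[i], 0.0);
      supply += P.d[i];
      bool any = false;
      for (int j = 0; j < P.m; ++j) {
        if (P.caps[j] < P.d[i] - EPS) continue;
        net.add_edge(1 + i, 1 + P.n + j, P.d[i], P.CU(i, j));
        any = true;
      }
      if (!any) ok = false;
    }
    for (int j = 0; j < P.m; ++j) {
      net.add_edge(1 + P.n + j, T, P.caps[j], 0.0);
    }
    if (!ok) {
      return List::create(_["feasible"] = false, _["nodes"] = 0L,
                          _["proven"] = true, _["root_lb"] = R_PosInf);
    }
    auto [flow, lp_cost] = net.run(S, T);
    if (flow < supply - 1e-6) {
      return List::create(_["feasible"] = false, _["nodes"] = 0L,
                          _["proven"] = true, _["root_lb"] = R_PosInf);
    }
    // dual site prices v_j = pot[T] - pot[site_j], clamped at zero
    for (int j = 0; j < P.m; ++j) {
      v0[j] = std::max(0.0, net.pot[T] - net.pot[1 + P.n + j]);
    }
    // LP-guided incumbent: each facility to its largest-flow site, then
    // greedy repair of capacity violations
    for (int i = 0; i < P.n; ++i) {
      int jmax = -1;
      double fmax = -1.0;
      for (const Edge& e : net.g[1 + i]) {
        if (e.to == S) continue;
        double f = net.g[e.to][e.rev].cap;
        if (f > fmax) { fmax = f; jmax = e.to - 1 - P.n; }
      }
      search.assign_try[i] = jmax < 0 ? 0 : jmax;
    }
    search.repair();
    search.root_lb = lp_cost;
  }
  search.dfs(v0, 60);
  if (search.best_assign.empty() || search.best_obj >= upper - EPS) {
    return List::create(_["feasible"] = false, _["nodes"] = search.nodes,
                        _["proven"] = !search.aborted,
                        _["root_lb"] = search.root_lb);
  }
  IntegerVector out(P.n);
  for (int i = 0; i < P.n; ++i) out[i] = search.best_assign[i] + 1;
  return List::create(_["feasible"] = true,
                      _["objective"] = search.best_obj,
                      _["assignment"] = out,
                      _["nodes"] = search.nodes,
                      _["root_lb"] = search.root_lb,
                      _["proven"] = !search.aborted);
}
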