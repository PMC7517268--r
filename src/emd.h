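#ifndef SCHOOLPHI_EMD_H
#define SCHOOLPHI_EMD_H

// Exact minimum-cost transport between two non-negative mass vectors with
// equal totals (demand is rescaled to the supply total to absorb
// floating-point rounding in normalised distributions).  Successive
// shortest augmenting paths with Johnson potentials: exact for real
// masses, and at most O(n + m) augmentations in practice because nearly
// every augmentation exhausts a supply or a demand bin.
//
// Header-only template so the cost functor inlines; the hot paths call
// this hundreds of thousands of times on <= 64-bin distributions.

#include <algorithm>
#include <cmath>
#include <limits>
#include <stdexcept>
#include <vector>

namespace schoolphi {

const double MASS_EPS = 1e-12;

template <typename Cost>
double transport_min_cost(const std::vector<double>& supply,
                          const std::vector<double>& demand,
                          const Cost& cost) {
  static thread_local std::vector<int> src_idx, snk_idx, parent;
  static thread_local std::vector<double> sup, dem, rest_s, rest_t, pot, dist,
      flow, cmat;
  static thread_local std::vector<char> done;

  src_idx.clear(); snk_idx.clear(); sup.clear(); dem.clear();
  for (std::size_t i = 0; i < supply.size(); ++i)
    if (supply[i] > MASS_EPS) { src_idx.push_back((int)i); sup.push_back(supply[i]); }
  for (std::size_t j = 0; j < demand.size(); ++j)
    if (demand[j] > MASS_EPS) { snk_idx.push_back((int)j); dem.push_back(demand[j]); }
  if (src_idx.empty() || snk_idx.empty()) return 0.0;

  double total_sup = 0.0, total_dem = 0.0;
  for (double v : sup) total_sup += v;
  for (double v : dem) total_dem += v;
  const double scale = total_sup / total_dem;
  for (double& v : dem) v *= scale;

  const int n = (int)sup.size(), m = (int)dem.size();
  const int V = n + m;  // nodes: 0..n-1 sources, n..V-1 sinks
  flow.assign((std::size_t)n * m, 0.0);
  cmat.resize((std::size_t)n * m);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < m; ++j)
      cmat[(std::size_t)i * m + j] = cost(src_idx[i], snk_idx[j]);
  rest_s = sup; rest_t = dem;
  pot.assign(V, 0.0);
  const double INF = std::numeric_limits<double>::infinity();

  double remaining = total_sup;
  const double stop = 1e-12 * std::max(1.0, total_sup);
  long iter = 0;
  const long max_iter = 64L * (V + 2) * (V + 2);

  while (remaining > stop) {
    if (++iter > max_iter)
      throw std::runtime_error("transport solver failed to converge");
    dist.assign(V, INF);
    parent.assign(V, -1);
    done.assign(V, 0);
    for (int i = 0; i < n; ++i)
      if (rest_s[i] > MASS_EPS) dist[i] = 0.0;
    for (;;) {
      int u = -1; double best = INF;
      for (int v = 0; v < V; ++v)
        if (!done[v] && dist[v] < best) { best = dist[v]; u = v; }
      if (u < 0) break;
      done[u] = 1;
      if (u < n) {  // source -> every sink (forward arcs, infinite capacity)
        const double base = dist[u] + pot[u];
        const double* crow = &cmat[(std::size_t)u * m];
        for (int j = 0; j < m; ++j) {
          const int v = n + j;
          if (done[v]) continue;
          const double nd = base + crow[j] - pot[v];
          if (nd < dist[v] - 1e-15) { dist[v] = nd; parent[v] = u; }
        }
      } else {      // sink -> sources with positive flow (backward arcs)
        const int j = u - n;
        const double base = dist[u] + pot[u];
        for (int i = 0; i < n; ++i) {
          if (done[i] || flow[(std::size_t)i * m + j] <= MASS_EPS) continue;
          const double nd = base - cmat[(std::size_t)i * m + j] - pot[i];
          if (nd < dist[i] - 1e-15) { dist[i] = nd; parent[i] = u; }
        }
      }
    }
    int tstar = -1; double dbest = INF;
    for (int j = 0; j < m; ++j)
      if (rest_t[j] > MASS_EPS && dist[n + j] < dbest) { dbest = dist[n + j]; tstar = n + j; }
    if (tstar < 0)
      throw std::runtime_error("transport solver: no augmenting path");
    for (int v = 0; v < V; ++v)
      pot[v] += (dist[v] < INF) ? std::min(dist[v], dbest) : dbest;
    // Bottleneck along the alternating path.
    double bottleneck = rest_t[tstar - n];
    int v = tstar;
    while (parent[v] >= 0) {
      const int u = parent[v];
      if (v >= n) {
        if (parent[u] < 0) bottleneck = std::min(bottleneck, rest_s[u]);
      } else {
        bottleneck = std::min(bottleneck, flow[(std::size_t)v * m + (u - n)]);
      }
      v = u;
    }
    v = tstar;
    while (parent[v] >= 0) {
      const int u = parent[v];
      if (v >= n) flow[(std::size_t)u * m + (v - n)] += bottleneck;
      else        flow[(std::size_t)v * m + (u - n)] -= bottleneck;
      v = u;
    }
    rest_s[v] -= bottleneck;        // v is the originating source
    rest_t[tstar - n] -= bottleneck;
    remaining -= bottleneck;
  }

  double total = 0.0;
  for (std::size_t e = 0; e < flow.size(); ++e)
    if (flow[e] > MASS_EPS) total += flow[e] * cmat[e];
  return total;
}

inline int popcount_u(unsigned x) {
  int c = 0;
  while (x) { c += x & 1u; x >>= 1; }
  return c;
}

struct HammingCost {
  double operator()(int i, int j) const {
    return (double)popcount_u((unsigned)(i ^ j));
  }
};

inline double hamming_emd_vec(const std::vector<double>& p,
                              const std::vector<double>& q) {
  return transport_min_cost(p, q, HammingCost());
}

}  // namespace schoolphi

#endif
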