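// IIT 3.0 mechanism-level machinery for binary networks of up to 6 nodes.
//
// Conventions (documented package-wide):
//  * states are little-endian: node 0 is the least-significant bit of the
//    integer encoding of a collective state; TPM rows are ordered by that
//    integer, columns give P(node ON at t | previous full state).
//  * the TPM is state-by-node: the full transition probability factorises
//    over nodes (conditional independence).
//  * cause repertoires are Bayesian inversions under a uniform prior on
//    past states, combined multiplicatively across mechanism nodes and
//    renormalised; effect repertoires factorise over purview nodes.
//  * repertoire distances are earth mover's distances with the Hamming
//    ground metric on purview states.
//  * mechanism-level partitions are the standard IIT 3.0 bipartitions of
//    the (mechanism, purview) pair; ties are broken by enumeration order
//    (first minimiser kept).
//  * purview ties at equal phi: larger purview first, then the
//    lexicographically smallest node list.

#include <Rcpp.h>
#include "emd.h"

#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

const double PHI_EPS = 1e-10;  // |phi| below this is treated as zero

inline int popcount(unsigned x) { return schoolphi::popcount_u(x); }

inline int bit(int s, int i) { return (s >> i) & 1; }

// Distribution over the 2^|purview| states of a purview, little-endian in
// the order of the (ascending) purview node list.
typedef std::vector<double> Dist;

struct Net {
  NumericMatrix P;   // 2^k x k
  int k;
  std::vector<int> state;  // current state bits, length k
};

// Extract, from full previous-state integer r, the purview-local state
// index given purview node list (ascending).
inline int project_state(int r, const std::vector<int>& purview) {
  int z = 0;
  for (std::size_t j = 0; j < purview.size(); ++j)
    z |= bit(r, purview[j]) << j;
  return z;
}

Dist effect_rep(const Net& net, const std::vector<int>& mech,
                const std::vector<int>& mstate,
                const std::vector<int>& purview) {
  const int k = net.k, v = (int)purview.size();
  const int nstates = 1 << k;
  // Rows consistent with the clamped mechanism state.
  std::vector<double> p_on(v, 0.0);
  int nrows = 0;
  for (int r = 0; r < nstates; ++r) {
    bool ok = true;
    for (std::size_t a = 0; a < mech.size(); ++a)
      if (bit(r, mech[a]) != mstate[a]) { ok = false; break; }
    if (!ok) continue;
    ++nrows;
    for (int j = 0; j < v; ++j) p_on[j] += net.P(r, purview[j]);
  }
  for (int j = 0; j < v; ++j) p_on[j] /= nrows;
  Dist out(1 << v, 1.0);
  for (int z = 0; z < (1 << v); ++z)
    for (int j = 0; j < v; ++j)
      out[z] *= bit(z, j) ? p_on[j] : 1.0 - p_on[j];
  return out;
}

// Cause repertoire; sets *defined = false when the mechanism state is
// unreachable (zero normaliser).
Dist cause_rep(const Net& net, const std::vector<int>& mech,
               const std::vector<int>& mstate,
               const std::vector<int>& purview, bool* defined) {
  const int k = net.k, v = (int)purview.size();
  const int nstates = 1 << k, nz = 1 << v;
  *defined = true;
  Dist acc(nz, 1.0);
  if (mech.empty()) {
    for (int z = 0; z < nz; ++z) acc[z] = 1.0 / nz;
    return acc;
  }
  for (std::size_t a = 0; a < mech.size(); ++a) {
    Dist ci(nz, 0.0);
    const int i = mech[a];
    for (int r = 0; r < nstates; ++r) {
      const double w = mstate[a] ? net.P(r, i) : 1.0 - net.P(r, i);
      ci[project_state(r, purview)] += w;
    }
    for (int z = 0; z < nz; ++z) acc[z] *= ci[z];
  }
  double tot = 0.0;
  for (double x : acc) tot += x;
  if (tot <= 0.0) { *defined = false; return Dist(nz, 0.0); }
  for (double& x : acc) x /= tot;
  return acc;
}

double hamming_emd(const Dist& p, const Dist& q) {
  return schoolphi::hamming_emd_vec(p, q);
}

std::vector<int> mask_to_nodes(unsigned mask, const std::vector<int>& universe) {
  std::vector<int> out;
  for (std::size_t a = 0; a < universe.size(); ++a)
    if (mask & (1u << a)) out.push_back(universe[a]);
  return out;
}

std::vector<int> mask_to_states(unsigned mask, const std::vector<int>& values) {
  std::vector<int> out;
  for (std::size_t a = 0; a < values.size(); ++a)
    if (mask & (1u << a)) out.push_back(values[a]);
  return out;
}

struct PhiPartition {
  double phi;
  bool has_partition;
  unsigned mech0_mask, purv0_mask;  // masks relative to mech / purview lists
};

// Minimum-information partition of a single (mechanism, purview) pair.
PhiPartition small_phi_dir(const Net& net, const std::vector<int>& mech,
                           const std::vector<int>& mstate,
                           const std::vector<int>& purview, bool effect) {
  PhiPartition res;
  res.phi = 0.0;
  res.has_partition = false;
  res.mech0_mask = res.purv0_mask = 0u;
  const int m = (int)mech.size(), v = (int)purview.size();

  bool defined = true;
  Dist unpart = effect ? effect_rep(net, mech, mstate, purview)
                       : cause_rep(net, mech, mstate, purview, &defined);
  if (!defined) return res;  // unreachable mechanism state: phi_cause = 0

  // Positions of purview-part nodes within the full purview ordering.
  double best = -1.0;
  unsigned best_m0 = 0, best_p0 = 0;
  const int nz = 1 << v;

  // Unordered mechanism bipartitions (mech[0] pinned to part 1) crossed
  // with ordered purview bipartitions; a part must be non-degenerate.
  for (unsigned mmask = 0; mmask < (1u << m); ++mmask) {
    if (m > 0 && (mmask & 1u)) continue;  // pin mech[0] in part 1
    const unsigned m0 = mmask, m1 = ((1u << m) - 1u) & ~mmask;
    for (unsigned pmask = 0; pmask < (1u << v); ++pmask) {
      const unsigned p0 = pmask, p1 = ((1u << v) - 1u) & ~pmask;
      const int n_m0 = popcount(m0), n_m1 = popcount(m1);
      const int n_p0 = popcount(p0), n_p1 = popcount(p1);
      if ((n_m0 == 0 && n_p0 == 0) || (n_m1 == 0 && n_p1 == 0)) continue;

      // Part repertoires over their own purview pieces.
      std::vector<int> mech0 = mask_to_nodes(m0, mech);
      std::vector<int> mech1 = mask_to_nodes(m1, mech);
      std::vector<int> ms0 = mask_to_states(m0, mstate);
      std::vector<int> ms1 = mask_to_states(m1, mstate);
      std::vector<int> purv0 = mask_to_nodes(p0, purview);
      std::vector<int> purv1 = mask_to_nodes(p1, purview);

      Dist r0, r1;
      bool def0 = true, def1 = true;
      if (n_p0 > 0)
        r0 = effect ? effect_rep(net, mech0, ms0, purv0)
                    : cause_rep(net, mech0, ms0, purv0, &def0);
      if (n_p1 > 0)
        r1 = effect ? effect_rep(net, mech1, ms1, purv1)
                    : cause_rep(net, mech1, ms1, purv1, &def1);
      if (!def0 || !def1) continue;  // cannot happen if unpart is defined

      // Assemble the product distribution over the full purview.
      Dist part(nz, 1.0);
      for (int z = 0; z < nz; ++z) {
        double val = 1.0;
        if (n_p0 > 0) {
          int z0 = 0, a = 0;
          for (int j = 0; j < v; ++j)
            if (p0 & (1u << j)) { z0 |= bit(z, j) << a; ++a; }
          val *= r0[z0];
        }
        if (n_p1 > 0) {
          int z1 = 0, a = 0;
          for (int j = 0; j < v; ++j)
            if (p1 & (1u << j)) { z1 |= bit(z, j) << a; ++a; }
          val *= r1[z1];
        }
        part[z] = val;
      }

      // Total variation is a lower bound on the Hamming EMD (distinct
      // states are at ground distance >= 1), so partitions that cannot
      // beat the incumbent minimum are skipped without solving the
      // transport problem.  A pruned partition can neither beat nor tie
      // the incumbent, so the first-minimiser tie rule is unaffected.
      double tv = 0.0;
      for (int z = 0; z < nz; ++z) tv += std::fabs(unpart[z] - part[z]);
      tv *= 0.5;
      if (best >= 0.0 && tv > best + 1e-14) continue;

      const double d = hamming_emd(unpart, part);
      if (best < 0.0 || d < best - 1e-15) {
        best = d;
        best_m0 = m0;
        best_p0 = p0;
      }
      if (best <= 1e-15) break;  // cannot improve on zero; first wins ties
    }
    if (best >= 0.0 && best <= 1e-15) break;
  }

  if (best < 0.0) return res;  // no admissible partition (cannot happen)
  res.phi = best < PHI_EPS ? 0.0 : best;
  res.has_partition = true;
  res.mech0_mask = best_m0;
  res.purv0_mask = best_p0;
  return res;
}

// TRUE when purview `a` wins the tie against incumbent `b`:
// larger purview first, then lexicographically smaller node list.
bool purview_beats(const std::vector<int>& a, const std::vector<int>& b) {
  if (a.size() != b.size()) return a.size() > b.size();
  for (std::size_t i = 0; i < a.size() && i < b.size(); ++i) {
    if (a[i] != b[i]) return a[i] < b[i];
  }
  return false;
}

struct DirResult {
  double phi;
  std::vector<int> purview;
  Dist rep;
  bool any;
};

// phi^max over all non-empty purviews for one direction.
DirResult max_over_purviews(const Net& net, const std::vector<int>& mech,
                            const std::vector<int>& mstate, bool effect) {
  DirResult best;
  best.phi = -1.0;
  best.any = false;
  for (unsigned pv = 1; pv < (1u << net.k); ++pv) {
    std::vector<int> purview;
    for (int j = 0; j < net.k; ++j)
      if (pv & (1u << j)) purview.push_back(j);
    PhiPartition r = small_phi_dir(net, mech, mstate, purview, effect);
    const bool tie = best.any && std::fabs(r.phi - best.phi) <= PHI_EPS;
    if (!best.any || r.phi > best.phi + PHI_EPS ||
        (tie && purview_beats(purview, best.purview))) {
      bool defined = true;
      best.phi = r.phi;
      best.purview = purview;
      best.rep = effect ? effect_rep(net, mech, mstate, purview)
                        : cause_rep(net, mech, mstate, purview, &defined);
      best.any = true;
    }
  }
  return best;
}

Net make_net(const NumericMatrix& P, const IntegerVector& state) {
  Net net;
  net.P = P;
  net.k = P.ncol();
  if (P.nrow() != (1 << net.k))
    stop("TPM must have 2^k rows for k columns");
  if (state.size() != net.k) stop("state must have one bit per node");
  net.state = std::vector<int>(state.begin(), state.end());
  return net;
}

std::vector<int> as_nodes0(const IntegerVector& nodes, int k) {
  std::vector<int> out(nodes.begin(), nodes.end());
  for (int x : out)
    if (x < 0 || x >= k) stop("node index out of range");
  for (std::size_t i = 1; i < out.size(); ++i)
    if (out[i] <= out[i - 1]) stop("node subsets must be strictly increasing");
  return out;
}

}  // namespace

// [[Rcpp::export]]
NumericVector cpp_effect_repertoire(NumericMatrix P, IntegerVector state,
                                    IntegerVector mechanism,
                                    IntegerVector purview) {
  Net net = make_net(P, state);
  std::vector<int> mech = as_nodes0(mechanism, net.k);
  std::vector<int> purv = as_nodes0(purview, net.k);
  std::vector<int> mstate;
  for (int i : mech) mstate.push_back(net.state[i]);
  Dist d = effect_rep(net, mech, mstate, purv);
  return NumericVector(d.begin(), d.end());
}

// [[Rcpp::export]]
List cpp_cause_repertoire(NumericMatrix P, IntegerVector state,
                          IntegerVector mechanism, IntegerVector purview) {
  Net net = make_net(P, state);
  std::vector<int> mech = as_nodes0(mechanism, net.k);
  std::vector<int> purv = as_nodes0(purview, net.k);
  std::vector<int> mstate;
  for (int i : mech) mstate.push_back(net.state[i]);
  bool defined = true;
  Dist d = cause_rep(net, mech, mstate, purv, &defined);
  return List::create(_["distribution"] = NumericVector(d.begin(), d.end()),
                      _["defined"] = defined);
}

// [[Rcpp::export]]
List cpp_small_phi(NumericMatrix P, IntegerVector state,
                   IntegerVector mechanism, IntegerVector purview,
                   bool effect) {
  Net net = make_net(P, state);
  std::vector<int> mech = as_nodes0(mechanism, net.k);
  std::vector<int> purv = as_nodes0(purview, net.k);
  std::vector<int> mstate;
  for (int i : mech) mstate.push_back(net.state[i]);
  PhiPartition r = small_phi_dir(net, mech, mstate, purv, effect);
  List part = R_NilValue;
  if (r.has_partition) {
    part = List::create(
        _["mechanism_part1"] = wrap(mask_to_nodes(r.mech0_mask, mech)),
        _["purview_part1"] = wrap(mask_to_nodes(r.purv0_mask, purv)),
        _["mechanism_part2"] =
            wrap(mask_to_nodes(~r.mech0_mask & ((1u << mech.size()) - 1u), mech)),
        _["purview_part2"] =
            wrap(mask_to_nodes(~r.purv0_mask & ((1u << purv.size()) - 1u), purv)));
  }
  return List::create(_["phi"] = r.phi, _["partition"] = part);
}

// [[Rcpp::export]]
List cpp_concept(NumericMatrix P, IntegerVector state, IntegerVector mechanism) {
  Net net = make_net(P, state);
  std::vector<int> mech = as_nodes0(mechanism, net.k);
  std::vector<int> mstate;
  for (int i : mech) mstate.push_back(net.state[i]);
  DirResult ca = max_over_purviews(net, mech, mstate, false);
  DirResult ef = max_over_purviews(net, mech, mstate, true);
  const double phi = std::min(ca.phi, ef.phi);
  return List::create(
      _["mechanism"] = wrap(mech), _["phi"] = phi < PHI_EPS ? 0.0 : phi,
      _["phi_cause"] = ca.phi, _["phi_effect"] = ef.phi,
      _["cause_purview"] = wrap(ca.purview),
      _["effect_purview"] = wrap(ef.purview),
      _["cause_rep"] = NumericVector(ca.rep.begin(), ca.rep.end()),
      _["effect_rep"] = NumericVector(ef.rep.begin(), ef.rep.end()),
      _["exists"] = phi > PHI_EPS);
}

// All concepts of the (already conditioned) k-node system in `state`.
// [[Rcpp::export]]
List cpp_constellation(NumericMatrix P, IntegerVector state) {
  Net net = make_net(P, state);
  List out;
  for (unsigned mm = 1; mm < (1u << net.k); ++mm) {
    IntegerVector mech;
    for (int i = 0; i < net.k; ++i)
      if (mm & (1u << i)) mech.push_back(i);
    List cp = cpp_concept(P, state, mech);
    if (as<bool>(cp["exists"])) out.push_back(cp);
  }
  return out;
}

// Extended EMD between two constellations.  cause/effect repertoires are
// passed expanded over the full subsystem state space, one column per
// concept; the last column of each matrix is the null concept.  Supplies
// are the phi values of constellation 1 plus sum(phi2) on the null
// column; demands the phi values of constellation 2 plus sum(phi1).
// [[Rcpp::export]]
double cpp_constellation_distance(NumericMatrix cause1, NumericMatrix effect1,
                                  NumericVector phi1, NumericMatrix cause2,
                                  NumericMatrix effect2, NumericVector phi2) {
  const int n1 = cause1.ncol() - 1, n2 = cause2.ncol() - 1;
  const int ns = cause1.nrow();
  if (n1 == 0 && n2 == 0) return 0.0;
  std::vector<double> cost((n1 + 1) * (n2 + 1), 0.0);
  Dist pa(ns), pb(ns);
  for (int a = 0; a <= n1; ++a) {
    for (int b = 0; b <= n2; ++b) {
      if (a == n1 && b == n2) continue;  // null -> null is free
      double d = 0.0;
      for (int pass = 0; pass < 2; ++pass) {
        const NumericMatrix& m1 = pass == 0 ? cause1 : effect1;
        const NumericMatrix& m2 = pass == 0 ? cause2 : effect2;
        double linf = 0.0;
        for (int s = 0; s < ns; ++s) {
          pa[s] = m1(s, a); pb[s] = m2(s, b);
          linf = std::max(linf, std::fabs(pa[s] - pb[s]));
        }
        if (linf > 1e-12) d += hamming_emd(pa, pb);
      }
      cost[a * (n2 + 1) + b] = d;
    }
  }
  double sp1 = 0.0, sp2 = 0.0;
  for (double x : phi1) sp1 += x;
  for (double x : phi2) sp2 += x;
  std::vector<double> supply(phi1.begin(), phi1.end());
  supply.push_back(sp2);
  std::vector<double> demand(phi2.begin(), phi2.end());
  demand.push_back(sp1);
  return schoolphi::transport_min_cost(
      supply, demand,
      [&](int i, int j) { return cost[i * (n2 + 1) + j]; });
}

// [[Rcpp::export]]
double cpp_hamming_emd(NumericVector p, NumericVector q) {
  if (p.size() != q.size()) stop("distributions must have equal length");
  Dist a(p.begin(), p.end()), b(q.begin(), q.end());
  return hamming_emd(a, b);
}
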