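#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Alignment state between webs A (nA species) and B (nB species).
//
// The smaller side is padded with dummy species so that a state is a
// bijection p over m = max(nA, nB) indices: p[ia] = ib, where ia < nA is a
// real A-species (dummy otherwise) and ib < nB a real B-species. A real
// species mapped to a dummy partner is unpaired.
//
// Costs:
//  kind 0 (simple): sum over real-real pairs of (1 - rho) plus epsilon per
//    unpaired real species on either side.
//  kind 1 (neighborhood): each real-real pairing x = (a, b) contributes
//    sum over pairings (alpha, beta) joining a neighbor of a to a neighbor
//    of b of (1 - rho(alpha, beta)), plus epsilon * (u_a + u_b) where u_a
//    counts neighbors of a not paired to any neighbor of b (and vice
//    versa). An unpaired real species contributes epsilon * its degree.
//    With two neighbor systems (in- and out-neighbors separately) the
//    contribution is evaluated per system and summed; the default is a
//    single system holding the union of in- and out-neighbors.
//
// Swap moves are evaluated incrementally: the two swapped pairings are
// recomputed in full, and every other affected pairing is adjusted at the
// level of the individual neighbor-pair terms that change, using boolean
// adjacency tables for O(1) neighbor-membership tests. The R-level
// reference implementation of the same costs is the correctness oracle.

struct Aligner {
  int nA, nB, m, kind, ns;
  double eps;
  NumericMatrix rho;
  // per system: neighbor lists (0-based), reverse lists (revA[s][j] holds
  // the i with j in nbA[s][i]; equal to nbA for the symmetric union
  // system), and boolean membership tables
  std::vector<std::vector<std::vector<int> > > nbA, nbB, revA, revB;
  std::vector<std::vector<char> > adjA, adjB;
  std::vector<int> p, q;  // mapping and inverse over m indices

  Aligner(NumericMatrix rho_, List nbA_, List nbB_, double eps_, int kind_)
      : kind(kind_), eps(eps_), rho(rho_) {
    nA = rho.nrow();
    nB = rho.ncol();
    m = std::max(nA, nB);
    ns = nbA_.size();
    nbA.resize(ns); nbB.resize(ns);
    revA.resize(ns); revB.resize(ns);
    adjA.resize(ns); adjB.resize(ns);
    for (int s = 0; s < ns; ++s) {
      List la = nbA_[s], lb = nbB_[s];
      nbA[s].resize(nA); nbB[s].resize(nB);
      revA[s].resize(nA); revB[s].resize(nB);
      adjA[s].assign((size_t)nA * nA, 0);
      adjB[s].assign((size_t)nB * nB, 0);
      for (int i = 0; i < nA; ++i) {
        IntegerVector v = la[i];
        for (int t = 0; t < v.size(); ++t) {
          int j = v[t] - 1;
          nbA[s][i].push_back(j);
          revA[s][j].push_back(i);
          adjA[s][(size_t)i * nA + j] = 1;
        }
      }
      for (int i = 0; i < nB; ++i) {
        IntegerVector v = lb[i];
        for (int t = 0; t < v.size(); ++t) {
          int j = v[t] - 1;
          nbB[s][i].push_back(j);
          revB[s][j].push_back(i);
          adjB[s][(size_t)i * nB + j] = 1;
        }
      }
    }
    p.assign(m, 0);
    q.assign(m, 0);
  }

  inline bool nb_of_a(int s, int a, int a2) const {
    return adjA[s][(size_t)a * nA + a2];
  }
  inline bool nb_of_b(int s, int b, int b2) const {
    return adjB[s][(size_t)b * nB + b2];
  }

  void set_state(const std::vector<int>& init) {
    p = init;
    for (int i = 0; i < m; ++i) q[p[i]] = i;
  }

  double contrib(int ia) const {
    const int ib = p[ia];
    const bool ra = ia < nA, rb = ib < nB;
    if (!ra && !rb) return 0.0;
    if (kind == 0) {
      if (ra && rb) return 1.0 - rho(ia, ib);
      return eps;
    }
    double out = 0.0;
    if (ra && !rb) {
      for (int s = 0; s < ns; ++s) out += eps * nbA[s][ia].size();
      return out;
    }
    if (!ra && rb) {
      for (int s = 0; s < ns; ++s) out += eps * nbB[s][ib].size();
      return out;
    }
    for (int s = 0; s < ns; ++s) {
      const std::vector<int>& na = nbA[s][ia];
      const std::vector<int>& nb = nbB[s][ib];
      for (size_t t = 0; t < na.size(); ++t) {
        const int al = na[t], be = p[al];
        if (be < nB && nb_of_b(s, ib, be))
          out += 1.0 - rho(al, be);
        else
          out += eps;  // u_a term
      }
      for (size_t t = 0; t < nb.size(); ++t) {
        const int be = nb[t], al = q[be];
        if (!(al < nA && nb_of_a(s, ia, al))) out += eps;  // u_b term
      }
    }
    return out;
  }

  double full_cost() const {
    double c = 0.0;
    for (int i = 0; i < m; ++i) c += contrib(i);
    return c;
  }

  void apply_swap(int i1, int i2) {
    std::swap(p[i1], p[i2]);
    q[p[i1]] = i1;
    q[p[i2]] = i2;
  }

  // term owned by pairing (c, d): neighbor alpha of c paired (or not) with
  // a neighbor of d under partner b_of_alpha
  inline double g_term(int s, int d, int alpha, int b_alpha) const {
    if (b_alpha < nB && nb_of_b(s, d, b_alpha))
      return 1.0 - rho(alpha, b_alpha);
    return eps;
  }

  // cost change of swapping the partners of a-indices i1 and i2
  double swap_delta(int i1, int i2) {
    const int b1 = p[i1], b2 = p[i2];
    double delta = 0.0;
    // the two swapped pairings, recomputed in full
    const double before = contrib(i1) + contrib(i2);
    apply_swap(i1, i2);
    delta += contrib(i1) + contrib(i2) - before;
    apply_swap(i1, i2);
    if (kind == 0) return delta;
    // other pairings: only terms touching i1, i2 (a side) or b1, b2
    // (b side) change
    for (int s = 0; s < ns; ++s) {
      const int as[2] = { i1, i2 };
      const int newb[2] = { b2, b1 };
      const int oldb[2] = { b1, b2 };
      for (int t = 0; t < 2; ++t) {
        const int al = as[t];
        if (al >= nA) continue;
        const std::vector<int>& v = revA[s][al];  // c with al in N(c)
        for (size_t u = 0; u < v.size(); ++u) {
          const int c = v[u];
          if (c == i1 || c == i2) continue;
          const int d = p[c];
          if (d >= nB) continue;  // unpaired pairing: constant eps * deg
          delta += g_term(s, d, al, newb[t]) - g_term(s, d, al, oldb[t]);
        }
      }
      const int bs[2] = { b1, b2 };
      const int newq[2] = { i2, i1 };
      const int oldq[2] = { i1, i2 };
      for (int t = 0; t < 2; ++t) {
        const int be = bs[t];
        if (be >= nB) continue;
        const std::vector<int>& v = revB[s][be];  // d with be in N(d)
        for (size_t u = 0; u < v.size(); ++u) {
          const int d = v[u];
          const int c = q[d];
          if (c == i1 || c == i2 || c >= nA) continue;
          const bool match_old = oldq[t] < nA && nb_of_a(s, c, oldq[t]);
          const bool match_new = newq[t] < nA && nb_of_a(s, c, newq[t]);
          delta += eps * ((match_new ? 0 : 1) - (match_old ? 0 : 1));
        }
      }
    }
    return delta;
  }

  // first-improvement local search until no improving swap remains
  double polish() {
    for (int pass = 0; pass < 200; ++pass) {
      bool improved = false;
      for (int i1 = 0; i1 < m - 1; ++i1) {
        for (int i2 = i1 + 1; i2 < m; ++i2) {
          if (swap_delta(i1, i2) < -1e-12) {
            apply_swap(i1, i2);
            improved = true;
          }
        }
      }
      if (!improved) break;
    }
    return full_cost();
  }
};

static List state_result(Aligner& al, double cost) {
  IntegerVector map(al.nA);
  for (int i = 0; i < al.nA; ++i)
    map[i] = (al.p[i] < al.nB) ? al.p[i] + 1 : NA_INTEGER;
  return List::create(_["map_ab"] = map, _["cost"] = cost);
}

// [[Rcpp::export]]
double alignment_cost_cpp(NumericMatrix rho, List nbA, List nbB,
                          double epsilon, int cost_kind, IntegerVector state0) {
  Aligner al(rho, nbA, nbB, epsilon, cost_kind);
  std::vector<int> init(state0.begin(), state0.end());
  al.set_state(init);
  return al.full_cost();
}

// [[Rcpp::export]]
List sa_align_cpp(NumericMatrix rho, List nbA, List nbB, double epsilon,
                  int cost_kind, IntegerVector state0, double T0,
                  double cooling, int sweep, int max_stale, double t_min) {
  Aligner al(rho, nbA, nbB, epsilon, cost_kind);
  std::vector<int> init(state0.begin(), state0.end());
  al.set_state(init);
  const int m = al.m;
  double cur = al.full_cost();

  if (T0 <= 0.0) {  // auto-calibration: ~80% acceptance of uphill moves
    double up = 0.0;
    int nup = 0;
    for (int t = 0; t < 200; ++t) {
      int i1 = (int)(unif_rand() * m), i2 = (int)(unif_rand() * m);
      if (i1 >= m) i1 = m - 1;
      if (i2 >= m) i2 = m - 1;
      if (i1 == i2) continue;
      const double d = al.swap_delta(i1, i2);
      if (d > 0) { up += d; ++nup; }
    }
    T0 = (nup > 0) ? (up / nup) / std::log(1.0 / 0.8) : 1.0;
  }

  double T = T0;
  std::vector<int> bestp = al.p;
  double best = cur;
  int stale = 0;
  while (true) {
    bool improved = false;
    for (int s = 0; s < sweep; ++s) {
      int i1 = (int)(unif_rand() * m), i2 = (int)(unif_rand() * m);
      if (i1 >= m) i1 = m - 1;
      if (i2 >= m) i2 = m - 1;
      if (i1 == i2) continue;
      const double d = al.swap_delta(i1, i2);
      if (d <= 0.0 || unif_rand() < std::exp(-d / T)) {
        al.apply_swap(i1, i2);
        cur += d;
        if (cur < best - 1e-12) {
          best = cur;
          bestp = al.p;
          improved = true;
        }
      }
    }
    cur = al.full_cost();  // resync the accumulated cost
    if (cur < best - 1e-12) { best = cur; bestp = al.p; improved = true; }
    stale = improved ? 0 : stale + 1;
    T *= cooling;
    if (best <= 1e-12 || stale >= max_stale || T < t_min) break;
  }
  al.set_state(bestp);
  best = al.polish();
  return state_result(al, best);
}

// [[Rcpp::export]]
List exhaustive_align_cpp(NumericMatrix rho, List nbA, List nbB,
                          double epsilon, int cost_kind) {
  Aligner al(rho, nbA, nbB, epsilon, cost_kind);
  const int m = al.m;
  std::vector<int> perm(m), bestp;
  for (int i = 0; i < m; ++i) perm[i] = i;
  double best = R_PosInf;
  do {
    al.set_state(perm);
    const double c = al.full_cost();
    if (c < best - 1e-12) {
      best = c;
      bestp = perm;
    }
  } while (std::next_permutation(perm.begin(), perm.end()));
  al.set_state(bestp);
  return state_result(al, best);
}
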