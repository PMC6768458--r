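// Simulation kernels: Gillespie direct-method SSA and the synchronous-step
// agent engine.  Both use R's RNG stream so set.seed() governs
// reproducibility.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double wrap01(double v) {  // periodic unit interval
  return v - std::floor(v);
}

static double falling(double n, int a) {
  double out = 1.0;
  for (int c = 0; c < a; ++c) out *= (n - c);
  return out;
}

// Direct-method Gillespie.  `rates` already includes constant-species
// proportion factors; the V power applied is V^(1 - sum(alpha_j)).
// [[Rcpp::export(name = ".ssa_core")]]
List ssa_core(IntegerVector init, NumericVector rates, IntegerMatrix alpha,
              IntegerMatrix stoich, double V, double tmax,
              int max_events, bool record) {
  const int ns = init.size();
  const int nr = rates.size();
  std::vector<double> pref(nr);
  for (int j = 0; j < nr; ++j) {
    int sa = 0;
    for (int i = 0; i < ns; ++i) sa += alpha(i, j);
    pref[j] = rates[j] * std::pow(V, 1.0 - sa);
  }
  std::vector<double> n(ns);
  for (int i = 0; i < ns; ++i) n[i] = init[i];

  std::vector<double> times;
  std::vector<double> states;
  double t = 0.0;
  times.push_back(t);
  for (int i = 0; i < ns; ++i) states.push_back(n[i]);

  std::vector<double> a(nr);
  int events = 0;
  bool truncated = false;
  while (true) {
    double a0 = 0.0;
    for (int j = 0; j < nr; ++j) {
      double aj = pref[j];
      for (int i = 0; i < ns; ++i) {
        int al = alpha(i, j);
        if (al > 0) aj *= falling(n[i], al);
      }
      if (aj < 0) aj = 0;
      a[j] = aj;
      a0 += aj;
    }
    if (a0 <= 0.0) break;
    double tau = R::exp_rand() / a0;
    if (t + tau > tmax) break;
    t += tau;
    double u = unif_rand() * a0;
    int j = 0;
    double acc = a[0];
    while (u > acc && j < nr - 1) acc += a[++j];
    for (int i = 0; i < ns; ++i) n[i] += stoich(i, j);
    ++events;
    if (record) {
      times.push_back(t);
      for (int i = 0; i < ns; ++i) states.push_back(n[i]);
    }
    if (events >= max_events) { truncated = true; break; }
  }
  // closing record at tmax (state persists after the last event)
  double tend = truncated ? t : tmax;
  times.push_back(tend);
  for (int i = 0; i < ns; ++i) states.push_back(n[i]);

  const int nrow = times.size();
  NumericMatrix sm(nrow, ns);
  for (int r = 0; r < nrow; ++r)
    for (int i = 0; i < ns; ++i) sm(r, i) = states[(size_t)r * ns + i];
  return List::create(_["times"] = NumericVector(times.begin(), times.end()),
                      _["states"] = sm,
                      _["events"] = events,
                      _["truncated"] = truncated);
}

// Agent engine.  topo_kind: 0 complete, 1 static adjacency, 2 dynamic
// geometric (correlated random walk on the unit square with periodic
// boundary, adjacency rebuilt each step).
// spont rows: from, to, prob.  inter rows: s_init, s_partner, t_init,
// t_partner, prob (orientation-resolved; probabilities include dt).
// [[Rcpp::export(name = ".agents_core")]]
List agents_core(IntegerVector state0, int topo_kind, List adj,
                 NumericMatrix pos0, double radius, double speed,
                 double sigma_turn, NumericMatrix spont, NumericMatrix inter,
                 int nstates, int nsteps, bool record_positions) {
  const int n = state0.size();
  std::vector<int> state(n);
  for (int i = 0; i < n; ++i) state[i] = state0[i];

  // spontaneous rules grouped by state
  std::vector<std::vector<std::pair<int, double> > > sp(nstates);
  for (int r = 0; r < spont.nrow(); ++r) {
    sp[(int)spont(r, 0)].push_back(
      std::make_pair((int)spont(r, 1), spont(r, 2)));
  }
  // interactive rules grouped by (initiator state, partner state)
  struct IRule { int t1, t2; double p; };
  std::vector<std::vector<IRule> > ir((size_t)nstates * nstates);
  for (int r = 0; r < inter.nrow(); ++r) {
    IRule rule;
    rule.t1 = (int)inter(r, 2);
    rule.t2 = (int)inter(r, 3);
    rule.p = inter(r, 4);
    ir[(size_t)inter(r, 0) * nstates + (size_t)inter(r, 1)].push_back(rule);
  }

  std::vector<std::vector<int> > nbr;
  if (topo_kind == 1) {
    nbr.resize(n);
    for (int i = 0; i < n; ++i) {
      IntegerVector v = adj[i];
      nbr[i].assign(v.begin(), v.end());  // already 0-based
    }
  }

  std::vector<double> px(n), py(n), heading(n);
  if (topo_kind == 2) {
    for (int i = 0; i < n; ++i) {
      px[i] = pos0(i, 0);
      py[i] = pos0(i, 1);
      heading[i] = unif_rand() * 2.0 * M_PI;
    }
    nbr.resize(n);
  }

  IntegerMatrix counts(nsteps + 1, nstates);
  for (int i = 0; i < n; ++i) counts(0, state[i])++;
  NumericMatrix pos_out;
  if (record_positions && topo_kind == 2) {
    pos_out = NumericMatrix(nsteps + 1, 2 * n);
    for (int i = 0; i < n; ++i) {
      pos_out(0, 2 * i) = px[i];
      pos_out(0, 2 * i + 1) = py[i];
    }
  }

  std::vector<int> order(n), updated(n);
  const double r2 = radius * radius;

  for (int step = 1; step <= nsteps; ++step) {
    if (topo_kind == 2) {
      for (int i = 0; i < n; ++i) {
        heading[i] += norm_rand() * sigma_turn;
        px[i] = wrap01(px[i] + speed * std::cos(heading[i]));
        py[i] = wrap01(py[i] + speed * std::sin(heading[i]));
        nbr[i].clear();
      }
      for (int i = 0; i < n; ++i) {
        for (int j = i + 1; j < n; ++j) {
          double dx = std::fabs(px[i] - px[j]);
          double dy = std::fabs(py[i] - py[j]);
          if (dx > 0.5) dx = 1.0 - dx;  // periodic distance
          if (dy > 0.5) dy = 1.0 - dy;
          if (dx * dx + dy * dy <= r2) {
            nbr[i].push_back(j);
            nbr[j].push_back(i);
          }
        }
      }
    }

    for (int i = 0; i < n; ++i) { order[i] = i; updated[i] = 0; }
    for (int i = n - 1; i > 0; --i) {  // Fisher-Yates
      int j = (int)std::floor(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(order[i], order[j]);
    }

    for (int oi = 0; oi < n; ++oi) {
      int a = order[oi];
      if (updated[a]) continue;
      // partner selection (uniform over neighbours)
      int partner = -1;
      if (topo_kind == 0) {
        if (n > 1) {
          int idx = (int)std::floor(unif_rand() * (n - 1));
          if (idx >= n - 1) idx = n - 2;
          partner = (idx >= a) ? idx + 1 : idx;
        }
      } else {
        const std::vector<int> &nb = nbr[a];
        if (!nb.empty()) {
          int idx = (int)std::floor(unif_rand() * nb.size());
          if (idx >= (int)nb.size()) idx = nb.size() - 1;
          partner = nb[idx];
        }
      }
      // one uniform draw over the cumulative candidate list, so each
      // candidate fires with probability exactly rate * dt
      double u = unif_rand();
      double acc = 0.0;
      bool fired = false;
      const std::vector<std::pair<int, double> > &ss = sp[state[a]];
      for (size_t k = 0; k < ss.size(); ++k) {
        acc += ss[k].second;
        if (u < acc) {
          state[a] = ss[k].first;
          updated[a] = 1;
          fired = true;
          break;
        }
      }
      if (!fired && partner >= 0 && !updated[partner]) {
        const std::vector<IRule> &rules =
          ir[(size_t)state[a] * nstates + (size_t)state[partner]];
        for (size_t k = 0; k < rules.size(); ++k) {
          acc += rules[k].p;
          if (u < acc) {
            state[a] = rules[k].t1;
            state[partner] = rules[k].t2;
            updated[a] = 1;
            updated[partner] = 1;
            break;
          }
        }
      }
    }

    for (int s = 0; s < nstates; ++s) counts(step, s) = 0;
    for (int i = 0; i < n; ++i) counts(step, state[i])++;
    if (record_positions && topo_kind == 2) {
      for (int i = 0; i < n; ++i) {
        pos_out(step, 2 * i) = px[i];
        pos_out(step, 2 * i + 1) = py[i];
      }
    }
  }

  List out = List::create(_["counts"] = counts,
                          _["final_state"] = IntegerVector(state.begin(), state.end()));
  if (record_positions && topo_kind == 2) out["positions"] = pos_out;
  return out;
}
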