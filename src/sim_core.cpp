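// Compiled engines for the navigation and two-stage simulations.
//
// These mirror the pure-R per-step operations (agent_step, nav_step,
// softmax_select, draw_reward_location) exactly, including the order in
// which the R random stream is consumed and the use of extended-
// precision accumulators where base R's sum()/cumsum() use them, so that
// both engines produce bit-identical trajectories from the same seed.
// R's RNG is used throughout (unif_rand), so seeds set with set.seed()
// in R govern the compiled runs too.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

struct DualAgent {
  int n;
  bool sr1, sr2;
  double a1p, a1m, a2p, a2m, a_sr, beta, gamma;
  std::vector<double> V1, V2;     // IR values
  std::vector<double> sig1, sig2; // SR matrices, row-major n x n
  std::vector<double> w1, w2;

  void init(int n_states) {
    n = n_states;
    if (sr1) {
      sig1.assign((size_t)n * n, 0.0);
      w1.assign(n, 0.0);
    } else {
      V1.assign(n, 0.0);
    }
    if (sr2) {
      sig2.assign((size_t)n * n, 0.0);
      w2.assign(n, 0.0);
    } else {
      V2.assign(n, 0.0);
    }
  }

  // s is 0-based throughout.
  double sys_value(bool first, int s) const {
    if (first ? sr1 : sr2) {
      const std::vector<double>& sig = first ? sig1 : sig2;
      const std::vector<double>& w = first ? w1 : w2;
      const double* row = sig.data() + (size_t)s * n;
      long double acc = 0.0L; // matches base R sum()'s accumulator
      for (int j = 0; j < n; ++j) acc += row[j] * w[j];
      return (double)acc;
    }
    return first ? V1[s] : V2[s];
  }

  double integrated(int s) const {
    return (sys_value(true, s) + sys_value(false, s)) / 2.0;
  }

  void update_system(bool first, int s, int s_next, double delta,
                     bool terminal, bool update_features) {
    double a_eff = (delta >= 0.0) ? (first ? a1p : a2p) : (first ? a1m : a2m);
    if (first ? sr1 : sr2) {
      std::vector<double>& sig = first ? sig1 : sig2;
      std::vector<double>& w = first ? w1 : w2;
      double* row = sig.data() + (size_t)s * n;
      std::vector<double> pre(row, row + n);
      if (update_features) {
        std::vector<double> succ(n, 0.0);
        if (!terminal) {
          const double* srow = sig.data() + (size_t)s_next * n;
          for (int j = 0; j < n; ++j) succ[j] = gamma * srow[j];
        }
        for (int j = 0; j < n; ++j) {
          double dsr = (j == s ? 1.0 : 0.0) + succ[j] - pre[j];
          row[j] = pre[j] + a_sr * dsr;
        }
      }
      // weight update uses the feature row as updated this step
      for (int j = 0; j < n; ++j) w[j] += a_eff * row[j] * delta;
    } else {
      std::vector<double>& V = first ? V1 : V2;
      V[s] += a_eff * delta;
    }
  }

  // One learning step: shared TD-RPE from integrated pre-update values,
  // then per-system updates.
  double step(int s, int s_next, double reward, bool terminal,
              bool update_features) {
    double v_cur = integrated(s);
    double delta =
        terminal ? (reward - v_cur) : (gamma * integrated(s_next) - v_cur);
    update_system(true, s, s_next, delta, terminal, update_features);
    update_system(false, s, s_next, delta, terminal, update_features);
    return delta;
  }
};

// Softmax draw; consumes one uniform variate. Mirrors softmax_select().
int softmax_pick(const std::vector<double>& vals, double beta) {
  int n = (int)vals.size();
  double m = vals[0];
  for (int i = 1; i < n; ++i)
    if (vals[i] > m) m = vals[i];
  std::vector<double> wts(n);
  long double tot = 0.0L;
  for (int i = 0; i < n; ++i) {
    wts[i] = std::exp(beta * (vals[i] - m));
    tot += wts[i];
  }
  double total = (double)tot;
  double u = unif_rand();
  long double acc = 0.0L; // matches base R cumsum()'s accumulator
  for (int i = 0; i < n; ++i) {
    acc += wts[i] / total;
    if (u <= (double)acc) return i;
  }
  return n - 1;
}

// Categorical draw from a probability row; consumes one uniform variate.
int categorical_pick(const double* p, int n) {
  double u = unif_rand();
  long double acc = 0.0L;
  for (int i = 0; i < n; ++i) {
    acc += p[i];
    if (u <= (double)acc) return i;
  }
  return n - 1;
}

// Mirrors draw_reward_location(): one uniform for the special/normal
// decision, a second only when a normal candidate is picked.
int draw_reward(double p_special, int special, const std::vector<int>& cands) {
  if (unif_rand() < p_special) return special;
  int k = (int)(unif_rand() * 8);
  if (k > 7) k = 7;
  int idx = 0;
  for (int c : cands) {
    if (c == special) continue;
    if (idx == k) return c;
    ++idx;
  }
  return special; // not reachable
}

} // namespace

// [[Rcpp::export]]
List sim_nav_cpp(bool sr1, bool sr2, double a1p, double a1m, double a2p,
                 double a2m, double a_sr, double beta, double gamma,
                 int n_noreward, int epoch_length, int n_epochs,
                 double p_special, IntegerVector candidates,
                 IntegerVector special_order, int reset_period,
                 IntegerVector fixed_order, bool want_snapshot) {
  const int n_side = 5, n_states = 25;
  const int T = n_noreward + epoch_length * n_epochs;
  const bool fixed = fixed_order.size() > 0;

  DualAgent ag;
  ag.sr1 = sr1;
  ag.sr2 = sr2;
  ag.a1p = a1p;
  ag.a1m = a1m;
  ag.a2p = a2p;
  ag.a2m = a2m;
  ag.a_sr = a_sr;
  ag.beta = beta;
  ag.gamma = gamma;
  ag.init(n_states);

  // neighbour lists in left, right, down, up order (0-based indices)
  std::vector<std::vector<int>> nb(n_states);
  for (int s = 0; s < n_states; ++s) {
    int x = s % n_side, y = s / n_side;
    if (x > 0) nb[s].push_back(s - 1);
    if (x < n_side - 1) nb[s].push_back(s + 1);
    if (y > 0) nb[s].push_back(s - n_side);
    if (y < n_side - 1) nb[s].push_back(s + n_side);
  }

  std::vector<int> cands(candidates.begin(), candidates.end());
  for (int& c : cands) --c; // to 0-based
  std::vector<int> order(special_order.begin(), special_order.end());
  for (int& c : order) --c;
  std::vector<int> fixed_ord(fixed_order.begin(), fixed_order.end());
  for (int& c : fixed_ord) --c;

  int pos = 0; // start state (1,1)
  int reward_state = -1, epoch = 0, special = -1, cyc = 0;
  int cur_place_epoch = 0, cur_place_state = -1;
  std::vector<int> goal_times, place_epochs, place_states;
  NumericVector snap_v1(n_states, NA_REAL), snap_v2(n_states, NA_REAL);
  int snap_place_epoch = NA_INTEGER, snap_place_state = NA_INTEGER,
      snap_special = NA_INTEGER, snap_time = NA_INTEGER;

  RNGScope scope;

  auto place_new = [&]() {
    if (fixed) {
      reward_state = fixed_ord[cyc % (int)fixed_ord.size()];
      ++cyc;
    } else {
      reward_state = draw_reward(p_special, special, cands);
    }
    cur_place_epoch = epoch;
    cur_place_state = reward_state;
  };

  std::vector<double> vals;
  for (int t = 1; t <= T; ++t) {
    if (reward_state >= 0 && pos == reward_state) {
      // consume: terminal TD-RPE, teleport occupies step t+1
      ag.step(pos, -1, 1.0, true, true);
      goal_times.push_back(t);
      place_epochs.push_back(cur_place_epoch);
      place_states.push_back(cur_place_state + 1);
      if (want_snapshot) {
        for (int s = 0; s < n_states; ++s) {
          snap_v1[s] = ag.sys_value(true, s);
          snap_v2[s] = ag.sys_value(false, s);
        }
        snap_place_epoch = cur_place_epoch;
        snap_place_state = cur_place_state + 1;
        snap_special = fixed ? NA_INTEGER : special + 1;
        snap_time = t;
      }
      place_new(); // new reward placed at the consumption step
      pos = 0;
    } else {
      const std::vector<int>& cand_next = nb[pos];
      vals.resize(cand_next.size());
      for (size_t i = 0; i < cand_next.size(); ++i)
        vals[i] = ag.integrated(cand_next[i]);
      int nxt = cand_next[softmax_pick(vals, beta)];
      ag.step(pos, nxt, 0.0, false, true);
      pos = nxt;
    }
    // bookkeeping effective at t + 1
    int tn = t + 1;
    if (tn > n_noreward && tn <= T) {
      int ep = (tn - n_noreward - 1) / epoch_length + 1;
      if (ep != epoch) {
        epoch = ep;
        if (!fixed) special = order[ep - 1];
      }
      if (tn == n_noreward + 1) {
        place_new();
      } else if (reset_period > 0 &&
                 (tn - n_noreward - 1) % reset_period == 0) {
        place_new();
      }
    }
  }

  NumericVector v1(n_states), v2(n_states);
  for (int s = 0; s < n_states; ++s) {
    v1[s] = ag.sys_value(true, s);
    v2[s] = ag.sys_value(false, s);
  }
  List sys1 = sr1 ? List::create(
                        _["rep"] = "SR",
                        _["sigma"] = NumericMatrix(n_states, n_states,
                                                   ag.sig1.begin()),
                        _["w"] = NumericVector(ag.w1.begin(), ag.w1.end()))
                  : List::create(_["rep"] = "IR",
                                 _["V"] = NumericVector(ag.V1.begin(),
                                                        ag.V1.end()));
  List sys2 = sr2 ? List::create(
                        _["rep"] = "SR",
                        _["sigma"] = NumericMatrix(n_states, n_states,
                                                   ag.sig2.begin()),
                        _["w"] = NumericVector(ag.w2.begin(), ag.w2.end()))
                  : List::create(_["rep"] = "IR",
                                 _["V"] = NumericVector(ag.V2.begin(),
                                                        ag.V2.end()));

  return List::create(
      _["total_rewards"] = (int)goal_times.size(),
      _["goal_times"] = IntegerVector(goal_times.begin(), goal_times.end()),
      _["placement_epochs"] =
          IntegerVector(place_epochs.begin(), place_epochs.end()),
      _["placement_states"] =
          IntegerVector(place_states.begin(), place_states.end()),
      _["v_system1"] = v1, _["v_system2"] = v2, _["system1"] = sys1,
      _["system2"] = sys2,
      _["snapshot"] = List::create(
          _["v_system1"] = snap_v1, _["v_system2"] = snap_v2,
          _["place_epoch"] = snap_place_epoch,
          _["place_state"] = snap_place_state, _["special"] = snap_special,
          _["time"] = snap_time));
}

// NOTE: sigma rows of the SR matrix are transposed into row-major order
// on the R side; NumericMatrix above is column-major, so the matrix is
// filled accordingly (sig is row-major: entry (s, j) at s * n + j, which
// lands at column s, row j of the column-major buffer). The R wrapper
// transposes it back.

// [[Rcpp::export]]
List sim_twostage_cpp(bool sr1, bool sr2, double a1p, double a1m, double a2p,
                      double a2m, double a_sr, double beta, double gamma,
                      int n_first, int n_pairs, NumericMatrix trans,
                      NumericMatrix schedule, NumericMatrix sigma_init) {
  const int n_second = 2 * n_pairs;
  const int n = n_first + n_second;
  const int n_trials = schedule.nrow();

  DualAgent ag;
  ag.sr1 = sr1;
  ag.sr2 = sr2;
  ag.a1p = a1p;
  ag.a1m = a1m;
  ag.a2p = a2p;
  ag.a2m = a2m;
  ag.a_sr = a_sr;
  ag.beta = beta;
  ag.gamma = gamma;
  ag.init(n);
  if (sr1 || sr2) {
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < n; ++j) {
        if (sr1) ag.sig1[(size_t)i * n + j] = sigma_init(i, j);
        if (sr2) ag.sig2[(size_t)i * n + j] = sigma_init(i, j);
      }
  }

  std::vector<double> trow(n_pairs);
  IntegerVector first_choice(n_trials), pair_reached(n_trials),
      second_choice(n_trials), rewards(n_trials);
  std::vector<double> vals;

  RNGScope scope;

  int total = 0;
  for (int k = 0; k < n_trials; ++k) {
    // first-stage choice among options 0..n_first-1
    vals.resize(n_first);
    for (int i = 0; i < n_first; ++i) vals[i] = ag.integrated(i);
    int o1 = softmax_pick(vals, beta);
    // stage transition
    for (int p = 0; p < n_pairs; ++p) trow[p] = trans(o1, p);
    int pair = categorical_pick(trow.data(), n_pairs);
    // second-stage choice among the reached pair's two options
    int s1 = n_first + 2 * pair;
    vals.resize(2);
    vals[0] = ag.integrated(s1);
    vals[1] = ag.integrated(s1 + 1);
    int o2 = s1 + softmax_pick(vals, beta);
    // SARSA-type first-stage TD-RPE and updates (SR features of the
    // chosen first-stage option updated here, after the transition)
    ag.step(o1, o2, 0.0, false, true);
    // outcome, then second-stage TD-RPE reflecting the first-stage
    // updates; second-stage SR rows are terminal and never updated
    double p_rew = schedule(k, o2 - n_first);
    int R = (unif_rand() < p_rew) ? 1 : 0;
    ag.step(o2, -1, (double)R, true, false);

    first_choice[k] = o1 + 1;
    pair_reached[k] = pair + 1;
    second_choice[k] = o2 + 1;
    rewards[k] = R;
    total += R;
  }

  NumericVector v1(n), v2(n);
  for (int s = 0; s < n; ++s) {
    v1[s] = ag.sys_value(true, s);
    v2[s] = ag.sys_value(false, s);
  }
  return List::create(
      _["total_rewards"] = total, _["first_choice"] = first_choice,
      _["pair"] = pair_reached, _["second_choice"] = second_choice,
      _["rewards"] = rewards, _["v_system1"] = v1, _["v_system2"] = v2);
}
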