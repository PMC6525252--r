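#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Continuous-time (Gillespie) integration of ribosome traffic on one mRNA.
//
// State: ascending A-site codon positions; exclusion keeps successive
// A-sites >= d codons apart. Events: forward step at the codon-specific
// rate omega[i-1] (termination at beta from the last codon), drop-off at
// gamma from every codon except the last, initiation at alpha when codons
// 1..d are clear.
//
// move_rule = 0 ("exclusion"): the event set contains realizable
//   transitions only; a blocked forward step has zero rate.
// move_rule = 1 ("paired"): blocked attempts stay in the event set and set
//   a per-ribosome (or initiation-site) flag; when the blocking ribosome
//   advances, one flagged immediate follower advances in the same event.

struct SimState {
  std::vector<int> pos;        // ascending A-site positions
  std::vector<char> flag;      // blocked-attempt flags (paired rule)
  std::vector<double> attach;  // attach time per ribosome
  bool init_flag = false;
  long init_tot = 0, comp_tot = 0, drop_tot = 0;
  long init_w = 0, comp_w = 0, drop_w = 0;  // within measurement window
  double transit_sum = 0.0;
  long transit_n = 0;
};

static inline bool can_initiate(const SimState &s, int d) {
  return s.pos.empty() || s.pos.front() > d;
}

static void do_initiate(SimState &s, double t, bool window) {
  s.pos.insert(s.pos.begin(), 1);
  s.flag.insert(s.flag.begin(), 0);
  s.attach.insert(s.attach.begin(), t);
  s.init_tot++;
  if (window) s.init_w++;
}

// [[Rcpp::export]]
List cpp_gillespie(NumericVector omega, double alpha, double beta,
                   double gamma, int d, double burn_in, double measure,
                   IntegerVector init_positions, int move_rule,
                   double max_events) {
  const int n = omega.size();
  const double t_end = burn_in + measure;
  SimState s;
  for (int i = 0; i < init_positions.size(); ++i) {
    s.pos.push_back(init_positions[i]);
    s.flag.push_back(0);
    s.attach.push_back(0.0);
  }
  NumericVector occ(n);   // time-integrated A-site occupancy over the window
  std::vector<double> rates;
  double t = 0.0;
  double n_events = 0.0;
  bool absorbed = false;

  while (t < t_end) {
    if (++n_events > max_events)
      stop("event budget exceeded (%.0f events); shorten burn_in/measure",
           max_events);
    const int N = s.pos.size();
    rates.assign(N + 1, 0.0);
    double Q = 0.0;
    // slot k (0..N-1): combined forward/terminate + drop-off for ribosome k
    for (int k = 0; k < N; ++k) {
      double rk;
      if (s.pos[k] == n) {
        rk = beta;  // termination from the last codon
      } else {
        bool blocked = (k + 1 < N) && (s.pos[k + 1] - s.pos[k] <= d);
        double mv = (move_rule == 1 || !blocked) ? omega[s.pos[k] - 1] : 0.0;
        rk = mv + gamma;
      }
      rates[k] = rk;
      Q += rk;
    }
    // slot N: initiation
    {
      double ri = 0.0;
      if (alpha > 0.0 && (move_rule == 1 || can_initiate(s, d))) ri = alpha;
      rates[N] = ri;
      Q += ri;
    }
    if (Q <= 0.0) {
      if (t == 0.0 && s.pos.empty())
        stop("absorbing state: no ribosomes and initiation rate is zero");
      absorbed = true;
      break;
    }
    double dt = -std::log(R::unif_rand()) / Q;
    // window overlap of [t, t+dt]
    double w0 = std::max(t, burn_in), w1 = std::min(t + dt, t_end);
    if (w1 > w0)
      for (int k = 0; k < (int)s.pos.size(); ++k) occ[s.pos[k] - 1] += w1 - w0;
    t += dt;
    if (t > t_end) break;
    bool window = (t > burn_in);

    // pick event
    double r = R::unif_rand() * Q, acc = 0.0;
    int k = -1;
    for (int m = 0; m <= N; ++m) {
      acc += rates[m];
      if (r < acc) { k = m; break; }
    }
    if (k < 0) k = N;

    if (k == N) {  // initiation
      if (can_initiate(s, d)) do_initiate(s, t, window);
      else s.init_flag = true;  // paired rule only
      continue;
    }
    // within-ribosome split: forward/terminate vs drop-off
    double r_in = rates[k] * R::unif_rand();
    bool is_term = (s.pos[k] == n);
    double fwd = is_term ? beta
                         : ((move_rule == 1 ||
                             !((k + 1 < N) && (s.pos[k + 1] - s.pos[k] <= d)))
                                ? omega[s.pos[k] - 1]
                                : 0.0);
    if (!is_term && r_in >= fwd) {  // drop-off
      s.pos.erase(s.pos.begin() + k);
      s.flag.erase(s.flag.begin() + k);
      s.attach.erase(s.attach.begin() + k);
      s.drop_tot++;
      if (window) s.drop_w++;
      continue;
    }
    if (is_term) {  // termination
      double a0 = s.attach[k];
      s.pos.erase(s.pos.begin() + k);
      s.flag.erase(s.flag.begin() + k);
      s.attach.erase(s.attach.begin() + k);
      s.comp_tot++;
      if (window) {
        s.comp_w++;
        s.transit_sum += t - a0;
        s.transit_n++;
      }
      if (move_rule == 1) {
        int f = k - 1;
        if (f >= 0 && s.flag[f] && s.pos[f] < n) {
          bool ok = (f + 1 < (int)s.pos.size())
                        ? (s.pos[f + 1] - (s.pos[f] + 1) >= d)
                        : true;
          if (ok) { s.pos[f]++; s.flag[f] = 0; }
        }
        if (s.pos.empty() || s.pos.front() > d) {
          if (s.init_flag) { do_initiate(s, t, window); s.init_flag = false; }
        }
      }
      continue;
    }
    // forward step
    bool blocked = (k + 1 < N) && (s.pos[k + 1] - s.pos[k] <= d);
    if (blocked) {  // only reachable under the paired rule
      s.flag[k] = 1;
      continue;
    }
    s.pos[k]++;
    s.flag[k] = 0;
    if (move_rule == 1) {
      int f = k - 1;
      if (f >= 0 && s.flag[f] && s.pos[f] < n &&
          s.pos[k] - (s.pos[f] + 1) >= d) {
        s.pos[f]++;
        s.flag[f] = 0;
      }
      if (k == 0 && s.init_flag && s.pos[0] > d) {
        do_initiate(s, t, window);
        s.init_flag = false;
      }
    }
  }

  double current = (measure > 0) ? s.comp_w / measure : NA_REAL;
  NumericVector density(n);
  if (measure > 0) for (int i = 0; i < n; ++i) density[i] = occ[i] / measure;
  return List::create(
      _["current"] = current, _["density"] = density,
      _["completions"] = (double)s.comp_w, _["dropoffs"] = (double)s.drop_w,
      _["initiations"] = (double)s.init_w,
      _["completions_total"] = (double)s.comp_tot,
      _["dropoffs_total"] = (double)s.drop_tot,
      _["initiations_total"] = (double)s.init_tot,
      _["final_positions"] = IntegerVector(s.pos.begin(), s.pos.end()),
      _["mean_transit"] =
          s.transit_n > 0 ? s.transit_sum / s.transit_n : NA_REAL,
      _["n_transit"] = (double)s.transit_n, _["absorbed"] = absorbed);
}

// Fixed-increment integration: time advances by dt; per step each event
// fires with probability rate*dt. Ribosomes are updated from the 3' leader
// backwards so that a follower freed within the step can advance into the
// vacated site, mirroring the simultaneous-move behaviour in the small-dt
// limit.
// [[Rcpp::export]]
List cpp_fixed_step(NumericVector omega, double alpha, double beta,
                    double gamma, int d, double dt, double burn_in,
                    double measure, IntegerVector init_positions) {
  const int n = omega.size();
  const double t_end = burn_in + measure;
  SimState s;
  for (int i = 0; i < init_positions.size(); ++i) {
    s.pos.push_back(init_positions[i]);
    s.flag.push_back(0);
    s.attach.push_back(0.0);
  }
  NumericVector occ(n);
  double t = 0.0;
  while (t < t_end) {
    bool window = (t >= burn_in);
    double wdt = window ? std::min(dt, t_end - t) : 0.0;
    if (window)
      for (size_t k = 0; k < s.pos.size(); ++k) occ[s.pos[k] - 1] += wdt;
    // leader (largest position) first
    for (int k = (int)s.pos.size() - 1; k >= 0; --k) {
      double u = R::unif_rand();
      if (s.pos[k] == n) {
        if (u < beta * dt) {
          double a0 = s.attach[k];
          s.pos.erase(s.pos.begin() + k);
          s.flag.erase(s.flag.begin() + k);
          s.attach.erase(s.attach.begin() + k);
          s.comp_tot++;
          if (window) {
            s.comp_w++;
            s.transit_sum += t - a0;
            s.transit_n++;
          }
        }
        continue;
      }
      double pm = omega[s.pos[k] - 1] * dt;
      if (u < pm) {
        bool blocked = (k + 1 < (int)s.pos.size()) &&
                       (s.pos[k + 1] - s.pos[k] <= d);
        if (!blocked) s.pos[k]++;
      } else if (u < pm + gamma * dt) {
        s.pos.erase(s.pos.begin() + k);
        s.flag.erase(s.flag.begin() + k);
        s.attach.erase(s.attach.begin() + k);
        s.drop_tot++;
        if (window) s.drop_w++;
      }
    }
    if (alpha > 0.0 && R::unif_rand() < alpha * dt && can_initiate(s, d))
      do_initiate(s, t, window);
    t += dt;
  }
  double current = (measure > 0) ? s.comp_w / measure : NA_REAL;
  NumericVector density(n);
  if (measure > 0) for (int i = 0; i < n; ++i) density[i] = occ[i] / measure;
  return List::create(
      _["current"] = current, _["density"] = density,
      _["completions"] = (double)s.comp_w, _["dropoffs"] = (double)s.drop_w,
      _["initiations"] = (double)s.init_w,
      _["completions_total"] = (double)s.comp_tot,
      _["dropoffs_total"] = (double)s.drop_tot,
      _["initiations_total"] = (double)s.init_tot,
      _["final_positions"] = IntegerVector(s.pos.begin(), s.pos.end()),
      _["mean_transit"] =
          s.transit_n > 0 ? s.transit_sum / s.transit_n : NA_REAL,
      _["n_transit"] = (double)s.transit_n, _["absorbed"] = false);
}

// Secondary-structure energy minimization for the 5' window: base-pair
// energies with a stacking bonus, minimum hairpin loop of `min_loop`
// unpaired nucleotides. seq is 0=A, 1=C, 2=G, 3=T/U. Returns the minimum
// free energy and a dot-bracket structure.
static double pair_e(int a, int b, double e_gc, double e_au, double e_gu) {
  if ((a == 2 && b == 1) || (a == 1 && b == 2)) return e_gc;
  if ((a == 0 && b == 3) || (a == 3 && b == 0)) return e_au;
  if ((a == 2 && b == 3) || (a == 3 && b == 2)) return e_gu;
  return R_PosInf;
}

// [[Rcpp::export]]
List cpp_fold(IntegerVector seq, double e_gc, double e_au, double e_gu,
              double e_stack, int min_loop) {
  const int n = seq.size();
  const double INF = R_PosInf;
  // V(i,j): min energy with (i,j) paired; W(i,j): min energy on [i,j]
  std::vector<std::vector<double> > V(n, std::vector<double>(n, INF)),
      W(n, std::vector<double>(n, 0.0));
  for (int span = min_loop + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      double e = pair_e(seq[i], seq[j], e_gc, e_au, e_gu);
      if (R_FINITE(e)) {
        double best = W[i + 1][j - 1];
        // stacking bonus when the inner structure is exactly (i+1, j-1)
        if (R_FINITE(V[i + 1][j - 1]))
          best = std::min(best, V[i + 1][j - 1] + e_stack);
        V[i][j] = e + best;
      }
      double w = W[i][j - 1];  // j unpaired
      for (int k = i; k <= j - min_loop - 1; ++k) {
        if (!R_FINITE(V[k][j])) continue;
        double cand = (k > i ? W[i][k - 1] : 0.0) + V[k][j];
        if (cand < w) w = cand;
      }
      if (w > 0) w = 0.0;  // empty structure always admissible
      W[i][j] = w;
    }
  }
  // traceback
  std::string db(n, '.');
  std::vector<std::pair<std::pair<int, int>, int> > stack;  // (i,j), mode 0=W 1=V
  if (n > 1) stack.push_back(std::make_pair(std::make_pair(0, n - 1), 0));
  while (!stack.empty()) {
    int i = stack.back().first.first, j = stack.back().first.second,
        mode = stack.back().second;
    stack.pop_back();
    if (i >= j) continue;
    if (mode == 1) {
      db[i] = '(';
      db[j] = ')';
      double e = pair_e(seq[i], seq[j], e_gc, e_au, e_gu);
      double inner = V[i][j] - e;
      if (j - 1 - (i + 1) > min_loop && R_FINITE(V[i + 1][j - 1]) &&
          std::abs(inner - (V[i + 1][j - 1] + e_stack)) < 1e-9) {
        stack.push_back(std::make_pair(std::make_pair(i + 1, j - 1), 1));
      } else if (std::abs(inner - W[i + 1][j - 1]) < 1e-9) {
        stack.push_back(std::make_pair(std::make_pair(i + 1, j - 1), 0));
      }
      continue;
    }
    if (W[i][j] >= 0.0) continue;  // empty
    if (std::abs(W[i][j] - W[i][j - 1]) < 1e-9) {
      stack.push_back(std::make_pair(std::make_pair(i, j - 1), 0));
      continue;
    }
    bool done = false;
    for (int k = i; k <= j - min_loop - 1 && !done; ++k) {
      if (!R_FINITE(V[k][j])) continue;
      double cand = (k > i ? W[i][k - 1] : 0.0) + V[k][j];
      if (std::abs(W[i][j] - cand) < 1e-9) {
        if (k > i) stack.push_back(std::make_pair(std::make_pair(i, k - 1), 0));
        stack.push_back(std::make_pair(std::make_pair(k, j), 1));
        done = true;
      }
    }
  }
  double mfe = (n > 1) ? W[0][n - 1] : 0.0;
  return List::create(_["energy"] = mfe, _["structure"] = db);
}
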