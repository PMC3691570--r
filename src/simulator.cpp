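// Hybrid exact/deterministic simulator of a continuous-time multitype
// branching process: pretreatment growth from a single sensitive cell to
// detection size M, then treatment (simultaneous or sequential) until
// eradication, relapse at size N, or a time cap.
//
// Subpopulations below `threshold` cells are simulated exactly (event-driven
// birth/death/mutation); larger ones follow deterministic exponential growth
// with mutational influx between compartments solved in closed form
// (the compartment graph is triangular, so trajectories are finite sums of
// exponentials), and mutant seeding into small compartments is an
// inhomogeneous Poisson process sampled by inversion of its closed-form
// cumulative hazard. Compartments switch mode in both directions when they
// cross the threshold, so extinction of declining clones stays stochastic.
//
// Compartments are split by resistance bits, by the number of mutational
// steps carried (for costly resistance: a direct cross-resistance jump
// counts 1, a two-step path counts 2) and by epoch of origin (founded before
// vs after the first treatment start), which supports classification of
// failures as preexisting vs de novo.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct Comp { int bits; int nmut; int pre; };
struct Chan { int src; double cnt; int tgt_pre; int tgt_post; };
struct Term { double a; double lam; };

const double INF = std::numeric_limits<double>::infinity();

struct Engine {
  // parameters
  int k, nc;
  double b, d, bt, dt, u, c;
  double M, Nrel, threshold, max_time;
  bool seq;
  std::vector<Comp> comps;
  std::vector<Chan> chans;

  // state
  std::vector<double> N;
  std::vector<int> ex;       // 1 = exact mode
  double t;
  int phase;                 // 0 pretreatment, >=1 treatment phase number
  int adminMask;
  bool armed;
  int restarts;
  double t_detect, t_first_relapse;
  double E_res;              // residual exponential variate for seeding

  // per-phase cached rates
  std::vector<double> bc, dc, ntot, r;
  std::vector<char> resf;   // resistant to every currently administered drug
  // deterministic trajectories for the current step (from step start)
  std::vector<std::vector<Term> > terms;

  // trajectory recording
  bool record;
  double rec_dt, next_rec;
  std::vector<double> rec_rows;   // time + nc counts per row

  void setup(int k_, double b_, double d_, double bt_, double dt_, double u_,
             double c_, double n1, double n2, double n12, double M_,
             double Nrel_, bool seq_, double thr, double maxt) {
    k = k_; b = b_; d = d_; bt = bt_; dt = dt_; u = u_; c = c_;
    M = M_; Nrel = Nrel_; seq = seq_; threshold = thr; max_time = maxt;
    comps.clear(); chans.clear();
    if (k == 1) {
      Comp cs[] = { {0, 0, 1}, {1, 1, 1}, {1, 1, 0} };
      comps.assign(cs, cs + 3);
      Chan ch[] = { {0, n1, 1, 2} };
      chans.assign(ch, ch + 1);
    } else {
      Comp cs[] = { {0, 0, 1},
                    {1, 1, 1}, {1, 1, 0},   // resistant to drug 1 only
                    {2, 1, 1}, {2, 1, 0},   // resistant to drug 2 only
                    {3, 1, 1}, {3, 1, 0},   // dual via one cross mutation
                    {3, 2, 1}, {3, 2, 0} }; // dual via two steps
      comps.assign(cs, cs + 9);
      Chan ch[] = { {0, n1, 1, 2}, {0, n2, 3, 4}, {0, n12, 5, 6},
                    {1, n2 + n12, 7, 8}, {2, n2 + n12, 7, 8},
                    {3, n1 + n12, 7, 8}, {4, n1 + n12, 7, 8} };
      chans.assign(ch, ch + 7);
    }
    nc = (int)comps.size();
    N.assign(nc, 0.0); ex.assign(nc, 1);
    bc.assign(nc, 0.0); dc.assign(nc, 0.0); ntot.assign(nc, 0.0);
    r.assign(nc, 0.0); resf.assign(nc, 0);
    terms.assign(nc, std::vector<Term>());
    t = 0.0; phase = 0; adminMask = 0; armed = false; restarts = 0;
    t_detect = NA_REAL; t_first_relapse = NA_REAL;
    E_res = ::exp_rand();
    record = false; rec_dt = 1.0; next_rec = 0.0; rec_rows.clear();
  }

  int chan_target(const Chan& ch) const {
    return phase == 0 ? ch.tgt_pre : ch.tgt_post;
  }

  void compute_rates() {
    for (int i = 0; i < nc; ++i) {
      bool resist = (phase == 0) ||
        ((comps[i].bits & adminMask) == adminMask);
      resf[i] = (phase > 0 && resist) ? 1 : 0;
      if (resist) {
        bc[i] = (b - d) * std::pow(1.0 - c, comps[i].nmut) + d;
        dc[i] = d;
      } else {
        bc[i] = bt; dc[i] = dt;
      }
      ntot[i] = 0.0;
    }
    for (size_t j = 0; j < chans.size(); ++j)
      ntot[chans[j].src] += chans[j].cnt;
    for (int i = 0; i < nc; ++i)
      r[i] = bc[i] * (1.0 - u * ntot[i]) - dc[i];
  }

  // Exact solution of the (triangular) deterministic subsystem over the
  // coming step, as sums of exponentials in the step-local time.
  void build_det() {
    for (int i = 0; i < nc; ++i) {
      terms[i].clear();
      if (ex[i]) continue;
      Term t0 = { N[i], r[i] };
      terms[i].push_back(t0);
      for (size_t j = 0; j < chans.size(); ++j) {
        const Chan& ch = chans[j];
        if (chan_target(ch) != i || ex[ch.src] || ch.cnt <= 0) continue;
        double alpha = bc[ch.src] * u * ch.cnt;
        const std::vector<Term>& ts = terms[ch.src];
        for (size_t m = 0; m < ts.size(); ++m) {
          double dr = ts[m].lam - r[i];
          if (std::fabs(dr) < 1e-12) dr = (dr >= 0 ? 1e-12 : -1e-12);
          double co = ts[m].a * alpha / dr;
          Term tp = { co, ts[m].lam }; terms[i].push_back(tp);
          Term tm = { -co, r[i] };     terms[i].push_back(tm);
        }
      }
    }
  }

  double det_val(int i, double tau) const {
    double v = 0.0;
    for (size_t m = 0; m < terms[i].size(); ++m) {
      double e = terms[i][m].lam * tau;
      v += terms[i][m].a * std::exp(e > 700.0 ? 700.0 : e);
    }
    return v < 0 ? 0.0 : v;
  }

  double comp_val(int i, double tau) const {
    return ex[i] ? N[i] : det_val(i, tau);
  }

  double total_at(double tau) const {
    double v = 0.0;
    for (int i = 0; i < nc; ++i) v += comp_val(i, tau);
    return v;
  }

  // cells resistant to every currently administered drug
  double resistant_at(double tau) const {
    double v = 0.0;
    for (int i = 0; i < nc; ++i) if (resf[i]) v += comp_val(i, tau);
    return v;
  }

  double resistant_now() const {
    double v = 0.0;
    for (int i = 0; i < nc; ++i) if (resf[i]) v += N[i];
    return v;
  }

  // integral over [0, tau] of one deterministic trajectory
  double det_integral(int i, double tau) const {
    double v = 0.0;
    for (size_t m = 0; m < terms[i].size(); ++m) {
      double lam = terms[i][m].lam;
      double e = lam * tau;
      if (std::fabs(e) < 1e-9)
        v += terms[i][m].a * tau * (1.0 + 0.5 * e);
      else
        v += terms[i][m].a * (std::exp(e > 700.0 ? 700.0 : e) - 1.0) / lam;
    }
    return v < 0 ? 0.0 : v;
  }

  // cumulative seeding hazard: deterministic sources -> exact targets
  double seed_hazard(double tau) const {
    double H = 0.0;
    for (size_t j = 0; j < chans.size(); ++j) {
      const Chan& ch = chans[j];
      if (ex[ch.src] || !ex[chan_target(ch)] || ch.cnt <= 0) continue;
      H += bc[ch.src] * u * ch.cnt * det_integral(ch.src, tau);
    }
    return H;
  }

  double seed_rate_at(const Chan& ch, double tau) const {
    return bc[ch.src] * u * ch.cnt * det_val(ch.src, tau);
  }

  // solve f(tau) = target for increasing-at-crossing f via bisection
  template <class F>
  double bisect(F f, double lo, double hi, double target,
                int iters = 40) const {
    for (int it = 0; it < iters; ++it) {
      double mid = 0.5 * (lo + hi);
      if (f(mid) >= target) hi = mid; else lo = mid;
    }
    return hi;
  }

  void record_upto(double tau) {
    if (!record) return;
    while (next_rec <= t + tau + 1e-12) {
      double loc = next_rec - t;
      if (loc < 0) loc = 0;
      rec_rows.push_back(next_rec);
      for (int i = 0; i < nc; ++i) rec_rows.push_back(comp_val(i, loc));
      next_rec += rec_dt;
    }
  }

  void advance_det(double tau) {
    record_upto(tau);
    for (int i = 0; i < nc; ++i)
      if (!ex[i]) N[i] = det_val(i, tau);
    t += tau;
  }

  void reset_pre() {
    for (int i = 0; i < nc; ++i) { N[i] = 0.0; ex[i] = 1; }
    N[0] = 1.0; t = 0.0;
    if (record) { rec_rows.clear(); next_rec = 0.0; }
  }

  void mode_switch_up() {
    for (int i = 0; i < nc; ++i)
      if (ex[i] && N[i] >= threshold) ex[i] = 0;
  }

  double total_now() const {
    double v = 0.0;
    for (int i = 0; i < nc; ++i) v += N[i];
    return v;
  }

  // Apply one exact event for compartment i at current time; returns
  // 1 if a structural change occurred (mutation into a det compartment,
  // threshold up-crossing), else 0.
  int exact_event(int i, double& Rex) {
    double pr = unif_rand() * (bc[i] + dc[i]);
    if (pr < dc[i]) {                       // death
      N[i] -= 1.0; Rex -= (bc[i] + dc[i]);
      return 0;
    }
    // division; offspring mutates with probability u * ntot
    if (ntot[i] > 0 && unif_rand() < u * ntot[i]) {
      double pick = unif_rand() * ntot[i], acc = 0.0;
      for (size_t j = 0; j < chans.size(); ++j) {
        if (chans[j].src != i || chans[j].cnt <= 0) continue;
        acc += chans[j].cnt;
        if (pick <= acc) {
          int tgt = chan_target(chans[j]);
          N[tgt] += 1.0;
          if (!ex[tgt]) return 1;           // influx into deterministic pool
          Rex += (bc[tgt] + dc[tgt]);
          if (N[tgt] >= threshold) return 1;
          return 0;
        }
      }
      return 0; // unreachable
    }
    N[i] += 1.0; Rex += (bc[i] + dc[i]);
    if (N[i] >= threshold) return 1;
    return 0;
  }

  // One hybrid step. Returns an event code:
  // 0 = advanced (nothing terminal), 1 = detection reached (phase 0),
  // 2 = relapse (treatment), 3 = all extinct, 4 = time cap.
  int step() {
    compute_rates();
    build_det();

    bool any_det = false;
    double rmax = 1e-6;
    for (int i = 0; i < nc; ++i) {
      if (!ex[i]) any_det = true;
      double ar = std::fabs(r[i]);
      if (ar > rmax) rmax = ar;
    }

    double remain = max_time - t;
    if (remain <= 0) return 4;
    double h = std::min(remain, std::max(1e-3, std::min(0.5 / rmax, 100.0)));
    if (record) {
      double to_rec = next_rec - t;
      if (to_rec > 1e-9 && to_rec < h) h = to_rec + 1e-9;
    }

    double tcand = h;
    int ev = 0;                 // 0 boundary, 2 down-cross, 3 seed, 4 total-cross
    int ev_comp = -1;

    if (any_det) {
      // deterministic compartment falling below threshold (switch back to
      // exact mode strictly below it, so the up-switch cannot retrigger)
      double down_target = std::max(threshold - 1.0, 0.5);
      for (int i = 0; i < nc; ++i) {
        if (ex[i]) continue;
        if (det_val(i, tcand) <= down_target && N[i] > down_target) {
          int ii = i;
          const Engine* self = this;
          double tau = bisect([self, ii](double x) {
            return -self->det_val(ii, x);
          }, 0.0, tcand, -down_target);
          if (tau < tcand) { tcand = tau; ev = 2; ev_comp = i; }
        }
      }
      // total burden crossing (detection size M or relapse size N)
      double target = (phase == 0) ? M : (armed ? Nrel : INF);
      if (std::isfinite(target) && total_at(tcand) >= target &&
          total_at(0.0) < target) {
        const Engine* self = this;
        double tau = bisect([self](double x) {
          return self->total_at(x);
        }, 0.0, tcand, target);
        if (tau <= tcand) { tcand = tau; ev = 4; }
      }
      // regimen-resistant subpopulation alone reaching the relapse size
      // (catches progression even when the total burden never shrank)
      if (phase > 0 && resistant_at(tcand) >= Nrel &&
          resistant_at(0.0) < Nrel) {
        const Engine* self = this;
        double tau = bisect([self](double x) {
          return self->resistant_at(x);
        }, 0.0, tcand, Nrel);
        if (tau <= tcand) { tcand = tau; ev = 4; }
      }
      // mutant seeding into exact compartments
      double H = seed_hazard(tcand);
      if (H >= E_res) {
        const Engine* self = this;
        double tau = bisect([self](double x) {
          return self->seed_hazard(x);
        }, 0.0, tcand, E_res);
        if (tau <= tcand) { tcand = tau; ev = 3; }
      }
    }

    // exact-mode Gillespie within [0, tcand]
    double Rex = 0.0;
    for (int i = 0; i < nc; ++i)
      if (ex[i]) Rex += N[i] * (bc[i] + dc[i]);
    double tau_cur = 0.0;
    bool structural = false;
    while (Rex > 1e-300) {
      double dt_ev = exp_rand() / Rex;
      if (tau_cur + dt_ev >= tcand) break;
      tau_cur += dt_ev;
      // choose exact compartment
      double pick = unif_rand() * Rex, acc = 0.0;
      int i = -1;
      for (int q = 0; q < nc; ++q) {
        if (!ex[q] || N[q] <= 0) continue;
        acc += N[q] * (bc[q] + dc[q]);
        if (pick <= acc) { i = q; break; }
      }
      if (i < 0) continue;
      if (exact_event(i, Rex)) { structural = true; break; }
      // terminal checks (totals are current only when no det compartments)
      if (!any_det) {
        double tot = total_now();
        if (phase == 0) {
          if (tot >= M) { advance_det(tau_cur); return 1; }
          if (tot <= 0) { restarts += 1; reset_pre(); return 0; }
        } else {
          if (tot <= 0) { advance_det(tau_cur); return 3; }
          if (!armed && tot <= 0.95 * Nrel) armed = true;
          if ((armed && tot >= Nrel) || resistant_now() >= Nrel) {
            advance_det(tau_cur); return 2;
          }
        }
      }
    }

    if (structural) {
      double consumed = seed_hazard(tau_cur);
      E_res -= consumed; if (E_res < 1e-300) E_res = R::exp_rand();
      advance_det(tau_cur);
      mode_switch_up();
      return post_checks();
    }

    // no structural exact event: the deterministic-side candidate fires
    if (ev == 3) {
      advance_det(tcand);
      // pick the seeding channel proportional to its instantaneous rate
      double tot = 0.0;
      for (size_t j = 0; j < chans.size(); ++j) {
        const Chan& ch = chans[j];
        if (ex[ch.src] || !ex[chan_target(ch)] || ch.cnt <= 0) continue;
        tot += seed_rate_at(ch, tcand);
      }
      double pick = unif_rand() * tot, acc = 0.0;
      for (size_t j = 0; j < chans.size(); ++j) {
        const Chan& ch = chans[j];
        if (ex[ch.src] || !ex[chan_target(ch)] || ch.cnt <= 0) continue;
        acc += seed_rate_at(ch, tcand);
        if (pick <= acc) { N[chan_target(ch)] += 1.0; break; }
      }
      E_res = R::exp_rand();
      mode_switch_up();
      return post_checks();
    }

    E_res -= seed_hazard(tcand);
    if (E_res < 1e-300) E_res = R::exp_rand();
    advance_det(tcand);

    if (ev == 2 && ev_comp >= 0) {          // down-crossing: back to exact
      ex[ev_comp] = 1;
      N[ev_comp] = std::floor(N[ev_comp] + 0.5);
    }
    if (ev == 4) return (phase == 0) ? 1 : 2;
    mode_switch_up();
    return post_checks();
  }

  int post_checks() {
    double tot = total_now();
    if (phase == 0) {
      if (tot <= 0) { restarts += 1; reset_pre(); return 0; }
      if (tot >= M) return 1;
    } else {
      if (tot <= 0) return 3;
      if (!armed && tot <= 0.95 * Nrel) armed = true;
      if ((armed && tot >= Nrel) || resistant_now() >= Nrel) return 2;
    }
    if (t >= max_time) return 4;
    return 0;
  }

  // run pretreatment until detection; returns false on time cap
  bool run_pre() {
    reset_pre();
    for (;;) {
      int code = step();
      if (code == 1) { t_detect = t; return true; }
      if (code == 4) return false;
    }
  }

  void start_treatment(int phase_no) {
    phase = phase_no;
    if (k == 1) adminMask = 1;
    else if (!seq) adminMask = 3;
    else adminMask = (phase_no == 1) ? 1 : 2;
    armed = false;
  }

  // returns status 0 eradicated, 1 relapse/failure, 2 time cap;
  // cause: 0 none, 1 preexisting, 2 de novo
  void run_treatment(int& status, int& cause, double& t_rel) {
    start_treatment(1);
    for (;;) {
      int code = step();
      if (code == 3) { status = 0; cause = 0; t_rel = NA_REAL; return; }
      if (code == 4) { status = 2; cause = 0; t_rel = NA_REAL; return; }
      if (code == 2) {
        if (seq && phase == 1) {
          t_first_relapse = t;
          start_treatment(2);
          continue;
        }
        status = 1; t_rel = t;
        cause = classify();
        return;
      }
    }
  }

  int classify() const {
    int driver = -1; double best = 0.0;
    for (int i = 0; i < nc; ++i) {
      if (comps[i].bits == 0) continue;
      if ((comps[i].bits & adminMask) != adminMask) continue;
      if (N[i] > best) { best = N[i]; driver = i; }
    }
    if (driver < 0) return 2;
    return comps[driver].pre ? 1 : 2;
  }
};

Engine* make_engine(List cfg) {
  Engine* e = new Engine();
  int k = as<int>(cfg["k"]);
  e->setup(k, as<double>(cfg["b"]), as<double>(cfg["d"]),
           as<double>(cfg["b_treat"]), as<double>(cfg["d_treat"]),
           as<double>(cfg["u"]), as<double>(cfg["c"]),
           as<double>(cfg["n1"]), k == 1 ? 0.0 : as<double>(cfg["n2"]),
           k == 1 ? 0.0 : as<double>(cfg["n12"]),
           as<double>(cfg["M"]), as<double>(cfg["N"]),
           as<bool>(cfg["sequential"]), as<double>(cfg["threshold"]),
           as<double>(cfg["max_time"]));
  return e;
}

NumericMatrix traj_matrix(const Engine& e) {
  int ncol = e.nc + 1;
  int nrow = (int)(e.rec_rows.size() / ncol);
  NumericMatrix m(nrow, ncol);
  for (int i = 0; i < nrow; ++i)
    for (int j = 0; j < ncol; ++j)
      m(i, j) = e.rec_rows[(size_t)i * ncol + j];
  return m;
}

} // namespace

// [[Rcpp::export]]
List cpp_sim_courses(List cfg, int reps, bool pre_only, bool record,
                     double rec_dt) {
  Engine* e = make_engine(cfg);
  int nc = e->nc;
  IntegerVector status(reps), cause(reps), restarts(reps);
  NumericVector t_det(reps), t_rel(reps), t_rel1(reps);
  NumericMatrix det_state(reps, nc), fin_state(reps, nc);
  List trajs(record ? reps : 0);

  for (int rep = 0; rep < reps; ++rep) {
    if (rep % 64 == 0) Rcpp::checkUserInterrupt();
    e->setup(e->k, e->b, e->d, e->bt, e->dt, e->u, e->c,
             e->chans[0].cnt,
             e->k == 1 ? 0.0 : e->chans[1].cnt,
             e->k == 1 ? 0.0 : e->chans[2].cnt,
             e->M, e->Nrel, e->seq, e->threshold, e->max_time);
    e->record = record; e->rec_dt = rec_dt;
    bool ok = e->run_pre();
    for (int i = 0; i < nc; ++i) det_state(rep, i) = e->N[i];
    t_det[rep] = e->t_detect;
    restarts[rep] = e->restarts;
    if (!ok) {
      status[rep] = 2; cause[rep] = NA_INTEGER;
      t_rel[rep] = NA_REAL; t_rel1[rep] = NA_REAL;
    } else if (pre_only) {
      status[rep] = NA_INTEGER; cause[rep] = NA_INTEGER;
      t_rel[rep] = NA_REAL; t_rel1[rep] = NA_REAL;
    } else {
      int st, ca; double tr;
      e->run_treatment(st, ca, tr);
      status[rep] = st; cause[rep] = ca; t_rel[rep] = tr;
      t_rel1[rep] = e->t_first_relapse;
    }
    for (int i = 0; i < nc; ++i) fin_state(rep, i) = e->N[i];
    if (record) trajs[rep] = traj_matrix(*e);
  }
  List out = List::create(
    _["status"] = status, _["cause"] = cause, _["restarts"] = restarts,
    _["detection_time"] = t_det, _["relapse_time"] = t_rel,
    _["first_relapse_time"] = t_rel1,
    _["state_at_detection"] = det_state, _["final_state"] = fin_state);
  if (record) out["trajectories"] = trajs;
  delete e;
  return out;
}

// [[Rcpp::export]]
List cpp_run_treatment(List cfg, NumericVector init_state, bool record,
                       double rec_dt) {
  Engine* e = make_engine(cfg);
  if ((int)init_state.size() != e->nc) {
    delete e;
    stop("init_state has wrong length");
  }
  for (int i = 0; i < e->nc; ++i) {
    e->N[i] = init_state[i];
    e->ex[i] = (e->N[i] < e->threshold) ? 1 : 0;
  }
  e->t = 0.0; e->t_detect = 0.0;
  e->record = record; e->rec_dt = rec_dt;
  int st, ca; double tr;
  e->run_treatment(st, ca, tr);
  List out = List::create(
    _["status"] = st, _["cause"] = ca, _["relapse_time"] = tr,
    _["first_relapse_time"] = e->t_first_relapse,
    _["final_state"] = NumericVector(e->N.begin(), e->N.end()),
    _["time"] = e->t);
  if (record) out["trajectory"] = traj_matrix(*e);
  delete e;
  return out;
}

// Exact single-type birth-death process from n0 cells: returns 1 if the
// lineage goes extinct before reaching `cap` cells or `max_time`.
// [[Rcpp::export]]
IntegerVector cpp_single_type_extinct(double b, double d, double n0,
                                      double cap, double max_time,
                                      int reps) {
  IntegerVector out(reps);
  for (int rep = 0; rep < reps; ++rep) {
    if (rep % 256 == 0) Rcpp::checkUserInterrupt();
    double n = n0, t = 0.0;
    int res = NA_INTEGER;
    while (true) {
      if (n <= 0) { res = 1; break; }
      if (n >= cap) { res = 0; break; }
      double rate = n * (b + d);
      t += exp_rand() / rate;
      if (t > max_time) { res = 0; break; }
      if (unif_rand() * (b + d) < b) n += 1.0; else n -= 1.0;
    }
    out[rep] = res;
  }
  return out;
}
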