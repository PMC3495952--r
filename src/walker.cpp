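// Hybrid event-driven integrator for the ankle-actuated point-mass walker.
//
// One step cycle: double stance (actuated four-bar linkage, second-order ODE
// in the hip angle theta) from theta = alpha until the ankle angle psi
// reaches mu (spring released) -- optionally extended while a perturbation
// pulse keeps the total ankle torque positive -- then single stance
// (inverted pendulum) until theta = -alpha, then an inelastic collision
// scaling theta_dot by cos(2*alpha) and resetting theta to +alpha.
//
// States integrated: y = (theta, theta_dot, w_spring, w_pulse) where the w's
// accumulate the work done by the spring and by the pulse (integral T dpsi).

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>
using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

struct Par {
  double m, L, l, g, alpha, mu, k, a;
};

struct Pulse {
  bool present;
  double A, width, tau_p, delta, eps_cap;
  int leg;     // parity of the perturbed leg (0/1)
  int policy;  // 0 = TRUNCATE_AT_MU, 1 = EXTEND_WHILE_POSITIVE
};

struct Num {
  double rtol, atol, h_init, h_max, fixed_step; // fixed_step <= 0: adaptive
  bool strict;
};

struct Geom {
  double AC2, AC, psi, spsi, dpsi;
};

static inline Geom geom(const Par& p, double th) {
  Geom g;
  g.AC2 = p.a * p.a + p.L * p.L - 2.0 * p.a * p.L * std::sin(th);
  g.AC = std::sqrt(g.AC2);
  double c = (p.l * p.l + p.L * p.L - g.AC2) / (2.0 * p.l * p.L);
  if (c > 1.0) c = 1.0;
  if (c < -1.0) c = -1.0;
  g.psi = std::acos(c);
  g.spsi = std::sin(g.psi);
  if (g.spsi < 1e-12) g.spsi = 1e-12; // guarded; the cap event fires first
  g.dpsi = -p.a * std::cos(th) / (p.l * g.spsi);
  return g;
}

// phase: 0 double stance, 1 single stance. pulse_on already gated.
static inline void rhs(const Par& p, int phase, bool pulse_on, double A,
                       const double* y, double* dy) {
  if (phase == 0) {
    Geom g = geom(p, y[0]);
    double Ts = p.k * std::max(p.mu - g.psi, 0.0);
    double Tp = pulse_on ? A : 0.0;
    dy[0] = y[1];
    dy[1] = (p.m * p.g * p.L * std::sin(y[0]) + (Ts + Tp) * g.dpsi) /
            (p.m * p.L * p.L);
    dy[2] = Ts * g.dpsi * y[1];
    dy[3] = Tp * g.dpsi * y[1];
  } else {
    dy[0] = y[1];
    dy[1] = p.g / p.L * std::sin(y[0]);
    dy[2] = 0.0;
    dy[3] = 0.0;
  }
}

// Dormand-Prince 5(4). Returns y5 (5th order) and the embedded error.
static void dp45(const Par& p, int phase, bool pulse_on, double A,
                 double t, const double* y, double h,
                 double* y5, double* err) {
  static const double
    c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5, c5 = 8.0 / 9;
  static const double
    a21 = 1.0 / 5,
    a31 = 3.0 / 40, a32 = 9.0 / 40,
    a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9,
    a51 = 19372.0 / 6561, a52 = -25360.0 / 2187, a53 = 64448.0 / 6561,
    a54 = -212.0 / 729,
    a61 = 9017.0 / 3168, a62 = -355.0 / 33, a63 = 46732.0 / 5247,
    a64 = 49.0 / 176, a65 = -5103.0 / 18656,
    b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
    b5 = -2187.0 / 6784, b6 = 11.0 / 84,
    e1 = 71.0 / 57600, e3 = -71.0 / 16695, e4 = 71.0 / 1920,
    e5 = -17253.0 / 339200, e6 = 22.0 / 525, e7 = -1.0 / 40;
  (void)t; (void)c2; (void)c3; (void)c4; (void)c5; // autonomous within a segment
  double k1[4], k2[4], k3[4], k4[4], k5[4], k6[4], k7[4], yt[4];
  rhs(p, phase, pulse_on, A, y, k1);
  for (int i = 0; i < 4; ++i) yt[i] = y[i] + h * a21 * k1[i];
  rhs(p, phase, pulse_on, A, yt, k2);
  for (int i = 0; i < 4; ++i) yt[i] = y[i] + h * (a31 * k1[i] + a32 * k2[i]);
  rhs(p, phase, pulse_on, A, yt, k3);
  for (int i = 0; i < 4; ++i)
    yt[i] = y[i] + h * (a41 * k1[i] + a42 * k2[i] + a43 * k3[i]);
  rhs(p, phase, pulse_on, A, yt, k4);
  for (int i = 0; i < 4; ++i)
    yt[i] = y[i] + h * (a51 * k1[i] + a52 * k2[i] + a53 * k3[i] + a54 * k4[i]);
  rhs(p, phase, pulse_on, A, yt, k5);
  for (int i = 0; i < 4; ++i)
    yt[i] = y[i] + h * (a61 * k1[i] + a62 * k2[i] + a63 * k3[i] +
                        a64 * k4[i] + a65 * k5[i]);
  rhs(p, phase, pulse_on, A, yt, k6);
  for (int i = 0; i < 4; ++i)
    y5[i] = y[i] + h * (b1 * k1[i] + b3 * k3[i] + b4 * k4[i] +
                        b5 * k5[i] + b6 * k6[i]);
  rhs(p, phase, pulse_on, A, y5, k7);
  for (int i = 0; i < 4; ++i)
    err[i] = h * (e1 * k1[i] + e3 * k3[i] + e4 * k4[i] + e5 * k5[i] +
                  e6 * k6[i] + e7 * k7[i]);
}

// classic RK4 (fixed-step replication mode, and event re-integration)
static void rk4(const Par& p, int phase, bool pulse_on, double A,
                const double* y, double h, double* yn) {
  double k1[4], k2[4], k3[4], k4[4], yt[4];
  rhs(p, phase, pulse_on, A, y, k1);
  for (int i = 0; i < 4; ++i) yt[i] = y[i] + 0.5 * h * k1[i];
  rhs(p, phase, pulse_on, A, yt, k2);
  for (int i = 0; i < 4; ++i) yt[i] = y[i] + 0.5 * h * k2[i];
  rhs(p, phase, pulse_on, A, yt, k3);
  for (int i = 0; i < 4; ++i) yt[i] = y[i] + h * k3[i];
  rhs(p, phase, pulse_on, A, yt, k4);
  for (int i = 0; i < 4; ++i)
    yn[i] = y[i] + h / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
}

// Event ids.
enum Ev { EV_TOEOFF = 0, EV_FALLBACK = 1, EV_CAP = 2, EV_HEEL = 3 };

static inline double evfun(const Par& p, const Pulse& P, int id, const double* y) {
  switch (id) {
    case EV_TOEOFF:  return geom(p, y[0]).psi - p.mu;
    case EV_FALLBACK: return y[1];
    case EV_CAP:     return geom(p, y[0]).psi - (M_PI - P.eps_cap);
    case EV_HEEL:    return y[0] + p.alpha;
  }
  return 0.0;
}

static inline bool pulse_active_at(const Pulse& P, double t) {
  if (!P.present || P.A <= 0.0) return false;
  double x = t - P.delta;
  double r = x - P.tau_p * std::floor(x / P.tau_p);
  return r < P.width;
}

// earliest pulse on/off boundary strictly after t (with a tiny guard)
static inline double next_pulse_boundary(const Pulse& P, double t) {
  if (!P.present || P.A <= 0.0) return INF;
  double x = t - P.delta;
  double n = std::floor(x / P.tau_p);
  double best = INF;
  for (int j = -1; j <= 1; ++j) {
    double on = P.delta + (n + j) * P.tau_p;
    double off = on + P.width;
    if (on > t + 1e-9 && on < best) best = on;
    if (off > t + 1e-9 && off < best) best = off;
  }
  return best;
}

struct MinTrack {
  double min_FB, min_f;
  MinTrack() : min_FB(INF), min_f(INF) {}
};

static inline double grf_FB(const Par& p, bool pulse_on, double A,
                            const double* y) {
  Geom g = geom(p, y[0]);
  double T = p.k * std::max(p.mu - g.psi, 0.0) + (pulse_on ? A : 0.0);
  double FA = T * g.AC / (p.l * p.L * g.spsi);
  double phi = std::atan2(p.L * std::cos(y[0]), p.a - p.L * std::sin(y[0]));
  return p.m * p.g * std::cos(y[0]) - p.m * p.L * y[1] * y[1] -
         FA * std::sin(phi - y[0]);
}

static inline double grf_ss(const Par& p, const double* y) {
  return p.m * (p.g * std::cos(y[0]) - p.L * y[1] * y[1]);
}

struct Recorder {
  bool on;
  std::vector<double> rows; // t, theta, theta_dot, phase, pulse_on, w_s, w_p
  void push(double t, const double* y, int phase, bool pulse_on) {
    if (!on) return;
    rows.push_back(t); rows.push_back(y[0]); rows.push_back(y[1]);
    rows.push_back((double)phase); rows.push_back(pulse_on ? 1.0 : 0.0);
    rows.push_back(y[2]); rows.push_back(y[3]);
  }
};

// Integrate one phase segment from (t, y) until seg_end or the earliest
// enabled event. Returns -1 if seg_end reached, else the event id; t and y
// are advanced to the stopping point.
static int integrate_to(const Par& p, const Pulse& P, int phase, bool pulse_on,
                        double& t, double* y, double seg_end,
                        const std::vector<int>& events, const Num& num,
                        Recorder& rec, MinTrack& mt, double& h) {
  double e0[4];
  for (size_t i = 0; i < events.size(); ++i) e0[i] = evfun(p, P, events[i], y);
  double guard_end = t + 60.0; // no phase of this model lasts a minute
  while (t < seg_end - 1e-13 && t < guard_end) {
    double hstep = (num.fixed_step > 0.0) ? num.fixed_step
                                          : std::min(h, num.h_max);
    if (t + hstep > seg_end) hstep = seg_end - t;
    double y5[4], err[4];
    bool accept = true;
    if (num.fixed_step > 0.0) {
      rk4(p, phase, pulse_on, P.A, y, hstep, y5);
    } else {
      dp45(p, phase, pulse_on, P.A, t, y, hstep, y5, err);
      double en = 0.0;
      for (int i = 0; i < 4; ++i) {
        double sc = num.atol + num.rtol * std::max(std::fabs(y[i]), std::fabs(y5[i]));
        double e = std::fabs(err[i]) / sc;
        if (e > en) en = e;
      }
      if (en > 1.0) {
        h = hstep * std::max(0.2, 0.9 * std::pow(en, -0.25));
        accept = false;
      } else {
        double fac = 0.9 * std::pow(std::max(en, 1e-16), -0.2);
        h = hstep * std::min(5.0, std::max(0.2, fac));
      }
    }
    if (!accept) continue;
    // event check over [t, t + hstep]
    int hit = -1;
    double t_hit = INF;
    for (size_t i = 0; i < events.size(); ++i) {
      double e1 = evfun(p, P, events[i], y5);
      if (e0[i] == 0.0) { e0[i] = e1; continue; } // left a root at segment start
      if (e1 == 0.0 || (e0[i] > 0.0) != (e1 > 0.0)) {
        // bisect within the step; y(tm) via a single RK4 sub-step
        double lo = 0.0, hi = hstep, ym[4];
        for (int it = 0; it < 100 && (hi - lo) > 1e-14 * std::max(1.0, t); ++it) {
          double mid = 0.5 * (lo + hi);
          rk4(p, phase, pulse_on, P.A, y, mid, ym);
          double em = evfun(p, P, events[i], ym);
          if (em == 0.0) { lo = hi = mid; break; }
          if ((em > 0.0) == (e0[i] > 0.0)) lo = mid; else hi = mid;
        }
        double tm = t + hi;
        if (tm < t_hit) { t_hit = tm; hit = (int)i; }
      }
    }
    if (hit >= 0) {
      double ym[4];
      rk4(p, phase, pulse_on, P.A, y, t_hit - t, ym);
      for (int i = 0; i < 4; ++i) y[i] = ym[i];
      t = t_hit;
      if (phase == 0) mt.min_FB = std::min(mt.min_FB, grf_FB(p, pulse_on, P.A, y));
      else            mt.min_f = std::min(mt.min_f, grf_ss(p, y));
      rec.push(t, y, phase, pulse_on);
      return events[hit];
    }
    t += hstep;
    for (int i = 0; i < 4; ++i) y[i] = y5[i];
    for (size_t i = 0; i < events.size(); ++i) e0[i] = evfun(p, P, events[i], y);
    if (phase == 0) mt.min_FB = std::min(mt.min_FB, grf_FB(p, pulse_on, P.A, y));
    else            mt.min_f = std::min(mt.min_f, grf_ss(p, y));
    rec.push(t, y, phase, pulse_on);
  }
  return -1;
}

// [[Rcpp::export(name = ".walk_cpp")]]
List walk_cpp(List par_, double theta_dot0, int n_steps,
              Nullable<List> pulse_, List num_, bool record,
              double t0 = 0.0, int trailing0 = 0) {
  Par p;
  p.m = as<double>(par_["m"]); p.L = as<double>(par_["L"]);
  p.l = as<double>(par_["l"]); p.g = as<double>(par_["g"]);
  p.alpha = as<double>(par_["alpha"]); p.mu = as<double>(par_["mu"]);
  p.k = as<double>(par_["k"]); p.a = as<double>(par_["a"]);

  Pulse P; P.present = false; P.A = 0; P.width = 0.1; P.tau_p = 1.0;
  P.delta = 0; P.leg = 0; P.policy = 1; P.eps_cap = 0.01;
  if (pulse_.isNotNull()) {
    List pl(pulse_);
    P.present = true;
    P.A = as<double>(pl["amplitude"]);
    P.width = as<double>(pl["width"]);
    P.tau_p = as<double>(pl["period"]);
    P.delta = as<double>(pl["offset"]);
    P.leg = as<int>(pl["leg"]);
    P.policy = as<int>(pl["policy"]);
    P.eps_cap = as<double>(pl["eps_cap"]);
  }

  Num num;
  num.rtol = as<double>(num_["rtol"]); num.atol = as<double>(num_["atol"]);
  num.h_init = as<double>(num_["h_init"]); num.h_max = as<double>(num_["h_max"]);
  num.fixed_step = as<double>(num_["fixed_step"]);
  num.strict = as<bool>(num_["strict"]);

  const double cos2a = std::cos(2.0 * p.alpha);
  double t = t0;
  double y[4] = {p.alpha, theta_dot0, 0.0, 0.0};
  int trailing = trailing0;
  double h = num.h_init;

  Recorder rec; rec.on = record;
  rec.push(t, y, 0, false);

  const int NCOL = 18;
  std::vector<double> steps; steps.reserve((size_t)n_steps * NCOL);
  std::string termination = "COMPLETED";
  int term_step = -1;

  for (int s = 0; s < n_steps; ++s) {
    double t_start = t, td_start = y[1];
    y[2] = 0.0; y[3] = 0.0;
    MinTrack mt;
    bool capped = false, extended = false;
    if (y[1] >= 0.0) { termination = "FALL_BACK"; term_step = s; break; }
    mt.min_FB = grf_FB(p, pulse_active_at(P, t) && trailing == P.leg, P.A, y);

    // ---- double stance ----
    bool ds_done = false, terminated = false;
    double toe_t = NA_REAL, theta_to = NA_REAL, td_to = NA_REAL;
    while (!ds_done && !terminated) {
      bool gated = P.present && P.A > 0.0 && trailing == P.leg;
      bool p_on = gated && pulse_active_at(P, t + 1e-9);
      double seg_end = gated ? next_pulse_boundary(P, t) : INF;
      std::vector<int> evs;
      if (!extended) evs.push_back(EV_TOEOFF);
      else evs.push_back(EV_CAP);
      evs.push_back(EV_FALLBACK);
      evs.push_back(EV_HEEL);
      int code = integrate_to(p, P, 0, p_on, t, y, seg_end, evs, num, rec, mt, h);
      if (code == -1) {
        if (extended) { ds_done = true; } // pulse off ends the extension
        // else: pulse boundary; loop re-gates and continues
      } else if (code == EV_TOEOFF) {
        if (P.policy == 1 && p_on) { extended = true; }
        else ds_done = true;
      } else if (code == EV_CAP) {
        capped = true; ds_done = true;
        if (num.strict) { termination = "LINKAGE_SINGULARITY"; terminated = true; }
      } else if (code == EV_FALLBACK) {
        termination = "FALL_BACK"; terminated = true;
      } else if (code == EV_HEEL) {
        ds_done = true; // degenerate: double stance carried to heel strike
      }
      if (y[0] <= -p.alpha + 1e-12) ds_done = true;
    }
    if (terminated) { term_step = s; break; }
    toe_t = t; theta_to = y[0]; td_to = y[1];
    double w_s = y[2], w_p = y[3];

    // ---- single stance ----
    double td_pre = NA_REAL;
    if (y[0] > -p.alpha + 1e-12) {
      mt.min_f = grf_ss(p, y);
      std::vector<int> evs; evs.push_back(EV_HEEL); evs.push_back(EV_FALLBACK);
      int code = integrate_to(p, P, 1, false, t, y, INF, evs, num, rec, mt, h);
      if (code == EV_FALLBACK) { termination = "FALL_BACK"; term_step = s; break; }
      if (code == -1) { termination = "FALL_BACK"; term_step = s; break; } // guard
    }
    td_pre = y[1];

    bool flyoff = (mt.min_FB < 0.0) || (mt.min_f < 0.0);
    if (num.strict && flyoff) { termination = "FLY_OFF"; term_step = s; break; }

    // ---- collision ----
    double td_post = cos2a * td_pre;
    double t_end = t;
    y[0] = p.alpha; y[1] = td_post;
    int new_trailing = 1 - trailing;

    double row[NCOL] = {
      (double)s, (double)trailing, t_start, toe_t, t_end,
      toe_t - t_start, t_end - t_start,
      td_start, theta_to, td_to, td_pre, td_post,
      w_s + w_p, w_p, mt.min_FB, mt.min_f,
      capped ? 1.0 : 0.0, extended ? 1.0 : 0.0
    };
    for (int i = 0; i < NCOL; ++i) steps.push_back(row[i]);
    trailing = new_trailing;
    rec.push(t, y, 0, false);
  }

  int nrow = (int)(steps.size() / NCOL);
  NumericMatrix sm(nrow, NCOL);
  for (int r = 0; r < nrow; ++r)
    for (int c = 0; c < NCOL; ++c) sm(r, c) = steps[(size_t)r * NCOL + c];
  colnames(sm) = CharacterVector::create(
    "step_index", "trailing_leg", "t_start", "toe_off_time", "heel_strike_time",
    "double_stance_duration", "duration",
    "theta_dot_start", "theta_toe_off", "theta_dot_toe_off",
    "theta_dot_pre", "theta_dot_post",
    "ankle_work", "pulse_work", "min_grf_leading", "min_grf_single_stance",
    "capped", "extended");

  SEXP traj = R_NilValue;
  if (record) {
    int tn = (int)(rec.rows.size() / 7);
    NumericMatrix tm(tn, 7);
    for (int r = 0; r < tn; ++r)
      for (int c = 0; c < 7; ++c) tm(r, c) = rec.rows[(size_t)r * 7 + c];
    colnames(tm) = CharacterVector::create(
      "t", "theta", "theta_dot", "phase", "pulse_on", "w_spring", "w_pulse");
    traj = tm;
  }

  return List::create(
    _["steps"] = sm,
    _["termination"] = termination,
    _["term_step"] = term_step,
    _["t_final"] = t,
    _["state_final"] = NumericVector::create(y[0], y[1]),
    _["trailing_final"] = trailing,
    _["trajectory"] = traj);
}
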