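#include <Rcpp.h>
using namespace Rcpp;

// Fast path for cohort-scale simulation of the Super G task.
//
// Semantics are shared exactly with the pure-R reference engine
// (R/engine.R): semi-implicit Euler on the sample grid, keys evaluated at
// the start of each step, ties on the planet boundary count as inside, and
// the per-attempt plan draw consumes the R RNG stream in a fixed order
// (lapse uniform, then four normals: t_go, tau_right, tau_left, t_rev).

struct Cfg {
  double hold, mw, trial_dur, land_dur, dt, rate, accel, dist, radius;
  int n_steps;       // steps per attempt; samples 0..n_steps
  int land_samples;  // consecutive in-target samples required to land
  int n_trials;
  int max_resets;
};

static Cfg as_cfg(const List& cfg) {
  Cfg c;
  c.hold = cfg["hold_duration"];
  c.mw = cfg["movement_window"];
  c.trial_dur = cfg["trial_duration"];
  c.land_dur = cfg["landing_duration"];
  double rate = cfg["sample_rate"];
  c.rate = rate;
  c.dt = 1.0 / rate;
  c.accel = cfg["force_accel"];
  c.dist = cfg["planet_distance"];
  c.radius = cfg["planet_radius"];
  c.n_steps = (int)std::lround(c.trial_dur * rate);
  c.land_samples = (int)std::lround(c.land_dur * rate);
  c.n_trials = cfg["n_trials"];
  c.max_resets = cfg["max_resets"];
  return c;
}

struct Plan {
  bool lapse;
  double t_go, tau_r, tau_l, t_rev;
};

// params: t_go_mean, tau_right, rho, t_rev_mean, timing_sd, lapse_prob
static Plan draw_plan(const double* p) {
  Plan pl;
  pl.lapse = unif_rand() < p[5];
  if (pl.lapse) {
    pl.t_go = pl.tau_r = pl.tau_l = pl.t_rev = 0.0;
    return pl;
  }
  double sd = p[4];
  pl.t_go = p[0] + norm_rand() * sd;
  pl.tau_r = std::max(0.0, p[1] + norm_rand() * sd);
  pl.tau_l = std::max(0.0, p[2] * pl.tau_r + norm_rand() * sd);
  pl.t_rev = std::max(pl.t_go + pl.tau_r, p[3] + norm_rand() * sd);
  return pl;
}

struct TrialOut {
  double sr, tr, tint, rt, rt_go;
  bool success;
  int resets;
};

static inline bool key_right(const Plan& pl, double t) {
  return !pl.lapse && t >= pl.t_go && t < pl.t_go + pl.tau_r;
}
static inline bool key_left(const Plan& pl, double t) {
  return !pl.lapse && t >= pl.t_rev && t < pl.t_rev + pl.tau_l;
}

// Simulate one attempt; returns true if an early-exit reset occurred.
// On a completed attempt (no reset) fills `out` with the trial metrics.
static bool simulate_attempt(const Plan& pl, const Cfg& c, TrialOut& out) {
  // long-double accumulators mirror R's cumsum() so the R reference engine
  // and this fast path produce bitwise-identical trajectories
  long double vacc = 0.0L, xacc = 0.0L;
  double x = 0.0, v = 0.0;
  double win_end = c.hold + c.mw;
  double rt = NA_REAL, tr = NA_REAL;
  int run = 0, n_left = 0, n_right = 0, n_in_target = 0;
  bool success = false;
  bool kl_prev = key_left(pl, 0.0);

  // sample 0 at t = 0: x = 0 inside start planet, nothing to score
  if (kl_prev && 0.0 >= c.hold) tr = 0.0;  // unreachable (hold > 0), kept for clarity

  for (int s = 1; s <= c.n_steps; s++) {
    double t_prev = (s - 1) * c.dt;
    double t = s * c.dt;
    double a = c.accel * ((key_right(pl, t_prev) ? 1.0 : 0.0) -
                          (key_left(pl, t_prev) ? 1.0 : 0.0));
    double a_dt = a * c.dt;
    vacc += (long double)a_dt;
    v = (double)vacc;
    double v_dt = v * c.dt;
    xacc += (long double)v_dt;
    x = (double)xacc;

    if (t < c.hold && std::abs(x) > c.radius) {
      out.resets++;
      return true;  // early exit: reset this trial's clock and state
    }

    bool kl = key_left(pl, t);
    bool kr = key_right(pl, t);
    bool in_window = t >= c.hold && t < win_end;
    if (in_window) {
      if (kl) n_left++;
      if (kr) n_right++;
      if (kl && !kl_prev && ISNA(tr)) tr = t;
      if (ISNA(rt) && std::abs(x) > c.radius) rt = t;
      bool in_target = std::abs(x - c.dist) <= c.radius;
      if (in_target) {
        n_in_target++;
        run++;
        if (run == c.land_samples) {
          success = true;  // landed: trial ends, remaining samples not emitted
          break;
        }
      } else {
        run = 0;
      }
    }
    kl_prev = kl;
  }

  out.sr = n_right > 0 ? (double)n_left / (double)n_right : NA_REAL;
  out.tr = tr;
  out.tint = n_in_target / c.rate;
  out.rt = rt;
  out.rt_go = ISNA(rt) ? NA_REAL : rt - c.hold;
  out.success = success;
  return false;
}

static TrialOut run_trial_fast(const double* params, const Cfg& c) {
  TrialOut out;
  out.resets = 0;
  for (;;) {
    Plan pl = draw_plan(params);
    bool reset = simulate_attempt(pl, c, out);
    if (!reset) return out;
    if (out.resets >= c.max_resets) {
      // abandoned after repeated early exits: failed trial, nothing scored
      out.sr = NA_REAL; out.tr = NA_REAL; out.tint = 0.0;
      out.rt = NA_REAL; out.rt_go = NA_REAL; out.success = false;
      return out;
    }
  }
}

// Per-trial metrics for one session. Columns:
// sr, tr, tint, rt, rt_go, success, resets (times in seconds).
// [[Rcpp::export]]
NumericMatrix sg_session_metrics_cpp(NumericVector params, List config) {
  Cfg c = as_cfg(config);
  NumericMatrix m(c.n_trials, 7);
  colnames(m) = CharacterVector::create("sr", "tr", "tint", "rt", "rt_go",
                                        "success", "resets");
  for (int i = 0; i < c.n_trials; i++) {
    TrialOut out = run_trial_fast(REAL(params), c);
    m(i, 0) = out.sr;
    m(i, 1) = out.tr;
    m(i, 2) = out.tint;
    m(i, 3) = out.rt;
    m(i, 4) = out.rt_go;
    m(i, 5) = out.success ? 1.0 : 0.0;
    m(i, 6) = out.resets;
  }
  return m;
}

// Session-mean metrics for a whole cohort; one row per participant.
// param_matrix: n x 6 (t_go_mean, tau_right, rho, t_rev_mean, timing_sd,
// lapse_prob). Means are over trials where the metric is defined.
// [[Rcpp::export]]
NumericMatrix sg_cohort_metrics_cpp(NumericMatrix param_matrix, List config) {
  Cfg c = as_cfg(config);
  int n = param_matrix.nrow();
  NumericMatrix res(n, 11);
  colnames(res) = CharacterVector::create(
      "mean_sr", "mean_tr", "mean_tint", "mean_rt", "mean_rt_go",
      "n_success", "n_sr", "n_tr", "n_tint", "n_rt", "n_resets");
  double p[6];
  for (int i = 0; i < n; i++) {
    for (int j = 0; j < 6; j++) p[j] = param_matrix(i, j);
    double sum_sr = 0, sum_tr = 0, sum_tint = 0, sum_rt = 0, sum_rt_go = 0;
    int n_sr = 0, n_tr = 0, n_rt = 0, n_succ = 0, n_resets = 0;
    for (int k = 0; k < c.n_trials; k++) {
      TrialOut out = run_trial_fast(p, c);
      if (!ISNA(out.sr)) { sum_sr += out.sr; n_sr++; }
      if (!ISNA(out.tr)) { sum_tr += out.tr; n_tr++; }
      sum_tint += out.tint;
      if (!ISNA(out.rt)) { sum_rt += out.rt; sum_rt_go += out.rt_go; n_rt++; }
      if (out.success) n_succ++;
      n_resets += out.resets;
    }
    res(i, 0) = n_sr > 0 ? sum_sr / n_sr : NA_REAL;
    res(i, 1) = n_tr > 0 ? sum_tr / n_tr : NA_REAL;
    res(i, 2) = sum_tint / c.n_trials;
    res(i, 3) = n_rt > 0 ? sum_rt / n_rt : NA_REAL;
    res(i, 4) = n_rt > 0 ? sum_rt_go / n_rt : NA_REAL;
    res(i, 5) = n_succ;
    res(i, 6) = n_sr;
    res(i, 7) = n_tr;
    res(i, 8) = c.n_trials;  // tint defined on every trial
    res(i, 9) = n_rt;
    res(i, 10) = n_resets;
  }
  return res;
}
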