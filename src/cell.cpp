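// Single-cell (0D) driver for the ventricular membrane model.
// Integration: Rush-Larsen exponential updates for HH gates, forward Euler
// for V and concentrations, exact rate evaluation at every step.
#include <Rcpp.h>
#include "tt06.h"

using namespace Rcpp;
using namespace tt06;

static NumericVector wrap_state(const double* s) {
  NumericVector out(NSTATE);
  CharacterVector nm(NSTATE);
  for (int k = 0; k < NSTATE; ++k) {
    out[k] = s[k];
    nm[k] = state_name(k);
  }
  out.attr("names") = nm;
  return out;
}

static void unwrap_state(const NumericVector& v, double* s) {
  if (v.size() != NSTATE) stop("state vector must have %d entries", NSTATE);
  for (int k = 0; k < NSTATE; ++k) s[k] = v[k];
}

static void check_finite(const double* s, double t) {
  for (int k = 0; k < NSTATE; ++k) {
    if (!std::isfinite(s[k]))
      stop("non-finite state variable '%s' at t = %.3f ms", state_name(k), t);
  }
}

// One integration step with exact (non-tabulated) rates.
static double cell_step(double* s, double dt, double gks_scale, double istim) {
  double ginf[NGATE], gexp[NGATE];
  const double V = s[iV];
  for (int g = 0; g < NGATE; ++g) {
    double inf, tau;
    gate_inf_tau(g, V, inf, tau);
    ginf[g] = inf;
    gexp[g] = std::exp(-dt / tau);
  }
  VFactors vf = vfactors(V);
  double ENa, EK, EKs, ECa;
  reversals(s, ENa, EK, EKs, ECa);
  double dV = step_membrane(s, dt, gks_scale, istim, vf, ginf, gexp,
                            ENa, EK, EKs, ECa, xk1_inf(V - EK));
  s[iV] += dt * dV;
  return dV;
}

// [[Rcpp::export]]
NumericVector cpp_cell_init() {
  double s[NSTATE];
  init_state(s);
  return wrap_state(s);
}

// [[Rcpp::export]]
NumericVector cpp_cell_step(NumericVector state, double dt, double gks_scale,
                            double istim) {
  double s[NSTATE];
  unwrap_state(state, s);
  check_finite(s, 0.0);   // name the offending input variable, not its fallout
  cell_step(s, dt, gks_scale, istim);
  check_finite(s, dt);
  return wrap_state(s);
}

// Pace a cell for n_beats at cycle length cl.  A rectangular depolarizing
// stimulus of `stim_amp` (uA/uF) and `stim_dur` (ms) starts each cycle.
// Records V every `sample_dt` ms for the last `record_beats` cycles.
// [[Rcpp::export]]
List cpp_cell_pace(NumericVector state, double gks_scale, double dt, double cl,
                   int n_beats, double stim_amp, double stim_dur,
                   double sample_dt, int record_beats) {
  if (dt <= 0) stop("dt must be positive");
  if (cl <= 0) stop("cycle length must be positive");
  double s[NSTATE];
  unwrap_state(state, s);

  int steps_per_beat = (int)std::lround(cl / dt);
  int sample_every = std::max(1, (int)std::lround(sample_dt / dt));
  int rec_from_beat = std::max(0, n_beats - record_beats);

  std::vector<double> tout, vout;
  NumericVector peakV(n_beats), crossed(n_beats);

  for (int b = 0; b < n_beats; ++b) {
    double pk = -1e9;
    bool up = false;
    bool rec = (b >= rec_from_beat);
    if (rec && b == rec_from_beat) { // single sample at recording start
      tout.push_back(0.0);
      vout.push_back(s[iV]);
    }
    double vprev = s[iV];
    for (int k = 0; k < steps_per_beat; ++k) {
      double t = k * dt;
      double istim = (t < stim_dur) ? stim_amp : 0.0;
      cell_step(s, dt, gks_scale, istim);
      if (s[iV] > pk) pk = s[iV];
      if (vprev < -20.0 && s[iV] >= -20.0) up = true;
      vprev = s[iV];
      if (rec && ((k + 1) % sample_every == 0)) {
        tout.push_back((double)(b - rec_from_beat) * cl + (k + 1) * dt);
        vout.push_back(s[iV]);
      }
      if (!std::isfinite(s[iV]))
        check_finite(s, b * cl + t);
    }
    check_finite(s, (b + 1) * cl);
    peakV[b] = pk;
    crossed[b] = up ? 1.0 : 0.0;
  }

  return List::create(_["state"] = wrap_state(s),
                      _["time"] = NumericVector(tout.begin(), tout.end()),
                      _["V"] = NumericVector(vout.begin(), vout.end()),
                      _["peak_V"] = peakV,
                      _["captured"] = crossed);
}

// Free-running (no stimulus schedule) integration used for quiescence and
// fixed-point checks; returns the state and a sampled trace.
// [[Rcpp::export]]
List cpp_cell_run(NumericVector state, double gks_scale, double dt,
                  double duration, double istim, double stim_until,
                  double sample_dt) {
  double s[NSTATE];
  unwrap_state(state, s);
  int nstep = (int)std::lround(duration / dt);
  int sample_every = std::max(1, (int)std::lround(sample_dt / dt));
  std::vector<double> tout, vout;
  tout.push_back(0.0);
  vout.push_back(s[iV]);
  for (int k = 0; k < nstep; ++k) {
    double t = k * dt;
    cell_step(s, dt, gks_scale, (t < stim_until) ? istim : 0.0);
    if ((k + 1) % sample_every == 0) {
      tout.push_back((k + 1) * dt);
      vout.push_back(s[iV]);
    }
  }
  check_finite(s, duration);
  return List::create(_["state"] = wrap_state(s),
                      _["time"] = NumericVector(tout.begin(), tout.end()),
                      _["V"] = NumericVector(vout.begin(), vout.end()));
}
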