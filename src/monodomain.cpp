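// Monodomain reaction-diffusion time loop on a triangulated sheet.
//
// Operator splitting per step: membrane update (Rush-Larsen gates via
// voltage lookup tables sampled from the exact rate functions in tt06.h,
// forward Euler for concentrations) followed by a backward-Euler diffusion
// solve (M + dt K) V = M V* with lumped mass M, by Jacobi-preconditioned
// conjugate gradients warm-started from the previous voltage field.
//
// Reversal potentials (4 logs/node) are refreshed every `rev_every` steps;
// intracellular concentrations drift by < 1e-3 mM over that window so the
// induced voltage error is far below the solver's discretization error.
#include <Rcpp.h>
#include "tt06.h"

using namespace Rcpp;
using namespace tt06;

namespace {

constexpr double VMIN = -120.0, VMAX = 100.0, VSTEP = 0.05;
constexpr int NV = (int)((VMAX - VMIN) / VSTEP) + 1;
constexpr double UMIN = -60.0, UMAX = 220.0;
constexpr int NU = (int)((UMAX - UMIN) / VSTEP) + 1;

// One interleaved row of 28 doubles per voltage-grid point so a node's
// lookup touches two contiguous rows: 11 gate steady states, 11 gate
// exponentials exp(-dt/tau), 6 current factors.
constexpr int TROW = 2 * NGATE + 6;

struct Tables {
  std::vector<double> t;    // TROW * NV
  std::vector<double> xk1;  // NU
  void build(double dt) {
    t.resize((size_t)TROW * NV);
    xk1.resize(NU);
    for (int i = 0; i < NV; ++i) {
      double V = VMIN + i * VSTEP;
      double* row = &t[(size_t)TROW * i];
      for (int g = 0; g < NGATE; ++g) {
        double inf, tau;
        gate_inf_tau(g, V, inf, tau);
        row[g] = inf;
        row[NGATE + g] = std::exp(-dt / tau);
      }
      VFactors f = vfactors(V);
      row[2 * NGATE + 0] = f.cal_c1;
      row[2 * NGATE + 1] = f.cal_c2;
      row[2 * NGATE + 2] = f.naca_e1;
      row[2 * NGATE + 3] = f.naca_e2;
      row[2 * NGATE + 4] = f.nak_f;
      row[2 * NGATE + 5] = f.pk_f;
    }
    for (int i = 0; i < NU; ++i) xk1[i] = xk1_inf(UMIN + i * VSTEP);
  }
};

struct CSR {
  int n;
  const int* p;     // row pointers (n+1)
  const int* j;     // column indices
  std::vector<double> a; // values of A = M + dt*K
  std::vector<double> dinv;
};

// y = A x
inline void spmv(const CSR& A, const double* x, double* y) {
  for (int i = 0; i < A.n; ++i) {
    double acc = 0.0;
    for (int k = A.p[i]; k < A.p[i + 1]; ++k) acc += A.a[k] * x[A.j[k]];
    y[i] = acc;
  }
}

// Jacobi-PCG; x holds the warm start on entry, solution on exit.
int pcg(const CSR& A, const double* b, double* x, double tol, int maxit,
        std::vector<double>& r, std::vector<double>& z, std::vector<double>& pv,
        std::vector<double>& q) {
  const int n = A.n;
  spmv(A, x, r.data());
  double bnorm2 = 0.0;
  for (int i = 0; i < n; ++i) {
    r[i] = b[i] - r[i];
    bnorm2 += b[i] * b[i];
  }
  double tol2 = tol * tol * (bnorm2 > 0 ? bnorm2 : 1.0);
  double rz = 0.0;
  for (int i = 0; i < n; ++i) {
    z[i] = A.dinv[i] * r[i];
    rz += r[i] * z[i];
  }
  double rnorm2 = 0.0;
  for (int i = 0; i < n; ++i) rnorm2 += r[i] * r[i];
  if (rnorm2 <= tol2) return 0;
  std::copy(z.begin(), z.end(), pv.begin());
  int it = 0;
  for (; it < maxit; ++it) {
    spmv(A, pv.data(), q.data());
    double pq = 0.0;
    for (int i = 0; i < n; ++i) pq += pv[i] * q[i];
    double alpha = rz / pq;
    rnorm2 = 0.0;
    for (int i = 0; i < n; ++i) {
      x[i] += alpha * pv[i];
      r[i] -= alpha * q[i];
      rnorm2 += r[i] * r[i];
    }
    if (rnorm2 <= tol2) { ++it; break; }
    double rz_new = 0.0;
    for (int i = 0; i < n; ++i) {
      z[i] = A.dinv[i] * r[i];
      rz_new += r[i] * z[i];
    }
    double beta = rz_new / rz;
    rz = rz_new;
    for (int i = 0; i < n; ++i) pv[i] = z[i] + beta * pv[i];
  }
  return it;
}

inline void table_weights(double V, int& i0, double& w) {
  double f = (V - VMIN) / VSTEP;
  if (f < 0) f = 0;
  if (f > NV - 2) f = NV - 2;
  i0 = (int)f;
  w = f - i0;
}

} // namespace

// [[Rcpp::export]]
List cpp_monodomain_run(IntegerVector Kp, IntegerVector Kj, NumericVector Kx,
                        NumericVector mlump, NumericVector gks_node,
                        NumericVector stim_node, NumericVector init_state,
                        double dt, double cl, int n_beats, double stim_dur,
                        double sample_dt, int record_from_beat,
                        double stop_margin, int rev_every, double cg_tol,
                        int cg_maxit, bool track_rt) {
  const int n = mlump.size();
  if (Kp.size() != n + 1) stop("stiffness row pointer length mismatch");
  if (gks_node.size() != n || stim_node.size() != n)
    stop("per-node parameter length mismatch");
  if (init_state.size() != NSTATE) stop("initial state must have %d entries", NSTATE);
  if (dt <= 0 || cl <= 0 || n_beats < 1) stop("invalid time stepping parameters");

  // A = M + dt K  (same sparsity as K)
  CSR A;
  A.n = n;
  A.p = INTEGER(Kp);
  A.j = INTEGER(Kj);
  A.a.resize(Kx.size());
  A.dinv.resize(n);
  for (int i = 0; i < n; ++i) {
    for (int k = A.p[i]; k < A.p[i + 1]; ++k) {
      double v = dt * Kx[k];
      if (A.j[k] == i) {
        v += mlump[i];
        A.dinv[i] = 1.0 / v;
      }
      A.a[k] = v;
    }
  }

  Tables tab;
  tab.build(dt);

  // node states, node-major
  std::vector<double> S((size_t)n * NSTATE);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < NSTATE; ++k) S[(size_t)i * NSTATE + k] = init_state[k];

  std::vector<double> V(n, init_state[iV]), Vprev(n, init_state[iV]), b(n);
  std::vector<double> ENa(n), EK(n), EKs(n), ECa(n);
  std::vector<double> cg_r(n), cg_z(n), cg_p(n), cg_q(n);

  const int steps_per_beat = (int)std::lround(cl / dt);
  const int sample_every = std::max(1, (int)std::lround(sample_dt / dt));
  const int rec_from = std::max(0, record_from_beat);
  const int rec_beats = std::max(0, n_beats - rec_from);
  const int nsamp = rec_beats > 0 ? rec_beats * (steps_per_beat / sample_every) + 1 : 0;

  NumericMatrix Vrec(nsamp > 0 ? n : 0, nsamp);
  NumericVector rec_t(nsamp);
  int isamp = 0;

  NumericMatrix AT(n, n_beats), RT(n, n_beats);
  std::fill(AT.begin(), AT.end(), NA_REAL);
  std::fill(RT.begin(), RT.end(), NA_REAL);
  IntegerVector n_act(n_beats);
  double cg_iter_total = 0;
  long nsolve = 0;

  bool stopped = false;
  double t_end = 0.0;

  for (int beat = 0; beat < n_beats && !stopped; ++beat) {
    double* at = &AT(0, beat);
    double* rt = &RT(0, beat);
    int activated = 0;
    double all_active_since = -1.0;

    if (beat >= rec_from && isamp == 0) { // sample at start of first recorded beat
      for (int i = 0; i < n; ++i) Vrec(i, 0) = V[i];
      rec_t[0] = 0.0;
      isamp = 1;
    }

    for (int k = 0; k < steps_per_beat; ++k) {
      double t = k * dt;
      bool stim_on = (t < stim_dur);

      if ((k % rev_every) == 0) {
        for (int i = 0; i < n; ++i)
          reversals(&S[(size_t)i * NSTATE], ENa[i], EK[i], EKs[i], ECa[i]);
      }

      // membrane (reaction) substep
      for (int i = 0; i < n; ++i) {
        double* s = &S[(size_t)i * NSTATE];
        s[iV] = V[i];
        double v = V[i];
        if (v < -150.0 || v > 150.0 || !std::isfinite(v))
          stop("instability: V = %.1f mV at node %d, t = %.2f ms (beat %d)",
               v, i + 1, beat * cl + t, beat + 1);
        int i0; double w;
        table_weights(v, i0, w);
        const double* r0 = &tab.t[(size_t)TROW * i0];
        const double* r1 = r0 + TROW;
        double ginf[NGATE], gexp[NGATE];
        for (int g = 0; g < NGATE; ++g) {
          ginf[g] = r0[g] + w * (r1[g] - r0[g]);
          gexp[g] = r0[NGATE + g] + w * (r1[NGATE + g] - r0[NGATE + g]);
        }
        const double* f0 = r0 + 2 * NGATE;
        const double* f1 = r1 + 2 * NGATE;
        VFactors vf;
        vf.cal_c1 = f0[0] + w * (f1[0] - f0[0]);
        vf.cal_c2 = f0[1] + w * (f1[1] - f0[1]);
        vf.naca_e1 = f0[2] + w * (f1[2] - f0[2]);
        vf.naca_e2 = f0[3] + w * (f1[3] - f0[3]);
        vf.nak_f = f0[4] + w * (f1[4] - f0[4]);
        vf.pk_f = f0[5] + w * (f1[5] - f0[5]);
        // I_K1 factor from u = V - E_K
        double uf = (v - EK[i] - UMIN) / VSTEP;
        if (uf < 0) uf = 0;
        if (uf > NU - 2) uf = NU - 2;
        int u0 = (int)uf;
        double uw = uf - u0;
        double xk1 = tab.xk1[u0] + uw * (tab.xk1[u0 + 1] - tab.xk1[u0]);
        double istim = stim_on ? stim_node[i] : 0.0;
        double dV = step_membrane(s, dt, gks_node[i], istim, vf, ginf, gexp,
                                  ENa[i], EK[i], EKs[i], ECa[i], xk1);
        b[i] = mlump[i] * (v + dt * dV);
      }

      // diffusion substep
      int its = pcg(A, b.data(), V.data(), cg_tol, cg_maxit, cg_r, cg_z, cg_p, cg_q);
      cg_iter_total += its;
      ++nsolve;

      // crossing detection on the post-step field
      double tn = (k + 1) * dt;
      for (int i = 0; i < n; ++i) {
        double v0 = Vprev[i], v1 = V[i];
        if (ISNA(at[i]) && v0 < -20.0 && v1 >= -20.0) {
          at[i] = tn - dt * (v1 - (-20.0)) / (v1 - v0);
          ++activated;
        } else if (track_rt && !ISNA(at[i]) && ISNA(rt[i]) && v0 >= -70.0 &&
                   v1 < -70.0 && tn > at[i]) {
          rt[i] = tn - dt * ((-70.0) - v1) / (v0 - v1);
        }
      }
      std::copy(V.begin(), V.end(), Vprev.begin());

      if (beat >= rec_from && ((k + 1) % sample_every == 0) && isamp < nsamp) {
        for (int i = 0; i < n; ++i) Vrec(i, isamp) = V[i];
        rec_t[isamp] = (double)(beat - rec_from) * cl + tn;
        ++isamp;
      }

      t_end = beat * cl + tn;
      if (stop_margin >= 0 && activated == n) {
        if (all_active_since < 0) all_active_since = tn;
        else if (tn - all_active_since >= stop_margin) { stopped = true; break; }
      }
      if ((k & 1023) == 0) Rcpp::checkUserInterrupt();
    }
    n_act[beat] = activated;
  }

  // final per-node voltage back into state array for export
  for (int i = 0; i < n; ++i) S[(size_t)i * NSTATE + iV] = V[i];

  NumericMatrix Sout(NSTATE, n);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < NSTATE; ++k) Sout(k, i) = S[(size_t)i * NSTATE + k];

  return List::create(_["V"] = Vrec, _["time"] = rec_t,
                      _["AT"] = AT, _["RT"] = RT,
                      _["n_activated"] = n_act,
                      _["cg_mean_iter"] = nsolve ? cg_iter_total / nsolve : 0.0,
                      _["stopped_early"] = stopped, _["t_end"] = t_end,
                      _["final_state"] = Sout);
}
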