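// Ten Tusscher-Panfilov (2006) human ventricular membrane model, epicardial
// parameter set.  Shared by the single-cell driver and the tissue solver:
// the tissue path samples the same rate functions into lookup tables, so the
// two integration paths share one definition of the model.
//
// Units: mV, ms, mM; currents in pA/pF (= uA/uF, so dV/dt in mV/ms).
#ifndef BZEP_TT06_H
#define BZEP_TT06_H

#include <cmath>

namespace tt06 {

// --- physical constants -------------------------------------------------
constexpr double Rgas = 8314.472;     // mJ/(mol K)
constexpr double Frdy = 96485.3415;   // C/mol
constexpr double Temp = 310.0;        // K
constexpr double RTONF = Rgas * Temp / Frdy;   // mV

// --- extracellular concentrations (mM) ---------------------------------
constexpr double Ko = 5.4, Cao = 2.0, Nao = 140.0;

// --- cell geometry / capacitance (original formulation) ------------------
constexpr double Vc = 0.016404, Vsr = 0.001094, Vss = 0.00005468;
constexpr double CAP = 0.185;

// --- buffering ----------------------------------------------------------
constexpr double Bufc = 0.2,  Kbufc = 0.001;
constexpr double Bufsr = 10.0, Kbufsr = 0.3;
constexpr double Bufss = 0.4, Kbufss = 0.00025;

// --- SR calcium handling ------------------------------------------------
constexpr double Vmaxup = 0.006375, Kup = 0.00025;
constexpr double Vrel = 0.102, k1p = 0.15, k2p = 0.045, k3 = 0.060,
                 k4 = 0.005, EC = 1.5, maxsr = 2.5, minsr = 1.0;
constexpr double Vleak = 0.00036, Vxfer = 0.0038;

// --- maximal conductances / permeabilities (epicardial) ------------------
constexpr double gNa = 14.838, gK1 = 5.405, gKr = 0.153, gKs_epi = 0.392;
constexpr double gto_epi = 0.294, gCaL = 0.00003980;
constexpr double gbna = 0.00029, gbca = 0.000592;
constexpr double gpCa = 0.1238, KpCa = 0.0005, gpK = 0.0146;
constexpr double pKNa = 0.03;
constexpr double knak = 2.724, KmK = 1.0, KmNa = 40.0;
constexpr double knaca = 1000.0, KmNai = 87.5, KmCa = 1.38, ksat = 0.1,
                 gam = 0.35, alpha_naca = 2.5;

// --- state vector layout -------------------------------------------------
// 19 states; gates contiguous for Rush-Larsen updates.
// The 11 voltage-dependent HH gates occupy a contiguous block (iM..iXs)
// in the rate-function order of gate_inf_tau(); fCass (a Ca_ss-dependent
// gate) deliberately sits outside that block.
enum StateIdx {
  iV = 0, iKi, iNai, iCai, iCass, iCasr, iRbar,
  iM, iH, iJ, iD, iF, iF2, iR, iS, iXr1, iXr2, iXs, iFcass
};
constexpr int NSTATE = 19;
constexpr int NGATE  = 11;           // V-dependent HH gates (m..xs)
constexpr int GATE0  = iM;           // first V-gate slot

inline const char* state_name(int k) {
  static const char* nm[NSTATE] = {
    "V", "K_i", "Na_i", "Ca_i", "Ca_ss", "Ca_sr", "Rbar",
    "m", "h", "j", "d", "f", "f2", "r", "s", "xr1", "xr2", "xs", "fCass"};
  return nm[k];
}

// Published epicardial initial conditions (resting, unpaced).
inline void init_state(double* s) {
  s[iV] = -86.2; s[iKi] = 138.3; s[iNai] = 7.67;
  s[iCai] = 0.00007; s[iCass] = 0.00007; s[iCasr] = 1.3; s[iRbar] = 1.0;
  s[iM] = 0.0; s[iH] = 0.75; s[iJ] = 0.75;
  s[iD] = 0.0; s[iF] = 1.0; s[iF2] = 1.0; s[iFcass] = 1.0;
  s[iR] = 0.0; s[iS] = 1.0; s[iXr1] = 0.0; s[iXr2] = 1.0; s[iXs] = 0.0;
  // (order of assignments is by name; layout per StateIdx)
}

// --- Hodgkin-Huxley rate functions (steady state + time constant) --------
// Gate order: m h j d f f2 r s xr1 xr2 xs
inline void gate_inf_tau(int g, double V, double& inf, double& tau) {
  switch (g) {
  case 0: { // m
    double a = 1.0 / (1.0 + std::exp((-60.0 - V) / 5.0));
    double b = 0.1 / (1.0 + std::exp((V + 35.0) / 5.0)) +
               0.1 / (1.0 + std::exp((V - 50.0) / 200.0));
    inf = 1.0 / std::pow(1.0 + std::exp((-56.86 - V) / 9.03), 2);
    tau = a * b;
    break;
  }
  case 1: { // h
    inf = 1.0 / std::pow(1.0 + std::exp((V + 71.55) / 7.43), 2);
    double a, b;
    if (V >= -40.0) {
      a = 0.0;
      b = 0.77 / (0.13 * (1.0 + std::exp(-(V + 10.66) / 11.1)));
    } else {
      a = 0.057 * std::exp(-(V + 80.0) / 6.8);
      b = 2.7 * std::exp(0.079 * V) + 310000.0 * std::exp(0.3485 * V);
    }
    tau = 1.0 / (a + b);
    break;
  }
  case 2: { // j
    inf = 1.0 / std::pow(1.0 + std::exp((V + 71.55) / 7.43), 2);
    double a, b;
    if (V >= -40.0) {
      a = 0.0;
      b = 0.6 * std::exp(0.057 * V) / (1.0 + std::exp(-0.1 * (V + 32.0)));
    } else {
      a = (-25428.0 * std::exp(0.2444 * V) - 6.948e-6 * std::exp(-0.04391 * V)) *
          (V + 37.78) / (1.0 + std::exp(0.311 * (V + 79.23)));
      b = 0.02424 * std::exp(-0.01052 * V) /
          (1.0 + std::exp(-0.1378 * (V + 40.14)));
    }
    tau = 1.0 / (a + b);
    break;
  }
  case 3: { // d
    inf = 1.0 / (1.0 + std::exp((-8.0 - V) / 7.5));
    double a = 1.4 / (1.0 + std::exp((-35.0 - V) / 13.0)) + 0.25;
    double b = 1.4 / (1.0 + std::exp((V + 5.0) / 5.0));
    double c = 1.0 / (1.0 + std::exp((50.0 - V) / 20.0));
    tau = a * b + c;
    break;
  }
  case 4: { // f
    inf = 1.0 / (1.0 + std::exp((V + 20.0) / 7.0));
    tau = 1102.5 * std::exp(-(V + 27.0) * (V + 27.0) / 225.0) +
          200.0 / (1.0 + std::exp((13.0 - V) / 10.0)) +
          180.0 / (1.0 + std::exp((V + 30.0) / 10.0)) + 20.0;
    break;
  }
  case 5: { // f2
    inf = 0.67 / (1.0 + std::exp((V + 35.0) / 7.0)) + 0.33;
    tau = 562.0 * std::exp(-(V + 27.0) * (V + 27.0) / 240.0) +
          31.0 / (1.0 + std::exp((25.0 - V) / 10.0)) +
          80.0 / (1.0 + std::exp((V + 30.0) / 10.0));
    break;
  }
  case 6: { // r (epi)
    inf = 1.0 / (1.0 + std::exp((20.0 - V) / 6.0));
    tau = 9.5 * std::exp(-(V + 40.0) * (V + 40.0) / 1800.0) + 0.8;
    break;
  }
  case 7: { // s (epi)
    inf = 1.0 / (1.0 + std::exp((V + 20.0) / 5.0));
    tau = 85.0 * std::exp(-(V + 45.0) * (V + 45.0) / 320.0) +
          5.0 / (1.0 + std::exp((V - 20.0) / 5.0)) + 3.0;
    break;
  }
  case 8: { // xr1
    inf = 1.0 / (1.0 + std::exp((-26.0 - V) / 7.0));
    tau = (450.0 / (1.0 + std::exp((-45.0 - V) / 10.0))) *
          (6.0 / (1.0 + std::exp((V + 30.0) / 11.5)));
    break;
  }
  case 9: { // xr2
    inf = 1.0 / (1.0 + std::exp((V + 88.0) / 24.0));
    tau = (3.0 / (1.0 + std::exp((-60.0 - V) / 20.0))) *
          (1.12 / (1.0 + std::exp((V - 60.0) / 20.0)));
    break;
  }
  default: { // 10: xs
    inf = 1.0 / (1.0 + std::exp((-5.0 - V) / 14.0));
    tau = (1400.0 / std::sqrt(1.0 + std::exp((5.0 - V) / 6.0))) *
          (1.0 / (1.0 + std::exp((V - 35.0) / 15.0))) + 80.0;
    break;
  }
  }
}

// --- voltage-dependent current factors (tabulated for tissue) ------------
struct VFactors {
  double cal_c1, cal_c2;   // I_CaL = gCaL*d*f*f2*fCass*(c1*Ca_ss - c2)
  double naca_e1, naca_e2; // exp(gam V F/RT), exp((gam-1) V F/RT)
  double nak_f;            // voltage factor of I_NaK
  double pk_f;             // voltage factor of I_pK
};

inline VFactors vfactors(double V) {
  VFactors vf;
  double vfrt2 = 2.0 * (V - 15.0) / RTONF;
  double fac;  // F * x / (exp(x) - 1), finite at x = 0
  if (std::fabs(vfrt2) < 1e-5) {
    fac = Frdy / (1.0 + 0.5 * vfrt2 + vfrt2 * vfrt2 / 6.0);
  } else {
    fac = Frdy * vfrt2 / (std::exp(vfrt2) - 1.0);
  }
  double e2v = std::exp(vfrt2);
  vf.cal_c1 = 2.0 * fac * 0.25 * e2v;   // 4*(V-15)F/RT * F * 0.25 e2v/(e2v-1)
  vf.cal_c2 = 2.0 * fac * Cao;
  vf.naca_e1 = std::exp(gam * V / RTONF);
  vf.naca_e2 = std::exp((gam - 1.0) * V / RTONF);
  vf.nak_f = 1.0 / (1.0 + 0.1245 * std::exp(-0.1 * V / RTONF) +
                    0.0353 * std::exp(-V / RTONF));
  vf.pk_f = 1.0 / (1.0 + std::exp((25.0 - V) / 5.98));
  return vf;
}

// Inward-rectifier open probability as a function of u = V - E_K.
inline double xk1_inf(double u) {
  double a = 0.1 / (1.0 + std::exp(0.06 * (u - 200.0)));
  double b = (3.0 * std::exp(0.0002 * (u + 100.0)) + std::exp(0.1 * (u - 10.0))) /
             (1.0 + std::exp(-0.5 * u));
  return a / (a + b);
}

// 1 - exp(-x) for small positive x (x <= ~0.05) without calling exp.
inline double one_m_exp_small(double x) {
  return x * (1.0 - 0.5 * x * (1.0 - x / 3.0));
}

// --- one membrane step (Rush-Larsen gates + forward-Euler the rest) ------
// gexp[g] = exp(-dt/tau_g), ginf[g] = steady state, both at current V.
// xk1v = inward-rectifier open probability at V - E_K (exact or tabulated).
// Returns dV/dt contribution of ionic + stimulus currents (mV/ms); the
// caller advances V (single cell) or hands it to the PDE splitting (tissue).
inline double step_membrane(double* s, double dt, double gks_scale,
                            double Istim, const VFactors& vf,
                            const double* ginf, const double* gexp,
                            double ENa, double EK, double EKs, double ECa,
                            double xk1v) {
  const double V = s[iV];

  // gates
  for (int g = 0; g < NGATE; ++g) {
    double& x = s[GATE0 + g];
    x = ginf[g] - (ginf[g] - x) * gexp[g];
  }
  // fCass gate depends on Ca_ss
  {
    double q = s[iCass] / 0.05;
    double den = 1.0 + q * q;
    double inf = 0.6 / den + 0.4;
    double tau = 80.0 / den + 2.0;
    s[iFcass] += (inf - s[iFcass]) * one_m_exp_small(dt / tau);
  }

  // currents (pA/pF)
  double INa = gNa * s[iM] * s[iM] * s[iM] * s[iH] * s[iJ] * (V - ENa);
  double ICaL = gCaL * s[iD] * s[iF] * s[iF2] * s[iFcass] *
                (vf.cal_c1 * s[iCass] - vf.cal_c2);
  double Ito = gto_epi * s[iR] * s[iS] * (V - EK);
  double IKr = gKr * std::sqrt(Ko / 5.4) * s[iXr1] * s[iXr2] * (V - EK);
  double IKs = gKs_epi * gks_scale * s[iXs] * s[iXs] * (V - EKs);
  double IK1 = gK1 * std::sqrt(Ko / 5.4) * xk1v * (V - EK);
  double Nai3 = s[iNai] * s[iNai] * s[iNai];
  double INaCa = knaca *
      (vf.naca_e1 * Nai3 * Cao - vf.naca_e2 * Nao * Nao * Nao * s[iCai] * alpha_naca) /
      ((KmNai * KmNai * KmNai + Nao * Nao * Nao) * (KmCa + Cao) *
       (1.0 + ksat * vf.naca_e2));
  double INaK = knak * (Ko / (Ko + KmK)) * (s[iNai] / (s[iNai] + KmNa)) * vf.nak_f;
  double IpCa = gpCa * s[iCai] / (s[iCai] + KpCa);
  double IpK = gpK * vf.pk_f * (V - EK);
  double IbNa = gbna * (V - ENa);
  double IbCa = gbca * (V - ECa);

  // SR calcium fluxes (mM/ms)
  double kcasr = maxsr - (maxsr - minsr) / (1.0 + (EC / s[iCasr]) * (EC / s[iCasr]));
  double k1 = k1p / kcasr;
  double k2 = k2p * kcasr;
  double Cass2 = s[iCass] * s[iCass];
  double O = k1 * Cass2 * s[iRbar] / (k3 + k1 * Cass2);
  s[iRbar] += dt * (-k2 * s[iCass] * s[iRbar] + k4 * (1.0 - s[iRbar]));
  double Irel = Vrel * O * (s[iCasr] - s[iCass]);
  double Ileak = Vleak * (s[iCasr] - s[iCai]);
  double Iup = Vmaxup / (1.0 + (Kup / s[iCai]) * (Kup / s[iCai]));
  double Ixfer = Vxfer * (s[iCass] - s[iCai]);

  // buffered concentration updates
  double bc = 1.0 / (1.0 + Bufc * Kbufc / ((s[iCai] + Kbufc) * (s[iCai] + Kbufc)));
  double bsr = 1.0 / (1.0 + Bufsr * Kbufsr / ((s[iCasr] + Kbufsr) * (s[iCasr] + Kbufsr)));
  double bss = 1.0 / (1.0 + Bufss * Kbufss / ((s[iCass] + Kbufss) * (s[iCass] + Kbufss)));
  double dCai = bc * ((Ileak - Iup) * Vsr / Vc + Ixfer -
                      (IbCa + IpCa - 2.0 * INaCa) * CAP / (2.0 * Vc * Frdy));
  double dCasr = bsr * (Iup - Irel - Ileak);
  double dCass = bss * (-ICaL * CAP / (2.0 * Vss * Frdy) + Irel * Vsr / Vss -
                        Ixfer * Vc / Vss);
  s[iCai] += dt * dCai;
  s[iCasr] += dt * dCasr;
  s[iCass] += dt * dCass;
  s[iNai] += dt * (-(INa + IbNa + 3.0 * INaK + 3.0 * INaCa) * CAP / (Vc * Frdy));
  s[iKi] += dt * (-(IK1 + Ito + IKr + IKs - 2.0 * INaK + IpK - Istim) *
                  CAP / (Vc * Frdy));

  double Iion = INa + ICaL + Ito + IKr + IKs + IK1 + INaCa + INaK + IpCa +
                IpK + IbNa + IbCa;
  return -Iion + Istim;   // mV/ms; Istim > 0 depolarizes
}

// Reversal potentials from current concentrations.
inline void reversals(const double* s, double& ENa, double& EK, double& EKs,
                      double& ECa) {
  ENa = RTONF * std::log(Nao / s[iNai]);
  EK = RTONF * std::log(Ko / s[iKi]);
  EKs = RTONF * std::log((Ko + pKNa * Nao) / (s[iKi] + pKNa * s[iNai]));
  ECa = 0.5 * RTONF * std::log(Cao / s[iCai]);
}

} // namespace tt06

#endif
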