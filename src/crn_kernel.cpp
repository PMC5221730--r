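// Courtemanche-Ramirez-Nattel (1998) human atrial membrane model.
// Chronic-AF remodeling enters through the parameter vector built on the R
// side. Units throughout: mV, ms, mM, pA/pF, cm. Fixed-step integration:
// Rush-Larsen for Hodgkin-Huxley gates, forward Euler for V and
// concentrations. Voltage-dependent gate kinetics and current shape factors
// are tabulated over V in [-100, 70] mV (0.05 mV grid, linear interpolation);
// the tables depend on dt only, never on the scalable parameters, so scaled
// populations share the arithmetic path exactly.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <cstdio>
#ifdef __SSE2__
#include <xmmintrin.h>
#endif
using namespace Rcpp;

// flush denormals to zero inside the hot loops (decaying gates otherwise
// linger in the subnormal range at a large per-op cost)
static inline void set_ftz() {
#ifdef __SSE2__
  _mm_setcsr(_mm_getcsr() | 0x8040);
#endif
}

static const double RGAS = 8.3143, TEMP = 310.0, FARADAY = 96.4867;
static const double RTF = RGAS * TEMP / FARADAY;
static const double CM = 100.0;                       // pF
static const double VI = 13668.0, VUP = 1109.52, VREL = 96.48; // um^3
static const double KO = 5.4, NAO = 140.0, CAO = 1.8; // mM
static const double KMNAI = 10.0, KMKO = 1.5;
static const double KMNA = 87.5, KMCA = 1.38, KSAT = 0.1, GAMA = 0.35;
static const double TRPN = 0.07, KMTRPN = 0.0005;
static const double CMDN = 0.05, KMCMDN = 0.00238;
static const double CSQN = 10.0, KMCSQN = 0.8;
static const double CAUPMAX = 15.0, KUP = 0.00092;
static const double TAU_TR = 180.0, TAU_U = 8.0, TAU_FCA = 2.0;
static const double KQ10 = 3.0;

// state layout (NSTATE = 21)
enum { iV = 0, iM, iH, iJ, iOA, iOI, iUA, iUI, iXR, iXS, iD, iF, iFCA,
       iU, iVV, iW, iNAI, iKI, iCAI, iCAUP, iCAREL };
static const int NSTATE = 21;

// parameter layout (order contract shared with R/cell-params.R)
enum { pGNA = 0, pGCAL, pGTO, pGKUR, pGKR, pGKS, pGK1, pINAK, pINACA,
       pIUP, pIPCA, pGBNA, pGBCA, pKREL };
static const int NPAR = 14;

struct Pars {
  double gNa, gCaL, gto, gKur, gKr, gKs, gK1, INaK, INaCa, Iup, IpCa,
         gbNa, gbCa, Krel;
};

static double* par_field(Pars& q, int idx) {
  switch (idx) {
    case pGNA: return &q.gNa;    case pGCAL: return &q.gCaL;
    case pGTO: return &q.gto;    case pGKUR: return &q.gKur;
    case pGKR: return &q.gKr;    case pGKS: return &q.gKs;
    case pGK1: return &q.gK1;    case pINAK: return &q.INaK;
    case pINACA: return &q.INaCa; case pIUP: return &q.Iup;
    case pIPCA: return &q.IpCa;  case pGBNA: return &q.gbNa;
    case pGBCA: return &q.gbCa;  case pKREL: return &q.Krel;
  }
  stop("invalid parameter index %d", idx);
}

static Pars unpack(const NumericVector& p) {
  if (p.size() != NPAR) stop("parameter vector must have %d entries", NPAR);
  Pars q;
  q.gNa = p[pGNA];   q.gCaL = p[pGCAL]; q.gto = p[pGTO];  q.gKur = p[pGKUR];
  q.gKr = p[pGKR];   q.gKs = p[pGKS];   q.gK1 = p[pGK1];  q.INaK = p[pINAK];
  q.INaCa = p[pINACA]; q.Iup = p[pIUP]; q.IpCa = p[pIPCA];
  q.gbNa = p[pGBNA]; q.gbCa = p[pGBCA]; q.Krel = p[pKREL];
  return q;
}

// ---- voltage-dependent gate kinetics (exact formulas) ----------------------

struct GateVK { double inf, tau; };

static inline double safe_ratio(double num, double den, double lim) {
  // limit value at removable singularities of the rate expressions
  return (std::fabs(den) < 1e-10) ? lim : num / den;
}

static void gates_of_v(double V, GateVK g[12]) {
  // order: m h j oa oi ua ui xr xs d f w
  double am = safe_ratio(0.32 * (V + 47.13),
                         1.0 - std::exp(-0.1 * (V + 47.13)), 3.2);
  double bm = 0.08 * std::exp(-V / 11.0);
  g[0].inf = am / (am + bm); g[0].tau = 1.0 / (am + bm);

  double ah, bh, aj, bj;
  if (V >= -40.0) {
    ah = 0.0;
    bh = 1.0 / (0.13 * (1.0 + std::exp(-(V + 10.66) / 11.1)));
    aj = 0.0;
    bj = 0.3 * std::exp(-2.535e-7 * V) / (1.0 + std::exp(-0.1 * (V + 32.0)));
  } else {
    ah = 0.135 * std::exp(-(V + 80.0) / 6.8);
    bh = 3.56 * std::exp(0.079 * V) + 3.1e5 * std::exp(0.35 * V);
    aj = (-1.2714e5 * std::exp(0.2444 * V) - 3.474e-5 * std::exp(-0.04391 * V))
         * (V + 37.78) / (1.0 + std::exp(0.311 * (V + 79.23)));
    bj = 0.1212 * std::exp(-0.01052 * V) /
         (1.0 + std::exp(-0.1378 * (V + 40.14)));
  }
  g[1].inf = ah / (ah + bh); g[1].tau = 1.0 / (ah + bh);
  g[2].inf = aj / (aj + bj); g[2].tau = 1.0 / (aj + bj);

  double aoa = 0.65 / (std::exp(-(V + 10.0) / 8.5) +
                       std::exp(-(V - 30.0) / 59.0));
  double boa = 0.65 / (2.5 + std::exp((V + 82.0) / 17.0));
  g[3].inf = 1.0 / (1.0 + std::exp(-(V + 20.47) / 17.54));
  g[3].tau = 1.0 / ((aoa + boa) * KQ10);

  double aoi = 1.0 / (18.53 + std::exp((V + 113.7) / 10.95));
  double boi = 1.0 / (35.56 + std::exp(-(V + 1.26) / 7.44));
  g[4].inf = 1.0 / (1.0 + std::exp((V + 43.1) / 5.3));
  g[4].tau = 1.0 / ((aoi + boi) * KQ10);

  // ua shares alpha/beta with oa
  g[5].inf = 1.0 / (1.0 + std::exp(-(V + 30.3) / 9.6));
  g[5].tau = g[3].tau;

  double aui = 1.0 / (21.0 + std::exp(-(V - 185.0) / 28.0));
  double bui = std::exp((V - 158.0) / 16.0);
  g[6].inf = 1.0 / (1.0 + std::exp((V - 99.45) / 27.48));
  g[6].tau = 1.0 / ((aui + bui) * KQ10);

  double axr = safe_ratio(0.0003 * (V + 14.1),
                          1.0 - std::exp(-(V + 14.1) / 5.0), 0.0015);
  double bxr = safe_ratio(7.3898e-5 * (V - 3.3328),
                          std::exp((V - 3.3328) / 5.1237) - 1.0,
                          7.3898e-5 * 5.1237);
  g[7].inf = 1.0 / (1.0 + std::exp(-(V + 14.1) / 6.5));
  g[7].tau = 1.0 / (axr + bxr);

  double axs = safe_ratio(4e-5 * (V - 19.9),
                          1.0 - std::exp(-(V - 19.9) / 17.0), 4e-5 * 17.0);
  double bxs = safe_ratio(3.5e-5 * (V - 19.9),
                          std::exp((V - 19.9) / 9.0) - 1.0, 3.5e-5 * 9.0);
  g[8].inf = 1.0 / std::sqrt(1.0 + std::exp(-(V - 19.9) / 12.7));
  g[8].tau = 0.5 / (axs + bxs);

  double ed = std::exp(-(V + 10.0) / 6.24);
  g[9].inf = 1.0 / (1.0 + std::exp(-(V + 10.0) / 8.0));
  g[9].tau = (std::fabs(V + 10.0) < 1e-10)
               ? 6.24 / (0.035 * 2.0)  // limit of (1-e)/(0.035 (V+10)(1+e))
               : (1.0 - ed) / (0.035 * (V + 10.0) * (1.0 + ed));

  g[10].inf = 1.0 / (1.0 + std::exp((V + 28.0) / 6.9));
  g[10].tau = 9.0 / (0.0197 * std::exp(-0.0337 * 0.0337 *
                                       (V + 10.0) * (V + 10.0)) + 0.02);

  double ew = std::exp(-(V - 7.9) / 5.0);
  g[11].inf = 1.0 - 1.0 / (1.0 + std::exp(-(V - 40.0) / 17.0));
  g[11].tau = (std::fabs(V - 7.9) < 1e-10)
                ? 6.0 * 0.2 / 1.3
                : 6.0 * (1.0 - ew) / ((1.0 + 0.3 * ew) * (V - 7.9));
}

// voltage-only auxiliary factors
struct AuxVK { double ik1r, gkurv, ikrr, fnak, e1, e2; };

static AuxVK aux_of_v(double V) {
  AuxVK a;
  a.ik1r  = 1.0 / (1.0 + std::exp(0.07 * (V + 80.0)));
  a.gkurv = 0.005 + 0.05 / (1.0 + std::exp(-(V - 15.0) / 13.0));
  a.ikrr  = 1.0 / (1.0 + std::exp((V + 15.0) / 22.4));
  double sigma = (std::exp(NAO / 67.3) - 1.0) / 7.0;
  a.fnak  = 1.0 / (1.0 + 0.1245 * std::exp(-0.1 * V / RTF) +
                   0.0365 * sigma * std::exp(-V / RTF));
  a.e1 = std::exp(GAMA * V / RTF);
  a.e2 = std::exp((GAMA - 1.0) * V / RTF);
  return a;
}

// ---- lookup table ----------------------------------------------------------
// per V row: 12 x (inf, rl = exp(-dt/tau)) then ik1r gkurv ikrr fnak e1 e2
static const int NCOL = 30;
static const double VMIN = -100.0, VMAX = 70.0, DVTAB = 0.25;

struct Lut {
  std::vector<double> t;
  int nrow;
  double built_dt;
  void build(double dt) {
    nrow = (int)std::floor((VMAX - VMIN) / DVTAB) + 2;
    t.assign((size_t)nrow * NCOL, 0.0);
    for (int r = 0; r < nrow; ++r) {
      double V = VMIN + r * DVTAB;
      GateVK g[12]; gates_of_v(V, g);
      AuxVK a = aux_of_v(V);
      double* row = &t[(size_t)r * NCOL];
      for (int k = 0; k < 12; ++k) {
        row[2 * k] = g[k].inf;
        row[2 * k + 1] = std::exp(-dt / g[k].tau);
      }
      row[24] = a.ik1r; row[25] = a.gkurv; row[26] = a.ikrr;
      row[27] = a.fnak; row[28] = a.e1;    row[29] = a.e2;
    }
    built_dt = dt;
  }
};

// sigmoid table for the SR-release gating signal Fn: u_inf = sig(au),
// v_inf = 1 - sig(au + 200), tau_v = 1.91 + 2.09 * sig(au), where
// au = (Fn - 3.4175e-13) / 1.367e-15 and the v midpoint sits exactly 200
// slope units below the u midpoint
static const double SIGX0 = -60.0, SIGX1 = 260.0, SIGDX = 0.05;
static const int NSIG = (int)((SIGX1 - SIGX0) / SIGDX) + 2;
struct SigTab {
  std::vector<double> t;
  SigTab() : t(NSIG) {
    for (int i = 0; i < NSIG; ++i)
      t[i] = 1.0 / (1.0 + std::exp(-(SIGX0 + i * SIGDX)));
  }
  inline double operator()(double x) const {
    if (x <= SIGX0) return 0.0;
    if (x >= SIGX1) return 1.0;
    double q = (x - SIGX0) / SIGDX;
    int i = (int)q;
    double fr = q - i;
    return t[i] + fr * (t[i + 1] - t[i]);
  }
};
static const SigTab SIG;

// slowly varying, concentration-dependent quantities, refreshed every
// CACHE_EVERY steps (0.4 ms at the default step): reversal potentials and
// the Nai-dependent Na/K-pump saturation
static const int CACHE_EVERY = 16;
struct SlowCache { double ENa, EK, ECa, nakf; };

static inline void refresh_cache(const double* s, SlowCache& c) {
  c.ENa = RTF * std::log(NAO / s[iNAI]);
  c.EK  = RTF * std::log(KO / s[iKI]);
  c.ECa = 0.5 * RTF * std::log(CAO / s[iCAI]);
  c.nakf = 1.0 / (1.0 + std::pow(KMNAI / s[iNAI], 1.5));
}

// ---- one reaction step (shared by cell and tissue loops) -------------------

static inline void cell_step(double* s, const Pars& p, double stim, double dt,
                             const Lut& lut, double rl_fca, double rl_u,
                             const SlowCache& cache) {
  double V = s[iV];
  double vq = (V - VMIN) / DVTAB;
  if (!(vq >= 0.0)) vq = 0.0; // also catches NaN: the caller's per-frame
                              // finiteness check then reports divergence
  double vmaxq = (double)(lut.nrow - 2);
  if (vq > vmaxq) vq = vmaxq;
  int r0 = (int)vq;
  double fr = vq - r0;
  const double* A = &lut.t[(size_t)r0 * NCOL];
  const double* B = A + NCOL;
#define TAB(k) (A[k] + fr * (B[k] - A[k]))

  double ENa = cache.ENa, EK = cache.EK, ECa = cache.ECa;

  double INa  = p.gNa * s[iM] * s[iM] * s[iM] * s[iH] * s[iJ] * (V - ENa);
  double IK1  = p.gK1 * (V - EK) * TAB(24);
  double Ito  = p.gto * s[iOA] * s[iOA] * s[iOA] * s[iOI] * (V - EK);
  double IKur = p.gKur * TAB(25) * s[iUA] * s[iUA] * s[iUA] * s[iUI] * (V - EK);
  double IKr  = p.gKr * s[iXR] * (V - EK) * TAB(26);
  double IKs  = p.gKs * s[iXS] * s[iXS] * (V - EK);
  double ICaL = p.gCaL * s[iD] * s[iF] * s[iFCA] * (V - 65.0);
  double INaK = p.INaK * TAB(27) * (KO / (KO + KMKO)) * cache.nakf;
  double e1 = TAB(28), e2 = TAB(29);
  double na3 = s[iNAI] * s[iNAI] * s[iNAI];
  double INaCa = p.INaCa * (e1 * na3 * CAO - e2 * NAO * NAO * NAO * s[iCAI]) /
                 ((KMNA * KMNA * KMNA + NAO * NAO * NAO) * (KMCA + CAO) *
                  (1.0 + KSAT * e2));
  double IbNa = p.gbNa * (V - ENa);
  double IbCa = p.gbCa * (V - ECa);
  double IpCa = p.IpCa * s[iCAI] / (0.0005 + s[iCAI]);

  double Irel = p.Krel * s[iU] * s[iU] * s[iVV] * s[iW] * (s[iCAREL] - s[iCAI]);
  double Itr  = (s[iCAUP] - s[iCAREL]) / TAU_TR;
  double Iup  = p.Iup / (1.0 + KUP / s[iCAI]);
  double Ileak = p.Iup * s[iCAUP] / CAUPMAX;

  // SR release gating driven by flux signal Fn (currents as total pA)
  double Fn = 1e-12 * VREL * Irel -
              (5e-13 / FARADAY) * (0.5 * ICaL * CM - 0.2 * INaCa * CM);
  double au = (Fn - 3.4175e-13) / 13.67e-16;
  double su = SIG(au);
  double u_inf = su;
  double tau_v = 1.91 + 2.09 * su;
  double v_inf = 1.0 - SIG(au + 200.0);
  double fca_inf = 1.0 / (1.0 + s[iCAI] / 0.00035);

  double Iion = INa + IK1 + Ito + IKur + IKr + IKs + ICaL + IpCa + IbNa +
                IbCa + INaK + INaCa;

  // concentration derivatives
  double dNai = (-3.0 * INaK - 3.0 * INaCa - IbNa - INa) * CM / (FARADAY * VI);
  double dKi  = (2.0 * INaK - IK1 - Ito - IKur - IKr - IKs) * CM /
                (FARADAY * VI);
  double B1 = (2.0 * INaCa - IpCa - ICaL - IbCa) * CM / (2.0 * FARADAY * VI) +
              (VUP * (Ileak - Iup) + Irel * VREL) / VI;
  double B2 = 1.0 + TRPN * KMTRPN / ((s[iCAI] + KMTRPN) * (s[iCAI] + KMTRPN)) +
              CMDN * KMCMDN / ((s[iCAI] + KMCMDN) * (s[iCAI] + KMCMDN));
  double dCaup  = Iup - Ileak - Itr * VREL / VUP;
  double dCarel = (Itr - Irel) /
                  (1.0 + CSQN * KMCSQN /
                   ((s[iCAREL] + KMCSQN) * (s[iCAREL] + KMCSQN)));

  // forward Euler: V and concentrations
  s[iV]    = V + dt * (-(Iion) + stim);
  s[iNAI] += dt * dNai;
  s[iKI]  += dt * dKi;
  s[iCAI] += dt * B1 / B2;
  s[iCAUP] += dt * dCaup;
  s[iCAREL] += dt * dCarel;

  // Rush-Larsen: voltage-gated gates from the table
  s[iM]  = TAB(0)  + (s[iM]  - TAB(0))  * TAB(1);
  s[iH]  = TAB(2)  + (s[iH]  - TAB(2))  * TAB(3);
  s[iJ]  = TAB(4)  + (s[iJ]  - TAB(4))  * TAB(5);
  s[iOA] = TAB(6)  + (s[iOA] - TAB(6))  * TAB(7);
  s[iOI] = TAB(8)  + (s[iOI] - TAB(8))  * TAB(9);
  s[iUA] = TAB(10) + (s[iUA] - TAB(10)) * TAB(11);
  s[iUI] = TAB(12) + (s[iUI] - TAB(12)) * TAB(13);
  s[iXR] = TAB(14) + (s[iXR] - TAB(14)) * TAB(15);
  s[iXS] = TAB(16) + (s[iXS] - TAB(16)) * TAB(17);
  s[iD]  = TAB(18) + (s[iD]  - TAB(18)) * TAB(19);
  s[iF]  = TAB(20) + (s[iF]  - TAB(20)) * TAB(21);
  s[iW]  = TAB(22) + (s[iW]  - TAB(22)) * TAB(23);

  // Ca-/flux-gated gates; exp(-dt/tau_v) by 3rd-order Taylor (dt/tau_v is
  // at most ~0.013 at the default step, error below 1e-9)
  double zv = dt / tau_v;
  double rl_v = 1.0 - zv * (1.0 - 0.5 * zv * (1.0 - zv / 3.0));
  s[iFCA] = fca_inf + (s[iFCA] - fca_inf) * rl_fca;
  s[iU]   = u_inf + (s[iU] - u_inf) * rl_u;
  s[iVV]  = v_inf + (s[iVV] - v_inf) * rl_v;
#undef TAB
}

// ---- exact RHS (no tables, no Rush-Larsen) ---------------------------------

// [[Rcpp::export]]
NumericVector crn_derivatives(NumericVector params, NumericVector state,
                              double stim) {
  Pars p = unpack(params);
  if (state.size() != NSTATE) stop("state must have %d entries", NSTATE);
  double s[NSTATE];
  for (int k = 0; k < NSTATE; ++k) {
    s[k] = state[k];
    if (!std::isfinite(s[k]))
      stop("non-finite state entry at position %d", k + 1);
  }
  double V = s[iV];
  GateVK g[12]; gates_of_v(V, g);
  AuxVK a = aux_of_v(V);

  double ENa = RTF * std::log(NAO / s[iNAI]);
  double EK  = RTF * std::log(KO / s[iKI]);
  double ECa = 0.5 * RTF * std::log(CAO / s[iCAI]);
  double INa  = p.gNa * s[iM] * s[iM] * s[iM] * s[iH] * s[iJ] * (V - ENa);
  double IK1  = p.gK1 * (V - EK) * a.ik1r;
  double Ito  = p.gto * s[iOA] * s[iOA] * s[iOA] * s[iOI] * (V - EK);
  double IKur = p.gKur * a.gkurv * s[iUA] * s[iUA] * s[iUA] * s[iUI] * (V - EK);
  double IKr  = p.gKr * s[iXR] * (V - EK) * a.ikrr;
  double IKs  = p.gKs * s[iXS] * s[iXS] * (V - EK);
  double ICaL = p.gCaL * s[iD] * s[iF] * s[iFCA] * (V - 65.0);
  double INaK = p.INaK * a.fnak * (KO / (KO + KMKO)) /
                (1.0 + std::pow(KMNAI / s[iNAI], 1.5));
  double na3 = s[iNAI] * s[iNAI] * s[iNAI];
  double INaCa = p.INaCa * (a.e1 * na3 * CAO - a.e2 * NAO * NAO * NAO * s[iCAI]) /
                 ((KMNA * KMNA * KMNA + NAO * NAO * NAO) * (KMCA + CAO) *
                  (1.0 + KSAT * a.e2));
  double IbNa = p.gbNa * (V - ENa);
  double IbCa = p.gbCa * (V - ECa);
  double IpCa = p.IpCa * s[iCAI] / (0.0005 + s[iCAI]);
  double Irel = p.Krel * s[iU] * s[iU] * s[iVV] * s[iW] * (s[iCAREL] - s[iCAI]);
  double Itr  = (s[iCAUP] - s[iCAREL]) / TAU_TR;
  double Iup  = p.Iup / (1.0 + KUP / s[iCAI]);
  double Ileak = p.Iup * s[iCAUP] / CAUPMAX;
  double Fn = 1e-12 * VREL * Irel -
              (5e-13 / FARADAY) * (0.5 * ICaL * CM - 0.2 * INaCa * CM);
  double eu = std::exp(-(Fn - 3.4175e-13) / 13.67e-16);
  double u_inf = 1.0 / (1.0 + eu);
  double tau_v = 1.91 + 2.09 / (1.0 + eu);
  double v_inf = 1.0 - 1.0 / (1.0 + std::exp(-(Fn - 6.835e-14) / 13.67e-16));
  double fca_inf = 1.0 / (1.0 + s[iCAI] / 0.00035);

  double Iion = INa + IK1 + Ito + IKur + IKr + IKs + ICaL + IpCa + IbNa +
                IbCa + INaK + INaCa;

  NumericVector d(NSTATE);
  d[iV] = -(Iion) + stim;
  d[iM]  = (g[0].inf - s[iM]) / g[0].tau;
  d[iH]  = (g[1].inf - s[iH]) / g[1].tau;
  d[iJ]  = (g[2].inf - s[iJ]) / g[2].tau;
  d[iOA] = (g[3].inf - s[iOA]) / g[3].tau;
  d[iOI] = (g[4].inf - s[iOI]) / g[4].tau;
  d[iUA] = (g[5].inf - s[iUA]) / g[5].tau;
  d[iUI] = (g[6].inf - s[iUI]) / g[6].tau;
  d[iXR] = (g[7].inf - s[iXR]) / g[7].tau;
  d[iXS] = (g[8].inf - s[iXS]) / g[8].tau;
  d[iD]  = (g[9].inf - s[iD]) / g[9].tau;
  d[iF]  = (g[10].inf - s[iF]) / g[10].tau;
  d[iW]  = (g[11].inf - s[iW]) / g[11].tau;
  d[iFCA] = (fca_inf - s[iFCA]) / TAU_FCA;
  d[iU]  = (u_inf - s[iU]) / TAU_U;
  d[iVV] = (v_inf - s[iVV]) / tau_v;
  d[iNAI] = (-3.0 * INaK - 3.0 * INaCa - IbNa - INa) * CM / (FARADAY * VI);
  d[iKI]  = (2.0 * INaK - IK1 - Ito - IKur - IKr - IKs) * CM / (FARADAY * VI);
  double B1 = (2.0 * INaCa - IpCa - ICaL - IbCa) * CM / (2.0 * FARADAY * VI) +
              (VUP * (Ileak - Iup) + Irel * VREL) / VI;
  double B2 = 1.0 + TRPN * KMTRPN / ((s[iCAI] + KMTRPN) * (s[iCAI] + KMTRPN)) +
              CMDN * KMCMDN / ((s[iCAI] + KMCMDN) * (s[iCAI] + KMCMDN));
  d[iCAI] = B1 / B2;
  d[iCAUP]  = Iup - Ileak - Itr * VREL / VUP;
  d[iCAREL] = (Itr - Irel) /
              (1.0 + CSQN * KMCSQN /
               ((s[iCAREL] + KMCSQN) * (s[iCAREL] + KMCSQN)));
  return d;
}

// ---- single-cell pacing loop -----------------------------------------------

// [[Rcpp::export]]
List crn_cell_run(NumericVector params, NumericVector state0, double dt,
                  double duration, NumericVector stim_starts, double stim_dur,
                  double stim_amp, double sample_dt, bool record_states) {
  Pars p = unpack(params);
  if (state0.size() != NSTATE) stop("state must have %d entries", NSTATE);
  double s[NSTATE];
  for (int k = 0; k < NSTATE; ++k) s[k] = state0[k];

  set_ftz();
  Lut lut; lut.build(dt);
  double rl_fca = std::exp(-dt / TAU_FCA);
  double rl_u = std::exp(-dt / TAU_U);
  SlowCache cache;

  long nsteps = (long)std::llround(duration / dt);
  long sample_every = (long)std::llround(sample_dt / dt);
  if (sample_every < 1) sample_every = 1;
  long nsamp = nsteps / sample_every + 1;

  NumericVector tout(nsamp), vout(nsamp);
  NumericMatrix states;
  if (record_states) states = NumericMatrix(NSTATE, nsamp);

  int nstim = stim_starts.size();
  int si = 0; // next stimulus not yet finished
  long isamp = 0;
  for (long step = 0; step <= nsteps; ++step) {
    double t = step * dt;
    if (step % sample_every == 0 && isamp < nsamp) {
      tout[isamp] = t; vout[isamp] = s[iV];
      if (record_states)
        for (int k = 0; k < NSTATE; ++k) states(k, isamp) = s[k];
      ++isamp;
    }
    if (step == nsteps) break;
    while (si < nstim && t >= stim_starts[si] + stim_dur) ++si;
    double stim = 0.0;
    if (si < nstim && t >= stim_starts[si] && t < stim_starts[si] + stim_dur)
      stim = stim_amp;
    if (step % CACHE_EVERY == 0) refresh_cache(s, cache);
    cell_step(s, p, stim, dt, lut, rl_fca, rl_u, cache);
    if (!std::isfinite(s[iV])) {
      char buf[128];
      std::snprintf(buf, sizeof(buf),
                    "cell solver diverged (non-finite V) at t = %.3f ms",
                    (step + 1) * dt);
      stop(buf);
    }
  }
  NumericVector fin(NSTATE);
  for (int k = 0; k < NSTATE; ++k) fin[k] = s[k];
  List out = List::create(_["time"] = tout, _["V"] = vout,
                          _["final_state"] = fin);
  if (record_states) out["states"] = states;
  return out;
}

// ---- tissue (monodomain, operator split) -----------------------------------

// Laplacian passed as dgCMatrix slots (column pointers Lp, row indices Li,
// values Lx); symmetric weights, rows sum to zero (no-flux / closed surface).
// Godunov split at shared dt: reaction step then V += dt * D * (L V).

// [[Rcpp::export]]
List crn_tissue_run(NumericVector params, NumericMatrix state0,
                    IntegerVector Lp, IntegerVector Li, NumericVector Lx,
                    double D, double dt, double duration, double frame_dt,
                    List stims, int block_par, double block_factor,
                    double block_onset, double snapshot_t) {
  Pars p = unpack(params);
  if (state0.nrow() != NSTATE) stop("state0 must have %d rows", NSTATE);
  int n = state0.ncol();
  if (Lp.size() != n + 1) stop("Laplacian dimension mismatch");

  std::vector<double> S((size_t)NSTATE * n);
  for (int j = 0; j < n; ++j)
    for (int k = 0; k < NSTATE; ++k) S[(size_t)j * NSTATE + k] = state0(k, j);

  set_ftz();
  Lut lut; lut.build(dt);
  double rl_fca = std::exp(-dt / TAU_FCA);
  double rl_u = std::exp(-dt / TAU_U);
  std::vector<SlowCache> caches(n);

  // stimuli: list of list(nodes (1-based int), start, dur, amp)
  struct Stim { std::vector<int> nodes; double start, dur, amp; };
  std::vector<Stim> st;
  for (int q = 0; q < stims.size(); ++q) {
    List sq = stims[q];
    Stim one;
    IntegerVector nd = sq["nodes"];
    for (int k = 0; k < nd.size(); ++k) one.nodes.push_back(nd[k] - 1);
    one.start = as<double>(sq["start"]);
    one.dur = as<double>(sq["dur"]);
    one.amp = as<double>(sq["amp"]);
    st.push_back(one);
  }

  long nsteps = (long)std::llround(duration / dt);
  long frame_every = (long)std::llround(frame_dt / dt);
  if (frame_every < 1) frame_every = 1;
  long nframes = nsteps / frame_every + 1;

  NumericMatrix V(n, nframes);
  NumericVector ftime(nframes);
  std::vector<double> lapV(n), stim_now(n, 0.0);
  bool block_applied = false;
  Pars pb = p;
  if (block_par >= 0) *par_field(pb, block_par) *= block_factor;

  long snap_step = (snapshot_t >= 0.0) ? (long)std::llround(snapshot_t / dt) : -1;
  NumericMatrix snap;
  if (snap_step >= 0) snap = NumericMatrix(NSTATE, n);

  long iframe = 0;
  for (long step = 0; step <= nsteps; ++step) {
    double t = step * dt;
    if (step == snap_step)
      for (int j = 0; j < n; ++j)
        for (int k = 0; k < NSTATE; ++k) snap(k, j) = S[(size_t)j * NSTATE + k];
    if (step % frame_every == 0 && iframe < nframes) {
      ftime[iframe] = t;
      for (int j = 0; j < n; ++j) V(j, iframe) = S[(size_t)j * NSTATE + iV];
      // divergence check once per frame
      for (int j = 0; j < n; ++j)
        if (!std::isfinite(V(j, iframe))) {
          char buf[160];
          std::snprintf(buf, sizeof(buf),
            "tissue solver diverged (non-finite V) first at node %d, t = %.1f ms",
            j + 1, t);
          stop(buf);
        }
      ++iframe;
    }
    if (step == nsteps) break;

    bool blocked = (block_par >= 0 && t >= block_onset);
    const Pars& pc = blocked ? pb : p;

    // stimulus currents this step
    bool any_stim = false;
    for (size_t q = 0; q < st.size(); ++q)
      if (t >= st[q].start && t < st[q].start + st[q].dur) { any_stim = true; break; }
    if (any_stim) {
      std::fill(stim_now.begin(), stim_now.end(), 0.0);
      for (size_t q = 0; q < st.size(); ++q)
        if (t >= st[q].start && t < st[q].start + st[q].dur)
          for (size_t k = 0; k < st[q].nodes.size(); ++k)
            stim_now[st[q].nodes[k]] += st[q].amp;
    }

    // reaction
    if (step % CACHE_EVERY == 0)
      for (int j = 0; j < n; ++j) refresh_cache(&S[(size_t)j * NSTATE], caches[j]);
    for (int j = 0; j < n; ++j)
      cell_step(&S[(size_t)j * NSTATE], pc, any_stim ? stim_now[j] : 0.0,
                dt, lut, rl_fca, rl_u, caches[j]);

    // diffusion: V += dt * D * (L V)
    if (D != 0.0) {
      for (int j = 0; j < n; ++j) lapV[j] = 0.0;
      for (int col = 0; col < n; ++col) {
        double vc = S[(size_t)col * NSTATE + iV];
        for (int idx = Lp[col]; idx < Lp[col + 1]; ++idx)
          lapV[Li[idx]] += Lx[idx] * vc;
      }
      double c = dt * D;
      for (int j = 0; j < n; ++j) S[(size_t)j * NSTATE + iV] += c * lapV[j];
    } else {
      for (int j = 0; j < n; ++j) S[(size_t)j * NSTATE + iV] += 0.0;
    }
    if (block_par >= 0 && blocked) block_applied = true;
  }

  NumericMatrix fin(NSTATE, n);
  for (int j = 0; j < n; ++j)
    for (int k = 0; k < NSTATE; ++k) fin(k, j) = S[(size_t)j * NSTATE + k];

  List out = List::create(_["time"] = ftime, _["V"] = V, _["final_state"] = fin,
                          _["block_applied"] = block_applied);
  if (snap_step >= 0) out["snapshot"] = snap;
  return out;
}
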