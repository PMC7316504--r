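// Compute kernels: human ventricular ionic model (ten Tusscher & Panfilov 2006,
// epicardial default), the frequency-sensing BioICD Markov channel, and the 2D
// monodomain reaction-diffusion stepper.
//
// Numerics: Hodgkin-Huxley gates advance by the Rush-Larsen exponential scheme,
// concentrations and the RyR adaptation variable by forward Euler, the BioICD
// states by their exact per-step linear-ODE solution, and the membrane potential
// by forward Euler with the BioICD conductance term treated semi-implicitly
// (exact relaxation of g*(V - E)); the latter is required because the channel's
// maximal conductance violates the explicit stability bound when fully open.
//
// The tissue stepper uses voltage-indexed lookup tables (linear interpolation,
// 0.05 mV bins) for all voltage-dependent gate and current factors; a direct
// (table-free) path is kept for cross-checking. Double precision throughout.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <string>
#include <limits>
#include <type_traits>
using namespace Rcpp;

// ---------------------------------------------------------------- parameters

struct CellP {
  // physical constants
  double Rgas = 8314.472, Frd = 96485.3415, Tmp = 310.0;
  // external concentrations (mM)
  double Ko = 5.4, Cao = 2.0, Nao = 140.0;
  // intracellular volumes
  double Vc = 0.016404, Vsr = 0.001094, Vss = 0.00005468;
  double Cap = 0.185; // capacitance scaling of concentration updates
  // buffering
  double Bufc = 0.2, Kbufc = 0.001, Bufsr = 10.0, Kbufsr = 0.3,
         Bufss = 0.4, Kbufss = 0.00025;
  // SR calcium handling
  double Vmaxup = 0.006375, Kup = 0.00025, Vrel = 0.102,
         k1p = 0.15, k2p = 0.045, k3 = 0.060, k4 = 0.005,
         maxsr = 2.5, minsr = 1.0, EC = 1.5, Vleak = 0.00036, Vxfer = 0.0038;
  // conductances / maxima (epicardial defaults)
  double Gna = 14.838, Gcal = 3.98e-5, Gk1 = 5.405, Gto = 0.294,
         Gkr = 0.153, Gks = 0.392, Gbna = 0.00029, Gbca = 0.000592,
         Gpca = 0.1238, KpCa = 0.0005, Gpk = 0.0146;
  double pKNa = 0.03, KmK = 1.0, KmNa = 40.0, knak = 2.724;
  double knaca = 1000.0, KmNai = 87.5, KmCa = 1.38, ksat = 0.1, nab = 0.35;
  int subtype = 0;          // 0 epi, 1 endo, 2 mid (affects Gto/Gks/s-gate)
  double tauf_scale = 1.0;  // optional f-gate speed-up used by breakup preset
  double sc[12];            // per-current scale factors, see SC_* below
  // derived constants (finalize() fills them)
  double sqrtKo54 = 1.0, naca_pref = 0.0, cap_VcF = 0.0, cap_2VcF = 0.0,
         cap_2VssF = 0.0, VcOverVss = 0.0, VsrOverVss = 0.0, VsrOverVc = 0.0,
         EC2 = 0.0, Kup2 = 0.0, Nao3 = 0.0, gk1_eff = 0.0, gkr_eff = 0.0,
         gnak_eff = 0.0;
  double rtonf() const { return Rgas * Tmp / Frd; }
  void finalize() {
    sqrtKo54 = sqrt(Ko / 5.4);
    Nao3 = Nao * Nao * Nao;
    naca_pref = knaca / ((KmNai * KmNai * KmNai + Nao3) * (KmCa + Cao));
    cap_VcF = Cap / (Vc * Frd);
    cap_2VcF = Cap / (2.0 * Vc * Frd);
    cap_2VssF = Cap / (2.0 * Vss * Frd);
    VcOverVss = Vc / Vss;
    VsrOverVss = Vsr / Vss;
    VsrOverVc = Vsr / Vc;
    EC2 = EC * EC;
    Kup2 = Kup * Kup;
    gk1_eff = Gk1 * sqrtKo54;
    gkr_eff = Gkr * sqrtKo54;
    gnak_eff = knak * Ko / (Ko + KmK);
  }
  CellP() { for (int i = 0; i < 12; ++i) sc[i] = 1.0; }
};

// exp(-y) for small y >= 0 without a libm call; |error| < 1e-8 for y <= 0.02
static inline double exp_neg_small(double y) {
  if (y < 0.02) return 1.0 - y * (1.0 - y * (0.5 - y / 6.0));
  return exp(-y);
}

enum { SC_NA, SC_CAL, SC_K1, SC_TO, SC_NACA, SC_NAK,
       SC_KR, SC_KS, SC_BNA, SC_BCA, SC_PCA, SC_PK };

struct BioP {
  double gmax = 150.0, erev = 0.0;
  int    nsub = 8;
  double tauo = 1400.0, taua = 1400.0, kocscale = 2e4;
  int    catp = 5;
  double vgate = -60.0, vlow = -55.0, vhigh = 0.0;
  double kco_on = 1.0, koc_base = 7.0, k01_on = 1.0, k10_off = 200.0;
};

// state vector layout (after V): 20 entries per node
enum { iM, iH, iJ, iXr1, iXr2, iXs, iR, iS, iD, iF, iF2, iFCa, iRR,
       iCai, iCaSR, iCaSS, iNai, iKi, iO, iA1 };
static const int NS = 20;

static CellP cellp_from_list(const List& l) {
  CellP p;
  p.Ko = l["Ko"]; p.Cao = l["Cao"]; p.Nao = l["Nao"];
  p.Gna = l["Gna"]; p.Gcal = l["Gcal"]; p.Gk1 = l["Gk1"]; p.Gto = l["Gto"];
  p.Gkr = l["Gkr"]; p.Gks = l["Gks"]; p.Gbna = l["Gbna"]; p.Gbca = l["Gbca"];
  p.Gpca = l["Gpca"]; p.Gpk = l["Gpk"];
  p.subtype = l["subtype"]; p.tauf_scale = l["tauf_scale"];
  NumericVector sc = l["scales"];
  for (int i = 0; i < 12; ++i) p.sc[i] = sc[i];
  p.finalize();
  return p;
}

static BioP biop_from_list(const List& l) {
  BioP b;
  b.gmax = l["g_max"]; b.erev = l["e_rev"]; b.nsub = l["n_subunits"];
  b.tauo = l["tau_o"]; b.taua = l["tau_a"];
  b.kocscale = l["k_oc_catalysis_scale"]; b.catp = l["catalyst_power"];
  b.vgate = l["v_gate"]; b.vlow = l["v_cat_low"]; b.vhigh = l["v_cat_high"];
  b.kco_on = l["k_co_on"]; b.koc_base = l["k_oc_base"];
  b.k01_on = l["k01_on"]; b.k10_off = l["k10_off"];
  return b;
}

static inline double ipow(double x, int n) {
  double r = 1.0;
  while (n > 0) { if (n & 1) r *= x; x *= x; n >>= 1; }
  return r;
}

// ------------------------------------------------- gate steady states / taus
// order matches state indices iM..iF2 (11 voltage gates)

static void gate_inf_tau(const CellP& p, double V, double* inf, double* tau) {
  // m
  inf[iM] = 1.0 / ((1.0 + exp((-56.86 - V) / 9.03)) * (1.0 + exp((-56.86 - V) / 9.03)));
  {
    double am = 1.0 / (1.0 + exp((-60.0 - V) / 5.0));
    double bm = 0.1 / (1.0 + exp((V + 35.0) / 5.0)) + 0.10 / (1.0 + exp((V - 50.0) / 200.0));
    tau[iM] = am * bm;
  }
  // h
  {
    double e = 1.0 + exp((V + 71.55) / 7.43);
    inf[iH] = 1.0 / (e * e);
    double ah, bh;
    if (V >= -40.0) { ah = 0.0; bh = 0.77 / (0.13 * (1.0 + exp(-(V + 10.66) / 11.1))); }
    else { ah = 0.057 * exp(-(V + 80.0) / 6.8);
           bh = 2.7 * exp(0.079 * V) + 3.1e5 * exp(0.3485 * V); }
    tau[iH] = 1.0 / (ah + bh);
  }
  // j
  {
    double e = 1.0 + exp((V + 71.55) / 7.43);
    inf[iJ] = 1.0 / (e * e);
    double aj, bj;
    if (V >= -40.0) {
      aj = 0.0;
      bj = 0.6 * exp(0.057 * V) / (1.0 + exp(-0.1 * (V + 32.0)));
    } else {
      aj = (-2.5428e4 * exp(0.2444 * V) - 6.948e-6 * exp(-0.04391 * V)) * (V + 37.78) /
           (1.0 + exp(0.311 * (V + 79.23)));
      bj = 0.02424 * exp(-0.01052 * V) / (1.0 + exp(-0.1378 * (V + 40.14)));
    }
    tau[iJ] = 1.0 / (aj + bj);
  }
  // xr1, xr2
  inf[iXr1] = 1.0 / (1.0 + exp((-26.0 - V) / 7.0));
  tau[iXr1] = (450.0 / (1.0 + exp((-45.0 - V) / 10.0))) * (6.0 / (1.0 + exp((V + 30.0) / 11.5)));
  inf[iXr2] = 1.0 / (1.0 + exp((V + 88.0) / 24.0));
  tau[iXr2] = (3.0 / (1.0 + exp((-60.0 - V) / 20.0))) * (1.12 / (1.0 + exp((V - 60.0) / 20.0)));
  // xs
  inf[iXs] = 1.0 / (1.0 + exp((-5.0 - V) / 14.0));
  tau[iXs] = (1400.0 / sqrt(1.0 + exp((5.0 - V) / 6.0))) * (1.0 / (1.0 + exp((V - 35.0) / 15.0))) + 80.0;
  // transient outward r and s (subtype dependent s)
  inf[iR] = 1.0 / (1.0 + exp((20.0 - V) / 6.0));
  tau[iR] = 9.5 * exp(-(V + 40.0) * (V + 40.0) / 1800.0) + 0.8;
  if (p.subtype == 1) { // endo
    inf[iS] = 1.0 / (1.0 + exp((V + 28.0) / 5.0));
    tau[iS] = 1000.0 * exp(-(V + 67.0) * (V + 67.0) / 1000.0) + 8.0;
  } else {              // epi and mid
    inf[iS] = 1.0 / (1.0 + exp((V + 20.0) / 5.0));
    tau[iS] = 85.0 * exp(-(V + 45.0) * (V + 45.0) / 320.0) +
              5.0 / (1.0 + exp((V - 20.0) / 5.0)) + 3.0;
  }
  // d
  inf[iD] = 1.0 / (1.0 + exp((-8.0 - V) / 7.5));
  {
    double ad = 1.4 / (1.0 + exp((-35.0 - V) / 13.0)) + 0.25;
    double bd = 1.4 / (1.0 + exp((V + 5.0) / 5.0));
    double cd = 1.0 / (1.0 + exp((50.0 - V) / 20.0));
    tau[iD] = ad * bd + cd;
  }
  // f
  inf[iF] = 1.0 / (1.0 + exp((V + 20.0) / 7.0));
  {
    double af = 1102.5 * exp(-(V + 27.0) * (V + 27.0) / 225.0);
    double bf = 200.0 / (1.0 + exp((13.0 - V) / 10.0));
    double cf = 180.0 / (1.0 + exp((V + 30.0) / 10.0)) + 20.0;
    tau[iF] = (af + bf + cf) * p.tauf_scale;
  }
  // f2
  inf[iF2] = 0.67 / (1.0 + exp((V + 35.0) / 7.0)) + 0.33;
  {
    double af2 = 600.0 * exp(-(V + 25.0) * (V + 25.0) / 170.0);
    double bf2 = 31.0 / (1.0 + exp((25.0 - V) / 10.0));
    double cf2 = 16.0 / (1.0 + exp((V + 30.0) / 10.0));
    tau[iF2] = af2 + bf2 + cf2;
  }
}

// voltage-only current factors (direct evaluation)
static inline double f_ik1rec(double u) { // u = V - Ek
  double ak1 = 0.1 / (1.0 + exp(0.06 * (u - 200.0)));
  double bk1 = (3.0 * exp(0.0002 * (u + 100.0)) + exp(0.1 * (u - 10.0))) /
               (1.0 + exp(-0.5 * u));
  return ak1 / (ak1 + bk1);
}
static inline double f_ipkrec(double V) { return 1.0 / (1.0 + exp((25.0 - V) / 5.98)); }
static inline double f_nakrec(const CellP& p, double V) {
  double vfrt = V * p.Frd / (p.Rgas * p.Tmp);
  return 1.0 / (1.0 + 0.1245 * exp(-0.1 * vfrt) + 0.0353 * exp(-vfrt));
}
static inline double f_nacae1(const CellP& p, double V) {
  return exp(p.nab * V * p.Frd / (p.Rgas * p.Tmp));
}
static inline double f_nacae2(const CellP& p, double V) {
  return exp((p.nab - 1.0) * V * p.Frd / (p.Rgas * p.Tmp));
}
static inline double f_calE(const CellP& p, double V) {
  return exp(2.0 * (V - 15.0) * p.Frd / (p.Rgas * p.Tmp));
}
static inline double f_calA(const CellP& p, double V) {
  // 4 (V-15) F^2/(RT) / (exp(2 (V-15) F/RT) - 1), continuous limit 2F at V = 15
  double x = 2.0 * (V - 15.0) * p.Frd / (p.Rgas * p.Tmp);
  if (fabs(x) < 1e-7) return 2.0 * p.Frd;
  return 4.0 * (V - 15.0) * p.Frd * p.Frd / (p.Rgas * p.Tmp) / (exp(x) - 1.0);
}

// ------------------------------------------------------------ lookup tables

// Interleaved voltage tables: per 0.05 mV bin a contiguous block of NT
// entries (22 gate inf/rl pairs followed by merged current factors), so one
// node-step touches two adjacent blocks instead of 28 scattered arrays.
// Stored in single precision (built in double): the linear-interpolation
// error already dominates the rounding, and the direct double-precision
// path cross-checks the tables.
enum { TB_GATES = 0 /* 22 entries: inf,rl per gate */,
       TB_NAKREC = 22,
       TB_NACA1 = 23,   // naca_pref * sat(V) * e1(V) * Cao
       TB_NACA2 = 24,   // naca_pref * sat(V) * e2(V) * Nao^3 * 2.5
       TB_CAL1 = 25,    // Gcal * A(V) * 0.25 * E(V)
       TB_CAL2 = 26,    // Gcal * A(V) * Cao
       TB_IPKREC = 27, NT = 28 };

struct Tab {
  double vmin = -110.0, vmax = 70.0, inv_dv = 20.0; // 0.05 mV bins
  double umin = -60.0,  umax = 220.0;               // for V - Ek
  int nv = 0, nu = 0, nf = 1024;
  std::vector<float> blk;      // nv * NT interleaved
  std::vector<float> ik1rec;   // u-indexed
  std::vector<float> fcass_rl; // exp(-dt / (80 x + 2)) on x in [0, 1]
  double bio_rl_dep = 0.0, bio_rl_rest = 0.0;  // O-gate coefs at a1 = 0
  double a1_rl_in = 0.0, a1_rl_out = 0.0;      // a1 relaxation coefs
};

static void build_tables(const CellP& p, const BioP& b, double dt, Tab& t) {
  t.nv = (int)floor((t.vmax - t.vmin) * t.inv_dv) + 2;
  t.nu = (int)floor((t.umax - t.umin) * t.inv_dv) + 2;
  t.blk.assign((size_t)t.nv * NT, 0.0f);
  t.ik1rec.resize(t.nu);
  t.fcass_rl.resize(t.nf + 1);
  double inf[NS], tau[NS];
  for (int i = 0; i < t.nv; ++i) {
    double V = t.vmin + i / t.inv_dv;
    float* r = &t.blk[(size_t)i * NT];
    gate_inf_tau(p, V, inf, tau);
    for (int g = 0; g < 11; ++g) {
      r[2 * g] = (float)inf[g];
      r[2 * g + 1] = (float)exp(-dt / tau[g]);
    }
    double sat = 1.0 / (1.0 + p.ksat * f_nacae2(p, V));
    r[TB_NAKREC] = (float)f_nakrec(p, V);
    r[TB_NACA1] = (float)(p.naca_pref * sat * f_nacae1(p, V) * p.Cao);
    r[TB_NACA2] = (float)(p.naca_pref * sat * f_nacae2(p, V) * p.Nao3 * 2.5);
    r[TB_CAL1] = (float)(p.Gcal * f_calA(p, V) * 0.25 * f_calE(p, V));
    r[TB_CAL2] = (float)(p.Gcal * f_calA(p, V) * p.Cao);
    r[TB_IPKREC] = (float)f_ipkrec(V);
  }
  for (int i = 0; i < t.nu; ++i)
    t.ik1rec[i] = (float)f_ik1rec(t.umin + i / t.inv_dv);
  for (int i = 0; i <= t.nf; ++i) {
    double x = (double)i / t.nf;            // x = 1/(1 + (CaSS/0.05)^2)
    t.fcass_rl[i] = (float)exp(-dt / (80.0 * x + 2.0));
  }
  t.bio_rl_dep  = exp(-dt * b.kco_on   / b.tauo);  // V >= v_gate, a1 = 0
  t.bio_rl_rest = exp(-dt * b.koc_base / b.tauo);  // V <  v_gate, a1 = 0
  t.a1_rl_in    = exp(-dt * b.k01_on   / b.taua);  // inside catalyst window
  t.a1_rl_out   = exp(-dt * b.k10_off  / b.taua);  // outside window
}

struct VLook {
  const float* __restrict lo; const float* __restrict hi; double w;
  VLook(double V, const Tab& t) {
    double x = (V - t.vmin) * t.inv_dv;
    if (x < 0.0) x = 0.0;
    if (x > t.nv - 2) x = t.nv - 2;
    int i = (int)x; w = x - i;
    lo = &t.blk[(size_t)i * NT];
    hi = lo + NT;
  }
  inline double at(int k) const {
    double a = lo[k];
    return a + (hi[k] - a) * w;
  }
};

// ------------------------------------------------------------- ionic update
// One reaction step for a single node. Currents are evaluated on the entering
// state (as in the reference scheme); gates, concentrations and V then advance.
// Returns the BioICD current on the entering state (0 when disabled).

struct StepOut { double ibio; double iion; };

template <bool TAB>
__attribute__((always_inline))
static inline StepOut node_step(double& V, double* __restrict s, double* __restrict erev,
                                const CellP& p, const BioP& b, const Tab& t,
                                double dt, double istim, double lap,
                                bool bio_on) {
  double Ek = erev[0], Ena = erev[1], Eks = erev[2], Eca = erev[3];

  double inf[NS], tau[NS];
  double nakrec, naca1, naca2, cal1, cal2, ipkrec, ik1rec;
  VLook lv(V, t);
  if (TAB) {
    nakrec = lv.at(TB_NAKREC);
    naca1 = lv.at(TB_NACA1); naca2 = lv.at(TB_NACA2);
    cal1 = lv.at(TB_CAL1); cal2 = lv.at(TB_CAL2);
    ipkrec = lv.at(TB_IPKREC);
    double u = V - Ek;
    double x = (u - t.umin) * t.inv_dv;
    if (x < 0.0) x = 0.0;
    if (x > t.nu - 2) x = t.nu - 2;
    int iu = (int)x; double wu = x - iu;
    double a = t.ik1rec[iu];
    ik1rec = a + (t.ik1rec[iu + 1] - a) * wu;
  } else {
    gate_inf_tau(p, V, inf, tau);
    nakrec = f_nakrec(p, V);
    double sat = 1.0 / (1.0 + p.ksat * f_nacae2(p, V));
    naca1 = p.naca_pref * sat * f_nacae1(p, V) * p.Cao;
    naca2 = p.naca_pref * sat * f_nacae2(p, V) * p.Nao3 * 2.5;
    cal1 = p.Gcal * f_calA(p, V) * 0.25 * f_calE(p, V);
    cal2 = p.Gcal * f_calA(p, V) * p.Cao;
    ipkrec = f_ipkrec(V);
    ik1rec = f_ik1rec(V - Ek);
  }

  // combine the independent reciprocals of this step into one hardware
  // division (all denominators are strictly positive)
  double d1 = s[iCaSR] * s[iCaSR] + p.EC2;            // kCaSR
  double d2 = s[iCai] * s[iCai] + p.Kup2;             // Iup
  double d3 = p.KpCa + s[iCai];                       // IpCa
  double d4 = s[iNai] + p.KmNa;                       // INaK
  double d5 = 1.0 + s[iCaSS] * s[iCaSS] * 400.0;      // fcass (CaSS/0.05)^2
  double d12 = d1 * d2, d34 = d3 * d4;
  double rcp = 1.0 / (d12 * d34 * d5);
  double inv1 = rcp * d2 * d34 * d5, inv2 = rcp * d1 * d34 * d5;
  double inv3 = rcp * d12 * d4 * d5, inv4 = rcp * d12 * d3 * d5;
  double inv5 = rcp * d12 * d34;

  // --- currents on the entering state (pA/pF) ---
  double INa  = p.sc[SC_NA] * p.Gna * s[iM] * s[iM] * s[iM] * s[iH] * s[iJ] * (V - Ena);
  double ICaL = p.sc[SC_CAL] * s[iD] * s[iF] * s[iF2] * s[iFCa] *
                (cal1 * s[iCaSS] - cal2);
  double IK1  = p.sc[SC_K1] * p.gk1_eff * ik1rec * (V - Ek);
  double Ito  = p.sc[SC_TO] * p.Gto * s[iR] * s[iS] * (V - Ek);
  double IKr  = p.sc[SC_KR] * p.gkr_eff * s[iXr1] * s[iXr2] * (V - Ek);
  double IKs  = p.sc[SC_KS] * p.Gks * s[iXs] * s[iXs] * (V - Eks);
  double Nai3 = s[iNai] * s[iNai] * s[iNai];
  double INaCa = p.sc[SC_NACA] * (naca1 * Nai3 - naca2 * s[iCai]);
  double INaK = p.sc[SC_NAK] * p.gnak_eff * s[iNai] * inv4 * nakrec;
  double IpCa = p.sc[SC_PCA] * p.Gpca * s[iCai] * inv3;
  double IpK  = p.sc[SC_PK] * p.Gpk * ipkrec * (V - Ek);
  double IbNa = p.sc[SC_BNA] * p.Gbna * (V - Ena);
  double IbCa = p.sc[SC_BCA] * p.Gbca * (V - Eca);

  double O = s[iO];
  double On = bio_on ? ipow(O, b.nsub) : 0.0;
  double gbio = bio_on ? b.gmax * On : 0.0;
  double Ibio = gbio * (V - b.erev);

  double Iion = INa + ICaL + IK1 + Ito + INaCa + INaK + IKr + IKs +
                IbNa + IbCa + IpCa + IpK + Ibio;

  // --- SR calcium and intracellular concentrations (forward Euler with
  //     analytic treatment of instantaneous buffering) ---
  double CaSR = s[iCaSR], CaSS = s[iCaSS], Cai = s[iCai];
  double kCaSR = p.maxsr - (p.maxsr - p.minsr) * (CaSR * CaSR) * inv1;
  double k2 = p.k2p * kCaSR;
  double RR = s[iRR];
  double dRR = p.k4 * (1.0 - RR) - k2 * CaSS * RR;
  s[iRR] = RR + dt * dRR;
  double css2k1 = p.k1p * CaSS * CaSS;
  double OO = css2k1 * RR / (p.k3 * kCaSR + css2k1);

  double Irel  = p.Vrel * OO * (CaSR - CaSS);
  double Ileak = p.Vleak * (CaSR - CaSS);
  double Iup   = p.Vmaxup * Cai * Cai * inv2;
  double Ixfer = p.Vxfer * (CaSS - Cai);

  {
    double CaCSQN = p.Bufsr * CaSR / (CaSR + p.Kbufsr);
    double dCaSR = dt * (Iup - Irel - Ileak);
    double bjsr = p.Bufsr - CaCSQN - dCaSR - CaSR + p.Kbufsr;
    double cjsr = p.Kbufsr * (CaCSQN + dCaSR + CaSR);
    s[iCaSR] = (sqrt(bjsr * bjsr + 4.0 * cjsr) - bjsr) / 2.0;
  }
  {
    double CaSSBuf = p.Bufss * CaSS / (CaSS + p.Kbufss);
    double dCaSS = dt * (-Ixfer * p.VcOverVss + Irel * p.VsrOverVss -
                         ICaL * p.cap_2VssF);
    double bcss = p.Bufss - CaSSBuf - dCaSS - CaSS + p.Kbufss;
    double ccss = p.Kbufss * (CaSSBuf + dCaSS + CaSS);
    s[iCaSS] = (sqrt(bcss * bcss + 4.0 * ccss) - bcss) / 2.0;
  }
  {
    double CaBuf = p.Bufc * Cai / (Cai + p.Kbufc);
    double dCai = dt * (-(IbCa + IpCa - 2.0 * INaCa) * p.cap_2VcF -
                        (Iup - Ileak) * p.VsrOverVc + Ixfer);
    double bc = p.Bufc - CaBuf - dCai - Cai + p.Kbufc;
    double cc = p.Kbufc * (CaBuf + dCai + Cai);
    s[iCai] = (sqrt(bc * bc + 4.0 * cc) - bc) / 2.0;
  }
  s[iNai] += dt * (-(INa + IbNa + 3.0 * INaK + 3.0 * INaCa) * p.cap_VcF);
  s[iKi]  += dt * (-(istim + IK1 + Ito + IKr + IKs - 2.0 * INaK + IpK) * p.cap_VcF);

  // --- Rush-Larsen gate updates ---
  if (TAB) {
    for (int g = 0; g < 11; ++g) {
      double gi = lv.at(2 * g);
      s[g] = gi + (s[g] - gi) * lv.at(2 * g + 1);
    }
  } else {
    for (int g = 0; g < 11; ++g)
      s[g] = inf[g] + (s[g] - inf[g]) * exp(-dt / tau[g]);
  }
  {
    double fi = 0.6 * inv5 + 0.4;
    double rl;
    if (TAB) { // tabulated exp(-dt/(80 x + 2)) on x = inv5 in [0, 1]
      double xf = inv5 * t.nf;
      int ii = (int)xf;
      if (ii >= t.nf) ii = t.nf - 1;
      double wf = xf - ii;
      double a = t.fcass_rl[ii];
      rl = a + (t.fcass_rl[ii + 1] - a) * wf;
    } else {
      rl = exp(-dt / (80.0 * inv5 + 2.0));
    }
    s[iFCa] = fi + (s[iFCa] - fi) * rl;
  }

  // --- BioICD state (exact exponential per step, frozen V and frozen a1) ---
  if (bio_on) {
    double a1 = s[iA1];
    if (a1 < 1e-30) a1 = 0.0;       // flush decayed states before they
    if (O < 1e-30) O = 0.0;         // reach the subnormal range
    bool dep = (V >= b.vgate);
    double kco = dep ? b.kco_on : 0.0;
    double koc = dep ? 0.0 : b.koc_base;
    double koce = koc + b.kocscale * ipow(a1, b.catp);
    double rate = (kco + koce) / b.tauo;
    double Oinf = (kco + koce > 0.0) ? kco / (kco + koce) : O;
    double rl;
    if (a1 < 1e-3) rl = dep ? t.bio_rl_dep : t.bio_rl_rest;
    else           rl = exp_neg_small(rate * dt);
    s[iO] = Oinf + (O - Oinf) * rl;
    bool win = (V > b.vlow && V < b.vhigh);
    if (win) s[iA1] = 1.0 + (a1 - 1.0) * t.a1_rl_in;
    else     s[iA1] = a1 * t.a1_rl_out;
  }

  // --- membrane potential ---
  double Iother = Iion - Ibio + istim;
  if (gbio * dt > 1e-8) {
    double Vinf = b.erev - Iother / gbio;
    V = Vinf + (V - Vinf) * exp(-gbio * dt) + dt * lap;
  } else {
    V += dt * (lap - Iother - Ibio);
  }
  StepOut out; out.ibio = Ibio; out.iion = Iion;
  return out;
}

static inline void update_erev(const CellP& p, const double* s, double* e) {
  double rtonf = p.rtonf();
  e[0] = rtonf * log(p.Ko / s[iKi]);
  e[1] = rtonf * log(p.Nao / s[iNai]);
  e[2] = rtonf * log((p.Ko + p.pKNa * p.Nao) / (s[iKi] + p.pKNa * s[iNai]));
  e[3] = 0.5 * rtonf * log(p.Cao / s[iCai]);
}

// ------------------------------------------------------------- R interfaces

// [[Rcpp::export(name = ".gate_inf_tau_cpp")]]
List gate_inf_tau_cpp(double v, List cellp) {
  CellP p = cellp_from_list(cellp);
  double inf[NS], tau[NS];
  gate_inf_tau(p, v, inf, tau);
  NumericVector vi(11), vt(11);
  CharacterVector nm = CharacterVector::create("m", "h", "j", "xr1", "xr2",
                                               "xs", "r", "s", "d", "f", "f2");
  for (int g = 0; g < 11; ++g) { vi[g] = inf[g]; vt[g] = tau[g]; }
  vi.names() = nm; vt.names() = nm;
  return List::create(_["inf"] = vi, _["tau"] = vt);
}

// [[Rcpp::export(name = ".ionic_currents_cpp")]]
NumericVector ionic_currents_cpp(NumericVector state, List cellp, List biop,
                                 bool bio_on) {
  CellP p = cellp_from_list(cellp);
  BioP b = biop_from_list(biop);
  double V = state[0];
  std::vector<double> s(state.begin() + 1, state.end());
  double e[4];
  update_erev(p, s.data(), e);
  double Ek = e[0], Ena = e[1], Eks = e[2], Eca = e[3];
  double INa  = p.sc[SC_NA] * p.Gna * s[iM] * s[iM] * s[iM] * s[iH] * s[iJ] * (V - Ena);
  double ICaL = p.sc[SC_CAL] * p.Gcal * s[iD] * s[iF] * s[iF2] * s[iFCa] *
                f_calA(p, V) * (0.25 * s[iCaSS] * f_calE(p, V) - p.Cao);
  double IK1  = p.sc[SC_K1] * p.Gk1 * sqrt(p.Ko / 5.4) * f_ik1rec(V - Ek) * (V - Ek);
  double Ito  = p.sc[SC_TO] * p.Gto * s[iR] * s[iS] * (V - Ek);
  double IKr  = p.sc[SC_KR] * p.Gkr * sqrt(p.Ko / 5.4) * s[iXr1] * s[iXr2] * (V - Ek);
  double IKs  = p.sc[SC_KS] * p.Gks * s[iXs] * s[iXs] * (V - Eks);
  double Nai3 = s[iNai] * s[iNai] * s[iNai];
  double INaCa = p.sc[SC_NACA] * p.knaca *
      (1.0 / (p.KmNai * p.KmNai * p.KmNai + p.Nao * p.Nao * p.Nao)) *
      (1.0 / (p.KmCa + p.Cao)) * (1.0 / (1.0 + p.ksat * f_nacae2(p, V))) *
      (f_nacae1(p, V) * Nai3 * p.Cao -
       f_nacae2(p, V) * p.Nao * p.Nao * p.Nao * s[iCai] * 2.5);
  double INaK = p.sc[SC_NAK] * p.knak * (p.Ko / (p.Ko + p.KmK)) *
      (s[iNai] / (s[iNai] + p.KmNa)) * f_nakrec(p, V);
  double IpCa = p.sc[SC_PCA] * p.Gpca * s[iCai] / (p.KpCa + s[iCai]);
  double IpK  = p.sc[SC_PK] * p.Gpk * f_ipkrec(V) * (V - Ek);
  double IbNa = p.sc[SC_BNA] * p.Gbna * (V - Ena);
  double IbCa = p.sc[SC_BCA] * p.Gbca * (V - Eca);
  double Ibio = bio_on ? b.gmax * ipow(s[iO], b.nsub) * (V - b.erev) : 0.0;
  double tot = INa + ICaL + IK1 + Ito + INaCa + INaK + IKr + IKs +
               IbNa + IbCa + IpCa + IpK + Ibio;
  NumericVector out = NumericVector::create(
      _["i_na"] = INa, _["i_cal"] = ICaL, _["i_k1"] = IK1, _["i_to"] = Ito,
      _["i_naca"] = INaCa, _["i_nak"] = INaK, _["i_kr"] = IKr, _["i_ks"] = IKs,
      _["i_bna"] = IbNa, _["i_bca"] = IbCa, _["i_pca"] = IpCa, _["i_pk"] = IpK,
      _["i_bioicd"] = Ibio, _["total"] = tot);
  return out;
}

// Single-cell runner. Stimulus: explicit pulse start times (ms), rectangular
// pulses of given duration and amplitude. Optionally records every
// record_every ms. i_extra adds a constant background current.
// [[Rcpp::export(name = ".run_cell_cpp")]]
List run_cell_cpp(NumericVector state0, List cellp, List biop, bool bio_on,
                  double dt, double duration, NumericVector pulse_start,
                  double pulse_dur, double pulse_amp, double record_every,
                  bool use_tables, int erev_every, double t0) {
  CellP p = cellp_from_list(cellp);
  BioP b = biop_from_list(biop);
  Tab tb;
  build_tables(p, b, dt, tb);
  double V = state0[0];
  std::vector<double> s(state0.begin() + 1, state0.end());
  double e[4];
  update_erev(p, s.data(), e);

  long nsteps = (long)llround(duration / dt);
  int rec_every = std::max(1, (int)llround(record_every / dt));
  long nrec = nsteps / rec_every + 1;
  NumericVector rt(nrec), rv(nrec), ribio(nrec), ro(nrec), ra1(nrec), rstim(nrec);
  long ri = 0;

  int npulse = pulse_start.size();
  int pnext = 0;

  for (long k = 0; k <= nsteps; ++k) {
    double t = t0 + k * dt;
    double istim = 0.0;
    while (pnext < npulse && t >= pulse_start[pnext] + pulse_dur) ++pnext;
    for (int q = pnext; q < npulse && pulse_start[q] <= t; ++q)
      if (t < pulse_start[q] + pulse_dur) { istim = pulse_amp; break; }
    if (k % rec_every == 0 && ri < nrec) {
      rt[ri] = t; rv[ri] = V;
      ribio[ri] = bio_on ? b.gmax * ipow(s[iO], b.nsub) * (V - b.erev) : 0.0;
      ro[ri] = s[iO]; ra1[ri] = s[iA1]; rstim[ri] = (istim != 0.0) ? 1.0 : 0.0;
      ++ri;
    }
    if (k == nsteps) break;
    if (k % erev_every == 0) update_erev(p, s.data(), e);
    if (use_tables) node_step<true>(V, s.data(), e, p, b, tb, dt, istim, 0.0, bio_on);
    else            node_step<false>(V, s.data(), e, p, b, tb, dt, istim, 0.0, bio_on);
    if (!std::isfinite(V))
      stop("numerical blow-up: non-finite membrane potential at t = %f ms", t);
  }
  NumericVector sf(NS + 1);
  sf[0] = V;
  for (int i = 0; i < NS; ++i) sf[i + 1] = s[i];
  return List::create(_["time"] = rt, _["v"] = rv, _["i_bioicd"] = ribio,
                      _["o"] = ro, _["a1"] = ra1, _["stim"] = rstim,
                      _["state"] = sf);
}

// --------------------------------------------------------------- diffusion

// 5-point no-flux Laplacian; nodes of class 2 (fibroblast void) and 3 (scar
// core) are excluded from the stencil (internal no-flux), domain edges are
// mirrored. class: 0 myocyte, 1 grey-zone myocyte.
// [[Rcpp::export(name = ".laplacian_cpp")]]
NumericVector laplacian_cpp(NumericVector v, IntegerVector nodeclass,
                            int nx, int ny, double dx, double dcoef) {
  NumericVector out(nx * ny);
  double w = dcoef / (dx * dx);
  for (int y = 0; y < ny; ++y) {
    for (int x = 0; x < nx; ++x) {
      int i = y * nx + x;
      if (nodeclass[i] >= 2) { out[i] = 0.0; continue; }
      double acc = 0.0;
      if (x > 0      && nodeclass[i - 1]  < 2) acc += v[i - 1]  - v[i];
      if (x < nx - 1 && nodeclass[i + 1]  < 2) acc += v[i + 1]  - v[i];
      if (y > 0      && nodeclass[i - nx] < 2) acc += v[i - nx] - v[i];
      if (y < ny - 1 && nodeclass[i + nx] < 2) acc += v[i + nx] - v[i];
      out[i] = w * acc;
    }
  }
  return out;
}

// ------------------------------------------------------------ tissue runner

// [[Rcpp::export(name = ".run_tissue_cpp")]]
List run_tissue_cpp(IntegerVector nodeclass, int nx, int ny, double dx,
                    double dcoef, NumericMatrix state0, List cellp,
                    List cellp_gz, List biop, bool bio_on, double dt,
                    double duration, double t0, List events,
                    IntegerVector probe_idx, double probe_every,
                    double frame_every, double snap_every, double sync_v,
                    double reset_v, double act_v, double act_lockout,
                    bool use_tables, int erev_every, bool stop_if_quiescent,
                    double stop_after_reset_from) {
  int n = nx * ny;
  CellP pb = cellp_from_list(cellp);
  CellP pg = cellp_from_list(cellp_gz);
  BioP b = biop_from_list(biop);
  Tab tb;
  build_tables(pb, b, dt, tb); // gate kinetics shared by base and grey zone

  // state: double-buffered V, s[n*NS] node-major, erev[n*4]
  std::vector<double> Vbuf0(n), Vbuf1(n), S((size_t)n * NS), E((size_t)n * 4);
  std::vector<double> stim(n, 0.0);
  double* V = Vbuf0.data();
  double* Vnext = Vbuf1.data();
  for (int i = 0; i < n; ++i) {
    V[i] = Vnext[i] = state0(i, 0); // void/scar voltages stay fixed in both
    for (int q = 0; q < NS; ++q) S[(size_t)i * NS + q] = state0(i, q + 1);
  }
  std::vector<int> myo;
  myo.reserve(n);
  for (int i = 0; i < n; ++i) if (nodeclass[i] < 2) myo.push_back(i);
  for (int idx : myo) update_erev(nodeclass[idx] == 1 ? pg : pb,
                                  &S[(size_t)idx * NS], &E[(size_t)idx * 4]);

  // neighbour index table (-1: no coupling)
  std::vector<int> nb((size_t)n * 4, -1);
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      int i = y * nx + x;
      if (nodeclass[i] >= 2) continue;
      if (x > 0      && nodeclass[i - 1]  < 2) nb[(size_t)i * 4 + 0] = i - 1;
      if (x < nx - 1 && nodeclass[i + 1]  < 2) nb[(size_t)i * 4 + 1] = i + 1;
      if (y > 0      && nodeclass[i - nx] < 2) nb[(size_t)i * 4 + 2] = i - nx;
      if (y < ny - 1 && nodeclass[i + nx] < 2) nb[(size_t)i * 4 + 3] = i + nx;
    }

  // stimulus events
  int nev = events.size();
  std::vector<double> ev_t0(nev), ev_dur(nev), ev_amp(nev), ev_per(nev);
  std::vector<IntegerVector> ev_mask(nev);
  std::vector<char> ev_active(nev, 0);
  for (int q = 0; q < nev; ++q) {
    List ev = events[q];
    ev_t0[q] = ev["t_start"]; ev_dur[q] = ev["duration"];
    ev_amp[q] = ev["amplitude"]; ev_per[q] = ev["period"];
    ev_mask[q] = as<IntegerVector>(ev["mask"]);
  }

  long nsteps = (long)llround(duration / dt);
  int pr_every = std::max(1, (int)llround(probe_every / dt));
  int fr_every = std::max(1, (int)llround(frame_every / dt));
  long sn_every = snap_every > 0 ? std::max((long)1, (long)llround(snap_every / dt))
                                 : (long)-1;
  int npr = probe_idx.size();
  long nrec = nsteps / pr_every + 1;
  NumericMatrix pv(nrec, npr), pibio(nrec, npr), po(nrec, npr), pa1(nrec, npr);
  NumericVector ptime(nrec);
  long nfr = nsteps / fr_every + 1;
  NumericVector ft(nfr), fmax(nfr), fsync(nfr), freset(nfr);
  long nsn = sn_every > 0 ? nsteps / sn_every + 1 : 0;
  NumericMatrix snapv(nsn > 0 ? n : 1, nsn > 0 ? nsn : 1);
  NumericMatrix snapi(nsn > 0 ? n : 1, nsn > 0 ? nsn : 1);
  NumericVector sntime(nsn > 0 ? nsn : 0);

  std::vector<double> last_act(n, -1e30);
  std::vector<int> act_node; std::vector<double> act_time;
  act_node.reserve(1 << 16); act_time.reserve(1 << 16);

  double nmyo = (double)myo.size();
  long ri = 0, fi = 0, si = 0;
  double stopped_at = NA_REAL;
  bool any_stim = false;

  for (long k = 0; k <= nsteps; ++k) {
    double t = t0 + k * dt;

    // refresh stimulus field when any event switches on or off
    bool changed = false, any = false;
    for (int q = 0; q < nev; ++q) {
      double rel = t - ev_t0[q];
      bool on = false;
      if (rel >= -1e-9) {
        if (ev_per[q] > 0) {
          double ph = rel - floor(rel / ev_per[q]) * ev_per[q];
          on = ph < ev_dur[q] - 1e-9;
        } else on = rel < ev_dur[q] - 1e-9;
      }
      if (on != (bool)ev_active[q]) { changed = true; ev_active[q] = on; }
      any = any || on;
    }
    if (changed) {
      std::fill(stim.begin(), stim.end(), 0.0);
      for (int q = 0; q < nev; ++q)
        if (ev_active[q])
          for (int m : ev_mask[q]) stim[m] += ev_amp[q];
    }
    any_stim = any;

    // recording
    if (k % pr_every == 0 && ri < nrec) {
      ptime[ri] = t;
      for (int j = 0; j < npr; ++j) {
        int idx = probe_idx[j];
        double O = S[(size_t)idx * NS + iO];
        pv(ri, j) = V[idx];
        pibio(ri, j) = bio_on ? b.gmax * ipow(O, b.nsub) * (V[idx] - b.erev) : 0.0;
        po(ri, j) = O; pa1(ri, j) = S[(size_t)idx * NS + iA1];
      }
      ++ri;
    }
    if (k % fr_every == 0 && fi < nfr) {
      double mx = 0.0; long csync = 0, creset = 0;
      for (int idx : myo) {
        double vv = V[idx];
        if (vv > sync_v) ++csync;
        if (vv < reset_v) ++creset;
        if (bio_on) {
          double O = S[(size_t)idx * NS + iO];
          double ib = fabs(b.gmax * ipow(O, b.nsub) * (vv - b.erev));
          if (ib > mx) mx = ib;
        }
      }
      ft[fi] = t; fmax[fi] = mx;
      fsync[fi] = csync / nmyo; freset[fi] = creset / nmyo;
      // optional stop once the tissue-wide reset criterion has been met
      // (after the given time); the quantity of interest is then recorded
      if (std::isfinite(stop_after_reset_from) && t >= stop_after_reset_from &&
          freset[fi] >= 0.99) {
        ++fi;
        stopped_at = t;
        break;
      }
      if (stop_if_quiescent && !any_stim && t > t0 + 1.0 &&
          freset[fi] >= 0.999) {
        bool pending = false;
        for (int q = 0; q < nev; ++q) {
          if (ev_per[q] > 0) { pending = true; break; }
          if (t < ev_t0[q] + ev_dur[q]) { pending = true; break; }
        }
        if (!pending) { ++fi; stopped_at = t; break; }
      }
      ++fi;
    }
    if (sn_every > 0 && k % sn_every == 0 && si < nsn) {
      sntime[si] = t;
      for (int i = 0; i < n; ++i) {
        snapv(i, si) = V[i];
        double O = S[(size_t)i * NS + iO];
        snapi(i, si) = (bio_on && nodeclass[i] < 2)
                           ? b.gmax * ipow(O, b.nsub) * (V[i] - b.erev) : 0.0;
      }
      ++si;
    }
    if (k == nsteps) break;

    // fused diffusion + reaction: read neighbours from the entering buffer,
    // write the advanced voltage into the other buffer, then swap
    const double w = dcoef / (dx * dx);
    const bool do_erev = (k % erev_every == 0);
    auto sweep = [&](auto tab_tag) {
      constexpr bool TABX = decltype(tab_tag)::value;
      for (int idx : myo) {
        const CellP& p = nodeclass[idx] == 1 ? pg : pb;
        double* s = &S[(size_t)idx * NS];
        double* e = &E[(size_t)idx * 4];
        if (do_erev) update_erev(p, s, e);
        const int* nbi = &nb[(size_t)idx * 4];
        double vold = V[idx], acc = 0.0;
        if (nbi[0] >= 0) acc += V[nbi[0]] - vold;
        if (nbi[1] >= 0) acc += V[nbi[1]] - vold;
        if (nbi[2] >= 0) acc += V[nbi[2]] - vold;
        if (nbi[3] >= 0) acc += V[nbi[3]] - vold;
        double v = vold;
        node_step<TABX>(v, s, e, p, b, tb, dt, stim[idx], w * acc, bio_on);
        Vnext[idx] = v;
        if (vold <= act_v && v > act_v && t - last_act[idx] >= act_lockout) {
          last_act[idx] = t;
          act_node.push_back(idx);
          act_time.push_back(t);
        }
      }
    };
    if (use_tables) sweep(std::true_type{});
    else sweep(std::false_type{});
    std::swap(V, Vnext);
    if (k % 500 == 0) {
      int c = myo.size() > 0 ? myo[myo.size() / 2] : 0;
      if (!std::isfinite(V[c]))
        stop("numerical blow-up: non-finite membrane potential at t = %f ms, node %d", t, c);
      Rcpp::checkUserInterrupt();
    }
  }

  NumericMatrix sf(n, NS + 1);
  for (int i = 0; i < n; ++i) {
    sf(i, 0) = V[i];
    for (int q = 0; q < NS; ++q) sf(i, q + 1) = S[(size_t)i * NS + q];
  }
  // trim recorders to what was filled
  return List::create(
      _["state"] = sf,
      _["probe_time"] = ptime[Range(0, std::max((long)0, ri - 1))],
      _["probe_v"] = pv, _["probe_ibio"] = pibio, _["probe_o"] = po,
      _["probe_a1"] = pa1, _["n_probe_rec"] = (double)ri,
      _["frame_time"] = ft[Range(0, std::max((long)0, fi - 1))],
      _["frame_max_ibio"] = fmax[Range(0, std::max((long)0, fi - 1))],
      _["frame_frac_sync"] = fsync[Range(0, std::max((long)0, fi - 1))],
      _["frame_frac_reset"] = freset[Range(0, std::max((long)0, fi - 1))],
      _["snap_time"] = sntime, _["snap_v"] = snapv, _["snap_ibio"] = snapi,
      _["n_snap"] = (double)si,
      _["act_node"] = IntegerVector(act_node.begin(), act_node.end()),
      _["act_time"] = NumericVector(act_time.begin(), act_time.end()),
      _["stopped_at"] = stopped_at);
}
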