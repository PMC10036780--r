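// Core numerics for the coupled cardiomyocyte-fibroblast electromechanical model.
//
// Myocyte electrophysiology follows the ten Tusscher-Panfilov 2006 human
// ventricular formulation (epicardial variant) with the SR release channel
// replaced by a four-state (R/O/I/RI) ryanodine-receptor gating scheme with
// luminal Ca2+ regulation, and the generalized cytosolic Ca2+ buffer split
// into a dynamic Ca-troponin C pool (owned by the mechanics block) plus a
// residual instantaneous buffer of preserved total capacity.
//
// Mechanics: Hill-type rheology — contractile element CE in series with
// (SE || VS2), that chain in parallel with PE, n fibroblast elastic elements
// PEfb and viscous VS1, the whole branch in series with XSE.  Isometric
// constraint on the whole preparation; the internal CE velocity is obtained
// per step by bracketed Brent root-finding on the inner node force balance.
//
// Fibroblast: MacCannell active formulation (iKv, iK1, iNaK, ibNa) plus the
// length-dependent linear mechanosensitive current i_MS.
//
// Units: mV, ms, mM, pA/pF (myocyte currents), pA (fibroblast currents),
// nS (g_gap), forces normalized to the uncoupled-myocyte peak twitch force.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
#include <string>
using namespace Rcpp;

static const double RGAS = 8314.472;     // mJ/(mol K)
static const double FRDY = 96485.3415;   // C/mol
static const double TEMP = 310.0;        // K

// ---------------------------------------------------------------------------
// state vector layout (myocyte block, 26 entries; fibroblast i at 26+3i)
enum {
  iV = 0, iM, iH, iJ, iXR1, iXR2, iXS, iR, iS, iD, iF, iF2, iFCASS,
  iRYR_R, iRYR_O, iRYR_I, iRYR_RI,
  iNAI, iKI, iCAI, iCASS, iCASR, iCATNC,
  iL1, iL2, iNXB,
  NMYO
};

struct MyoParams {
  double GNa, GK1, Gto, GKr, GKs, GCaL, GbNa, GbCa, GpK, GpCa, KpCa;
  double PNaK, KmK, KmNa, kNaCa, KmNai, KmCa, ksat, gam, alp, pKNa;
  double Ko, Nao, Cao;
  double Vc, Vsr, Vss, Cm;
  double Bufc2, Kbufc, Bufsr, Kbufsr, Bufss, Kbufss;
  double Vmaxup, Kup, Vleak, Vxfer, Vrel;
  double koCa, kiCa, kom, kim, ec50SR, maxSR, minSR, hillSR;
  double x_ical, x_ikr, x_iks, x_serca;
  double stim_amp, stim_dur, stim_period, stim_start;
  double Atot, a_on, k_off0, kA, pi_min, pi_q;
};

struct MechParams {
  double a_pe, b_pe, a_fb, b_fb, a_se, b_se, a_xse, b_xse;
  double nu1, nu2;
  double F_scale, v_max, fv_curv;
  double k_att, k_det, det_v;
  double lam_lo, lam_hi;    // sarcomere-fraction ramp of length-dependent activation
  double Km_act;            // CaTnC (mM) half-activation of Xb attachment
  double base_frac;         // branch/sarcomere slack as fraction of L_max
  double F_norm;            // normalization: peak active force, uncoupled, 90% L_max
};

struct FbParams {
  double Cmf, GKv, GK1f, GbNaf, INaKmax, KmKf, KmNaf, Kif, Naif;
  double g_max, a_slope, vrev_lo, vrev_hi, len_lo, len_hi;
  int    vrev_neg_at_long;  // 1: vrev_lo at len_hi (default); 0: flipped
  double x_gmax, x_vrev;
};

static double getd(const List& l, const char* nm) {
  if (!l.containsElementNamed(nm)) stop(std::string("missing parameter: ") + nm);
  return as<double>(l[nm]);
}

static MyoParams parseMyo(const List& p) {
  MyoParams m;
  m.GNa = getd(p,"g_Na"); m.GK1 = getd(p,"g_K1"); m.Gto = getd(p,"g_to");
  m.GKr = getd(p,"g_Kr"); m.GKs = getd(p,"g_Ks"); m.GCaL = getd(p,"g_CaL");
  m.GbNa = getd(p,"g_bNa"); m.GbCa = getd(p,"g_bCa"); m.GpK = getd(p,"g_pK");
  m.GpCa = getd(p,"g_pCa"); m.KpCa = getd(p,"K_pCa");
  m.PNaK = getd(p,"P_NaK"); m.KmK = getd(p,"K_mK"); m.KmNa = getd(p,"K_mNa");
  m.kNaCa = getd(p,"k_NaCa"); m.KmNai = getd(p,"K_mNai"); m.KmCa = getd(p,"K_mCa");
  m.ksat = getd(p,"k_sat"); m.gam = getd(p,"gamma_ncx"); m.alp = getd(p,"alpha_ncx");
  m.pKNa = getd(p,"p_KNa");
  m.Ko = getd(p,"K_o"); m.Nao = getd(p,"Na_o"); m.Cao = getd(p,"Ca_o");
  m.Vc = getd(p,"V_c"); m.Vsr = getd(p,"V_sr"); m.Vss = getd(p,"V_ss");
  m.Cm = getd(p,"C_myo");
  m.Bufc2 = getd(p,"buf_c2"); m.Kbufc = getd(p,"K_bufc");
  m.Bufsr = getd(p,"buf_sr"); m.Kbufsr = getd(p,"K_bufsr");
  m.Bufss = getd(p,"buf_ss"); m.Kbufss = getd(p,"K_bufss");
  m.Vmaxup = getd(p,"V_maxup"); m.Kup = getd(p,"K_up");
  m.Vleak = getd(p,"V_leak"); m.Vxfer = getd(p,"V_xfer"); m.Vrel = getd(p,"V_rel");
  m.koCa = getd(p,"ryr_ko_ca"); m.kiCa = getd(p,"ryr_ki_ca");
  m.kom = getd(p,"ryr_k_om"); m.kim = getd(p,"ryr_k_im");
  m.ec50SR = getd(p,"ryr_ec50_sr"); m.maxSR = getd(p,"ryr_max_sr"); m.minSR = getd(p,"ryr_min_sr");
  m.hillSR = getd(p,"ryr_hill_sr");
  m.x_ical = getd(p,"x_ical"); m.x_ikr = getd(p,"x_ikr");
  m.x_iks = getd(p,"x_iks"); m.x_serca = getd(p,"x_serca");
  m.stim_amp = getd(p,"stim_amplitude"); m.stim_dur = getd(p,"stim_duration");
  m.stim_period = getd(p,"stim_period"); m.stim_start = getd(p,"stim_start");
  m.Atot = getd(p,"tnc_total"); m.a_on = getd(p,"tnc_a_on");
  m.k_off0 = getd(p,"tnc_k_off0"); m.kA = getd(p,"tnc_k_a");
  m.pi_min = getd(p,"tnc_pi_min"); m.pi_q = getd(p,"tnc_pi_q");
  return m;
}

static MechParams parseMech(const List& p) {
  MechParams m;
  m.a_pe = getd(p,"alpha_pe"); m.b_pe = getd(p,"beta_pe");
  m.a_fb = getd(p,"alpha_fb"); m.b_fb = getd(p,"beta_fb");
  m.a_se = getd(p,"alpha_se"); m.b_se = getd(p,"beta_se");
  m.a_xse = getd(p,"alpha_xse"); m.b_xse = getd(p,"beta_xse");
  m.nu1 = getd(p,"nu_vs1"); m.nu2 = getd(p,"nu_vs2");
  m.F_scale = getd(p,"f_ce_scale"); m.v_max = getd(p,"v_max");
  m.fv_curv = getd(p,"fv_curvature");
  m.k_att = getd(p,"xb_k_att"); m.k_det = getd(p,"xb_k_det"); m.det_v = getd(p,"xb_det_v");
  m.lam_lo = getd(p,"lambda_lo"); m.lam_hi = getd(p,"lambda_hi");
  m.Km_act = getd(p,"xb_km_catnc");
  m.base_frac = getd(p,"base_frac");
  m.F_norm = getd(p,"f_norm");
  return m;
}

static FbParams parseFb(const List& p) {
  FbParams f;
  f.Cmf = getd(p,"C_mf"); f.GKv = getd(p,"g_Kv"); f.GK1f = getd(p,"g_K1f");
  f.GbNaf = getd(p,"g_bNaf"); f.INaKmax = getd(p,"i_NaK_max");
  f.KmKf = getd(p,"K_mKf"); f.KmNaf = getd(p,"K_mNaf");
  f.Kif = getd(p,"K_if"); f.Naif = getd(p,"Na_if");
  f.g_max = getd(p,"g_max"); f.a_slope = getd(p,"a_slope");
  f.vrev_lo = getd(p,"v_rev_lo"); f.vrev_hi = getd(p,"v_rev_hi");
  f.len_lo = getd(p,"length_lo"); f.len_hi = getd(p,"length_hi");
  f.vrev_neg_at_long = (int)getd(p,"vrev_neg_at_long");
  f.x_gmax = getd(p,"x_gmax"); f.x_vrev = getd(p,"x_vrev");
  return f;
}

// ---------------------------------------------------------------------------
// TP06 gate steady states and time constants (12 gates; fcass uses Ca_ss)
static void gateTables(double V, double cass, double* inf, double* tau) {
  double a, b, c;
  // m
  inf[0] = 1.0 / pow(1.0 + exp((-56.86 - V) / 9.03), 2);
  a = 1.0 / (1.0 + exp((-60.0 - V) / 5.0));
  b = 0.1 / (1.0 + exp((V + 35.0) / 5.0)) + 0.10 / (1.0 + exp((V - 50.0) / 200.0));
  tau[0] = a * b;
  // h
  inf[1] = 1.0 / pow(1.0 + exp((V + 71.55) / 7.43), 2);
  if (V >= -40.0) {
    a = 0.0;
    b = 0.77 / (0.13 * (1.0 + exp(-(V + 10.66) / 11.1)));
  } else {
    a = 0.057 * exp(-(V + 80.0) / 6.8);
    b = 2.7 * exp(0.079 * V) + 3.1e5 * exp(0.3485 * V);
  }
  tau[1] = 1.0 / (a + b);
  // j
  inf[2] = inf[1];
  if (V >= -40.0) {
    a = 0.0;
    b = 0.6 * exp(0.057 * V) / (1.0 + exp(-0.1 * (V + 32.0)));
  } else {
    a = (-2.5428e4 * exp(0.2444 * V) - 6.948e-6 * exp(-0.04391 * V)) * (V + 37.78) /
        (1.0 + exp(0.311 * (V + 79.23)));
    b = 0.02424 * exp(-0.01052 * V) / (1.0 + exp(-0.1378 * (V + 40.14)));
  }
  tau[2] = 1.0 / (a + b);
  // xr1
  inf[3] = 1.0 / (1.0 + exp((-26.0 - V) / 7.0));
  a = 450.0 / (1.0 + exp((-45.0 - V) / 10.0));
  b = 6.0 / (1.0 + exp((V + 30.0) / 11.5));
  tau[3] = a * b;
  // xr2
  inf[4] = 1.0 / (1.0 + exp((V + 88.0) / 24.0));
  a = 3.0 / (1.0 + exp((-60.0 - V) / 20.0));
  b = 1.12 / (1.0 + exp((V - 60.0) / 20.0));
  tau[4] = a * b;
  // xs
  inf[5] = 1.0 / (1.0 + exp((-5.0 - V) / 14.0));
  a = 1400.0 / sqrt(1.0 + exp((5.0 - V) / 6.0));
  b = 1.0 / (1.0 + exp((V - 35.0) / 15.0));
  tau[5] = a * b + 80.0;
  // r
  inf[6] = 1.0 / (1.0 + exp((20.0 - V) / 6.0));
  tau[6] = 9.5 * exp(-(V + 40.0) * (V + 40.0) / 1800.0) + 0.8;
  // s (epicardial)
  inf[7] = 1.0 / (1.0 + exp((V + 20.0) / 5.0));
  tau[7] = 85.0 * exp(-(V + 45.0) * (V + 45.0) / 320.0) +
           5.0 / (1.0 + exp((V - 20.0) / 5.0)) + 3.0;
  // d
  inf[8] = 1.0 / (1.0 + exp((-8.0 - V) / 7.5));
  a = 1.4 / (1.0 + exp((-35.0 - V) / 13.0)) + 0.25;
  b = 1.4 / (1.0 + exp((V + 5.0) / 5.0));
  c = 1.0 / (1.0 + exp((50.0 - V) / 20.0));
  tau[8] = a * b + c;
  // f
  inf[9] = 1.0 / (1.0 + exp((V + 20.0) / 7.0));
  tau[9] = 1102.5 * exp(-(V + 27.0) * (V + 27.0) / 225.0) +
           200.0 / (1.0 + exp((13.0 - V) / 10.0)) +
           180.0 / (1.0 + exp((V + 30.0) / 10.0)) + 20.0;
  // f2
  inf[10] = 0.67 / (1.0 + exp((V + 35.0) / 7.0)) + 0.33;
  tau[10] = 562.0 * exp(-(V + 27.0) * (V + 27.0) / 240.0) +
            31.0 / (1.0 + exp((25.0 - V) / 10.0)) +
            80.0 / (1.0 + exp((V + 30.0) / 10.0));
  // fcass
  double q = (cass / 0.05) * (cass / 0.05);
  inf[11] = 0.6 / (1.0 + q) + 0.4;
  tau[11] = 80.0 / (1.0 + q) + 2.0;
}

struct Currents {
  double INa, IbNa, ICaL, IbCa, Ito, IKr, IKs, IK1, IpK, IpCa, INaK, INaCa;
  double total;                       // sarcolemmal sum, pA/pF
  double Irel, Iup, Ileak, Ixfer;     // mM/ms (SR-volume convention for up/leak/rel)
};

static void myoCurrents(const double* s, const MyoParams& p, Currents& c) {
  const double V = s[iV];
  const double rtf = RGAS * TEMP / FRDY;
  const double EK  = rtf * log(p.Ko / s[iKI]);
  const double ENa = rtf * log(p.Nao / s[iNAI]);
  const double EKs = rtf * log((p.Ko + p.pKNa * p.Nao) / (s[iKI] + p.pKNa * s[iNAI]));
  const double ECa = 0.5 * rtf * log(p.Cao / std::max(s[iCAI], 1e-12));

  c.INa  = p.GNa * s[iM]*s[iM]*s[iM] * s[iH] * s[iJ] * (V - ENa);
  c.IbNa = p.GbNa * (V - ENa);
  // L-type Ca current (GHK-like driving term of TP06)
  {
    double z = 2.0 * (V - 15.0) * FRDY / (RGAS * TEMP);
    double gate = p.x_ical * p.GCaL * s[iD] * s[iF] * s[iF2] * s[iFCASS];
    if (fabs(z) > 1e-7) {
      c.ICaL = gate * 4.0 * (V - 15.0) * FRDY * FRDY / (RGAS * TEMP) *
               (0.25 * s[iCASS] * exp(z) - p.Cao) / (exp(z) - 1.0);
    } else {
      // limit at V = 15 mV
      c.ICaL = gate * 2.0 * FRDY * (0.25 * s[iCASS] - p.Cao);
    }
  }
  c.IbCa = p.GbCa * (V - ECa);
  c.Ito  = p.Gto * s[iR] * s[iS] * (V - EK);
  c.IKr  = p.x_ikr * p.GKr * sqrt(p.Ko / 5.4) * s[iXR1] * s[iXR2] * (V - EK);
  c.IKs  = p.x_iks * p.GKs * s[iXS] * s[iXS] * (V - EKs);
  {
    double aK1 = 0.1 / (1.0 + exp(0.06 * (V - EK - 200.0)));
    double bK1 = (3.0 * exp(0.0002 * (V - EK + 100.0)) + exp(0.1 * (V - EK - 10.0))) /
                 (1.0 + exp(-0.5 * (V - EK)));
    c.IK1 = p.GK1 * sqrt(p.Ko / 5.4) * aK1 / (aK1 + bK1) * (V - EK);
  }
  c.IpK  = p.GpK * (V - EK) / (1.0 + exp((25.0 - V) / 5.98));
  c.IpCa = p.GpCa * s[iCAI] / (s[iCAI] + p.KpCa);
  c.INaK = p.PNaK * (p.Ko / (p.Ko + p.KmK)) * (s[iNAI] / (s[iNAI] + p.KmNa)) /
           (1.0 + 0.1245 * exp(-0.1 * V * FRDY / (RGAS * TEMP)) +
            0.0353 * exp(-V * FRDY / (RGAS * TEMP)));
  {
    double vf = V * FRDY / (RGAS * TEMP);
    c.INaCa = p.kNaCa *
      (exp(p.gam * vf) * s[iNAI]*s[iNAI]*s[iNAI] * p.Cao -
       exp((p.gam - 1.0) * vf) * p.Nao*p.Nao*p.Nao * s[iCAI] * p.alp) /
      ((p.KmNai*p.KmNai*p.KmNai + p.Nao*p.Nao*p.Nao) * (p.KmCa + p.Cao) *
       (1.0 + p.ksat * exp((p.gam - 1.0) * vf)));
  }
  c.total = c.INa + c.IbNa + c.ICaL + c.IbCa + c.Ito + c.IKr + c.IKs + c.IK1 +
            c.IpK + c.IpCa + c.INaK + c.INaCa;

  c.Iup   = (s[iCAI] > 0.0)
            ? p.x_serca * p.Vmaxup / (1.0 + (p.Kup * p.Kup) / (s[iCAI] * s[iCAI]))
            : 0.0;
  c.Ileak = p.Vleak * (s[iCASR] - s[iCAI]);
  c.Ixfer = p.Vxfer * (s[iCASS] - s[iCAI]);
  c.Irel  = p.Vrel * s[iRYR_O] * (s[iCASR] - s[iCASS]);
}

// RyR four-state gating: R <-> O (Ca_ss^2), O <-> I (Ca_ss), I <-> RI, RI <-> R
// with luminal regulation through kCaSR(Ca_sr).
static void ryrRates(double cass, double casr, const MyoParams& p,
                     double& koSRCa, double& kiSRCa) {
  double kCaSR = p.maxSR - (p.maxSR - p.minSR) /
                 (1.0 + pow(p.ec50SR / casr, p.hillSR));
  koSRCa = p.koCa / kCaSR;
  kiSRCa = p.kiCa;   // inactivation is load-independent in this calibration
}

static void ryrDerivs(const double* s, const MyoParams& p, double* d4) {
  double ko, ki;
  ryrRates(s[iCASS], s[iCASR], p, ko, ki);
  double cass = s[iCASS];
  double R = s[iRYR_R], O = s[iRYR_O], I = s[iRYR_I], RI = s[iRYR_RI];
  double f_RO = ko * cass * cass * R - p.kom * O;
  double f_OI = ki * cass * O - p.kim * I;
  double f_IRI = p.kom * I - ko * cass * cass * RI;
  double f_RIR = p.kim * RI - ki * cass * R;
  d4[0] = f_RIR - f_RO;   // dR
  d4[1] = f_RO - f_OI;    // dO
  d4[2] = f_OI - f_IRI;   // dI
  d4[3] = f_IRI - f_RIR;  // dRI
}

// CaTnC off-rate with Xb cooperativity: k_off0 * exp(-kA*A) * pi(Nxb),
// pi strictly decreasing in Nxb.
static double catncKoff(double A, double Nxb, const MyoParams& p) {
  double pi = p.pi_min + (1.0 - p.pi_min) * exp(-p.pi_q * Nxb);
  return p.k_off0 * exp(-p.kA * A) * pi;
}

// ---------------------------------------------------------------------------
// Mechanics
static inline double fexp(double alpha, double beta, double l) {
  return beta * (exp(alpha * l) - 1.0);
}

// force-velocity factor, p(0)=1, monotone increasing in v, capped lengthening
static double fvFactor(double v, const MechParams& m) {
  if (v <= 0.0) {
    double num = m.v_max + v;
    if (num <= 0.0) return 0.0;
    return num / (m.v_max - v / m.fv_curv);
  }
  double slope = (1.0 + 1.0 / m.fv_curv) / m.v_max; // shortening-side slope at 0
  return 1.5 - 0.5 * exp(-2.0 * slope * v);
}

// overlap ramp for length-dependent activation (ascending limb)
static double lambdaOf(double sarc_frac, const MechParams& m) {
  double x = (sarc_frac - m.lam_lo) / (m.lam_hi - m.lam_lo);
  if (x < 0.0) x = 0.0;
  if (x > 1.0) x = 1.0;
  return x;
}

struct MechSolution {
  double v1, dl2;
  double F_ce, F_pe, F_pefb, F_se, F_xse, F_vs1, F_vs2, residual;
  int iterations;
  bool ok;
};

// The contractile branch is CE with its lattice damping VS2 across the
// sarcomere coordinate l1, in series with SE; the branch transmits
// F_SE(l2 - l1) = F_CE_active(Nxb, l1, v1) + nu2*v1 (inner balance, solved
// for v1).  The outer node then gives dl2 explicitly:
//   F_XSE(L - base - l2) = F_PE + n*F_PEfb + F_branch + nu1*dl2
// so the whole-preparation balance holds to machine precision and the
// reported residual is the inner-node imbalance at the accepted root.
static MechSolution mechSolve(double l1, double l2, double Nxb,
                              double L, int n, const MechParams& m) {
  MechSolution sol; sol.ok = true; sol.iterations = 0;
  double l3 = L - m.base_frac - l2;
  double F_xse = fexp(m.a_xse, m.b_xse, l3);
  double F_pe  = fexp(m.a_pe, m.b_pe, l2);
  double F_fb1 = fexp(m.a_fb, m.b_fb, l2);
  double F_se  = fexp(m.a_se, m.b_se, l2 - l1);
  double Fpar  = F_pe + n * F_fb1;
  double sarc  = m.base_frac + l1;
  double act   = m.F_scale * Nxb * lambdaOf(sarc, m);

  auto G = [&](double v1) {
    return F_se - act * fvFactor(v1, m) - m.nu2 * v1;
  };

  // bracket the root: G is strictly decreasing in v1
  double lo = -m.v_max * 0.999, hi = 10.0 * m.v_max;
  double Glo = G(lo), Ghi = G(hi);
  int guard = 0;
  while (Glo < 0.0 && guard++ < 60) { lo -= m.v_max; Glo = G(lo); }
  guard = 0;
  while (Ghi > 0.0 && guard++ < 60) { hi += 10.0 * m.v_max; Ghi = G(hi); }
  if (Glo < 0.0 || Ghi > 0.0) { sol.ok = false; sol.v1 = 0.0; }
  else {
    // Illinois false-position (bracketed, superlinear on smooth G)
    double a = lo, b = hi, fa = Glo, fb = Ghi, c = 0.5 * (a + b), fc;
    int side = 0;
    for (int it = 0; it < 200; ++it) {
      sol.iterations = it + 1;
      c = (fabs(fa - fb) > 1e-300) ? (a - fa * (b - a) / (fb - fa)) : 0.5 * (a + b);
      if (c <= a || c >= b) c = 0.5 * (a + b);
      fc = G(c);
      if (fabs(fc) < 1e-13 || (b - a) < 1e-16) break;
      if (fc > 0.0) {
        a = c; fa = fc;
        if (side == 1) fb *= 0.5;
        side = 1;
      } else {
        b = c; fb = fc;
        if (side == -1) fa *= 0.5;
        side = -1;
      }
    }
    sol.v1 = c;
  }
  // outer node: explicit parallel-branch rate (F_branch = F_SE at the root)
  sol.dl2 = (F_xse - Fpar - F_se) / m.nu1;
  sol.F_ce  = act * fvFactor(sol.v1, m);  // active CE force
  sol.F_pe  = F_pe;
  sol.F_pefb = F_fb1;
  sol.F_se  = F_se;
  sol.F_xse = F_xse;
  sol.F_vs1 = m.nu1 * sol.dl2;
  sol.F_vs2 = m.nu2 * sol.v1;             // CE lattice damping
  // whole-preparation balance with the transmitted contractile-branch force
  sol.residual = F_xse - (F_pe + n * F_fb1 + (sol.F_ce + sol.F_vs2) + sol.F_vs1);
  return sol;
}

static double xbRate(double Nxb, double A_mM, double l1, double v1,
                     const MechParams& m) {
  double sarc = m.base_frac + l1;
  double A2 = A_mM * A_mM;
  double Mact = A2 / (A2 + m.Km_act * m.Km_act);
  double katt = m.k_att * lambdaOf(sarc, m) * Mact;
  double kdet = m.k_det * (1.0 + m.det_v * fabs(v1) / m.v_max);
  return katt * (1.0 - Nxb) - kdet * Nxb;
}

// ---------------------------------------------------------------------------
// Fibroblast
struct FbCurrents { double iKv, iK1, iNaK, ibNa, total; };

static void fbCurrents(double Vf, double rkv, double skv, const FbParams& f,
                       FbCurrents& c) {
  const double rtf = RGAS * TEMP / FRDY;
  const double Ko = 5.4, Nao = 140.0;
  double EK = rtf * log(Ko / f.Kif);
  double ENa = rtf * log(Nao / f.Naif);
  double aK1 = 0.1 / (1.0 + exp(0.06 * (Vf - EK - 200.0)));
  double bK1 = (3.0 * exp(0.0002 * (Vf - EK + 100.0)) + exp(0.1 * (Vf - EK - 10.0))) /
               (1.0 + exp(-0.5 * (Vf - EK)));
  c.iKv  = f.GKv * rkv * skv * (Vf - EK) * f.Cmf;          // pA
  c.iK1  = f.GK1f * aK1 / (aK1 + bK1) * (Vf - EK) * f.Cmf;
  c.iNaK = f.INaKmax * (Ko / (Ko + f.KmKf)) *
           (pow(f.Naif, 1.5) / (pow(f.Naif, 1.5) + pow(f.KmNaf, 1.5))) *
           (Vf + 150.0) / (Vf + 200.0) * f.Cmf;
  c.ibNa = f.GbNaf * (Vf - ENa) * f.Cmf;
  c.total = c.iKv + c.iK1 + c.iNaK + c.ibNa;
}

static void fbGateTables(double Vf, double* inf, double* tau) {
  inf[0] = 1.0 / (1.0 + exp(-(Vf + 20.0) / 11.0));
  tau[0] = 20.3 + 138.0 * exp(-pow((Vf + 20.0) / 25.9, 2));
  inf[1] = 1.0 / (1.0 + exp((Vf + 23.0) / 7.0));
  tau[1] = 1574.0 + 5268.0 * exp(-pow((Vf + 23.0) / 22.7, 2));
}

static double vrevOf(double len_frac, const FbParams& f) {
  double t = (len_frac - f.len_lo) / (f.len_hi - f.len_lo);
  double v_at_lo = f.vrev_neg_at_long ? f.vrev_hi : f.vrev_lo;
  double v_at_hi = f.vrev_neg_at_long ? f.vrev_lo : f.vrev_hi;
  double v = v_at_lo + t * (v_at_hi - v_at_lo);
  return v / f.x_vrev;
}

static double mscCurrent(double len_frac, double dl, double Vf, const FbParams& f) {
  double a = 1.0 + f.a_slope * dl;
  if (a < 0.0) a = 0.0;
  return f.x_gmax * f.g_max * a * (Vf - vrevOf(len_frac, f));  // pA
}

// ---------------------------------------------------------------------------
// Exported granular functions

// [[Rcpp::export]]
List cpp_myo_currents(NumericVector state, List pars) {
  MyoParams p = parseMyo(pars);
  std::vector<double> s(state.begin(), state.end());
  Currents c;
  myoCurrents(s.data(), p, c);
  return List::create(
    _["i_Na"] = c.INa, _["i_bNa"] = c.IbNa, _["i_CaL"] = c.ICaL,
    _["i_bCa"] = c.IbCa, _["i_to"] = c.Ito, _["i_Kr"] = c.IKr,
    _["i_Ks"] = c.IKs, _["i_K1"] = c.IK1, _["i_pK"] = c.IpK,
    _["i_pCa"] = c.IpCa, _["i_NaK"] = c.INaK, _["i_NaCa"] = c.INaCa,
    _["i_myo_total"] = c.total,
    _["I_rel"] = c.Irel, _["I_up"] = c.Iup, _["I_leak"] = c.Ileak,
    _["I_xfer"] = c.Ixfer);
}

// [[Rcpp::export]]
NumericMatrix cpp_gate_tables(double V, double cass) {
  double inf[12], tau[12];
  gateTables(V, cass, inf, tau);
  NumericMatrix out(2, 12);
  CharacterVector nm = CharacterVector::create(
    "m","h","j","xr1","xr2","xs","r","s","d","f","f2","fcass");
  for (int k = 0; k < 12; ++k) { out(0, k) = inf[k]; out(1, k) = tau[k]; }
  colnames(out) = nm;
  rownames(out) = CharacterVector::create("inf", "tau");
  return out;
}

// [[Rcpp::export]]
List cpp_ryr(NumericVector state, List pars) {
  MyoParams p = parseMyo(pars);
  std::vector<double> s(state.begin(), state.end());
  double d4[4];
  ryrDerivs(s.data(), p, d4);
  double irel = p.Vrel * s[iRYR_O] * (s[iCASR] - s[iCASS]);
  return List::create(_["I_rel"] = irel,
                      _["d_occ"] = NumericVector::create(d4[0], d4[1], d4[2], d4[3]));
}

// [[Rcpp::export]]
List cpp_sr_fluxes(NumericVector state, List pars) {
  MyoParams p = parseMyo(pars);
  std::vector<double> s(state.begin(), state.end());
  Currents c;
  myoCurrents(s.data(), p, c);
  return List::create(_["I_up"] = c.Iup, _["I_leak"] = c.Ileak, _["I_xfer"] = c.Ixfer);
}

// [[Rcpp::export]]
double cpp_catnc_koff(double catnc_mM, double n_xb, List pars) {
  MyoParams p = parseMyo(pars);
  return catncKoff(catnc_mM, n_xb, p);
}

// [[Rcpp::export]]
double cpp_catnc_rate(double catnc_mM, double ca_i, double n_xb, List pars,
                      double koff_frozen) {
  MyoParams p = parseMyo(pars);
  double koff = (koff_frozen >= 0.0) ? koff_frozen : catncKoff(catnc_mM, n_xb, p);
  return p.a_on * ca_i * (p.Atot - catnc_mM) - koff * catnc_mM;
}

// [[Rcpp::export]]
double cpp_xb_rate(double n_xb, double catnc_mM, double l1, double v1, List mechp) {
  MechParams m = parseMech(mechp);
  return xbRate(n_xb, catnc_mM, l1, v1, m);
}

// [[Rcpp::export]]
List cpp_mech_solve(double l1, double l2, double n_xb, double L, int n, List mechp) {
  MechParams m = parseMech(mechp);
  MechSolution s = mechSolve(l1, l2, n_xb, L, n, m);
  return List::create(
    _["v1"] = s.v1, _["dl2"] = s.dl2,
    _["F_CE"] = s.F_ce, _["F_PE"] = s.F_pe, _["F_PEfb"] = s.F_pefb,
    _["F_SE"] = s.F_se, _["F_XSE"] = s.F_xse,
    _["F_VS1"] = s.F_vs1, _["F_VS2"] = s.F_vs2,
    _["residual"] = s.residual, _["iterations"] = s.iterations,
    _["ok"] = s.ok);
}

// [[Rcpp::export]]
List cpp_element_forces(double l1, double l2, double l3, double v1, double dl2,
                        double n_xb, int n, List mechp) {
  MechParams m = parseMech(mechp);
  double sarc = m.base_frac + l1;
  double fce = m.F_scale * n_xb * lambdaOf(sarc, m) * fvFactor(v1, m);
  return List::create(
    _["F_CE"] = fce,
    _["F_PE"] = fexp(m.a_pe, m.b_pe, l2),
    _["F_PEfb"] = fexp(m.a_fb, m.b_fb, l2),
    _["F_SE"] = fexp(m.a_se, m.b_se, l2 - l1),
    _["F_XSE"] = fexp(m.a_xse, m.b_xse, l3),
    _["F_VS1"] = m.nu1 * dl2,
    _["F_VS2"] = m.nu2 * (dl2 - v1),
    _["n"] = n);
}

// [[Rcpp::export]]
double cpp_fexp(double alpha, double beta, double l) { return fexp(alpha, beta, l); }

// [[Rcpp::export]]
List cpp_fb_currents(double v_cf, double r_kv, double s_kv, List fbpars) {
  FbParams f = parseFb(fbpars);
  FbCurrents c;
  fbCurrents(v_cf, r_kv, s_kv, f, c);
  return List::create(_["i_Kv"] = c.iKv, _["i_K1"] = c.iK1,
                      _["i_NaK"] = c.iNaK, _["i_bNa"] = c.ibNa,
                      _["i_cf"] = c.total);
}

// [[Rcpp::export]]
NumericMatrix cpp_fb_gate_tables(double v_cf) {
  double inf[2], tau[2];
  fbGateTables(v_cf, inf, tau);
  NumericMatrix out(2, 2);
  for (int k = 0; k < 2; ++k) { out(0, k) = inf[k]; out(1, k) = tau[k]; }
  colnames(out) = CharacterVector::create("r_kv", "s_kv");
  rownames(out) = CharacterVector::create("inf", "tau");
  return out;
}

// [[Rcpp::export]]
double cpp_msc_current(double len_frac, double dl, double v_cf, List fbpars) {
  FbParams f = parseFb(fbpars);
  return mscCurrent(len_frac, dl, v_cf, f);
}

// [[Rcpp::export]]
double cpp_vrev(double len_frac, List fbpars) {
  FbParams f = parseFb(fbpars);
  return vrevOf(len_frac, f);
}

// ---------------------------------------------------------------------------
// Full ensemble integration.
//
// mode: 0 = single, 1 = model1 (electrotonic coupling only),
//       2 = model2 (electrotonic + mechanical coupling + i_MS)

// [[Rcpp::export]]
List cpp_simulate(NumericVector init, List cfg, List myopars, List mechpars,
                  List fbpars) {
  MyoParams P = parseMyo(myopars);
  MechParams M = parseMech(mechpars);
  FbParams FB = parseFb(fbpars);

  const int mode = as<int>(cfg["mode_code"]);
  const int n = as<int>(cfg["n"]);
  const double ggap = as<double>(cfg["g_gap"]);
  const double L = as<double>(cfg["initial_length"]);
  const double duration = as<double>(cfg["duration"]);
  const double out_dt = as<double>(cfg["output_dt"]);
  const double dt = as<double>(cfg["dt"]);
  const double t0 = as<double>(cfg["t_start"]);
  const double clamp_time = as<double>(cfg["clamp_time"]); // absolute ms, <0: off
  const bool rec_cur = as<bool>(cfg["record_currents"]);

  const int n_fb_mech = (mode == 2) ? n : 0;   // fibroblast elastic load only in model 2
  const bool use_ms = (mode == 2);
  const int nst = NMYO + 3 * n;
  if (init.size() != nst) stop("state dimension mismatch: expected %d, got %d", nst, (int)init.size());

  std::vector<double> s(init.begin(), init.end());
  const double l2_init = s[iL2];

  const long nsteps = (long)llround(duration / dt);
  const long out_every = std::max(1L, (long)llround(out_dt / dt));
  const long nout = nsteps / out_every + 1;

  // trace channels
  int base_ch = 13;                  // time..koff list below
  int cur_ch = rec_cur ? 8 : 0;
  int ncols = base_ch + cur_ch + 2 * n;
  NumericMatrix trace(nout, ncols);
  CharacterVector cn(ncols);
  {
    int k = 0;
    cn[k++] = "time_ms"; cn[k++] = "V_myo_mV"; cn[k++] = "Ca_i_mM";
    cn[k++] = "Ca_sr_mM"; cn[k++] = "Ca_ss_mM"; cn[k++] = "CaTnC_uM";
    cn[k++] = "N_xb"; cn[k++] = "F_active_norm"; cn[k++] = "F_total_norm";
    cn[k++] = "sarc_frac"; cn[k++] = "branch_frac"; cn[k++] = "ryr_open";
    cn[k++] = "catnc_koff_per_ms";
    if (rec_cur) {
      cn[k++] = "i_CaL_pApF"; cn[k++] = "i_NaCa_pApF"; cn[k++] = "i_K1_pApF";
      cn[k++] = "i_Kr_pApF"; cn[k++] = "i_Ks_pApF"; cn[k++] = "I_rel_mM_ms";
      cn[k++] = "I_up_mM_ms"; cn[k++] = "i_stim_pApF";
    }
    for (int i = 0; i < n; ++i) {
      cn[k++] = "V_cf" + std::to_string(i + 1) + "_mV";
      cn[k++] = "i_MS" + std::to_string(i + 1) + "_pA";
    }
    colnames(trace) = cn;
  }

  double koff_frozen = -1.0;
  double max_residual = 0.0;
  double F_rest = NA_REAL;          // diastolic total force of this run
  bool solver_fail = false;
  double fail_t = 0.0;

  double inf[12], tau[12], finf[2], ftau[2], d4[4];
  Currents C;
  long orow = 0;

  // rest force baseline from the initial mechanical configuration
  {
    MechSolution ms0 = mechSolve(s[iL1], s[iL2], s[iNXB], L, n_fb_mech, M);
    F_rest = ms0.F_xse;
  }

  for (long step = 0; step <= nsteps; ++step) {
    double t = t0 + step * dt;

    // ---- instantaneous quantities
    myoCurrents(s.data(), P, C);
    double istim = 0.0;
    {
      double tp = t - P.stim_start;
      if (P.stim_period > 0 && tp >= 0) {
        double ph = tp - floor(tp / P.stim_period) * P.stim_period;
        if (ph < P.stim_dur) istim = P.stim_amp;
      }
    }
    MechSolution ms = mechSolve(s[iL1], s[iL2], s[iNXB], L, n_fb_mech, M);
    if (!ms.ok && !solver_fail) { solver_fail = true; fail_t = t; }
    if (fabs(ms.residual) > max_residual) max_residual = fabs(ms.residual);

    // cooperativity clamp
    if (clamp_time >= 0.0 && t >= clamp_time && koff_frozen < 0.0)
      koff_frozen = catncKoff(s[iCATNC], s[iNXB], P);
    double koff = (koff_frozen >= 0.0) ? koff_frozen : catncKoff(s[iCATNC], s[iNXB], P);
    double dA = P.a_on * s[iCAI] * (P.Atot - s[iCATNC]) - koff * s[iCATNC];

    // fibroblast currents
    double gap_sum = 0.0;          // pA/pF on myocyte
    std::vector<double> ims(n, 0.0), icf(n, 0.0);
    double lf = M.base_frac + s[iL2];             // fibroblast length fraction
    double dl = s[iL2] - l2_init;                 // deformation since run start
    for (int i = 0; i < n; ++i) {
      double* fs = s.data() + NMYO + 3 * i;
      FbCurrents fc;
      fbCurrents(fs[0], fs[1], fs[2], FB, fc);
      icf[i] = fc.total;
      if (use_ms) ims[i] = mscCurrent(lf, dl, fs[0], FB);
      gap_sum += ggap * (s[iV] - fs[0]);
    }

    // ---- record
    if (step % out_every == 0 && orow < nout) {
      int k = 0;
      trace(orow, k++) = t;
      trace(orow, k++) = s[iV];
      trace(orow, k++) = s[iCAI];
      trace(orow, k++) = s[iCASR];
      trace(orow, k++) = s[iCASS];
      trace(orow, k++) = s[iCATNC] * 1000.0;
      trace(orow, k++) = s[iNXB];
      trace(orow, k++) = (ms.F_xse - F_rest) / M.F_norm;
      trace(orow, k++) = ms.F_xse / M.F_norm;
      trace(orow, k++) = M.base_frac + s[iL1];
      trace(orow, k++) = lf;
      trace(orow, k++) = s[iRYR_O];
      trace(orow, k++) = koff;
      if (rec_cur) {
        trace(orow, k++) = C.ICaL; trace(orow, k++) = C.INaCa;
        trace(orow, k++) = C.IK1; trace(orow, k++) = C.IKr;
        trace(orow, k++) = C.IKs; trace(orow, k++) = C.Irel;
        trace(orow, k++) = C.Iup; trace(orow, k++) = istim;
      }
      for (int i = 0; i < n; ++i) {
        trace(orow, k++) = s[NMYO + 3 * i];
        trace(orow, k++) = ims[i];
      }
      ++orow;
    }
    if (step == nsteps) break;

    // ---- updates
    // membrane potential (Eq. 2 extended with gap-junction drain)
    double dV = -(C.total + istim + gap_sum / P.Cm);
    // HH gates: Rush-Larsen
    gateTables(s[iV], s[iCASS], inf, tau);
    for (int g = 0; g < 12; ++g) {
      double* gv = &s[iM + g];
      *gv = inf[g] + (*gv - inf[g]) * exp(-dt / tau[g]);
    }
    // RyR: per-state exponential update with renormalization
    {
      double ko, ki;
      ryrRates(s[iCASS], s[iCASR], P, ko, ki);
      double cass = s[iCASS];
      double R = s[iRYR_R], O = s[iRYR_O], I = s[iRYR_I], RI = s[iRYR_RI];
      double gain[4], loss[4];
      gain[0] = P.kim * RI + P.kom * O;    loss[0] = ki * cass + ko * cass * cass;
      gain[1] = ko * cass * cass * R + P.kim * I; loss[1] = P.kom + ki * cass;
      gain[2] = ki * cass * O + ko * cass * cass * RI; loss[2] = P.kim + P.kom;
      gain[3] = P.kom * I + ki * cass * R; loss[3] = ko * cass * cass + P.kim;
      double x[4] = {R, O, I, RI};
      for (int q = 0; q < 4; ++q) {
        if (loss[q] > 1e-12) {
          double xinf = gain[q] / loss[q];
          x[q] = xinf + (x[q] - xinf) * exp(-loss[q] * dt);
        } else {
          x[q] += dt * gain[q];
        }
      }
      double sum = x[0] + x[1] + x[2] + x[3];
      for (int q = 0; q < 4; ++q) s[iRYR_R + q] = x[q] / sum;
    }
    // ionic concentrations (TP06 bookkeeping; stimulus carried by K+).
    // C_myo is held in pF; flux conversions need uF to match the TP06
    // volume conventions.
    {
      double f1 = (P.Cm * 1e-3) / (P.Vc * FRDY);
      double dNai = -(C.INa + C.IbNa + 3.0 * C.INaK + 3.0 * C.INaCa) * f1;
      double dKi = -(C.IK1 + C.Ito + C.IKr + C.IKs - 2.0 * C.INaK + C.IpK + istim +
                     gap_sum / P.Cm) * f1;
      double jca = (C.Ileak - C.Iup) * P.Vsr / P.Vc + C.Ixfer -
                   (C.IbCa + C.IpCa - 2.0 * C.INaCa) * (P.Cm * 1e-3) / (2.0 * P.Vc * FRDY);
      double bfac = 1.0 / (1.0 + P.Bufc2 * P.Kbufc / pow(s[iCAI] + P.Kbufc, 2));
      double dCai = bfac * (jca - dA);
      double bsr = 1.0 / (1.0 + P.Bufsr * P.Kbufsr / pow(s[iCASR] + P.Kbufsr, 2));
      double dCasr = bsr * (C.Iup - C.Ileak - C.Irel);
      double bss = 1.0 / (1.0 + P.Bufss * P.Kbufss / pow(s[iCASS] + P.Kbufss, 2));
      double dCass = bss * (-C.Ixfer * P.Vc / P.Vss + C.Irel * P.Vsr / P.Vss -
                            C.ICaL * (P.Cm * 1e-3) / (2.0 * P.Vss * FRDY));
      s[iNAI] += dt * dNai;
      s[iKI]  += dt * dKi;
      s[iCAI] += dt * dCai;
      s[iCASR] += dt * dCasr;
      s[iCASS] += dt * dCass;
      if (s[iCAI] < 1e-9) s[iCAI] = 1e-9;
      if (s[iCASS] < 1e-9) s[iCASS] = 1e-9;
      if (s[iCASR] < 1e-9) s[iCASR] = 1e-9;
    }
    s[iV] += dt * dV;
    s[iCATNC] += dt * dA;
    if (s[iCATNC] < 0.0) s[iCATNC] = 0.0;
    if (s[iCATNC] > P.Atot) s[iCATNC] = P.Atot;
    // mechanics
    s[iL1] += dt * ms.v1;
    s[iL2] += dt * ms.dl2;
    s[iNXB] += dt * xbRate(s[iNXB], s[iCATNC], s[iL1], ms.v1, M);
    if (s[iNXB] < 0.0) s[iNXB] = 0.0;
    if (s[iNXB] > 1.0) s[iNXB] = 1.0;
    // fibroblasts
    for (int i = 0; i < n; ++i) {
      double* fs = s.data() + NMYO + 3 * i;
      double dVf = -(icf[i] + ims[i] + ggap * (fs[0] - s[iV])) / FB.Cmf;
      fbGateTables(fs[0], finf, ftau);
      fs[1] = finf[0] + (fs[1] - finf[0]) * exp(-dt / ftau[0]);
      fs[2] = finf[1] + (fs[2] - finf[1]) * exp(-dt / ftau[1]);
      fs[0] += dt * dVf;
    }
    if (!std::isfinite(s[iV]))
      stop("solver failure: non-finite membrane potential at t = %g ms", t);
  }
  (void)d4;

  NumericVector fin(s.begin(), s.end());
  return List::create(
    _["trace"] = trace,
    _["final_state"] = fin,
    _["max_residual"] = max_residual,
    _["mech_solver_failed"] = solver_fail,
    _["mech_fail_time"] = fail_t,
    _["koff_frozen"] = koff_frozen,
    _["f_rest"] = F_rest);
}
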