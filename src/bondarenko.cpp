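// Bondarenko et al. (2004) mouse ventricular ionic model (apex variant),
// explicit-Euler stepper vectorized over cells.
//
// Units: mV, ms, uM; currents per-capacitance (pA/pF), so dV/dt = -I_ion +
// I_stim is in mV/ms with C_m normalized to 1 uF/cm^2. The Markov chains
// (fast Na+, L-type Ca2+, RyR, rapid delayed rectifier) are integrated with
// every chain state explicit, so each chain conserves total occupancy to
// rounding error. Voltage-dependent rates are tabulated once on a fixed
// voltage grid and linearly interpolated; concentration-dependent terms are
// evaluated exactly.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace bdk {

// physical constants and cell geometry
const double F = 96.5;          // C/mmol
const double RT_F = 8.314 * 298.0 / 96.5; // mV
const double Acap = 1.534e-4;   // cm^2
const double Vmyo = 25.84e-6;   // uL
const double Vss  = 1.485e-9;   // uL
const double VJSR = 0.12e-6;    // uL
const double VNSR = 2.098e-6;   // uL
const double Ko  = 5400.0;      // uM
const double Nao = 140000.0;    // uM
const double Cao = 1800.0;      // uM
// Acap*Cm/(V*F) charge-to-concentration factors (Cm = 1 uF/cm^2)
const double fmyo = Acap * 1.0 / (Vmyo * F);
const double fss  = Acap * 1.0 / (Vss  * F);

// maximal conductances / fluxes (apex)
const double GNa = 13.0, GNab = 0.0026;
const double GCaL = 0.1729, ECaL = 63.0, ICaLmax = 7.0;
const double GKtof = 0.4067, GKtos = 0.0;
const double GKs = 0.00575, GKur = 0.16, GKss = 0.05, GKr = 0.078;
const double GClCa = 10.0, ECl = -40.0, KmCl = 10.0;
const double GK1 = 0.55;
const double INaKmax = 0.88, KmNai = 21000.0, KmKo = 1500.0;
const double kNaCa = 292.8, KmNa = 87500.0, KmCa = 1380.0,
             ksat = 0.1, eta_ncx = 0.35;
const double IpCamax = 1.0, KmpCa = 0.5;
// SR / buffers
const double v1 = 4.5, v2 = 1.74e-5, v3 = 0.45, Kmup = 0.5;
const double tau_tr = 20.0, tau_xfer = 8.0;
const double CMDNtot = 50.0, KmCMDN = 0.238;
const double CSQNtot = 15000.0, KmCSQN = 800.0;
const double LTRPNtot = 70.0, HTRPNtot = 140.0;
const double kp_htrpn = 0.00237, km_htrpn = 3.2e-5;
const double kp_ltrpn = 0.0327, km_ltrpn = 0.0196;
// RyR
const double ka_p = 0.006075, ka_m = 0.07125;
const double kb_p = 0.00405, kb_m = 0.965;
const double kc_p = 0.009, kc_m = 0.0008;
// L-type Ca Markov
const double Kpcmax = 0.23324, Kpchalf = 20.0, Kpcb = 0.0005;

// state indices within eta
enum {
  iCai, iCass, iCaJSR, iCaNSR, iLTRPN, iHTRPN,
  iPRyR, iPC1, iPO1, iPO2, iPC2,
  iC1, iC2, iC3, iC4, iO, iI1, iI2, iI3,
  iCNa3, iCNa2, iCNa1, iONa, iIFNa, iI1Na, iI2Na, iICNa2, iICNa3,
  iCK0, iCK1, iCK2, iOK, iIK,
  iatof, iitof, iatos, iitos, inKs, iaur, iiur, iaKss, iiKss,
  iNai, iKi, N_STATES
};

const char *state_names[N_STATES] = {
  "Cai", "Cass", "CaJSR", "CaNSR", "LTRPN_Ca", "HTRPN_Ca",
  "P_RyR", "P_C1", "P_O1", "P_O2", "P_C2",
  "C1", "C2", "C3", "C4", "O", "I1", "I2", "I3",
  "C_Na3", "C_Na2", "C_Na1", "O_Na", "IF_Na", "I1_Na", "I2_Na",
  "IC_Na2", "IC_Na3",
  "C_K0", "C_K1", "C_K2", "O_K", "I_K",
  "a_to_f", "i_to_f", "a_to_s", "i_to_s", "n_Ks", "a_ur", "i_ur",
  "a_Kss", "i_Kss", "Nai", "Ki"
};

// tabulated voltage-dependent rates
enum {
  rA11, rA12, rA13, rB11, rB12, rB13, rANA3, rBNA3, rANA2, rBNA2,
  rLCCA, rLCCB, rKPCF,
  rKRA0, rKRB0, rKRA1, rKRB1, rKRAI, rKRBI,
  rATOFA, rATOFB, rITOFA, rITOFB,
  rASS, rISS, rTAUR_I, rTIUR_I, rTITOS_I, rTAKSS_I,
  rNKSA, rNKSB,
  rNCX1, rNCX2, rFNAK1, rFNAK2, rOCLCA, rPRYRG,
  N_RATES
};

const double VMIN = -150.0, VMAX = 100.0, DV = 0.05;
const int NV = (int)((VMAX - VMIN) / DV) + 2;

static std::vector<double> TAB; // [rate * NV + k]

static void fill_tables() {
  TAB.assign((size_t)N_RATES * NV, 0.0);
  for (int k = 0; k < NV; ++k) {
    double V = VMIN + k * DV;
    double *t = &TAB[0];
#define SET(r, v) t[(size_t)(r) * NV + k] = (v)
    // fast Na+ Markov rates
    SET(rA11, 3.802 / (0.1027 * exp(-(V + 2.5) / 17.0)
                       + 0.20 * exp(-(V + 2.5) / 150.0)));
    SET(rA12, 3.802 / (0.1027 * exp(-(V + 2.5) / 15.0)
                       + 0.23 * exp(-(V + 2.5) / 150.0)));
    SET(rA13, 3.802 / (0.1027 * exp(-(V + 2.5) / 12.0)
                       + 0.25 * exp(-(V + 2.5) / 150.0)));
    SET(rB11, 0.1917 * exp(-(V + 2.5) / 20.3));
    SET(rB12, 0.20 * exp(-(V - 2.5) / 20.3));
    SET(rB13, 0.22 * exp(-(V - 7.5) / 20.3));
    double aNa3 = 2.0e-7 * exp(-(V + 7.0) / 7.7);
    double bNa3 = 0.0084 + 0.00002 * (V + 7.0);
    double aNa2 = 9.178 * exp(V / 29.68);
    double a13 = t[(size_t)rA13 * NV + k], b13 = t[(size_t)rB13 * NV + k];
    SET(rANA3, aNa3);
    SET(rBNA3, bNa3);
    SET(rANA2, aNa2);
    SET(rBNA2, a13 * aNa2 * aNa3 / (b13 * bNa3));
    // L-type Ca2+ Markov
    double a = 0.4 * exp((V + 12.0) / 10.0);
    double acorr = a * (1.0 + 0.7 * exp(-(V + 40.0) * (V + 40.0) / 10.0)
                        - 0.75 * exp(-(V + 20.0) * (V + 20.0) / 400.0))
                   / (1.0 + 0.12 * exp((V + 12.0) / 10.0));
    SET(rLCCA, acorr);
    SET(rLCCB, 0.05 * exp(-(V + 12.0) / 13.0));
    SET(rKPCF, 13.0 * (1.0 - exp(-(V + 14.5) * (V + 14.5) / 100.0)));
    // rapid delayed rectifier Markov
    SET(rKRA0, 0.022348 * exp(0.01176 * V));
    SET(rKRB0, 0.047002 * exp(-0.0631 * V));
    SET(rKRA1, 0.013733 * exp(0.038198 * V));
    SET(rKRB1, 0.0000689 * exp(-0.04178 * V));
    SET(rKRAI, 0.090821 * exp(0.023391 * (V + 5.0)));
    SET(rKRBI, 0.006497 * exp(-0.03268 * (V + 5.0)));
    // transient outward, fast (HH gates)
    SET(rATOFA, 0.18064 * exp(0.03577 * (V + 30.0)));
    SET(rATOFB, 0.3956 * exp(-0.06237 * (V + 30.0)));
    SET(rITOFA, 0.000152 * exp(-(V + 13.5) / 7.0)
                / (0.0067083 * exp(-(V + 33.5) / 7.0) + 1.0));
    SET(rITOFB, 0.00095 * exp((V + 33.5) / 7.0)
                / (0.051335 * exp((V + 33.5) / 7.0) + 1.0));
    // shared steady states and time constants
    SET(rASS, 1.0 / (1.0 + exp(-(V + 22.5) / 7.7)));
    SET(rISS, 1.0 / (1.0 + exp((V + 45.2) / 5.7)));
    SET(rTAUR_I, 1.0 / (0.493 * exp(-0.0629 * V) + 2.058));
    SET(rTIUR_I, 1.0 / (1200.0 - 170.0 / (1.0 + exp((V + 45.2) / 5.7))));
    SET(rTITOS_I, 1.0 / (270.0 + 1050.0 / (1.0 + exp((V + 45.2) / 5.7))));
    SET(rTAKSS_I, 1.0 / (39.3 * exp(-0.0862 * V) + 13.17));
    // slow delayed rectifier gate
    double dn = V + 26.5;
    double an = (fabs(dn) < 1e-6) ? 4.81333e-6 / 0.128
                                  : 4.81333e-6 * dn / (1.0 - exp(-0.128 * dn));
    SET(rNKSA, an);
    SET(rNKSB, 9.53333e-5 * exp(-0.038 * dn));
    // electrogenic pump/exchanger voltage factors
    SET(rNCX1, exp(eta_ncx * V / RT_F));
    SET(rNCX2, exp((eta_ncx - 1.0) * V / RT_F));
    SET(rFNAK1, exp(-0.1 * V / RT_F));
    SET(rFNAK2, exp(-V / RT_F));
    SET(rOCLCA, 0.2 / (1.0 + exp(-(V - 46.7) / 7.8)));
    SET(rPRYRG, exp(-(V - 5.0) * (V - 5.0) / 648.0));
#undef SET
  }
}

struct Rates {
  double r[N_RATES];
};

static inline void lookup(double V, Rates &out) {
  if (V < VMIN) V = VMIN;
  if (V > VMAX - DV) V = VMAX - DV;
  double u = (V - VMIN) / DV;
  int k = (int)u;
  double w = u - k;
  const double *t = &TAB[0];
  for (int r = 0; r < N_RATES; ++r) {
    const double *row = t + (size_t)r * NV + k;
    out.r[r] = row[0] + w * (row[1] - row[0]);
  }
}

// one explicit-Euler substep for one cell; returns dV/dt actually applied
static inline double step_cell(double &V, double *y, double stim, double dt) {
  Rates R;
  lookup(V, R);

  double Cai = y[iCai], Cass = y[iCass];
  double Nai = y[iNai], Ki = y[iKi];

  // reversal potentials
  double EK = RT_F * log(Ko / Ki);
  double ENa = RT_F * log((0.9 * Nao + 0.1 * Ko) / (0.9 * Nai + 0.1 * Ki));
  double ECaN = 0.5 * RT_F * log(Cao / Cai);
  double EKr = RT_F * log((0.98 * Ko + 0.02 * Nao) / (0.98 * Ki + 0.02 * Nai));

  // membrane currents (pA/pF)
  double INa = GNa * y[iONa] * (V - ENa);
  double INab = GNab * (V - ENa);
  double ICaL = GCaL * y[iO] * (V - ECaL);
  double IpCa = IpCamax * Cai * Cai / (KmpCa * KmpCa + Cai * Cai);
  double ICab = 0.000367 * (V - ECaN);
  double ncx_den = (KmNa * KmNa * KmNa + Nao * Nao * Nao) * (KmCa + Cao)
                   * (1.0 + ksat * R.r[rNCX2]);
  double INaCa = kNaCa / ncx_den
                 * (R.r[rNCX1] * Nai * Nai * Nai * Cao
                    - R.r[rNCX2] * Nao * Nao * Nao * Cai);
  double sigma_nak = (exp(Nao / 67300.0) - 1.0) / 7.0;
  double fNaK = 1.0 / (1.0 + 0.1245 * R.r[rFNAK1]
                       + 0.0365 * sigma_nak * R.r[rFNAK2]);
  double INaK = INaKmax * fNaK * (Ko / (Ko + KmKo))
                / (1.0 + pow(KmNai / Nai, 1.5));
  double Itof = GKtof * y[iatof] * y[iatof] * y[iatof] * y[iitof] * (V - EK);
  double Itos = GKtos * y[iatos] * y[iitos] * (V - EK);
  double IK1 = GK1 * (Ko / (Ko + 210.0)) * (V - EK)
               / (1.0 + exp(0.0896 * (V - EK)));
  double IKs = GKs * y[inKs] * y[inKs] * (V - EK);
  double IKur = GKur * y[iaur] * y[iiur] * (V - EK);
  double IKss = GKss * y[iaKss] * y[iiKss] * (V - EK);
  double IKr = GKr * y[iOK] * (V - EKr);
  double IClCa = GClCa * R.r[rOCLCA] * (Cai / (Cai + KmCl)) * (V - ECl);

  double Iion = INa + INab + ICaL + IpCa + ICab + INaCa + INaK
                + Itof + Itos + IK1 + IKs + IKur + IKss + IKr + IClCa;
  double dV = -Iion + stim;

  // Ca2+ fluxes (uM/ms)
  double Jrel = v1 * (y[iPO1] + y[iPO2]) * (y[iCaJSR] - Cass) * y[iPRyR];
  double Jtr = (y[iCaNSR] - y[iCaJSR]) / tau_tr;
  double Jxfer = (Cass - Cai) / tau_xfer;
  double Jleak = v2 * (y[iCaNSR] - Cai);
  double Jup = v3 * Cai * Cai / (Kmup * Kmup + Cai * Cai);
  double Jtrpn = kp_htrpn * Cai * (HTRPNtot - y[iHTRPN])
                 - km_htrpn * y[iHTRPN]
                 + kp_ltrpn * Cai * (LTRPNtot - y[iLTRPN])
                 - km_ltrpn * y[iLTRPN];
  double Bi = 1.0 / (1.0 + CMDNtot * KmCMDN
                     / ((KmCMDN + Cai) * (KmCMDN + Cai)));
  double Bss = 1.0 / (1.0 + CMDNtot * KmCMDN
                      / ((KmCMDN + Cass) * (KmCMDN + Cass)));
  double BJSR = 1.0 / (1.0 + CSQNtot * KmCSQN
                       / ((KmCSQN + y[iCaJSR]) * (KmCSQN + y[iCaJSR])));

  double dCai = Bi * (Jleak + Jxfer - Jup - Jtrpn
                      - 0.5 * fmyo * (ICab - 2.0 * INaCa + IpCa));
  double dCass = Bss * (Jrel * VJSR / Vss - Jxfer * Vmyo / Vss
                        - 0.5 * fss * ICaL);
  double dCaJSR = BJSR * (Jtr - Jrel);
  double dCaNSR = (Jup - Jleak) * Vmyo / VNSR - Jtr * VJSR / VNSR;
  double dLTRPN = kp_ltrpn * Cai * (LTRPNtot - y[iLTRPN])
                  - km_ltrpn * y[iLTRPN];
  double dHTRPN = kp_htrpn * Cai * (HTRPNtot - y[iHTRPN])
                  - km_htrpn * y[iHTRPN];
  double dPRyR = -0.04 * y[iPRyR]
                 - 0.1 * (ICaL / ICaLmax) * R.r[rPRYRG];

  // RyR Markov (PC1 <-> PO1 <-> PO2, PO1 <-> PC2)
  double Cass2 = Cass * Cass;
  double Cass3 = Cass2 * Cass, Cass4 = Cass2 * Cass2;
  double fo1 = ka_p * Cass4 * y[iPC1] - ka_m * y[iPO1];
  double fo2 = kb_p * Cass3 * y[iPO1] - kb_m * y[iPO2];
  double fc2 = kc_p * y[iPO1] - kc_m * y[iPC2];
  double dPC1 = -fo1;
  double dPO1 = fo1 - fo2 - fc2;
  double dPO2 = fo2;
  double dPC2 = fc2;

  // L-type Ca2+ Markov
  double al = R.r[rLCCA], bl = R.r[rLCCB];
  double gam = Kpcmax * Cass / (Kpchalf + Cass);
  double kpcf = R.r[rKPCF];
  double f12 = 4.0 * al * y[iC1] - bl * y[iC2];
  double f23 = 3.0 * al * y[iC2] - 2.0 * bl * y[iC3];
  double f34 = 2.0 * al * y[iC3] - 3.0 * bl * y[iC4];
  double f4o = al * y[iC4] - 4.0 * bl * y[iO];
  double foi1 = gam * y[iO] - Kpcb * y[iI1];
  double foi2 = kpcf * y[iO] - Kpcb * y[iI2];
  double fi13 = kpcf * y[iI1] - Kpcb * y[iI3];
  double fi23 = gam * y[iI2] - Kpcb * y[iI3];
  double dC1 = -f12;
  double dC2 = f12 - f23;
  double dC3 = f23 - f34;
  double dC4 = f34 - f4o;
  double dO = f4o - foi1 - foi2;
  double dI1 = foi1 - fi13;
  double dI2 = foi2 - fi23;
  double dI3 = fi13 + fi23;

  // fast Na+ Markov
  double a11 = R.r[rA11], a12 = R.r[rA12], a13 = R.r[rA13];
  double b11 = R.r[rB11], b12 = R.r[rB12], b13 = R.r[rB13];
  double a2 = R.r[rANA2], b2 = R.r[rBNA2];
  double a3 = R.r[rANA3], b3 = R.r[rBNA3];
  double a4 = a2 / 100.0, b4 = a3;
  double a5 = a2 / 95000.0, b5 = a3 / 50.0;
  double g32 = a11 * y[iCNa3] - b11 * y[iCNa2];
  double g21 = a12 * y[iCNa2] - b12 * y[iCNa1];
  double g1o = a13 * y[iCNa1] - b13 * y[iONa];
  double gof = a2 * y[iONa] - b2 * y[iIFNa];
  double gf1 = a4 * y[iIFNa] - b4 * y[iI1Na];
  double g12i = a5 * y[iI1Na] - b5 * y[iI2Na];
  double gfc1 = b3 * y[iIFNa] - a3 * y[iCNa1];    // IF -> CNa1 recovery
  double gic2 = b3 * y[iICNa2] - a3 * y[iCNa2];   // ICNa2 -> CNa2
  double gic3 = b3 * y[iICNa3] - a3 * y[iCNa3];   // ICNa3 -> CNa3
  double gi32 = a11 * y[iICNa3] - b11 * y[iICNa2];
  double gi21 = a12 * y[iICNa2] - b12 * y[iIFNa];
  double dCNa3 = -g32 + gic3;
  double dCNa2 = g32 - g21 + gic2;
  double dCNa1 = g21 - g1o + gfc1;
  double dONa = g1o - gof;
  double dIFNa = gof - gf1 - gfc1 + gi21;
  double dI1Na = gf1 - g12i;
  double dI2Na = g12i;
  double dICNa2 = gi32 - gi21 - gic2;
  double dICNa3 = -gi32 - gic3;

  // rapid delayed rectifier Markov
  double h01 = R.r[rKRA0] * y[iCK0] - R.r[rKRB0] * y[iCK1];
  double h12 = 0.023761 * y[iCK1] - 0.036778 * y[iCK2];
  double h2o = R.r[rKRA1] * y[iCK2] - R.r[rKRB1] * y[iOK];
  double hoi = R.r[rKRAI] * y[iOK] - R.r[rKRBI] * y[iIK];
  double dCK0 = -h01;
  double dCK1 = h01 - h12;
  double dCK2 = h12 - h2o;
  double dOK = h2o - hoi;
  double dIK = hoi;

  // HH gates
  double datof = R.r[rATOFA] * (1.0 - y[iatof]) - R.r[rATOFB] * y[iatof];
  double ditof = R.r[rITOFA] * (1.0 - y[iitof]) - R.r[rITOFB] * y[iitof];
  double datos = (R.r[rASS] - y[iatos]) * R.r[rTAUR_I];
  double ditos = (R.r[rISS] - y[iitos]) * R.r[rTITOS_I];
  double dnKs = R.r[rNKSA] * (1.0 - y[inKs]) - R.r[rNKSB] * y[inKs];
  double daur = (R.r[rASS] - y[iaur]) * R.r[rTAUR_I];
  double diur = (R.r[rISS] - y[iiur]) * R.r[rTIUR_I];
  double daKss = (R.r[rASS] - y[iaKss]) * R.r[rTAKSS_I];

  // ion concentrations
  double dNai = -(INa + INab + 3.0 * INaCa + 3.0 * INaK) * fmyo;
  double dKi = -(Itof + Itos + IK1 + IKs + IKss + IKur + IKr
                 - 2.0 * INaK) * fmyo;

  // Euler update
  V += dt * dV;
  y[iCai] += dt * dCai;      y[iCass] += dt * dCass;
  y[iCaJSR] += dt * dCaJSR;  y[iCaNSR] += dt * dCaNSR;
  y[iLTRPN] += dt * dLTRPN;  y[iHTRPN] += dt * dHTRPN;
  y[iPRyR] += dt * dPRyR;
  y[iPC1] += dt * dPC1; y[iPO1] += dt * dPO1;
  y[iPO2] += dt * dPO2; y[iPC2] += dt * dPC2;
  y[iC1] += dt * dC1; y[iC2] += dt * dC2; y[iC3] += dt * dC3;
  y[iC4] += dt * dC4; y[iO] += dt * dO;
  y[iI1] += dt * dI1; y[iI2] += dt * dI2; y[iI3] += dt * dI3;
  y[iCNa3] += dt * dCNa3; y[iCNa2] += dt * dCNa2; y[iCNa1] += dt * dCNa1;
  y[iONa] += dt * dONa; y[iIFNa] += dt * dIFNa;
  y[iI1Na] += dt * dI1Na; y[iI2Na] += dt * dI2Na;
  y[iICNa2] += dt * dICNa2; y[iICNa3] += dt * dICNa3;
  y[iCK0] += dt * dCK0; y[iCK1] += dt * dCK1; y[iCK2] += dt * dCK2;
  y[iOK] += dt * dOK; y[iIK] += dt * dIK;
  y[iatof] += dt * datof; y[iitof] += dt * ditof;
  y[iatos] += dt * datos; y[iitos] += dt * ditos;
  y[inKs] += dt * dnKs;
  y[iaur] += dt * daur; y[iiur] += dt * diur;
  y[iaKss] += dt * daKss; // iKss constant
  y[iNai] += dt * dNai; y[iKi] += dt * dKi;

  return dV;
}

} // namespace bdk

// Individual membrane currents at (V, eta), for regression tests and
// diagnostics. Returns the 15 currents in pA/pF.
// [[Rcpp::export(name = ".bdk_currents")]]
NumericVector bdk_currents(double V, NumericVector eta) {
  using namespace bdk;
  if (TAB.empty()) fill_tables();
  if (eta.size() != N_STATES) stop("eta must have %d entries", N_STATES);
  const double *y = REAL(eta);
  Rates R;
  lookup(V, R);
  double Cai = y[iCai], Nai = y[iNai], Ki = y[iKi];
  double EK = RT_F * log(Ko / Ki);
  double ENa = RT_F * log((0.9 * Nao + 0.1 * Ko) / (0.9 * Nai + 0.1 * Ki));
  double ECaN = 0.5 * RT_F * log(Cao / Cai);
  double EKr = RT_F * log((0.98 * Ko + 0.02 * Nao) / (0.98 * Ki + 0.02 * Nai));
  double ncx_den = (KmNa * KmNa * KmNa + Nao * Nao * Nao) * (KmCa + Cao)
                   * (1.0 + ksat * R.r[rNCX2]);
  double sigma_nak = (exp(Nao / 67300.0) - 1.0) / 7.0;
  double fNaK = 1.0 / (1.0 + 0.1245 * R.r[rFNAK1]
                       + 0.0365 * sigma_nak * R.r[rFNAK2]);
  NumericVector out = NumericVector::create(
    _["INa"] = GNa * y[iONa] * (V - ENa),
    _["INab"] = GNab * (V - ENa),
    _["ICaL"] = GCaL * y[iO] * (V - ECaL),
    _["IpCa"] = IpCamax * Cai * Cai / (KmpCa * KmpCa + Cai * Cai),
    _["ICab"] = 0.000367 * (V - ECaN),
    _["INaCa"] = kNaCa / ncx_den * (R.r[rNCX1] * Nai * Nai * Nai * Cao
                                    - R.r[rNCX2] * Nao * Nao * Nao * Cai),
    _["INaK"] = INaKmax * fNaK * (Ko / (Ko + KmKo))
                / (1.0 + pow(KmNai / Nai, 1.5)),
    _["Itof"] = GKtof * y[iatof] * y[iatof] * y[iatof] * y[iitof] * (V - EK),
    _["Itos"] = GKtos * y[iatos] * y[iitos] * (V - EK),
    _["IK1"] = GK1 * (Ko / (Ko + 210.0)) * (V - EK)
               / (1.0 + exp(0.0896 * (V - EK))),
    _["IKs"] = GKs * y[inKs] * y[inKs] * (V - EK),
    _["IKur"] = GKur * y[iaur] * y[iiur] * (V - EK),
    _["IKss"] = GKss * y[iaKss] * y[iiKss] * (V - EK),
    _["IKr"] = GKr * y[iOK] * (V - EKr),
    _["IClCa"] = GClCa * R.r[rOCLCA] * (Cai / (Cai + KmCl)) * (V - ECl));
  return out;
}

// [[Rcpp::export(name = ".bdk_n_states")]]
int bdk_n_states() { return bdk::N_STATES; }

// [[Rcpp::export(name = ".bdk_state_names")]]
CharacterVector bdk_state_names() {
  CharacterVector out(bdk::N_STATES);
  for (int i = 0; i < bdk::N_STATES; ++i) out[i] = bdk::state_names[i];
  return out;
}

// N_sub explicit-Euler substeps of dt for every cell; V (length n) and eta
// (N_STATES x n) are modified in place. stim is per-cell, pA/pF.
// [[Rcpp::export(name = ".bdk_step")]]
void bdk_step(NumericVector V, NumericMatrix eta, NumericVector stim,
              int n_sub, double dt) {
  if (bdk::TAB.empty()) bdk::fill_tables();
  int n = V.size();
  if (eta.nrow() != bdk::N_STATES || eta.ncol() != n)
    stop("eta must be %d x length(V)", bdk::N_STATES);
  double *v = REAL(V), *y = REAL(eta), *st = REAL(stim);
  for (int c = 0; c < n; ++c) {
    double *yc = y + (size_t)c * bdk::N_STATES;
    for (int s = 0; s < n_sub; ++s)
      bdk::step_cell(v[c], yc, st[c], dt);
  }
  // NaN guard: name the first offending variable
  for (int c = 0; c < n; ++c) {
    if (!std::isfinite(v[c]))
      stop("non-finite state after reaction step: V in cell %d", c + 1);
    const double *yc = y + (size_t)c * bdk::N_STATES;
    for (int s = 0; s < bdk::N_STATES; ++s)
      if (!std::isfinite(yc[s]))
        stop("non-finite state after reaction step: %s in cell %d",
             bdk::state_names[s], c + 1);
  }
}
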