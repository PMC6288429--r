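/* Human ventricular endocardial myocyte (O'Hara-Rudy 2011 formulation)
 * extended with T-tubular microdomain remodeling:
 *   - six LTCC subpopulations (A-F) weighted by location (T-tubular vs
 *     surface sarcolemma) and PKA phosphorylation state;
 *   - a sub-sarcolemmal Ca compartment (casl) sensed by surface LTCCs,
 *     redistributed NCX, and surface CaMK-phosphorylated LTCCs;
 *   - NCX redistribution and RyR orphaning proportional to T-tubule loss;
 *   - binary PKA phosphorylation populations for RyR, PLB/SERCA, IKs, INa,
 *     INaK, IKb and TnI.
 *
 * The same right-hand side serves the deSolve compiled interface
 * (ord_initmod/ord_derivs) and a direct .C entry point (c_ord_rhs).
 */

#include <R.h>
#include <math.h>

#define N_STATE 44
#define N_PARM  55
#define N_AUX   26

/* ---- state indices ---- */
enum {
  S_V = 0, S_NAI, S_NASS, S_KI, S_KSS, S_CAI, S_CASS, S_CANSR, S_CAJSR,
  S_M, S_HF, S_HS, S_J, S_HSP, S_JP, S_ML, S_HL, S_HLP,
  S_A, S_IF, S_IS, S_AP, S_IFP, S_ISP,
  S_D, S_FF, S_FS, S_FCAF, S_FCAS, S_JCA, S_NCA, S_FFP, S_FCAFP,
  S_XRF, S_XRS, S_XS1, S_XS2, S_XK1,
  S_JRELNP, S_JRELP, S_CAMKT,
  S_CASL, S_NCASL, S_JRELORPH
};

/* ---- parameter indices (keep in sync with ord_parameter_names() in R) ---- */
enum {
  P_ISTIM = 0, P_CLAMP,
  P_WA, P_WB, P_WC, P_WD, P_WE, P_WF,
  P_PA, P_PB, P_PC, P_PD, P_PE, P_PF,
  P_CAMK_SL, P_TT_CAMK_DYN,
  P_PK_RYR, P_PK_PLB, P_PK_IKS, P_PK_INA, P_PK_INAK, P_PK_IKB, P_PK_TNI,
  P_EFF_LTCC, P_EFF_RYR, P_EFF_PLB, P_EFF_IKS, P_EFF_INA, P_EFF_INAK,
  P_EFF_IKB, P_EFF_TNI,
  P_FTT,
  P_ORPH_AMP, P_ORPH_KM,
  P_VSL_FRAC, P_TAU_SL, P_SL_CDI,
  P_GNA, P_GNAL, P_GTO, P_PCA, P_GKR, P_GKS, P_GK1, P_GNCX, P_PNAK,
  P_GKB, P_PNAB, P_PCAB, P_GPCA, P_JRELSC, P_JUPSC,
  P_NAO, P_CAO, P_KO
};

/* physical constants */
static const double Rgas = 8314.0, Temp = 310.0, Frdy = 96485.0;

/* x / (exp(x) - 1), stable near x = 0 */
static double expg(double x)
{
  if (fabs(x) < 1e-5) return 1.0 / (1.0 + 0.5 * x + x * x / 6.0);
  return x / expm1(x);
}

/* O'Hara-Rudy allosteric NCX flux for a generic (na, ca) compartment.
 * Returns the current density contribution for a unit Gncx fraction. */
static double ncx_current(double v, double na, double ca,
                          double nao, double cao)
{
  const double kna1 = 15.0, kna2 = 5.0, kna3 = 88.12, kasymm = 12.5;
  const double wna = 6.0e4, wca = 6.0e4, wnaca = 5.0e3;
  const double kcaon = 1.5e6, kcaoff = 5.0e3;
  const double qna = 0.5224, qca = 0.1670;
  const double zna = 1.0, zca = 2.0;
  double vfrt = v * Frdy / (Rgas * Temp);
  double hca = exp(qca * vfrt), hna = exp(qna * vfrt);
  double h1 = 1.0 + na / kna3 * (1.0 + hna);
  double h2 = (na * hna) / (kna3 * h1);
  double h3 = 1.0 / h1;
  double h4 = 1.0 + na / kna1 * (1.0 + na / kna2);
  double h5 = na * na / (h4 * kna1 * kna2);
  double h6 = 1.0 / h4;
  double h7 = 1.0 + nao / kna3 * (1.0 + 1.0 / hna);
  double h8 = nao / (kna3 * hna * h7);
  double h9 = 1.0 / h7;
  double h10 = kasymm + 1.0 + nao / kna1 * (1.0 + nao / kna2);
  double h11 = nao * nao / (h10 * kna1 * kna2);
  double h12 = 1.0 / h10;
  double k1 = h12 * cao * kcaon;
  double k2 = kcaoff;
  double k3p = h9 * wca, k3pp = h8 * wnaca, k3 = k3p + k3pp;
  double k4p = h3 * wca / hca, k4pp = h2 * wnaca, k4 = k4p + k4pp;
  double k5 = kcaoff;
  double k6 = h6 * ca * kcaon;
  double k7 = h5 * h2 * wna;
  double k8 = h8 * h11 * wna;
  double x1 = k2 * k4 * (k7 + k6) + k5 * k7 * (k2 + k3);
  double x2 = k1 * k7 * (k4 + k5) + k4 * k6 * (k1 + k8);
  double x3 = k1 * k3 * (k7 + k6) + k8 * k6 * (k2 + k3);
  double x4 = k2 * k8 * (k4 + k5) + k3 * k5 * (k1 + k8);
  double E1 = x1 / (x1 + x2 + x3 + x4);
  double E2 = x2 / (x1 + x2 + x3 + x4);
  double E3 = x3 / (x1 + x2 + x3 + x4);
  double E4 = x4 / (x1 + x2 + x3 + x4);
  double KmCaAct = 150.0e-6;
  double allo = 1.0 / (1.0 + (KmCaAct / ca) * (KmCaAct / ca));
  double JncxNa = 3.0 * (E4 * k7 - E1 * k8) + E3 * k4pp - E2 * k3pp;
  double JncxCa = E2 * k2 - E1 * k1;
  return allo * (zna * JncxNa + zca * JncxCa);
}

void ord_rhs_core(double t, const double *y, double *dy, double *aux,
                  const double *p)
{
  const double nao = p[P_NAO], cao = p[P_CAO], ko = p[P_KO];

  /* geometry */
  const double Lcell = 0.01, rad = 0.0011;
  const double vcell = 1000.0 * 3.14 * rad * rad * Lcell;
  const double Ageo = 2.0 * 3.14 * rad * rad + 2.0 * 3.14 * rad * Lcell;
  const double Acap = 2.0 * Ageo;
  const double vmyo = 0.68 * vcell, vnsr = 0.0552 * vcell;
  const double vjsr = 0.0048 * vcell, vss = 0.02 * vcell;
  const double vsl = p[P_VSL_FRAC] * vcell;

  const double v = y[S_V];
  const double nai = y[S_NAI], nass = y[S_NASS];
  const double ki = y[S_KI], kss = y[S_KSS];
  const double cai = y[S_CAI], cass = y[S_CASS];
  const double cansr = y[S_CANSR], cajsr = y[S_CAJSR];
  const double casl = y[S_CASL];

  const double vfrt = v * Frdy / (Rgas * Temp);

  /* reversal potentials */
  double ENa = (Rgas * Temp / Frdy) * log(nao / nai);
  double EK = (Rgas * Temp / Frdy) * log(ko / ki);
  double PKNa = 0.01833;
  double EKs = (Rgas * Temp / Frdy) * log((ko + PKNa * nao) / (ki + PKNa * nai));

  /* CaMKII (driven by dyadic subspace Ca as in the baseline model) */
  const double KmCaMK = 0.15, aCaMK = 0.05, bCaMK = 0.00068;
  const double CaMKo = 0.05, KmCaM = 0.0015;
  double CaMKb = CaMKo * (1.0 - y[S_CAMKT]) / (1.0 + KmCaM / cass);
  double CaMKa = CaMKb + y[S_CAMKT];
  dy[S_CAMKT] = aCaMK * CaMKb * (CaMKb + y[S_CAMKT]) - bCaMK * y[S_CAMKT];

  /* ---- INa (fast) ---- */
  double mss = 1.0 / (1.0 + exp(-(v + 39.57) / 9.871));
  double tm = 1.0 / (6.765 * exp((v + 11.64) / 34.77) +
                     8.552 * exp(-(v + 77.42) / 5.955));
  dy[S_M] = (mss - y[S_M]) / tm;
  double hss = 1.0 / (1.0 + exp((v + 82.90) / 6.086));
  double thf = 1.0 / (1.432e-5 * exp(-(v + 1.196) / 6.285) +
                      6.149 * exp((v + 0.5096) / 20.27));
  double ths = 1.0 / (0.009794 * exp(-(v + 17.95) / 28.05) +
                      0.3343 * exp((v + 5.730) / 56.66));
  const double Ahf = 0.99, Ahs = 0.01;
  dy[S_HF] = (hss - y[S_HF]) / thf;
  dy[S_HS] = (hss - y[S_HS]) / ths;
  double h = Ahf * y[S_HF] + Ahs * y[S_HS];
  double jss = hss;
  double tj = 2.038 + 1.0 / (0.02136 * exp(-(v + 100.6) / 8.281) +
                             0.3052 * exp((v + 0.9941) / 38.45));
  dy[S_J] = (jss - y[S_J]) / tj;
  double hssp = 1.0 / (1.0 + exp((v + 89.1) / 6.086));
  double thsp = 3.0 * ths;
  dy[S_HSP] = (hssp - y[S_HSP]) / thsp;
  double hp = Ahf * y[S_HF] + Ahs * y[S_HSP];
  double tjp = 1.46 * tj;
  dy[S_JP] = (jss - y[S_JP]) / tjp;
  double fINap = 1.0 / (1.0 + KmCaMK / CaMKa);
  double GNa = p[P_GNA] * (1.0 + p[P_PK_INA] * (p[P_EFF_INA] - 1.0));
  double m3 = y[S_M] * y[S_M] * y[S_M];
  double INa = GNa * (v - ENa) * m3 *
    ((1.0 - fINap) * h * y[S_J] + fINap * hp * y[S_JP]);

  /* ---- INaL ---- */
  double mLss = 1.0 / (1.0 + exp(-(v + 42.85) / 5.264));
  double tmL = tm;
  dy[S_ML] = (mLss - y[S_ML]) / tmL;
  double hLss = 1.0 / (1.0 + exp((v + 87.61) / 7.488));
  double thL = 200.0;
  dy[S_HL] = (hLss - y[S_HL]) / thL;
  double hLssp = 1.0 / (1.0 + exp((v + 93.81) / 7.488));
  double thLp = 3.0 * thL;
  dy[S_HLP] = (hLssp - y[S_HLP]) / thLp;
  double fINaLp = 1.0 / (1.0 + KmCaMK / CaMKa);
  double INaL = p[P_GNAL] * (v - ENa) * y[S_ML] *
    ((1.0 - fINaLp) * y[S_HL] + fINaLp * y[S_HLP]);

  /* ---- Ito ---- */
  double ass = 1.0 / (1.0 + exp(-(v - 14.34) / 14.82));
  double ta = 1.0515 / (1.0 / (1.2089 * (1.0 + exp(-(v - 18.4099) / 29.3814))) +
                        3.5 / (1.0 + exp((v + 100.0) / 29.3814)));
  dy[S_A] = (ass - y[S_A]) / ta;
  double iss = 1.0 / (1.0 + exp((v + 43.94) / 5.711));
  double tiF = 4.562 + 1.0 / (0.3933 * exp(-(v + 100.0) / 100.0) +
                              0.08004 * exp((v + 50.0) / 16.59));
  double tiS = 23.62 + 1.0 / (0.001416 * exp(-(v + 96.52) / 59.05) +
                              1.780e-8 * exp((v + 114.1) / 8.079));
  double AiF = 1.0 / (1.0 + exp((v - 213.6) / 151.2));
  double AiS = 1.0 - AiF;
  dy[S_IF] = (iss - y[S_IF]) / tiF;
  dy[S_IS] = (iss - y[S_IS]) / tiS;
  double i_gate = AiF * y[S_IF] + AiS * y[S_IS];
  double assp = 1.0 / (1.0 + exp(-(v - 24.34) / 14.82));
  dy[S_AP] = (assp - y[S_AP]) / ta;
  double dti_develop = 1.354 + 1.0e-4 / (exp((v - 167.4) / 15.89) +
                                         exp(-(v - 12.23) / 0.2154));
  double dti_recover = 1.0 - 0.5 / (1.0 + exp((v + 70.0) / 20.0));
  double tiFp = dti_develop * dti_recover * tiF;
  double tiSp = dti_develop * dti_recover * tiS;
  dy[S_IFP] = (iss - y[S_IFP]) / tiFp;
  dy[S_ISP] = (iss - y[S_ISP]) / tiSp;
  double ip = AiF * y[S_IFP] + AiS * y[S_ISP];
  double fItop = 1.0 / (1.0 + KmCaMK / CaMKa);
  double Ito = p[P_GTO] * (v - EK) *
    ((1.0 - fItop) * y[S_A] * i_gate + fItop * y[S_AP] * ip);

  /* ---- ICaL gating (shared by all LTCC subpopulations) ---- */
  double dss = 1.0 / (1.0 + exp(-(v + 3.940) / 4.230));
  double td = 0.6 + 1.0 / (exp(-0.05 * (v + 6.0)) + exp(0.09 * (v + 14.0)));
  dy[S_D] = (dss - y[S_D]) / td;
  double fss = 1.0 / (1.0 + exp((v + 19.58) / 3.696));
  double tff = 7.0 + 1.0 / (0.0045 * exp(-(v + 20.0) / 10.0) +
                            0.0045 * exp((v + 20.0) / 10.0));
  double tfs = 1000.0 + 1.0 / (0.000035 * exp(-(v + 5.0) / 4.0) +
                               0.000035 * exp((v + 5.0) / 6.0));
  const double Aff = 0.6, Afs = 0.4;
  dy[S_FF] = (fss - y[S_FF]) / tff;
  dy[S_FS] = (fss - y[S_FS]) / tfs;
  double f = Aff * y[S_FF] + Afs * y[S_FS];
  double fcass = fss;
  double tfcaf = 7.0 + 1.0 / (0.04 * exp(-(v - 4.0) / 7.0) +
                              0.04 * exp((v - 4.0) / 7.0));
  double tfcas = 100.0 + 1.0 / (0.00012 * exp(-v / 3.0) +
                                0.00012 * exp(v / 7.0));
  double Afcaf = 0.3 + 0.6 / (1.0 + exp((v - 10.0) / 10.0));
  double Afcas = 1.0 - Afcaf;
  dy[S_FCAF] = (fcass - y[S_FCAF]) / tfcaf;
  dy[S_FCAS] = (fcass - y[S_FCAS]) / tfcas;
  double fca = Afcaf * y[S_FCAF] + Afcas * y[S_FCAS];
  double tjca = 75.0;
  dy[S_JCA] = (fcass - y[S_JCA]) / tjca;
  double tffp = 2.5 * tff;
  dy[S_FFP] = (fss - y[S_FFP]) / tffp;
  double fp = Aff * y[S_FFP] + Afs * y[S_FS];
  double tfcafp = 2.5 * tfcaf;
  dy[S_FCAFP] = (fcass - y[S_FCAFP]) / tfcafp;
  double fcap = Afcaf * y[S_FCAFP] + Afcas * y[S_FCAS];

  /* CDI mode fraction, one per sensed compartment */
  const double Kmn = 0.002, k2n = 1000.0;
  double km2n = y[S_JCA] * 1.0;
  double t4ss, t4sl;
  t4ss = 1.0 + Kmn / cass;  t4ss = t4ss * t4ss * t4ss * t4ss;
  t4sl = 1.0 + Kmn / casl;  t4sl = t4sl * t4sl * t4sl * t4sl;
  double anca_ss = 1.0 / (k2n / km2n + t4ss);
  /* surface-membrane channels outside the restricted dyadic geometry
   * enter the Ca-dependent-inactivation mode at an attenuated rate */
  double anca_sl = p[P_SL_CDI] / (k2n / km2n + t4sl);
  dy[S_NCA] = anca_ss * k2n - y[S_NCA] * km2n;
  dy[S_NCASL] = anca_sl * k2n - y[S_NCASL] * km2n;

  /* driving-force terms */
  double g2 = expg(2.0 * vfrt), g1 = expg(vfrt);
  double PhiCaL_ss = 2.0 * Frdy * (cass * exp(2.0 * vfrt) - 0.341 * cao) * g2;
  double PhiCaL_sl = 2.0 * Frdy * (casl * exp(2.0 * vfrt) - 0.341 * cao) * g2;
  double PhiCaNa_ss = Frdy * (0.75 * nass * exp(vfrt) - 0.75 * nao) * g1;
  double PhiCaNa_sl = Frdy * (0.75 * nai * exp(vfrt) - 0.75 * nao) * g1;
  double PhiCaK_ss = Frdy * (0.75 * kss * exp(vfrt) - 0.75 * ko) * g1;
  double PhiCaK_sl = Frdy * (0.75 * ki * exp(vfrt) - 0.75 * ko) * g1;

  double PCa = p[P_PCA];
  double PCaNa = 0.00125 * PCa, PCaK = 3.574e-4 * PCa;

  /* open-channel gating mix: base (no CaMK) and CaMK-phosphorylated
   * (the CaMK population carries the 1.1x permeability factor) */
  double gate_ss = y[S_D] * (f * (1.0 - y[S_NCA]) + y[S_JCA] * fca * y[S_NCA]);
  double gatep_ss = y[S_D] * (fp * (1.0 - y[S_NCA]) + y[S_JCA] * fcap * y[S_NCA]);
  double gate_sl = y[S_D] * (f * (1.0 - y[S_NCASL]) + y[S_JCA] * fca * y[S_NCASL]);
  double gatep_sl = y[S_D] * (fp * (1.0 - y[S_NCASL]) + y[S_JCA] * fcap * y[S_NCASL]);

  double fICaLp = 1.0 / (1.0 + KmCaMK / CaMKa);
  double camk_tt = (p[P_TT_CAMK_DYN] > 0.5) ? fICaLp : 0.0;
  double camk_sl = p[P_CAMK_SL];
  double mix_tt = (1.0 - camk_tt) * gate_ss + camk_tt * 1.1 * gatep_ss;
  double mix_sl = (1.0 - camk_sl) * gate_sl + camk_sl * 1.1 * gatep_sl;

  /* PKA amplitude per subgroup: (1 - p) + p * eff_ltcc */
  double e = p[P_EFF_LTCC] - 1.0;
  double amp_tt = p[P_WA] * (1.0 + p[P_PA] * e) +
                  p[P_WB] * (1.0 + p[P_PB] * e) +
                  p[P_WC] * (1.0 + p[P_PC] * e);
  double amp_sl = p[P_WD] * (1.0 + p[P_PD] * e) +
                  p[P_WE] * (1.0 + p[P_PE] * e) +
                  p[P_WF] * (1.0 + p[P_PF] * e);

  double ICaL_tt = amp_tt * PCa * PhiCaL_ss * mix_tt;
  double ICaL_sl = amp_sl * PCa * PhiCaL_sl * mix_sl;
  double ICaNa_tt = amp_tt * PCaNa * PhiCaNa_ss * mix_tt;
  double ICaNa_sl = amp_sl * PCaNa * PhiCaNa_sl * mix_sl;
  double ICaK_tt = amp_tt * PCaK * PhiCaK_ss * mix_tt;
  double ICaK_sl = amp_sl * PCaK * PhiCaK_sl * mix_sl;
  double ICaL = ICaL_tt + ICaL_sl;
  double ICaNa = ICaNa_tt + ICaNa_sl;
  double ICaK = ICaK_tt + ICaK_sl;

  /* ---- IKr ---- */
  double xrss = 1.0 / (1.0 + exp(-(v + 8.337) / 6.789));
  double txrf = 12.98 + 1.0 / (0.3652 * exp((v - 31.66) / 3.869) +
                               4.123e-5 * exp(-(v - 47.78) / 20.38));
  double txrs = 1.865 + 1.0 / (0.06629 * exp((v - 34.70) / 7.355) +
                               1.128e-5 * exp(-(v - 29.74) / 25.94));
  double Axrf = 1.0 / (1.0 + exp((v + 54.81) / 38.21));
  double Axrs = 1.0 - Axrf;
  dy[S_XRF] = (xrss - y[S_XRF]) / txrf;
  dy[S_XRS] = (xrss - y[S_XRS]) / txrs;
  double xr = Axrf * y[S_XRF] + Axrs * y[S_XRS];
  double rkr = 1.0 / ((1.0 + exp((v + 55.0) / 75.0)) *
                      (1.0 + exp((v - 10.0) / 30.0)));
  double IKr = p[P_GKR] * sqrt(ko / 5.4) * xr * rkr * (v - EK);

  /* ---- IKs ---- */
  double xs1ss = 1.0 / (1.0 + exp(-(v + 11.60) / 8.932));
  double txs1 = 817.3 + 1.0 / (2.326e-4 * exp((v + 48.28) / 17.80) +
                               0.001292 * exp(-(v + 210.0) / 230.0));
  dy[S_XS1] = (xs1ss - y[S_XS1]) / txs1;
  double xs2ss = xs1ss;
  double txs2 = 1.0 / (0.01 * exp((v - 50.0) / 20.0) +
                       0.0193 * exp(-(v + 66.54) / 31.0));
  dy[S_XS2] = (xs2ss - y[S_XS2]) / txs2;
  double KsCa = 1.0 + 0.6 / (1.0 + pow(3.8e-5 / cai, 1.4));
  double GKs = p[P_GKS] * (1.0 + p[P_PK_IKS] * (p[P_EFF_IKS] - 1.0));
  double IKs = GKs * KsCa * y[S_XS1] * y[S_XS2] * (v - EKs);

  /* ---- IK1 ---- */
  double xk1ss = 1.0 / (1.0 + exp(-(v + 2.5538 * ko + 144.59) /
                                  (1.5692 * ko + 3.8115)));
  double txk1 = 122.2 / (exp(-(v + 127.2) / 20.36) + exp((v + 236.8) / 69.33));
  dy[S_XK1] = (xk1ss - y[S_XK1]) / txk1;
  double rk1 = 1.0 / (1.0 + exp((v + 105.8 - 2.6 * ko) / 9.493));
  double IK1 = p[P_GK1] * sqrt(ko) * rk1 * y[S_XK1] * (v - EK);

  /* ---- NCX: native bulk (t-tubular region), native subspace fifth, and
   *      redistributed surface fraction sensing casl ---- */
  double Gncx = p[P_GNCX];
  double f_tt = p[P_FTT];
  double INaCa_tt = 0.8 * f_tt * Gncx * ncx_current(v, nai, cai, nao, cao);
  double INaCa_ss = 0.2 * Gncx * ncx_current(v, nass, cass, nao, cao);
  double INaCa_sl = 0.8 * (1.0 - f_tt) * Gncx *
    ncx_current(v, nai, casl, nao, cao);

  /* ---- INaK ---- */
  {
    /* filled below */
  }
  double k1p = 949.5, k1m = 182.4, k2p = 687.2, k2m = 39.4;
  double k3p_ = 1899.0, k3m = 79300.0, k4p_ = 639.0, k4m = 40.0;
  double Knai0 = 9.073, Knao0 = 27.78, delta = -0.1550;
  double Knai = Knai0 * exp(delta * vfrt / 3.0);
  double Knao = Knao0 * exp((1.0 - delta) * vfrt / 3.0);
  double Kki = 0.5, Kko = 0.3582;
  double MgADP = 0.05, MgATP = 9.8, Kmgatp = 1.698e-7;
  double Hconc = 1.0e-7, eP = 4.2, Khp = 1.698e-7, Knap = 224.0, Kxkur = 292.0;
  double Pfrac = eP / (1.0 + Hconc / Khp + nai / Knap + ki / Kxkur);
  double t_nai = 1.0 + nai / Knai, t_ki = 1.0 + ki / Kki;
  double t_nao = 1.0 + nao / Knao, t_ko = 1.0 + ko / Kko;
  double a1 = k1p * pow(nai / Knai, 3.0) /
    (pow(t_nai, 3.0) + pow(t_ki, 2.0) - 1.0);
  double b1 = k1m * MgADP;
  double a2 = k2p;
  double b2 = k2m * pow(nao / Knao, 3.0) /
    (pow(t_nao, 3.0) + pow(t_ko, 2.0) - 1.0);
  double a3 = k3p_ * pow(ko / Kko, 2.0) /
    (pow(t_nao, 3.0) + pow(t_ko, 2.0) - 1.0);
  double b3 = k3m * Pfrac * Hconc / (1.0 + MgATP / Kmgatp);
  double a4 = k4p_ * MgATP / Kmgatp / (1.0 + MgATP / Kmgatp);
  double b4 = k4m * pow(ki / Kki, 2.0) /
    (pow(t_nai, 3.0) + pow(t_ki, 2.0) - 1.0);
  double x1n = a4 * a1 * a2 + b2 * b4 * b3 + a2 * b4 * b3 + b3 * a1 * a2;
  double x2n = b2 * b1 * b4 + a1 * a2 * a3 + a3 * b1 * b4 + a2 * a3 * b4;
  double x3n = a2 * a3 * a4 + b3 * b2 * b1 + b2 * b1 * a4 + a3 * a4 * b1;
  double x4n = b4 * b3 * b2 + a3 * a4 * a1 + b2 * a4 * a1 + b3 * b2 * a1;
  double E1n = x1n / (x1n + x2n + x3n + x4n);
  double E2n = x2n / (x1n + x2n + x3n + x4n);
  double E3n = x3n / (x1n + x2n + x3n + x4n);
  double E4n = x4n / (x1n + x2n + x3n + x4n);
  double JnakNa = 3.0 * (E1n * a3 - E2n * b3);
  double JnakK = 2.0 * (E4n * b1 - E3n * a1);
  double Pnak = p[P_PNAK] * (1.0 + p[P_PK_INAK] * (p[P_EFF_INAK] - 1.0));
  double INaK = Pnak * (JnakNa + JnakK);

  /* ---- minor currents ---- */
  double xkb = 1.0 / (1.0 + exp(-(v - 14.48) / 18.34));
  double GKb = p[P_GKB] * (1.0 + p[P_PK_IKB] * (p[P_EFF_IKB] - 1.0));
  double IKb = GKb * xkb * (v - EK);
  double INab = p[P_PNAB] * Frdy * (nai * exp(vfrt) - nao) * g1;
  double ICab = p[P_PCAB] * 2.0 * Frdy *
    (cai * exp(2.0 * vfrt) - 0.341 * cao) * g2;
  double IpCa = p[P_GPCA] * cai / (0.0005 + cai);

  /* ---- diffusion fluxes ---- */
  double JdiffNa = (nass - nai) / 2.0;
  double JdiffK = (kss - ki) / 2.0;
  double Jdiff = (cass - cai) / 0.2;
  double Jdiffsl = (casl - cai) / p[P_TAU_SL];

  /* ---- SR release: dyad-coupled RyRs triggered by the per-channel
   *      T-tubular LTCC current; orphaned RyRs triggered by bulk Ca ---- */
  /* the dyad-coupled release trigger is the total T-tubular LTCC current:
   * redistribution (or phosphorylation) changes the trigger through the
   * current itself, as in the baseline formulation */
  double bt = 4.75, a_rel = 0.5 * bt;
  double btp = 1.25 * bt, a_relp = 0.5 * btp;
  double trig = -ICaL_tt;
  double jsr_gate = 1.0 / (1.0 + pow(1.5 / cajsr, 8.0));
  double Jrel_inf = a_rel * trig * jsr_gate;
  double Jrel_infp = a_relp * trig * jsr_gate;
  double tau_rel = bt / (1.0 + 0.0123 / cajsr);
  if (tau_rel < 0.001) tau_rel = 0.001;
  double tau_relp = btp / (1.0 + 0.0123 / cajsr);
  if (tau_relp < 0.001) tau_relp = 0.001;
  dy[S_JRELNP] = (Jrel_inf - y[S_JRELNP]) / tau_rel;
  dy[S_JRELP] = (Jrel_infp - y[S_JRELP]) / tau_relp;
  double fJrelp = 1.0 / (1.0 + KmCaMK / CaMKa);
  double ryr_amp = 1.0 + p[P_PK_RYR] * (p[P_EFF_RYR] - 1.0);
  double Jrel = p[P_JRELSC] * ryr_amp *
    ((1.0 - fJrelp) * y[S_JRELNP] + fJrelp * y[S_JRELP]);

  double act_orph = cai * cai / (cai * cai + p[P_ORPH_KM] * p[P_ORPH_KM]);
  double Jrelorph_inf = (1.0 - f_tt) * a_rel * p[P_ORPH_AMP] * act_orph *
    jsr_gate;
  dy[S_JRELORPH] = (Jrelorph_inf - y[S_JRELORPH]) / tau_rel;
  double Jrelorph = p[P_JRELSC] * ryr_amp * y[S_JRELORPH];

  /* ---- SERCA uptake: PKA(PLB) x CaMK populations ---- */
  double fJupp = 1.0 / (1.0 + KmCaMK / CaMKa);
  double km_up = 0.00092;
  double km_up_pka = 0.00092 * p[P_EFF_PLB];
  double pP = p[P_PK_PLB];
  double Jup_b = 0.004375 * cai / (cai + km_up);
  double Jup_pka = 0.004375 * cai / (cai + km_up_pka);
  double Jup_ck = 2.75 * 0.004375 * cai / (cai + km_up - 0.00017);
  double Jup_both = 2.75 * 0.004375 * cai / (cai + km_up_pka - 0.00017);
  double Jleak = 0.0039375 * cansr / 15.0;
  double Jup = p[P_JUPSC] *
    ((1.0 - pP) * (1.0 - fJupp) * Jup_b + pP * (1.0 - fJupp) * Jup_pka +
     (1.0 - pP) * fJupp * Jup_ck + pP * fJupp * Jup_both) - Jleak;
  double Jtr = (cansr - cajsr) / 100.0;

  /* ---- buffers ---- */
  const double cmdnmax = 0.05, kmcmdn = 0.00238;
  const double trpnmax = 0.07, kmtrpn = 0.0005;
  const double BSRmax = 0.047, KmBSR = 0.00087;
  const double BSLmax = 1.124, KmBSL = 0.0087;
  const double csqnmax = 10.0, kmcsqn = 0.8;
  double kmtrpn_p = kmtrpn * p[P_EFF_TNI];
  double pT = p[P_PK_TNI];
  double trpn_term = (1.0 - pT) * trpnmax * kmtrpn /
    ((kmtrpn + cai) * (kmtrpn + cai)) +
    pT * trpnmax * kmtrpn_p / ((kmtrpn_p + cai) * (kmtrpn_p + cai));
  double Bcai = 1.0 / (1.0 + cmdnmax * kmcmdn /
                       ((kmcmdn + cai) * (kmcmdn + cai)) + trpn_term);
  double Bcass = 1.0 / (1.0 + BSRmax * KmBSR / ((KmBSR + cass) * (KmBSR + cass)) +
                        BSLmax * KmBSL / ((KmBSL + cass) * (KmBSL + cass)));
  /* the sub-sarcolemmal shell carries the Shannon-type sarcolemmal buffers:
   * low-affinity phospholipid sites plus a high-affinity component that
   * dominates differential buffering at sub-micromolar Ca */
  const double SLLmax = 1.65, KmSLL = 0.013;
  const double SLHmax = 0.3, KmSLH = 0.0003;
  double Bcasl = 1.0 / (1.0 + SLLmax * KmSLL / ((KmSLL + casl) * (KmSLL + casl)) +
                        SLHmax * KmSLH / ((KmSLH + casl) * (KmSLH + casl)));
  double Bcajsr = 1.0 / (1.0 + csqnmax * kmcsqn /
                         ((kmcsqn + cajsr) * (kmcsqn + cajsr)));

  double Istim = p[P_ISTIM];

  /* ---- concentration balances ---- */
  dy[S_NAI] = -(INa + INaL + 3.0 * INaCa_tt + 3.0 * INaCa_sl + 3.0 * INaK +
                INab + ICaNa_sl) * Acap / (Frdy * vmyo) +
    JdiffNa * vss / vmyo;
  dy[S_NASS] = -(ICaNa_tt + 3.0 * INaCa_ss) * Acap / (Frdy * vss) - JdiffNa;
  dy[S_KI] = -(Ito + IKr + IKs + IK1 + IKb + Istim - 2.0 * INaK + ICaK_sl) *
    Acap / (Frdy * vmyo) + JdiffK * vss / vmyo;
  dy[S_KSS] = -ICaK_tt * Acap / (Frdy * vss) - JdiffK;
  dy[S_CAI] = Bcai * (-(IpCa + ICab - 2.0 * INaCa_tt) * Acap /
                      (2.0 * Frdy * vmyo) - Jup * vnsr / vmyo +
                      Jdiff * vss / vmyo + Jdiffsl * vsl / vmyo +
                      Jrelorph * vjsr / vmyo);
  dy[S_CASS] = Bcass * (-(ICaL_tt - 2.0 * INaCa_ss) * Acap /
                        (2.0 * Frdy * vss) + Jrel * vjsr / vss - Jdiff);
  dy[S_CASL] = Bcasl * (-(ICaL_sl - 2.0 * INaCa_sl) * Acap /
                        (2.0 * Frdy * vsl) - Jdiffsl);
  dy[S_CANSR] = Jup - Jtr * vjsr / vnsr;
  dy[S_CAJSR] = Bcajsr * (Jtr - Jrel - Jrelorph);

  double Itot = INa + INaL + Ito + ICaL + ICaNa + ICaK + IKr + IKs + IK1 +
    INaCa_tt + INaCa_ss + INaCa_sl + INaK + INab + IKb + IpCa + ICab + Istim;
  dy[S_V] = (p[P_CLAMP] > 0.5) ? 0.0 : -Itot;

  if (aux) {
    aux[0] = ICaL_tt;
    aux[1] = ICaL_sl;
    aux[2] = ICaL;
    aux[3] = ICaNa;
    aux[4] = ICaK;
    aux[5] = INa;
    aux[6] = INaL;
    aux[7] = Ito;
    aux[8] = IKr;
    aux[9] = IKs;
    aux[10] = IK1;
    aux[11] = INaCa_tt + INaCa_ss + INaCa_sl;
    aux[12] = INaCa_sl;
    aux[13] = INaK;
    aux[14] = IKb;
    aux[15] = INab;
    aux[16] = ICab;
    aux[17] = IpCa;
    aux[18] = Jrel;
    aux[19] = Jrelorph;
    aux[20] = Jup;
    aux[21] = Jdiff;
    aux[22] = Jdiffsl;
    aux[23] = CaMKa;
    aux[24] = Istim;
    aux[25] = Itot;
  }
}

/* ---------- deSolve compiled-model interface ---------- */

static double parms[N_PARM];

void ord_initmod(void (*odeparms)(int *, double *))
{
  int n = N_PARM;
  odeparms(&n, parms);
}

void ord_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
  if (*neq != N_STATE) error("ord_derivs: expected %d states", N_STATE);
  if (ip[0] < N_AUX) error("ord_derivs: nout too small");
  ord_rhs_core(*t, y, ydot, yout, parms);
}

/* ---------- direct .C entry point ---------- */

void c_ord_rhs(double *t, double *y, double *p, double *dy, double *aux)
{
  ord_rhs_core(*t, y, dy, aux, p);
}
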