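/* Whole-cell mouse ventricular myocyte model: compiled right-hand side for deSolve.
 *
 * State layout (41 variables) and parameter order must match .state_order and
 * .parm_order in R/parameters.R.  Units: ms, mV, pA/pF, concentrations in uM
 * (Na+/K+ carried in uM internally; user-facing accessors convert to mM).
 * Within one integration segment the stimulus is constant (parms[71]); the R
 * driver restarts the integrator at every stimulus edge.
 */
#include <R.h>
#include <math.h>

#define NPARMS 72
static double p[NPARMS];

#define Acap      p[0]
#define Cm        p[1]
#define Vmyo      p[2]
#define VJSR      p[3]
#define VNSR      p[4]
#define Vss       p[5]
#define Ko        p[6]
#define Nao       p[7]
#define Cao       p[8]
#define Fc        p[9]
#define TK        p[10]
#define Rgas      p[11]
#define v1        p[12]
#define v2        p[13]
#define v3        p[14]
#define Km_up     p[15]
#define tau_tr    p[16]
#define tau_xfer  p[17]
#define ka_p      p[18]
#define ka_m      p[19]
#define kb_p      p[20]
#define kb_m      p[21]
#define kc_p      p[22]
#define kc_m      p[23]
#define n_ryr     p[24]
#define m_ryr     p[25]
#define LTRPNtot  p[26]
#define HTRPNtot  p[27]
#define khtrpn_p  p[28]
#define khtrpn_m  p[29]
#define kltrpn_p  p[30]
#define kltrpn_m  p[31]
#define CMDNtot   p[32]
#define Km_CMDN   p[33]
#define CSQNtot   p[34]
#define Km_CSQN   p[35]
#define GCaL      p[36]
#define ECaL      p[37]
#define Kpc_max   p[38]
#define Kpc_half  p[39]
#define Kpcb      p[40]
#define ICaL_max  p[41]
#define GNa       p[42]
#define GNab      p[43]
#define GCab      p[44]
#define kNaCa     p[45]
#define Km_Na     p[46]
#define Km_Ca     p[47]
#define k_sat     p[48]
#define eta       p[49]
#define IpCa_max  p[50]
#define Km_pCa    p[51]
#define INaK_max  p[52]
#define Km_Nai    p[53]
#define Km_Ko     p[54]
#define GKtof     p[55]
#define GKtos     p[56]
#define GKur      p[57]
#define GKss      p[58]
#define GKs       p[59]
#define GKr       p[60]
#define kf_kr     p[61]
#define kb_kr     p[62]
#define GK1       p[63]
#define K1_half   p[64]
#define nK1       p[65]
#define sK1       p[66]
#define GClCa     p[67]
#define Km_Cl     p[68]
#define ECl       p[69]
#define slow_inact p[70]
#define istim_now p[71]

void myoburst_initmod(void (* odeparms)(int *, double *))
{
    int N = NPARMS;
    odeparms(&N, p);
}

void myoburst_derivs(int *neq, double *t, double *y, double *ydot,
                     double *yout, int *ip)
{
    /* --- unpack state ------------------------------------------------ */
    double V = y[0];
    double Cai = y[1], Cass = y[2], CaJSR = y[3], CaNSR = y[4];
    double LTRPNCa = y[5], HTRPNCa = y[6];
    double PO1 = y[7], PO2 = y[8], PC2 = y[9], PRyR = y[10];
    double OL = y[11], C2L = y[12], C3L = y[13], C4L = y[14];
    double I1L = y[15], I2L = y[16], I3L = y[17];
    double CNa2 = y[18], CNa1 = y[19], ONa = y[20], IFNa = y[21];
    double I1Na = y[22], I2Na = y[23], ICNa2 = y[24], ICNa3 = y[25];
    double Nai = y[26], Ki = y[27];
    double atof = y[28], itof = y[29], atos = y[30], itos = y[31];
    double nKs = y[32], aur = y[33], iur = y[34], aKss = y[35], iKss = y[36];
    double CK1 = y[37], CK2 = y[38], OK = y[39], IKr_I = y[40];

    double RTF = Rgas * TK / Fc;
    double VFRT = V / RTF;

    /* --- reversal potentials ----------------------------------------- */
    double ENa = RTF * log((0.9 * Nao + 0.1 * Ko) / (0.9 * Nai + 0.1 * Ki));
    double EK  = RTF * log(Ko / Ki);
    double EKr = RTF * log((0.98 * Ko + 0.02 * Nao) / (0.98 * Ki + 0.02 * Nai));
    double ECaN = 0.5 * RTF * log(Cao / Cai);

    /* --- fast Na+ current (9-state Markov scheme) ---------------------- */
    double aNa11 = 3.802 / (0.1027 * exp(-(V + 2.5) / 17.0) + 0.20 * exp(-(V + 2.5) / 150.0));
    double aNa12 = 3.802 / (0.1027 * exp(-(V + 2.5) / 15.0) + 0.23 * exp(-(V + 2.5) / 150.0));
    double aNa13 = 3.802 / (0.1027 * exp(-(V + 2.5) / 12.0) + 0.25 * exp(-(V + 2.5) / 150.0));
    double bNa11 = 0.1917 * exp(-(V + 2.5) / 20.3);
    double bNa12 = 0.20   * exp(-(V - 2.5) / 20.3);
    double bNa13 = 0.22   * exp(-(V - 7.5) / 20.3);
    double aNa3  = 7.0e-7 * exp(-(V + 7.0) / 7.7);
    double bNa3  = 0.0084 + 0.00002 * (V + 7.0);
    double aNa2  = 1.0 / (0.188495 * exp(-(V + 7.0) / 16.6) + 0.393956);
    double bNa2  = aNa13 * aNa2 * aNa3 / (bNa13 * bNa3);
    double aNa4  = aNa2 / 1000.0;
    double bNa4  = aNa3;
    double aNa5  = aNa2 / 95000.0;
    double bNa5  = aNa3 / 50.0;
    if (slow_inact < 0.5) {      /* variant without the slow states I1/I2 */
        aNa4 = 0.0; bNa4 = 0.0; aNa5 = 0.0; bNa5 = 0.0;
    }
    double CNa3 = 1.0 - (CNa2 + CNa1 + ONa + IFNa + I1Na + I2Na + ICNa2 + ICNa3);

    double INa = GNa * ONa * (V - ENa);

    ydot[18] = aNa11 * CNa3 + bNa12 * CNa1 + aNa3 * ICNa2
             - (bNa11 + aNa12 + bNa3) * CNa2;                       /* CNa2 */
    ydot[19] = aNa12 * CNa2 + bNa13 * ONa + aNa3 * IFNa
             - (bNa12 + aNa13 + bNa3) * CNa1;                       /* CNa1 */
    ydot[20] = aNa13 * CNa1 + bNa2 * IFNa - (bNa13 + aNa2) * ONa;   /* ONa  */
    ydot[21] = aNa2 * ONa + bNa3 * CNa1 + bNa4 * I1Na + aNa12 * ICNa2
             - (bNa2 + aNa3 + aNa4 + bNa12) * IFNa;                 /* IFNa */
    ydot[22] = aNa4 * IFNa + bNa5 * I2Na - (bNa4 + aNa5) * I1Na;    /* I1Na */
    ydot[23] = aNa5 * I1Na - bNa5 * I2Na;                           /* I2Na */
    ydot[24] = aNa11 * ICNa3 + bNa12 * IFNa + bNa3 * CNa2
             - (bNa11 + aNa12 + aNa3) * ICNa2;                      /* ICNa2 */
    ydot[25] = bNa11 * ICNa2 + bNa3 * CNa3 - (aNa11 + aNa3) * ICNa3;/* ICNa3 */

    /* --- L-type Ca2+ current (Markov) --------------------------------- */
    double aL = 0.4 * exp((V + 12.0) / 10.0) *
        (1.0 + 0.7 * exp(-(V + 40.0) * (V + 40.0) / 10.0)
             - 0.75 * exp(-(V + 20.0) * (V + 20.0) / 400.0)) /
        (1.0 + 0.12 * exp((V + 12.0) / 10.0));
    double bL = 0.05 * exp(-(V + 12.0) / 13.0);
    double gL = Kpc_max * Cass / (Kpc_half + Cass);
    double Kpcf = 13.0 * (1.0 - exp(-(V + 14.5) * (V + 14.5) / 100.0));
    double C1L = 1.0 - (OL + C2L + C3L + C4L + I1L + I2L + I3L);

    double ICaL = GCaL * OL * (V - ECaL);

    ydot[11] = aL * C4L - 4.0 * bL * OL + Kpcb * I1L - gL * OL
             + 0.001 * (aL * I2L - Kpcf * OL);                      /* OL  */
    ydot[12] = 4.0 * aL * C1L + 2.0 * bL * C3L - (bL + 3.0 * aL) * C2L; /* C2L */
    ydot[13] = 3.0 * aL * C2L + 3.0 * bL * C4L - (2.0 * bL + 2.0 * aL) * C3L; /* C3L */
    ydot[14] = 2.0 * aL * C3L + 4.0 * bL * OL - (3.0 * bL + aL) * C4L
             + 0.01 * (4.0 * Kpcb * bL * I1L - aL * gL * C4L)
             + 0.002 * (4.0 * bL * I2L - Kpcf * C4L)
             + 4.0 * bL * Kpcb * I3L - gL * Kpcf * C4L;             /* C4L */
    ydot[15] = gL * OL - Kpcb * I1L + 0.001 * (Kpcf * I3L - aL * I1L)
             + 0.01 * (aL * gL * C4L - 4.0 * Kpcb * bL * I1L);      /* I1L */
    ydot[16] = 0.001 * (Kpcf * OL - aL * I2L) + Kpcb * I3L - gL * I2L
             + 0.002 * (Kpcf * C4L - 4.0 * bL * I2L);               /* I2L */
    ydot[17] = 0.001 * (aL * I1L - Kpcf * I3L) + gL * I2L - Kpcb * I3L
             + gL * Kpcf * C4L - 4.0 * bL * Kpcb * I3L;             /* I3L */

    /* --- other sarcolemmal currents ----------------------------------- */
    double IpCa = IpCa_max * Cai * Cai / (Km_pCa * Km_pCa + Cai * Cai);

    double denom = (Km_Na * Km_Na * Km_Na + Nao * Nao * Nao) * (Km_Ca + Cao) *
                   (1.0 + k_sat * exp((eta - 1.0) * VFRT));
    double INaCa = kNaCa / denom *
        (exp(eta * VFRT) * Nai * Nai * Nai * Cao -
         exp((eta - 1.0) * VFRT) * Nao * Nao * Nao * Cai);

    double ICab = GCab * (V - ECaN);
    double INab = GNab * (V - ENa);

    double sigma = (exp(Nao / 67300.0) - 1.0) / 7.0;
    double fNaK = 1.0 / (1.0 + 0.1245 * exp(-0.1 * VFRT) + 0.0365 * sigma * exp(-VFRT));
    double INaK = INaK_max * fNaK * Ko / (Ko + Km_Ko) /
                  (1.0 + pow(Km_Nai / Nai, 1.5));

    double OClCa = 0.2 / (1.0 + exp(-(V - 46.7) / 7.8));
    double IClCa = GClCa * OClCa * Cai / (Cai + Km_Cl) * (V - ECl);

    /* --- K+ currents --------------------------------------------------- */
    double IKtof = GKtof * atof * atof * atof * itof * (V - EK);
    double IKtos = GKtos * atos * itos * (V - EK);
    double IKur  = GKur * aur * iur * (V - EK);
    double IKss  = GKss * aKss * iKss * (V - EK);
    double IKs   = GKs * nKs * nKs * (V - EK);
    double IKrc  = GKr * OK * (V - EKr);
    double IK1   = GK1 * pow(Ko / (Ko + K1_half), nK1) * (V - EK) /
                   (1.0 + exp(sK1 * (V - EK)));

    /* HH gates */
    double aa = 0.18064 * exp(0.03577 * (V + 30.0));
    double ba = 0.3956  * exp(-0.06237 * (V + 30.0));
    double ai = 0.000152 * exp(-(V + 13.5) / 7.0) /
                (0.0067083 * exp(-(V + 33.5) / 7.0) + 1.0);
    double bi = 0.00095 * exp((V + 33.5) / 7.0) /
                (0.051335 * exp((V + 33.5) / 7.0) + 1.0);
    ydot[28] = aa * (1.0 - atof) - ba * atof;
    ydot[29] = ai * (1.0 - itof) - bi * itof;

    double a_ss = 1.0 / (1.0 + exp(-(V + 22.5) / 7.7));
    double i_ss = 1.0 / (1.0 + exp((V + 45.2) / 5.7));
    double tau_tas = 0.493 * exp(-0.0629 * V) + 2.058;
    double tau_tis = 270.0 + 1050.0 / (1.0 + exp((V + 45.2) / 5.7));
    ydot[30] = (a_ss - atos) / tau_tas;
    ydot[31] = (i_ss - itos) / tau_tis;

    double dv = V + 26.5;
    double an = (fabs(dv) < 1e-6)
        ? 0.00000481333 / 0.128
        : 0.00000481333 * dv / (1.0 - exp(-0.128 * dv));
    double bn = 0.0000953333 * exp(-0.038 * dv);
    ydot[32] = an * (1.0 - nKs) - bn * nKs;

    double tau_aur = 0.493 * exp(-0.0629 * V) + 2.058;
    double tau_iur = 1200.0 - 170.0 / (1.0 + exp((V + 45.2) / 5.7));
    ydot[33] = (a_ss - aur) / tau_aur;
    ydot[34] = (i_ss - iur) / tau_iur;

    double tau_Kss = 39.3 * exp(-0.0862 * V) + 13.17;
    ydot[35] = (a_ss - aKss) / tau_Kss;
    ydot[36] = 0.0;

    /* IKr Markov */
    double aa0 = 0.022348 * exp(0.01176 * V);
    double ba0 = 0.047002 * exp(-0.0631 * V);
    double aa1 = 0.013733 * exp(0.038198 * V);
    double ba1 = 0.0000689 * exp(-0.04178 * V);
    double aikr = 0.090821 * exp(0.023391 * (V + 5.0));
    double bikr = 0.006497 * exp(-0.03268 * (V + 5.0));
    double CK0 = 1.0 - (CK1 + CK2 + OK + IKr_I);
    ydot[37] = aa0 * CK0 - ba0 * CK1 + kb_kr * CK2 - kf_kr * CK1;
    ydot[38] = kf_kr * CK1 - kb_kr * CK2 + ba1 * OK - aa1 * CK2;
    ydot[39] = aa1 * CK2 - ba1 * OK + bikr * IKr_I - aikr * OK;
    ydot[40] = aikr * OK - bikr * IKr_I;

    /* --- RyR and Ca2+ fluxes ------------------------------------------- */
    double PC1 = 1.0 - (PO1 + PO2 + PC2);
    double Cass_n = pow(Cass, n_ryr);
    double Cass_m = pow(Cass, m_ryr);
    ydot[7] = ka_p * Cass_n * PC1 - ka_m * PO1 - kb_p * Cass_m * PO1
            + kb_m * PO2 - kc_p * PO1 + kc_m * PC2;                 /* PO1 */
    ydot[8] = kb_p * Cass_m * PO1 - kb_m * PO2;                     /* PO2 */
    ydot[9] = kc_p * PO1 - kc_m * PC2;                              /* PC2 */
    ydot[10] = -0.04 * PRyR - 0.1 * (ICaL / ICaL_max) *
               exp(-(V - 5.0) * (V - 5.0) / 648.0);                 /* PRyR */

    double Jrel  = v1 * (PO1 + PO2) * (CaJSR - Cass) * PRyR;
    double Jtr   = (CaNSR - CaJSR) / tau_tr;
    double Jxfer = (Cass - Cai) / tau_xfer;
    double Jleak = v2 * (CaNSR - Cai);
    double Jup   = v3 * Cai * Cai / (Km_up * Km_up + Cai * Cai);
    double Jtrpn = khtrpn_p * Cai * (HTRPNtot - HTRPNCa) - khtrpn_m * HTRPNCa
                 + kltrpn_p * Cai * (LTRPNtot - LTRPNCa) - kltrpn_m * LTRPNCa;

    ydot[5] = kltrpn_p * Cai * (LTRPNtot - LTRPNCa) - kltrpn_m * LTRPNCa;
    ydot[6] = khtrpn_p * Cai * (HTRPNtot - HTRPNCa) - khtrpn_m * HTRPNCa;

    double Bi   = 1.0 / (1.0 + CMDNtot * Km_CMDN / ((Km_CMDN + Cai) * (Km_CMDN + Cai)));
    double Bss  = 1.0 / (1.0 + CMDNtot * Km_CMDN / ((Km_CMDN + Cass) * (Km_CMDN + Cass)));
    double BJSR = 1.0 / (1.0 + CSQNtot * Km_CSQN / ((Km_CSQN + CaJSR) * (Km_CSQN + CaJSR)));

    double fcur = Acap * Cm / (2.0 * Vmyo * Fc);
    double fss  = Acap * Cm / (2.0 * Vss * Fc);
    double fion = Acap * Cm / (Vmyo * Fc);

    ydot[1] = Bi * (Jleak + Jxfer - Jup - Jtrpn
                    - (ICab - 2.0 * INaCa + IpCa) * fcur);          /* Cai */
    ydot[2] = Bss * (Jrel * VJSR / Vss - Jxfer * Vmyo / Vss - ICaL * fss); /* Cass */
    ydot[3] = BJSR * (Jtr - Jrel);                                  /* CaJSR */
    ydot[4] = (Jup - Jleak) * Vmyo / VNSR - Jtr * VJSR / VNSR;      /* CaNSR */

    ydot[26] = -(INa + INab + 3.0 * INaCa + 3.0 * INaK) * fion;     /* Nai */
    ydot[27] = -(IKtof + IKtos + IK1 + IKs + IKss + IKur + IKrc
                 - 2.0 * INaK - istim_now) * fion;                  /* Ki */

    /* --- membrane potential -------------------------------------------- */
    double Iion = INa + ICaL + IpCa + INaCa + ICab + INab + INaK
                + IKtof + IKtos + IK1 + IKs + IKur + IKss + IKrc + IClCa;
    ydot[0] = -(Iion - istim_now);

    if (ip[0] >= 23) {
        yout[0]  = INa;   yout[1]  = ICaL;  yout[2]  = IpCa;  yout[3]  = INaCa;
        yout[4]  = ICab;  yout[5]  = INab;  yout[6]  = INaK;  yout[7]  = IKtof;
        yout[8]  = IKtos; yout[9]  = IK1;   yout[10] = IKs;   yout[11] = IKur;
        yout[12] = IKss;  yout[13] = IKrc;  yout[14] = IClCa; yout[15] = istim_now;
        yout[16] = Jup;   yout[17] = Jrel;  yout[18] = Jtr;   yout[19] = Jleak;
        yout[20] = Jxfer; yout[21] = Jtrpn; yout[22] = Iion;
    }
}
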