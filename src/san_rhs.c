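/* Right-hand side of the mouse sinoatrial-node pacemaker myocyte model.
 *
 * Coupled-clock single-cell formulation (membrane clock: If, ICaL, ICaT,
 * INa, IKr, IKs, Ito, Isus, IKACh, INaK, INCX, background Na/Ca; calcium
 * clock: SR release/uptake/transfer with a submembrane space). Compiled for
 * use with deSolve (dllname = "sanpop", func = "san_derivs",
 * initfunc = "san_initparms").
 *
 * Units: time ms, voltage mV, concentrations mM, current densities pA/pF.
 *
 * Parameter order (must match san_default_params() on the R side):
 *  0 G_CaL   1 G_CaT   2 G_Na    3 G_f     4 G_Kr    5 G_Ks    6 G_to
 *  7 G_sus   8 G_KACh  9 G_bNa  10 G_bCa  11 P_NaK  12 v_NCX  13 v_RyR
 * 14 v_up   15 cch_dose (uM)    16 y_shift (mV)     17 kach_K05 (uM)
 * 18 kach_hill          19 ca_shift (mV)
 *
 * State order: 0 V, 1 dL, 2 fL, 3 dT, 4 fT, 5 h, 6 pa, 7 n, 8 q, 9 r,
 * 10 y, 11 Casub, 12 Cai, 13 CaJSR, 14 CaNSR.
 */

#include <math.h>
#include <R.h>

#define N_PARMS 20
static double parms[N_PARMS];

#define G_CaL     parms[0]
#define G_CaT     parms[1]
#define G_Na      parms[2]
#define G_f       parms[3]
#define G_Kr      parms[4]
#define G_Ks      parms[5]
#define G_to      parms[6]
#define G_sus     parms[7]
#define G_KACh    parms[8]
#define G_bNa     parms[9]
#define G_bCa     parms[10]
#define P_NaK     parms[11]
#define v_NCX     parms[12]
#define v_RyR     parms[13]
#define v_up      parms[14]
#define CCH_DOSE  parms[15]
#define Y_SHIFT   parms[16]
#define KACH_K05  parms[17]
#define KACH_HILL parms[18]
#define CA_SHIFT  parms[19]

/* fixed physical constants and milieu */
static const double FARADAY = 96485.0;   /* C/mol */
static const double RTF     = 26.73;     /* mV at 310 K */
static const double Cm      = 25.0;      /* pF */
static const double Nao = 140.0, Nai = 8.0, Ko = 5.4, Ki = 140.0, Cao = 1.8;

/* cell compartment volumes, pL */
static const double Vsub = 0.035, Vi = 1.61, Vjsr = 0.0042, Vnsr = 0.0406;

/* Ca handling constants */
static const double K_rel = 0.0012, K_up = 0.0006;
static const double tau_tr = 60.0, tau_dif = 0.1;           /* ms */
static const double B_cm = 0.045, Kd_cm = 0.001;            /* calmodulin */
static const double B_tc = 0.031, Kd_tc = 0.0005;           /* troponin-C */
static const double B_cq = 10.0,  Kd_cq = 0.8;              /* calsequestrin */

void san_initparms(void (*odeparms)(int *, double *))
{
    int n = N_PARMS;
    odeparms(&n, parms);
}

void san_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    const double V = y[0], dL = y[1], fL = y[2], dT = y[3], fT = y[4];
    const double h = y[5], pa = y[6], nks = y[7], q = y[8], r = y[9];
    const double yf = y[10];
    const double Casub = fmax(y[11], 1e-8), Cai = fmax(y[12], 1e-8);
    const double CaJSR = fmax(y[13], 1e-8), CaNSR = fmax(y[14], 1e-8);

    const double E_Na = RTF * log(Nao / Nai);
    const double E_K  = RTF * log(Ko / Ki);
    const double E_Ks = RTF * log((Ko + 0.12 * Nao) / (Ki + 0.12 * Nai));
    const double E_Ca = 0.5 * RTF * log(Cao / Casub);

    /* --- gate steady states and time constants --- */
    const double dL_inf = 1.0 / (1.0 + exp(-(V + 20.3 + CA_SHIFT) / 4.2));
    const double tau_dL = 2.0;
    const double fL_inf = 1.0 / (1.0 + exp((V + 37.4) / 5.3));
    const double tau_fL = 44.0 + 230.0 * exp(-pow((V + 36.0) / 10.0, 2));
    const double fCa    = 0.00035 / (0.00035 + Casub);

    const double dT_inf = 1.0 / (1.0 + exp(-(V + 38.3 + CA_SHIFT) / 5.5));
    const double tau_dT = 1.0;
    const double fT_inf = 1.0 / (1.0 + exp((V + 58.7) / 3.8));
    const double tau_fT = 8.0 + 40.0 * exp(-pow((V + 50.0) / 15.0, 2));

    const double m_inf  = 1.0 / (1.0 + exp(-(V + 36.0) / 5.0));
    const double h_inf  = 1.0 / (1.0 + exp((V + 66.0) / 6.0));
    const double tau_h  = 1.0 + 25.0 * exp(-pow((V + 70.0) / 20.0, 2));

    const double pa_inf = 1.0 / (1.0 + exp(-(V + 21.5) / 7.5));
    const double tau_pa = 30.0 + 300.0 * exp(-pow((V + 25.0) / 25.0, 2));
    const double pi_inf = 1.0 / (1.0 + exp((V + 28.6) / 17.1));

    const double n_inf  = 1.0 / (1.0 + exp(-(V - 10.0) / 14.0));
    const double tau_n  = 300.0 + 500.0 * exp(-pow((V + 30.0) / 30.0, 2));

    const double q_inf  = 1.0 / (1.0 + exp((V + 49.0) / 13.0));
    const double tau_q  = 6.0 + 50.0 * exp(-pow((V + 44.0) / 15.0, 2));
    const double r_inf  = 1.0 / (1.0 + exp(-(V - 5.0) / 14.0));
    const double tau_r  = 2.5 + 10.0 * exp(-pow((V + 30.0) / 20.0, 2));

    const double y_inf  = 1.0 / (1.0 + exp((V + 80.0 - Y_SHIFT) / 9.0));
    const double tau_y  = 100.0 + 700.0 * exp(-pow((V + 95.0) / 30.0, 2));

    /* --- membrane currents, pA/pF --- */
    const double ICaL = G_CaL * dL * fL * fCa * (V - 45.0);
    const double ICaT = G_CaT * dT * fT * (V - 45.0);
    const double INa  = G_Na * m_inf * m_inf * m_inf * h * (V - E_Na);
    const double If   = G_f * yf * (V + 30.0);
    const double IKr  = G_Kr * pa * pi_inf * (V - E_K);
    const double IKs  = G_Ks * nks * nks * (V - E_Ks);
    const double Ito  = G_to * q * r * (V - E_K);
    const double Isus = G_sus * r * (V - E_K);

    /* acetylcholine-activated K+ current: Hill activation by the agonist
     * dose (carbachol, uM) with inward rectification */
    double act = 0.0;
    if (CCH_DOSE > 0.0) {
        const double dh = pow(CCH_DOSE, KACH_HILL);
        act = dh / (dh + pow(KACH_K05, KACH_HILL));
    }
    const double rect  = 1.0 / (1.0 + exp((V + 40.0) / 12.0));
    const double IKACh = G_KACh * act * rect * (V - E_K);

    const double sigma = (exp(Nao / 67.3) - 1.0) / 7.0;
    const double fNaK  = 1.0 / (1.0 + 0.1245 * exp(-0.1 * V / RTF)
                                + 0.0365 * sigma * exp(-V / RTF));
    const double INaK  = P_NaK * fNaK * (Ko / (Ko + 1.4))
                         * pow(Nai, 1.5) / (pow(Nai, 1.5) + pow(14.0, 1.5));

    const double ex1  = exp(0.5 * V / RTF), ex2 = exp(-0.5 * V / RTF);
    const double Nai3 = Nai * Nai * Nai, Nao3 = Nao * Nao * Nao;
    const double INCX = v_NCX * (Nai3 * Cao * ex1 - Nao3 * Casub * ex2)
                        / (1.0 + 0.0001 * (Nao3 * Casub + Nai3 * Cao));

    const double IbNa = G_bNa * (V - E_Na);
    const double IbCa = G_bCa * (V - E_Ca);

    const double Itot = ICaL + ICaT + INa + If + IKr + IKs + Ito + Isus
                        + IKACh + INaK + INCX + IbNa + IbCa;

    /* --- sarcoplasmic-reticulum Ca fluxes, mM/ms --- */
    const double relact = Casub * Casub / (Casub * Casub + K_rel * K_rel);
    const double j_rel  = v_RyR * (CaJSR - Casub) * relact;
    const double j_up   = v_up * Cai * Cai / (Cai * Cai + K_up * K_up);
    const double j_tr   = (CaNSR - CaJSR) / tau_tr;
    const double j_dif  = (Casub - Cai) / tau_dif;

    /* instantaneous buffering factors */
    const double b_sub = 1.0 / (1.0 + B_cm * Kd_cm / pow(Kd_cm + Casub, 2));
    const double b_i   = 1.0 / (1.0 + B_cm * Kd_cm / pow(Kd_cm + Cai, 2)
                                + B_tc * Kd_tc / pow(Kd_tc + Cai, 2));
    const double b_jsr = 1.0 / (1.0 + B_cq * Kd_cq / pow(Kd_cq + CaJSR, 2));

    ydot[0]  = -Itot;
    ydot[1]  = (dL_inf - dL) / tau_dL;
    ydot[2]  = (fL_inf - fL) / tau_fL;
    ydot[3]  = (dT_inf - dT) / tau_dT;
    ydot[4]  = (fT_inf - fT) / tau_fT;
    ydot[5]  = (h_inf - h) / tau_h;
    ydot[6]  = (pa_inf - pa) / tau_pa;
    ydot[7]  = (n_inf - nks) / tau_n;
    ydot[8]  = (q_inf - q) / tau_q;
    ydot[9]  = (r_inf - r) / tau_r;
    ydot[10] = (y_inf - yf) / tau_y;
    ydot[11] = b_sub * (-(ICaL + ICaT + IbCa - 2.0 * INCX) * Cm
                        / (2.0 * FARADAY * Vsub)
                        + j_rel * Vjsr / Vsub - j_dif);
    ydot[12] = b_i * (j_dif * Vsub / Vi - j_up * Vnsr / Vi);
    ydot[13] = b_jsr * (j_tr - j_rel);
    ydot[14] = j_up - j_tr * Vjsr / Vnsr;
}
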