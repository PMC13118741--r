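/* Coupled PK + folate + EGFR + tumour growth inhibition ODE system,
 * deSolve compiled-model interface.
 *
 * State vector (15):
 *  0 Xpem_a  1 Xpem_1  2 Xpem_2   PEM amounts, mg/kg
 *  3 Xosi_a  4 Xosi_1  5 Xosi_2   OSI amounts, mg/kg
 *  6 Enzyme  7 Folate  8 EGFR     normalised (baseline 1)
 *  9 X1  10 X2  11 X3  12 X4      tumour sub-volumes, mm3
 * 13 CumDead                      cumulative killed volume, mm3
 * 14 CumGrowth                    cumulative grown volume, mm3 (mass-balance audit)
 *
 * Parameters (35), all rates per hour:
 *  0 ka_pem 1 V1_pem 2 k12_pem 3 k21_pem 4 kel_pem 5 F_pem
 *  6 ka_osi 7 Fa_osi 8 V1_osi 9 k12_osi 10 k21_osi 11 kel_osi
 * 12 kout_enzyme 13 kout_folate 14 Emax_pem 15 EC50_pem 16 gamma_enzyme
 * 17 kout_EGFR 18 Imax_osi 19 EC50_osi 20 gamma_osi 21 k_feedback 22 gamma_feedback
 * 23 lambda0 24 lambda1 25 psi 26 k1 27 k2 28 Emax_folate 29 EC50_folate
 * 30 gamma_folate 31 gamma_EGFR 32 gamma_G1 33 kbim 34 gamma_bim
 */

#include <R.h>
#include <math.h>

#define NPAR 35
static double p[NPAR];

void pemosi_init(void (*odeparms)(int *, double *))
{
    int n = NPAR;
    odeparms(&n, p);
}

static double pos(double x) { return x > 0.0 ? x : 0.0; }

/* (1 + r^psi)^(1/psi), overflow-safe for large r */
static double simeoni_switch(double r, double psi)
{
    if (r <= 0.0) return 1.0;
    if (r <= 1.0) return pow(1.0 + pow(r, psi), 1.0 / psi);
    return r * pow(1.0 + pow(r, -psi), 1.0 / psi);
}

void pemosi_derivs(int *neq, double *t, double *y, double *ydot,
                   double *yout, int *ip)
{
    const double ka_pem = p[0], V1_pem = p[1], k12_pem = p[2], k21_pem = p[3],
        kel_pem = p[4];
    const double ka_osi = p[6], Fa_osi = p[7], V1_osi = p[8], k12_osi = p[9],
        k21_osi = p[10], kel_osi = p[11];
    const double kout_enz = p[12], kout_fol = p[13], Emax_pem = p[14],
        EC50_pem = p[15], g_enz = p[16];
    const double kout_EGFR = p[17], Imax_osi = p[18], EC50_osi = p[19],
        g_osi = p[20], k_fb = p[21], g_fb = p[22];
    const double lambda0 = p[23], lambda1 = p[24], psi = p[25], k1 = p[26],
        k2 = p[27], Emax_fol = p[28], EC50_fol = p[29], g_fol = p[30],
        g_EGFR = p[31], g_G1 = p[32], kbim = p[33], g_bim = p[34];

    /* plasma concentrations: PEM mg/L, OSI ug/L (x1000 from mg/L) */
    double Cpem = pos(y[1]) / V1_pem;
    double Cosi = pos(y[4]) / (V1_osi / Fa_osi) * 1000.0;

    /* PEM two-compartment, first-order absorption (i.p., F = 1 in input) */
    ydot[0] = -ka_pem * y[0];
    ydot[1] = ka_pem * y[0] - k12_pem * y[1] + k21_pem * y[2] - kel_pem * y[1];
    ydot[2] = k12_pem * y[1] - k21_pem * y[2];

    /* OSI two-compartment, oral; Fa scales absorption */
    ydot[3] = -Fa_osi * ka_osi * y[3];
    ydot[4] = Fa_osi * ka_osi * y[3] - k12_osi * y[4] + k21_osi * y[5]
        - kel_osi * y[4];
    ydot[5] = k12_osi * y[4] - k21_osi * y[5];

    /* folate module: PEM stimulates enzyme loss; folate synthesis tracks enzyme */
    double Enz = pos(y[6]), Fol = pos(y[7]);
    double stim_pem = 1.0 + Emax_pem * Cpem / (EC50_pem + Cpem);
    ydot[6] = kout_enz - kout_enz * y[6] * stim_pem;
    ydot[7] = pow(Enz, g_enz) * kout_fol - kout_fol * y[7];

    /* EGFR module: OSI stimulates loss; damaged fraction feeds back on synthesis */
    double X1 = pos(y[9]), X2 = pos(y[10]), X3 = pos(y[11]), X4 = pos(y[12]);
    double X = X1 + X2 + X3 + X4;
    double damaged = X > 0.0 ? (X2 + X3 + X4) / X : 0.0;
    double cg = pow(Cosi, g_osi);
    double stim_osi = 1.0 + Imax_osi * cg / (pow(EC50_osi, g_osi) + cg);
    double EGFR = pos(y[8]);
    ydot[8] = kout_EGFR * (1.0 + k_fb * pow(damaged, g_fb))
        - kout_EGFR * y[8] * stim_osi;

    /* tumour module (extended Simeoni) */
    double growth = lambda0 * X1 * pow(EGFR, g_EGFR)
        / simeoni_switch(lambda0 / lambda1 * X, psi);
    double D = pos(1.0 - Fol);
    double dg = pow(D, g_fol);
    double kill_amp = 1.0 + Emax_fol * dg / (pow(EC50_fol, g_fol) + dg);
    double egfr_gate = EGFR < 1.0 ? pow(EGFR, g_G1) : 1.0; /* G1 arrest gate saturates at baseline */
    double flux12 = k1 * X1 * kill_amp * egfr_gate; /* shared X1->X2 flux */
    double bim = 1.0 + kbim * pow(pos(1.0 - EGFR), g_bim);
    double k2b = k2 * bim;

    ydot[9]  = growth - flux12;
    ydot[10] = flux12 - k2b * X2;
    ydot[11] = k2b * X2 - k2b * X3;
    ydot[12] = k2b * X3 - k2b * X4;
    ydot[13] = k2b * X4;      /* total dead */
    ydot[14] = growth;        /* cumulative growth, audit only */

    if (*ip > 0) yout[0] = X;
}
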