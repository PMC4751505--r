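/* Two-compartment prostate tumor-immune ODE system.
 *
 * State order (15):
 *   0 A    androgen (relative)
 *   1 V    vaccine stimulus
 *   2 BI   anti-IL-2 antibody
 *   3 BR   anti-Treg antibody
 *   4 S    castration-sensitive tumor cells (CSPC)
 *   5 R    castration-resistant tumor cells (CRPC)
 *   6 Ag   shed tumor antigen
 *   7 DL   functional dendritic cells, lymphoid
 *   8 DrL  regulatory dendritic cells, lymphoid
 *   9 CL   CTL, lymphoid
 *  10 GL   Treg, lymphoid
 *  11 IL   IL-2, lymphoid
 *  12 CP   CTL, prostate
 *  13 GP   Treg, prostate
 *  14 IP   IL-2, prostate
 *
 * Parameter order (34): the 25 estimated rate constants in their canonical
 * 1..25 indexing, then the fixed constants delta_A, delta_V, delta_BI,
 * delta_BR, kappa, kappa_AI, kappa_AR, delta_I, and the castration
 * indicator chi_cx (1 iff the regimen includes CX).
 */
#include <R.h>

static double parms[34];

#define rho_S    parms[0]
#define delta_S  parms[1]
#define lambda_  parms[2]
#define rho_R    parms[3]
#define delta_R  parms[4]
#define eta_S    parms[5]
#define eta_R    parms[6]
#define theta_A  parms[7]
#define sigma_Ag parms[8]
#define delta_Ag parms[9]
#define alpha_D  parms[10]
#define omega_V  parms[11]
#define delta_D  parms[12]
#define alpha_Dr parms[13]
#define delta_Dr parms[14]
#define alpha_C  parms[15]
#define beta_I   parms[16]
#define xi_C     parms[17]
#define mu_C     parms[18]
#define tau_C    parms[19]
#define alpha_G  parms[20]
#define zeta_    parms[21]
#define mu_G     parms[22]
#define tau_G    parms[23]
#define sigma_I  parms[24]
#define delta_A  parms[25]
#define delta_V  parms[26]
#define delta_BI parms[27]
#define delta_BR parms[28]
#define kappa    parms[29]
#define kappa_AI parms[30]
#define kappa_AR parms[31]
#define delta_I  parms[32]
#define chi_cx   parms[33]

void prostimm_initmod(void (*odeparms)(int *, double *))
{
    int n = 34;
    odeparms(&n, parms);
}

static void rhs_one(const double *y, double *ydot, double chi)
{
    double A = y[0], V = y[1], BI = y[2], BR = y[3];
    double S = y[4], Rr = y[5], Ag = y[6];
    double DL = y[7], DrL = y[8], CL = y[9], GL = y[10], IL = y[11];
    double CP = y[12], GP = y[13], IP = y[14];

    double h = A / (theta_A + A);
    double cap = 1.0 - (S + Rr) / kappa;
    double stim = Ag + omega_V * V;

    ydot[0] = -delta_A * chi * A;
    ydot[1] = -delta_V * V;
    ydot[2] = -delta_BI * BI;
    ydot[3] = -delta_BR * BR;
    ydot[4] = rho_S * h * S * cap - delta_S * S
              - lambda_ * (1.0 - h) * S - eta_S * CP * S;
    ydot[5] = rho_R * Rr * cap - delta_R * Rr
              + lambda_ * (1.0 - h) * S - eta_R * CP * Rr;
    ydot[6] = sigma_Ag * (delta_S * S + delta_R * Rr
              + eta_S * CP * S + eta_R * CP * Rr) - delta_Ag * Ag;
    ydot[7] = alpha_D * stim - delta_D * DL;
    ydot[8] = alpha_Dr * stim * GL - delta_Dr * DrL;
    ydot[9] = alpha_C * DL * (1.0 + beta_I * IL)
              - xi_C * GL * CL - mu_C * CL - tau_C * CL;
    ydot[10] = alpha_G * IL * GL + zeta_ * DrL
               - mu_G * GL - tau_G * GL - kappa_AR * BR * GL;
    ydot[11] = sigma_I * CL - delta_I * IL - kappa_AI * BI * IL;
    ydot[12] = tau_C * CL - xi_C * GP * CP - mu_C * CP;
    ydot[13] = tau_G * GL + alpha_G * IP * GP - mu_G * GP
               - kappa_AR * BR * GP;
    ydot[14] = sigma_I * CP - delta_I * IP - kappa_AI * BI * IP;
}

void prostimm_derivs(int *neq, double *t, double *y, double *ydot,
                     double *yout, int *ip)
{
    rhs_one(y, ydot, chi_cx);
}

/* Stacked variant used by the calibration objective: up to 16 independent
 * copies of the system (one per treatment condition) integrated together
 * so one solver call evaluates every condition. Parameter layout:
 * parms[0..32] as above (chi_cx slot unused), parms[33] = number of
 * conditions n, parms[34..34+n-1] = per-condition castration flags. */
static double mparms[50];

void prostimm_initmod_multi(void (*odeparms)(int *, double *))
{
    int n = 50;
    odeparms(&n, mparms);
}

void prostimm_derivs_multi(int *neq, double *t, double *y, double *ydot,
                           double *yout, int *ip)
{
    int k, n = (int) mparms[33];
    for (k = 0; k < 34; k++) parms[k] = mparms[k];
    for (k = 0; k < n; k++)
        rhs_one(y + 15 * k, ydot + 15 * k, mparms[34 + k]);
}
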