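/* Compiled right-hand side of the yeast-extract growth model for deSolve.
 *
 * State vector y (g/L except DOTm in % saturation and V in L):
 *   0 X, 1 S, 2 A, 3 YEFA, 4 YEFB, 5 YEFC, 6 DOTm, 7 V
 *
 * Parameter vector (see .ye_parms_vector() on the R side, same order):
 *   0..26  kinetic/yield/carbon parameters
 *   27..30 reactor constants DOT_star, kLa, H, tau
 *   31..34 flags: yefa_on, yefb_on, carbon_literal, evap_conc
 *   35..41 feed segment: mode (0 const, 1 exponential), F_const, F0,
 *          mu_set, t_ref, Si, F_evap
 *   42     glucose depletion threshold for the root function
 *   43..44 bolus pulse interval and fixed pulse volume (< 0: use the
 *          exponential-equivalent volume computed from F0, mu_set, t_ref)
 *
 * Within one integration segment the feed is either constant or a single
 * exponential; feed start/stop and step changes are handled by segment
 * restarts on the R side, bolus pulses by the compiled event function.
 */

#include <math.h>

#define N_PARMS 45

static double parms[N_PARMS];

void yem_initmod(void (*odeparms)(int *, double *))
{
    int n = N_PARMS;
    odeparms(&n, parms);
}

static double clamp0(double x) { return x > 0.0 ? x : 0.0; }

void yem_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    const double q_S_max = parms[0],  K_S = parms[1];
    const double q_YEFA_max = parms[2], K_YEFA = parms[3];
    const double q_YEFB_max = parms[4], K_YEFB = parms[5];
    const double Ki_YEFA = parms[8], Ki_YEFB = parms[9];
    const double K_qSox = parms[10], Y_AS = parms[11];
    const double q_Ac_max = parms[12], K_A = parms[13], Ki_A_S = parms[14];
    const double q_m = parms[15], Y_XS_em = parms[16];
    const double Y_X_YEFA = parms[17], Y_X_YEFB = parms[18];
    const double Y_XA = parms[19];
    const double Y_OS = parms[20], Y_OA = parms[21], Y_O_YE = parms[22];
    const double C_X = parms[23], C_S = parms[24];
    const double C_A = parms[25], C_YE = parms[26];
    const double DOT_star = parms[27], kLa = parms[28], H = parms[29];
    const double tau = parms[30];
    const int yefa_on = parms[31] > 0.5, yefb_on = parms[32] > 0.5;
    const int lit = parms[33] > 0.5, evap_conc = parms[34] > 0.5;
    const int feed_mode = (int) parms[35];
    const double F_const = parms[36], F0 = parms[37], mu_set = parms[38];
    const double t_ref = parms[39], Si = parms[40], F_evap = parms[41];

    const double X = y[0], S = y[1], A = y[2];
    const double YEFA = y[3], YEFB = y[4], YEFC = y[5];
    const double DOTm = y[6], V = y[7];

    /* clamped concentrations for rate evaluation */
    const double Xc = clamp0(X), Sc = clamp0(S), Ac = clamp0(A);
    const double YEFAc = clamp0(YEFA), YEFBc = clamp0(YEFB);

    const double q_S = q_S_max * Sc / (Sc + K_S);
    const double q_YEFA = yefa_on ?
        q_YEFA_max * YEFAc / (YEFAc + K_YEFA) : 0.0;
    const double q_YEFB = yefb_on ?
        q_YEFB_max * YEFBc / (YEFBc + K_YEFB) : 0.0;

    const double alpha = K_qSox / (K_qSox + q_S);
    const double inhib = 1.0 + q_YEFA / Ki_YEFA + q_YEFB / Ki_YEFB;
    const double q_S_ox = q_S * alpha / inhib;
    const double q_S_of = q_S - q_S_ox;

    const double q_Ap = q_S_of * Y_AS;
    const double q_Ac = q_Ac_max / (1.0 + Sc / Ki_A_S) * Ac / (Ac + K_A);
    const double q_A = q_Ap - q_Ac;

    const double mu_S = (q_S_ox - q_m) * Y_XS_em;
    const double mu_YE = q_YEFA * Y_X_YEFA + q_YEFB * Y_X_YEFB;
    const double mu_A = q_Ac * Y_XA;
    const double mu = mu_S + mu_YE + mu_A;

    const double r_A = lit ? C_A / C_S : C_X / C_A;
    const double r_YE = lit ? C_YE / C_S : C_X / C_YE;
    double q_O = Y_OS * (q_S_ox - mu_S * C_X / C_S)
               + Y_OA * (q_Ac - mu_A * r_A)
               + Y_O_YE * ((q_YEFA + q_YEFB) - mu_YE * r_YE);
    if (q_O < 0.0) q_O = 0.0;

    const double DOT = DOT_star - q_O * Xc * H / kLa;

    double F = 0.0;
    if (feed_mode == 1) {
        F = F0 * exp(mu_set * (*t - t_ref));
    } else {
        F = F_const;
    }
    const double D = F / V;
    const double E = evap_conc ? F_evap / V : 0.0;

    ydot[0] = -D * X + mu * X + E * X;                 /* biomass   */
    ydot[1] = D * (Si - S) - q_S * X + E * S;          /* glucose   */
    ydot[2] = -D * A + q_A * X + E * A;                /* acetate   */
    ydot[3] = -D * YEFA - q_YEFA * X + E * YEFA;       /* fraction A */
    ydot[4] = -D * YEFB - q_YEFB * X + E * YEFB;       /* fraction B */
    ydot[5] = -D * YEFC + E * YEFC;                    /* fraction C */
    ydot[6] = (DOT - DOTm) / tau;                      /* probe      */
    ydot[7] = F - F_evap;                              /* volume     */

    if (ip[0] >= 2) {   /* optional algebraic outputs */
        yout[0] = DOT;
        yout[1] = q_O;
    }
}

/* root function: glucose crossing the depletion threshold */
void yem_root(int *neq, double *t, double *y, int *ng, double *gout,
              double *out, int *ip)
{
    gout[0] = y[1] - parms[42];
}

/* bolus event: instantaneous perfectly mixed addition of feed volume.
 * All concentrations are diluted by V/(V+v); glucose gains v*Si/(V+v). */
void yem_bolus(int *n, double *t, double *y)
{
    const double F0 = parms[37], mu_set = parms[38], t_ref = parms[39];
    const double Si = parms[40];
    const double interval = parms[43], fixed_vol = parms[44];
    double vb;

    if (fixed_vol >= 0.0) {
        vb = fixed_vol;
    } else if (mu_set > 0.0) {
        double r1 = *t - t_ref;
        vb = (F0 / mu_set) * (exp(mu_set * (r1 + interval)) -
                              exp(mu_set * r1));
    } else {
        vb = F0 * interval;
    }

    {
        const double Vold = y[7], Vnew = Vold + vb;
        int i;
        for (i = 0; i < 6; i++) y[i] *= Vold / Vnew;
        y[1] += vb * Si / Vnew;
        y[7] = Vnew;
    }
}
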