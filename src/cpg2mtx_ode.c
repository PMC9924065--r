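/* Two-compartment MTX model with catalyst-driven Michaelis-Menten
 * decomposition, for use as a deSolve compiled right-hand side.
 *
 * States: y[0] = xc (central amount, umol)
 *         y[1] = xp (peripheral amount, umol)
 *         y[2] = cumulative renally eliminated amount (umol)
 *         y[3] = cumulative degraded amount (MM + first-order non-renal, umol)
 *
 * The CPG2 (catalyst) concentration is a closed-form one-compartment
 * infusion superposition evaluated inside the RHS, so the coupled system
 * never integrates the enzyme itself.
 *
 * Parameter vector layout (padded to CPG2MTX_NPAR on the R side):
 *   p[0] kr, p[1] k12, p[2] k21, p[3] knr_de, p[4] alpha, p[5] km,
 *   p[6] vc, p[7] cpg2 CL, p[8] cpg2 V,
 *   p[9] n CPG2 infusions, then triplets (start, end, rate mg/h),
 *   next   n MTX infusions,  then triplets (start, end, rate umol/h).
 */
#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <math.h>

#define CPG2MTX_NPAR 400

static double p[CPG2MTX_NPAR];

void cpg2mtx_init(void (*odeparms)(int *, double *))
{
    int N = CPG2MTX_NPAR;
    odeparms(&N, p);
}

void cpg2mtx_derivs(int *neq, double *t, double *y, double *ydot,
                    double *yout, int *ip)
{
    const double kr = p[0], k12 = p[1], k21 = p[2], knr = p[3];
    const double alpha = p[4], km = p[5], vc = p[6];
    const double cl2 = p[7], v2 = p[8];
    const double ke2 = cl2 / v2;
    int off = 9;
    int i, n;
    double cc = 0.0, inr = 0.0;

    /* closed-form CPG2 concentration (mg/L) */
    n = (int)(p[off++] + 0.5);
    for (i = 0; i < n; i++) {
        double t0 = p[off], t1 = p[off + 1], rate = p[off + 2];
        off += 3;
        if (*t <= t0) continue;
        {
            double te = ((*t < t1) ? *t : t1) - t0;
            double post = (*t > t1) ? (*t - t1) : 0.0;
            if (cl2 > 1e-300)
                cc += rate / cl2 * (1.0 - exp(-ke2 * te)) * exp(-ke2 * post);
            else
                cc += rate * te / v2;  /* no-elimination limit */
        }
    }

    /* active MTX infusion rate (umol/h) */
    n = (int)(p[off++] + 0.5);
    for (i = 0; i < n; i++) {
        double t0 = p[off], t1 = p[off + 1], rate = p[off + 2];
        off += 3;
        if (*t >= t0 && *t < t1) inr += rate;
    }

    {
        double xc = y[0], xp = y[1];
        double conc = xc / vc;                      /* umol/L */
        double mm = alpha * cc * conc / (km + conc); /* umol/h */
        ydot[0] = inr - (kr + knr + k12) * xc + k21 * xp - mm;
        ydot[1] = k12 * xc - k21 * xp;
        ydot[2] = kr * xc;
        ydot[3] = mm + knr * xc;
    }

    if (ip[0] >= 1) yout[0] = cc;
}

static const R_CMethodDef CEntries[] = {
    {"cpg2mtx_init",   (DL_FUNC) &cpg2mtx_init,   1},
    {"cpg2mtx_derivs", (DL_FUNC) &cpg2mtx_derivs, 6},
    {NULL, NULL, 0}
};

void R_init_cpg2mtx(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
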