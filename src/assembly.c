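/* Moment equations for nucleation-dependent amyloid assembly.
 *
 * State y = (P, M): fibril number and fibril mass concentration (monomer
 * equivalents), both in molar.  Free monomer m = m_total - M by mass
 * conservation.  Parameters are passed through the deSolve parms mechanism:
 *
 *   parms = (k_n, k_plus, k_2, K_M, k_minus, n_c, n_2, m_total)
 *
 * K_M <= 0 encodes "no saturation" (single-step secondary nucleation);
 * the nested simpler models are obtained by zeroing rate constants.
 */
#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <math.h>

static double parms[8];
#define k_n    parms[0]
#define k_plus parms[1]
#define k_2    parms[2]
#define K_M    parms[3]
#define k_min  parms[4]
#define n_c    parms[5]
#define n_2    parms[6]
#define m_tot  parms[7]

void assembly_init(void (*odeparms)(int *, double *))
{
    int n = 8;
    odeparms(&n, parms);
}

void assembly_derivs(int *neq, double *t, double *y, double *ydot,
                     double *yout, int *ip)
{
    double P = y[0], M = y[1];
    double m = m_tot - M;
    if (m < 0.0) m = 0.0;
    if (P < 0.0) P = 0.0;

    double mn2 = (m > 0.0) ? pow(m, n_2) : 0.0;
    double sat = 1.0;
    if (K_M > 0.0 && R_FINITE(K_M))
        sat = 1.0 / (1.0 + mn2 / K_M);

    double prim = (m > 0.0) ? k_n * pow(m, n_c) : 0.0;

    ydot[0] = prim + k_min * M + k_2 * mn2 * M * sat;
    ydot[1] = 2.0 * k_plus * m * P;
}

static const R_CMethodDef CEntries[] = {
    {"assembly_init",   (DL_FUNC) &assembly_init,   1},
    {"assembly_derivs", (DL_FUNC) &assembly_derivs, 6},
    {NULL, NULL, 0}
};

void R_init_amylokin(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
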