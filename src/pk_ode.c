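/* Three-compartment disposition model with parallel linear and
 * Michaelis-Menten elimination from the central compartment, one-way
 * flow V2 -> V3 and slow return V3 -> V1.  deSolve compiled-model
 * convention: parameters are pushed in via the init function, the
 * (piecewise-constant) infusion rate is passed as the last parameter and
 * integration is restarted at every rate/parameter breakpoint from R.
 *
 * States (mg): y0 = A1 central, y1 = A2 peripheral-1, y2 = A3 peripheral-2.
 * Concentrations ug/mL == mg/L.
 */
#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

static double parms[10];
#define P_CL   parms[0]
#define P_V1   parms[1]
#define P_VMAX parms[2]
#define P_KM   parms[3]
#define P_Q2   parms[4]
#define P_V2   parms[5]
#define P_Q3   parms[6]
#define P_V3   parms[7]
#define P_QPC  parms[8]
#define P_RATE parms[9]

void pk_initmod(void (*odeparms)(int *, double *))
{
    int N = 10;
    odeparms(&N, parms);
}

void pk_derivs(int *neq, double *t, double *y, double *ydot,
               double *yout, int *ip)
{
    double c1 = y[0] / P_V1;
    double c2 = y[1] / P_V2;
    double c3 = y[2] / P_V3;
    /* saturable term only defined for positive concentrations; guard the
       Km + c1 singularity against small negative numerical excursions */
    double mm = c1 > 0 ? P_VMAX * c1 / (P_KM + c1) : 0.0;

    ydot[0] = P_RATE - P_CL * c1 - mm
              - P_Q2 * c1 + P_Q2 * c2 + P_QPC * c3;
    ydot[1] = P_Q2 * c1 - P_Q2 * c2 - P_Q3 * c2;
    ydot[2] = P_Q3 * c2 - P_QPC * c3;
}

static const R_CMethodDef CEntries[] = {
    {"pk_initmod", (DL_FUNC) &pk_initmod, 1},
    {"pk_derivs",  (DL_FUNC) &pk_derivs,  6},
    {NULL, NULL, 0}
};

SEXP pk_sim_c(SEXP, SEXP, SEXP, SEXP, SEXP, SEXP, SEXP, SEXP);

static const R_CallMethodDef CallEntries[] = {
    {"pk_sim_c", (DL_FUNC) &pk_sim_c, 8},
    {NULL, NULL, 0}
};

void R_init_avalpk(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, CallEntries, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
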