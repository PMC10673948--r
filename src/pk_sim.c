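/* Fast piecewise simulation of the three-compartment model: adaptive
 * Dormand-Prince 5(4) within each piecewise-constant segment, restarted
 * exactly at every rate/parameter breakpoint, landing exactly on the
 * requested output times.  One .Call per subject simulation; used in the
 * estimation / VPC inner loops where the R-level per-segment solver call
 * overhead would dominate.  Cross-checked against the lsoda path in the
 * test suite.
 */
#include <R.h>
#include <Rinternals.h>
#include <math.h>

typedef struct {
    double cl, v1, vmax, km, q2, v2, q3, v3, qpc, rate;
} pkpar;

static void rhs(const pkpar *p, const double *y, double *dy)
{
    double c1 = y[0] / p->v1;
    double c2 = y[1] / p->v2;
    double c3 = y[2] / p->v3;
    double mm = c1 > 0 ? p->vmax * c1 / (p->km + c1) : 0.0;
    dy[0] = p->rate - p->cl * c1 - mm - p->q2 * c1 + p->q2 * c2 + p->qpc * c3;
    dy[1] = p->q2 * c1 - p->q2 * c2 - p->q3 * c2;
    dy[2] = p->q3 * c2 - p->qpc * c3;
}

/* Dormand-Prince 5(4) coefficients */
static const double
    a21 = 1.0/5,
    a31 = 3.0/40, a32 = 9.0/40,
    a41 = 44.0/45, a42 = -56.0/15, a43 = 32.0/9,
    a51 = 19372.0/6561, a52 = -25360.0/2187, a53 = 64448.0/6561,
    a54 = -212.0/729,
    a61 = 9017.0/3168, a62 = -355.0/33, a63 = 46732.0/5247,
    a64 = 49.0/176, a65 = -5103.0/18656,
    b1 = 35.0/384, b3 = 500.0/1113, b4 = 125.0/192,
    b5 = -2187.0/6784, b6 = 11.0/84,
    e1 = 35.0/384 - 5179.0/57600, e3 = 500.0/1113 - 7571.0/16695,
    e4 = 125.0/192 - 393.0/640, e5 = -2187.0/6784 + 92097.0/339200,
    e6 = 11.0/84 - 187.0/2100, e7 = -1.0/40;

/* integrate one segment from t to tend; y updated in place; returns 0 ok */
static int dp45(const pkpar *p, double *y, double t, double tend,
                double rtol, double atol, double *hinit)
{
    double k1[3], k2[3], k3[3], k4[3], k5[3], k6[3], k7[3];
    double yt[3], ynew[3], err[3];
    double h = *hinit;
    long nstep = 0;
    if (h <= 0 || h > tend - t) h = tend - t;
    rhs(p, y, k1);
    while (t < tend - 1e-12) {
        if (t + h > tend) h = tend - t;
        for (int i = 0; i < 3; i++) yt[i] = y[i] + h * a21 * k1[i];
        rhs(p, yt, k2);
        for (int i = 0; i < 3; i++)
            yt[i] = y[i] + h * (a31 * k1[i] + a32 * k2[i]);
        rhs(p, yt, k3);
        for (int i = 0; i < 3; i++)
            yt[i] = y[i] + h * (a41 * k1[i] + a42 * k2[i] + a43 * k3[i]);
        rhs(p, yt, k4);
        for (int i = 0; i < 3; i++)
            yt[i] = y[i] + h * (a51 * k1[i] + a52 * k2[i] + a53 * k3[i]
                                + a54 * k4[i]);
        rhs(p, yt, k5);
        for (int i = 0; i < 3; i++)
            yt[i] = y[i] + h * (a61 * k1[i] + a62 * k2[i] + a63 * k3[i]
                                + a64 * k4[i] + a65 * k5[i]);
        rhs(p, yt, k6);
        for (int i = 0; i < 3; i++)
            ynew[i] = y[i] + h * (b1 * k1[i] + b3 * k3[i] + b4 * k4[i]
                                  + b5 * k5[i] + b6 * k6[i]);
        rhs(p, ynew, k7);
        double enorm = 0.0;
        for (int i = 0; i < 3; i++) {
            err[i] = h * (e1 * k1[i] + e3 * k3[i] + e4 * k4[i]
                          + e5 * k5[i] + e6 * k6[i] + e7 * k7[i]);
            double sc = atol + rtol * fmax(fabs(y[i]), fabs(ynew[i]));
            double r = err[i] / sc;
            enorm += r * r;
        }
        enorm = sqrt(enorm / 3.0);
        if (!R_FINITE(enorm)) return 1;
        if (enorm <= 1.0) {                    /* accept (FSAL) */
            t += h;
            for (int i = 0; i < 3; i++) { y[i] = ynew[i]; k1[i] = k7[i]; }
        }
        double fac = enorm > 0 ? 0.9 * pow(enorm, -0.2) : 5.0;
        if (fac < 0.2) fac = 0.2;
        if (fac > 5.0) fac = 5.0;
        h *= fac;
        if (h < 1e-12) return 1;
        if (++nstep > 5000000L) return 1;
    }
    *hinit = h;
    return 0;
}

/* .Call entry: segments (t0, t1, rate vectors; pars nseg x 9 matrix),
 * sorted output times, init state, tolerances.  Returns (nout + 1) x 3
 * matrix of amounts; the extra final row is the state at the last segment
 * end. */
SEXP pk_sim_c(SEXP s_t0, SEXP s_t1, SEXP s_rate, SEXP s_pars, SEXP s_times,
              SEXP s_init, SEXP s_rtol, SEXP s_atol)
{
    int nseg = LENGTH(s_t0);
    int nout = LENGTH(s_times);
    double *t0 = REAL(s_t0), *t1 = REAL(s_t1), *rate = REAL(s_rate);
    double *pm = REAL(s_pars), *tout = REAL(s_times);
    double rtol = asReal(s_rtol), atol = asReal(s_atol);
    double y[3] = { REAL(s_init)[0], REAL(s_init)[1], REAL(s_init)[2] };

    SEXP ans = PROTECT(allocMatrix(REALSXP, nout + 1, 3));
    double *out = REAL(ans);
    int iout = 0;

    for (int s = 0; s < nseg; s++) {
        pkpar p = { pm[s], pm[s + nseg], pm[s + 2 * nseg], pm[s + 3 * nseg],
                    pm[s + 4 * nseg], pm[s + 5 * nseg], pm[s + 6 * nseg],
                    pm[s + 7 * nseg], pm[s + 8 * nseg], rate[s] };
        double t = t0[s];
        double h = 0.0;
        if (iout < nout && tout[iout] <= t + 1e-12) {
            /* output exactly at segment start */
            while (iout < nout && tout[iout] <= t + 1e-12) {
                for (int i = 0; i < 3; i++) out[iout + i * (nout + 1)] = y[i];
                iout++;
            }
        }
        while (iout < nout && tout[iout] <= t1[s] + 1e-12) {
            double target = fmin(tout[iout], t1[s]);
            if (dp45(&p, y, t, target, rtol, atol, &h)) {
                UNPROTECT(1);
                error("ODE integration failed in segment %d near t = %g h",
                      s + 1, t);
            }
            t = target;
            for (int i = 0; i < 3; i++) out[iout + i * (nout + 1)] = y[i];
            iout++;
        }
        if (t < t1[s] - 1e-12) {
            if (dp45(&p, y, t, t1[s], rtol, atol, &h)) {
                UNPROTECT(1);
                error("ODE integration failed in segment %d near t = %g h",
                      s + 1, t);
            }
        }
    }
    for (int i = 0; i < 3; i++) out[nout + i * (nout + 1)] = y[i];
    UNPROTECT(1);
    return ans;
}
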