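/* Compiled RHS for the general Gompertz model, dV/dt = V^lambda (delta -
 * gamma log V), in deSolve's compiled-model convention. The state is
 * clamped to [1e-9, 1e2]: below the floor the logarithm is undefined
 * (lesions can reach volume 0), and far above the physical range (volumes
 * are normalized to about [0, 1]) unbounded growth only makes the problem
 * stiff for parameter candidates that the fit will reject anyway.
 */
#include <R.h>
#include <math.h>
#include <R_ext/Rdynload.h>

static double parms[3]; /* gamma, delta, lambda */

void tg_ggompertz_init(void (*odeparms)(int *, double *))
{
    int n = 3;
    odeparms(&n, parms);
}

void tg_ggompertz_rhs(int *neq, double *t, double *y, double *ydot,
                      double *yout, int *ip)
{
    double v = y[0];
    if (v < 1e-9) v = 1e-9;
    if (v > 1e2)  v = 1e2;
    ydot[0] = pow(v, parms[2]) * (parms[1] - parms[0] * log(v));
    if (y[0] >= 1e2 && ydot[0] > 0) ydot[0] = 0;
    if (y[0] <= 1e-9 && ydot[0] < 0) ydot[0] = 0;
}

static const R_CMethodDef CEntries[] = {
    {"tg_ggompertz_init", (DL_FUNC) &tg_ggompertz_init, 1},
    {"tg_ggompertz_rhs",  (DL_FUNC) &tg_ggompertz_rhs,  6},
    {NULL, NULL, 0}
};

void R_init_tumorgrowth(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
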