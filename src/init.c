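#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

SEXP C_nfkb_rhs(SEXP ySEXP, SEXP tSEXP, SEXP pSEXP);
void nfkb_initmod(void (*odeparms)(int *, double *));
void nfkb_derivs(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip);

static const R_CallMethodDef callMethods[] = {
    {"C_nfkb_rhs", (DL_FUNC) &C_nfkb_rhs, 3},
    {NULL, NULL, 0}
};

void R_init_nfkbswitch(DllInfo *info)
{
    R_registerRoutines(info, NULL, callMethods, NULL, NULL);
    /* deSolve looks the model functions up by name */
    R_useDynamicSymbols(info, TRUE);
}
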