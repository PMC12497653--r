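#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

SEXP C_conv1d_fwd(SEXP xs, SEXP ws, SEXP bs);
SEXP C_conv1d_bwd(SEXP xs, SEXP ws, SEXP dys);

static const R_CallMethodDef CallEntries[] = {
    {"C_conv1d_fwd", (DL_FUNC) &C_conv1d_fwd, 3},
    {"C_conv1d_bwd", (DL_FUNC) &C_conv1d_bwd, 3},
    {NULL, NULL, 0}
};

void R_init_holomap(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, CallEntries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
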