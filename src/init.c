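#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

SEXP C_gdiff_mpfr(SEXP y0_, SEXP yL_, SEXP h_, SEXP a_, SEXP sigma_, SEXP prec_);

static const R_CallMethodDef CallEntries[] = {
    {"C_gdiff_mpfr", (DL_FUNC) &C_gdiff_mpfr, 6},
    {NULL, NULL, 0}
};

void R_init_rodsphere(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, CallEntries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
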