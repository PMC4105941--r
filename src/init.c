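#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

SEXP C_mass_action_deriv(SEXP, SEXP, SEXP, SEXP, SEXP, SEXP, SEXP);
SEXP C_mass_action_rates(SEXP, SEXP, SEXP, SEXP, SEXP);

static const R_CallMethodDef CallEntries[] = {
    {"C_mass_action_deriv", (DL_FUNC) &C_mass_action_deriv, 7},
    {"C_mass_action_rates", (DL_FUNC) &C_mass_action_rates, 5},
    {NULL, NULL, 0}
};

void R_init_tgfsmad(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, CallEntries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
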