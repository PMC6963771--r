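#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

SEXP top_eigen_sym(SEXP A, SEXP kk);

static const R_CallMethodDef CallEntries[] = {
    {"top_eigen_sym", (DL_FUNC) &top_eigen_sym, 2},
    {NULL, NULL, 0}
};

void R_init_ensembleproj(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, CallEntries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
    R_forceSymbols(dll, TRUE);
}
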