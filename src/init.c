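#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

SEXP C_set_model(SEXP enc);
SEXP C_signal_eval(SEXP enc, SEXP t);
SEXP C_rates_eval(SEXP enc, SEXP y, SEXP s);
SEXP C_cle_path(SEXP enc, SEXP y0, SEXP dt, SEXP st, SEXP noise, SEXP policy);
SEXP C_cle_ensemble(SEXP enc, SEXP y0, SEXP dt, SEXP st, SEXP noise,
                    SEXP policy, SEXP nrep, SEXP out_idx, SEXP max_retry);

void hub_init(void (*odeparms)(int *, double *));
void hub_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip);

static const R_CallMethodDef call_methods[] = {
    {"C_set_model",    (DL_FUNC) &C_set_model,    1},
    {"C_signal_eval",  (DL_FUNC) &C_signal_eval,  2},
    {"C_rates_eval",   (DL_FUNC) &C_rates_eval,   3},
    {"C_cle_path",     (DL_FUNC) &C_cle_path,     6},
    {"C_cle_ensemble", (DL_FUNC) &C_cle_ensemble, 9},
    {NULL, NULL, 0}
};

/* hub_derivs / hub_init are looked up by name from deSolve */
static const R_CMethodDef c_methods[] = {
    {"hub_derivs", (DL_FUNC) &hub_derivs, 0},
    {"hub_init",   (DL_FUNC) &hub_init,   0},
    {NULL, NULL, 0}
};

void R_init_hubsens(DllInfo *dll)
{
    R_registerRoutines(dll, c_methods, call_methods, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
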