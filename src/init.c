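#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

void ord_initmod(void (*odeparms)(int *, double *));
void ord_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip);
void c_ord_rhs(double *t, double *y, double *p, double *dy, double *aux);

static const R_CMethodDef CEntries[] = {
  {"c_ord_rhs", (DL_FUNC) &c_ord_rhs, 5},
  {NULL, NULL, 0}
};

void R_init_cardiomd(DllInfo *dll)
{
  R_registerRoutines(dll, CEntries, NULL, NULL, NULL);
  R_useDynamicSymbols(dll, TRUE);
  /* ord_initmod / ord_derivs are looked up by deSolve via their names,
   * so dynamic symbol lookup must stay enabled. */
  R_RegisterCCallable("cardiomd", "ord_derivs", (DL_FUNC) &ord_derivs);
  R_RegisterCCallable("cardiomd", "ord_initmod", (DL_FUNC) &ord_initmod);
}
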