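#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

/* Rcpp attribute exports (RcppExports.cpp) */
extern SEXP _nvucvr_cpp_pencil_zeros(SEXP, SEXP, SEXP, SEXP);
extern SEXP _nvucvr_cpp_lyap(SEXP, SEXP);

/* deSolve compiled-model entry points (nvu_core.c) */
extern void nvu_initmod(void (*)(int *, double *));
extern void nvu_initforc(void (*)(int *, double *));
extern void nvu_derivs_c(int *, double *, double *, double *, double *, int *);
extern void nvu_derivs_direct(double *, double *, double *, double *);

static const R_CallMethodDef CallEntries[] = {
  {"_nvucvr_cpp_pencil_zeros", (DL_FUNC) &_nvucvr_cpp_pencil_zeros, 4},
  {"_nvucvr_cpp_lyap",         (DL_FUNC) &_nvucvr_cpp_lyap,         2},
  {NULL, NULL, 0}
};

/* deSolve looks these up by name with getNativeSymbolInfo(); registering
 * them as C routines keeps the lookup working with dynamic symbols off */
static const R_CMethodDef CEntries[] = {
  {"nvu_initmod",  (DL_FUNC) &nvu_initmod,  1},
  {"nvu_initforc", (DL_FUNC) &nvu_initforc, 1},
  {"nvu_derivs_c", (DL_FUNC) &nvu_derivs_c, 6},
  {"nvu_derivs_direct", (DL_FUNC) &nvu_derivs_direct, 4},
  {NULL, NULL, 0}
};

void R_init_nvucvr(DllInfo *dll) {
  R_registerRoutines(dll, CEntries, CallEntries, NULL, NULL);
  R_useDynamicSymbols(dll, FALSE);
}
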