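/* Generic mass-action derivative for the coagulation network.
 *
 * The reaction scheme is data-driven, so the stoichiometry matrix, rate
 * constants and reactant indices are staged from R via C_set_scheme() before
 * each integration and read by the deSolve-callable derivative. At most two
 * reactants per reaction (every reaction in the cascade is uni- or
 * bimolecular); a zero second index means unimolecular.
 */
#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

static SEXP stage = NULL; /* protected list(S, k, r1, r2) */
static double *S_ptr = NULL, *k_ptr = NULL;
static int *r1_ptr = NULL, *r2_ptr = NULL;
static int n_species = 0, n_react = 0;

SEXP C_set_scheme(SEXP S, SEXP k, SEXP r1, SEXP r2)
{
    SEXP dim = getAttrib(S, R_DimSymbol);
    if (dim == R_NilValue || LENGTH(dim) != 2)
        error("stoichiometry matrix must have a dim attribute");
    int nsp = INTEGER(dim)[0], nr = INTEGER(dim)[1];
    if (LENGTH(k) != nr || LENGTH(r1) != nr || LENGTH(r2) != nr)
        error("rate/index vectors must match the number of reactions");

    if (stage != NULL) {
        R_ReleaseObject(stage);
        stage = NULL;
    }
    SEXP lst = PROTECT(allocVector(VECSXP, 4));
    SET_VECTOR_ELT(lst, 0, duplicate(S));
    SET_VECTOR_ELT(lst, 1, duplicate(k));
    SET_VECTOR_ELT(lst, 2, duplicate(r1));
    SET_VECTOR_ELT(lst, 3, duplicate(r2));
    R_PreserveObject(lst);
    UNPROTECT(1);
    stage = lst;

    S_ptr = REAL(VECTOR_ELT(stage, 0));
    k_ptr = REAL(VECTOR_ELT(stage, 1));
    r1_ptr = INTEGER(VECTOR_ELT(stage, 2));
    r2_ptr = INTEGER(VECTOR_ELT(stage, 3));
    n_species = nsp;
    n_react = nr;
    return ScalarInteger(nr);
}

/* deSolve derivative: ydot = S %*% v, v_j = k_j * y[r1_j] * (y[r2_j] | 1) */
void C_derivs(int *neq, double *t, double *y, double *ydot, double *yout,
              int *ip)
{
    if (S_ptr == NULL || *neq != n_species)
        error("reaction scheme not staged for this state dimension");
    for (int i = 0; i < n_species; i++)
        ydot[i] = 0.0;
    for (int j = 0; j < n_react; j++) {
        double v = k_ptr[j] * y[r1_ptr[j] - 1];
        if (r2_ptr[j] > 0)
            v *= y[r2_ptr[j] - 1];
        const double *col = S_ptr + (size_t)j * n_species;
        for (int i = 0; i < n_species; i++)
            ydot[i] += col[i] * v;
    }
}

static const R_CallMethodDef call_entries[] = {
    {"C_set_scheme", (DL_FUNC)&C_set_scheme, 4},
    {NULL, NULL, 0}
};

void R_init_clotsim(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, call_entries, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE); /* deSolve looks C_derivs up by name */
}
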