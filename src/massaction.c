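/* Generic mass-action derivative for deSolve compiled models.
 *
 * The reaction network is passed through the fixed-length parms vector
 * (PARMS_LEN doubles, zero padded) with the layout
 *
 *   [0]              n_species (ns)
 *   [1]              n_reactions (nr)
 *   [2]              n_stoich triplets (nst)
 *   [3 .. 3+nr)      i1  (1-based reactant index)
 *   [.. +nr)         i2  (1-based second reactant index, 0 = none)
 *   [.. +nr)         k   (effective rate constant, factor included)
 *   [.. +nst)        st_sp  (1-based species index)
 *   [.. +nst)        st_rx  (1-based reaction index)
 *   [.. +nst)        st_co  (stoichiometric coefficient)
 *   [..]             n_receptor, then receptor indices (1-based)
 *   [..]             int_rate, int_mode (1 = first order, 2 = x pSTAT),
 *                    pS1 index, pS3 index (1-based)
 *
 * Flux of reaction r is k[r] * y[i1] * (i2 ? y[i2] : 1); receptor species
 * are additionally removed at int_rate (times free pSTAT1 + pSTAT3 when
 * int_mode == 2).
 */

#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

#define PARMS_LEN 4096
#define MAX_RX 256

static double parms[PARMS_LEN];

void statkin_initmod(void (*odeparms)(int *, double *))
{
    int n = PARMS_LEN;
    odeparms(&n, parms);
}

void statkin_derivs(int *neq, double *t, double *y, double *ydot,
                    double *yout, int *ip)
{
    const double *p = parms;
    int ns = (int) p[0];
    int nr = (int) p[1];
    int nst = (int) p[2];
    const double *i1 = p + 3;
    const double *i2 = i1 + nr;
    const double *k = i2 + nr;
    const double *st_sp = k + nr;
    const double *st_rx = st_sp + nst;
    const double *st_co = st_rx + nst;
    const double *q = st_co + nst;
    int n_rec = (int) q[0];
    const double *rec = q + 1;
    double int_rate = rec[n_rec];
    int int_mode = (int) rec[n_rec + 1];
    int ip1 = (int) rec[n_rec + 2] - 1;
    int ip3 = (int) rec[n_rec + 3] - 1;

    double v[MAX_RX];
    int r, s;

    for (r = 0; r < nr; r++) {
        int a = (int) i1[r] - 1;
        int b = (int) i2[r] - 1;
        v[r] = k[r] * y[a] * (b >= 0 ? y[b] : 1.0);
    }
    for (s = 0; s < ns; s++) ydot[s] = 0.0;
    for (s = 0; s < nst; s++) {
        ydot[(int) st_sp[s] - 1] += st_co[s] * v[(int) st_rx[s] - 1];
    }
    if (int_rate > 0.0) {
        double rint = int_rate;
        if (int_mode == 2) rint *= (y[ip1] + y[ip3]);
        for (s = 0; s < n_rec; s++) {
            int a = (int) rec[s] - 1;
            ydot[a] -= rint * y[a];
        }
    }
}

static const R_CMethodDef cMethods[] = {
    {"statkin_derivs", (DL_FUNC) &statkin_derivs, 6},
    {NULL, NULL, 0}
};

void R_init_statkin(DllInfo *dll)
{
    R_registerRoutines(dll, cMethods, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
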