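/* Mass-action ODE right-hand side for compartmental reaction networks.
 *
 * Rates are strict mass action: rate_j = k_j * y[r1_j] * y[r2_j] * y[mod_j],
 * with any absent slot (index 0) contributing a factor of 1, so zeroth-order
 * synthesis reactions return k_j.  Derivatives are S %*% rates with constant
 * (buffered) species clamped to zero derivative.
 */
#include <R.h>
#include <Rinternals.h>

SEXP C_mass_action_deriv(SEXP y_, SEXP k_, SEXP r1_, SEXP r2_, SEXP mod_,
                         SEXP stoich_, SEXP constMask_)
{
    int ns = LENGTH(y_);
    int nr = LENGTH(k_);
    double *y = REAL(y_);
    double *k = REAL(k_);
    int *r1 = INTEGER(r1_);
    int *r2 = INTEGER(r2_);
    int *mod = INTEGER(mod_);
    double *S = REAL(stoich_);    /* ns x nr, column-major */
    int *cm = INTEGER(constMask_);

    SEXP out = PROTECT(allocVector(REALSXP, ns));
    double *dy = REAL(out);
    for (int i = 0; i < ns; i++) dy[i] = 0.0;

    for (int j = 0; j < nr; j++) {
        double rate = k[j];
        if (r1[j] > 0) rate *= y[r1[j] - 1];
        if (r2[j] > 0) rate *= y[r2[j] - 1];
        if (mod[j] > 0) rate *= y[mod[j] - 1];
        if (rate == 0.0) continue;
        double *Sj = S + (size_t) j * ns;
        for (int i = 0; i < ns; i++) {
            if (Sj[i] != 0.0) dy[i] += Sj[i] * rate;
        }
    }
    for (int i = 0; i < ns; i++)
        if (cm[i]) dy[i] = 0.0;

    UNPROTECT(1);
    return out;
}

SEXP C_mass_action_rates(SEXP y_, SEXP k_, SEXP r1_, SEXP r2_, SEXP mod_)
{
    int nr = LENGTH(k_);
    double *y = REAL(y_);
    double *k = REAL(k_);
    int *r1 = INTEGER(r1_);
    int *r2 = INTEGER(r2_);
    int *mod = INTEGER(mod_);

    SEXP out = PROTECT(allocVector(REALSXP, nr));
    double *v = REAL(out);
    for (int j = 0; j < nr; j++) {
        double rate = k[j];
        if (r1[j] > 0) rate *= y[r1[j] - 1];
        if (r2[j] > 0) rate *= y[r2[j] - 1];
        if (mod[j] > 0) rate *= y[mod[j] - 1];
        v[j] = rate;
    }
    UNPROTECT(1);
    return out;
}
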