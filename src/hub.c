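/* Compiled core: signal evaluation, reaction propensities, ODE right-hand
 * side for deSolve's lsoda, and the Euler-Maruyama integrator for the
 * chemical Langevin equation.
 *
 * A model + signal pattern + parameter vector is flattened into a single
 * numeric "encoding" (built in R by encode_model()):
 *
 *   enc[0]    n_species
 *   enc[1]    n_reactions
 *   enc[2..6] signal: amplitude, beta_on, beta_off, t_switch, baseline
 *   then 9 slots per reaction:
 *     type, k, km, substrate_idx, modifier_idx, from_idx, to_idx,
 *     drift_on, noise_on
 *   indices are 1-based; 0 means "none".
 *
 * Reaction type codes (keep in sync with R/models.R):
 *   0 mass_action        k * S
 *   1 mm                 k * S / (km + S)
 *   2 mm_signal          k * s(t) * S / (km + S)
 *   3 mm_mod             k * M * S / (km + S)
 *   4 zero_order         k
 *   5 zero_order_signal  k * s(t)
 *   6 linear             k * S, unclamped (signed drift; validation systems)
 */

#include <R.h>
#include <Rinternals.h>
#include <Rmath.h>
#include <math.h>
#include <string.h>

#define MAX_ENC  512
#define MAX_SPEC 16
#define MAX_REAC 32

#define ENC_NSPEC 0
#define ENC_NREAC 1
#define ENC_SIG   2
#define ENC_REAC0 7
#define ENC_RLEN  9

static double hub_enc[MAX_ENC];

static double sig_eval(const double *enc, double t)
{
    double A    = enc[ENC_SIG];
    double bon  = enc[ENC_SIG + 1];
    double boff = enc[ENC_SIG + 2];
    double ts   = enc[ENC_SIG + 3];
    double base = enc[ENC_SIG + 4];
    double v;

    if (t <= ts) {
        v = base + A * (1.0 - exp(-bon * t));
    } else {
        double vts = base + A * (1.0 - exp(-bon * ts));
        v = vts * exp(-boff * (t - ts));
    }
    return v > 0.0 ? v : 0.0;
}

static double rate_eval(const double *r, const double *y, double s)
{
    int type = (int) r[0];
    double k = r[1], km = r[2];
    int sub = (int) r[3], mod = (int) r[4];
    /* clamp tiny negative solver excursions to zero before evaluating */
    double S = sub > 0 ? (y[sub - 1] > 0.0 ? y[sub - 1] : 0.0) : 1.0;
    double M = mod > 0 ? (y[mod - 1] > 0.0 ? y[mod - 1] : 0.0) : 1.0;

    switch (type) {
    case 0: return k * S;
    case 1: return k * S / (km + S);
    case 2: return k * s * S / (km + S);
    case 3: return k * M * S / (km + S);
    case 4: return k;
    case 5: return k * s;
    case 6: return k * (sub > 0 ? y[sub - 1] : 1.0);
    default: return 0.0;
    }
}

/* ---- deSolve interface ------------------------------------------------ */

void hub_init(void (*odeparms)(int *, double *))
{
    /* parameters arrive through C_set_model(), nothing to do here */
}

void hub_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    const double *enc = hub_enc;
    int ns = (int) enc[ENC_NSPEC];
    int nr = (int) enc[ENC_NREAC];
    double s = sig_eval(enc, *t);
    int i, j;

    for (i = 0; i < ns; i++) ydot[i] = 0.0;
    for (j = 0; j < nr; j++) {
        const double *r = enc + ENC_REAC0 + j * ENC_RLEN;
        int from, to;
        double a;
        if ((int) r[7] == 0) continue;      /* drift switched off */
        a = rate_eval(r, y, s);
        from = (int) r[5];
        to   = (int) r[6];
        if (from > 0) ydot[from - 1] -= a;
        if (to   > 0) ydot[to   - 1] += a;
    }
}

SEXP C_set_model(SEXP enc)
{
    int n = LENGTH(enc);
    if (n > MAX_ENC) error("model encoding too long (%d > %d)", n, MAX_ENC);
    memcpy(hub_enc, REAL(enc), n * sizeof(double));
    return R_NilValue;
}

/* direct access to the compiled signal/rate evaluators, for cross-checks */
SEXP C_signal_eval(SEXP enc, SEXP t)
{
    int i, n = LENGTH(t);
    SEXP out = PROTECT(allocVector(REALSXP, n));
    for (i = 0; i < n; i++)
        REAL(out)[i] = sig_eval(REAL(enc), REAL(t)[i]);
    UNPROTECT(1);
    return out;
}

SEXP C_rates_eval(SEXP enc, SEXP y, SEXP s)
{
    const double *e = REAL(enc);
    int nr = (int) e[ENC_NREAC];
    int j;
    SEXP out = PROTECT(allocVector(REALSXP, nr));
    for (j = 0; j < nr; j++)
        REAL(out)[j] = rate_eval(e + ENC_REAC0 + j * ENC_RLEN, REAL(y), asReal(s));
    UNPROTECT(1);
    return out;
}

/* ---- Euler-Maruyama CLE ---------------------------------------------- */

/* boundary policy codes: 0 clip, 1 reflect, 2 none */
static int cle_one(const double *enc, const double *y0, int ns,
                   double dt, double noise, int policy,
                   const long *steps_at, int nst, long nsteps,
                   double *rec /* nst x ns, column-major by species */)
{
    double y[MAX_SPEC], dy[MAX_SPEC], a[MAX_REAC];
    int nr = (int) enc[ENC_NREAC];
    int i, j, k = 0;
    long step;
    double sqdt = sqrt(dt);

    for (i = 0; i < ns; i++) y[i] = y0[i];

    for (step = 0; step <= nsteps; step++) {
        if (k < nst && step == steps_at[k]) {
            for (i = 0; i < ns; i++) {
                if (!R_FINITE(y[i])) return 1;
                rec[k + i * nst] = y[i];
            }
            k++;
        }
        if (step == nsteps) break;
        {
            double t = step * dt;
            double s = sig_eval(enc, t);
            for (j = 0; j < nr; j++)
                a[j] = rate_eval(enc + ENC_REAC0 + j * ENC_RLEN, y, s);
            for (i = 0; i < ns; i++) dy[i] = 0.0;
            for (j = 0; j < nr; j++) {
                const double *r = enc + ENC_REAC0 + j * ENC_RLEN;
                int from = (int) r[5], to = (int) r[6];
                double inc = 0.0;
                if ((int) r[7]) inc += a[j] * dt;
                if ((int) r[8] && noise > 0.0) {
                    double g = noise * sqrt(a[j] > 0.0 ? a[j] : 0.0) * sqdt;
                    inc += g * norm_rand();
                }
                if (from > 0) dy[from - 1] -= inc;
                if (to   > 0) dy[to   - 1] += inc;
            }
            for (i = 0; i < ns; i++) {
                y[i] += dy[i];
                if (policy == 0 && y[i] < 0.0) y[i] = 0.0;
                else if (policy == 1 && y[i] < 0.0) y[i] = -y[i];
            }
        }
    }
    return 0;
}

static void make_steps(const double *st, int nst, double dt,
                       long *steps_at, long *nsteps)
{
    int k;
    *nsteps = 0;
    for (k = 0; k < nst; k++) {
        steps_at[k] = (long) (st[k] / dt + 0.5);
        if (steps_at[k] > *nsteps) *nsteps = steps_at[k];
    }
}

SEXP C_cle_path(SEXP enc_, SEXP y0_, SEXP dt_, SEXP st_, SEXP noise_,
                SEXP policy_)
{
    const double *enc = REAL(enc_);
    int ns = (int) enc[ENC_NSPEC];
    int nst = LENGTH(st_);
    double dt = asReal(dt_);
    long steps_at[1024], nsteps;
    SEXP out;
    int bad;

    if (ns > MAX_SPEC) error("too many species");
    if (nst > 1024) error("too many sample times");
    make_steps(REAL(st_), nst, dt, steps_at, &nsteps);

    out = PROTECT(allocMatrix(REALSXP, nst, ns));
    GetRNGstate();
    bad = cle_one(enc, REAL(y0_), ns, dt, asReal(noise_), asInteger(policy_),
                  steps_at, nst, nsteps, REAL(out));
    PutRNGstate();
    if (bad) {
        int i;
        for (i = 0; i < nst * ns; i++) REAL(out)[i] = R_NaReal;
    }
    UNPROTECT(1);
    return out;
}

/* Replicate ensemble: returns n_rep x nst matrix of the output species.
 * Replicates advance a single RNG stream sequentially; a replicate that
 * goes non-finite is re-drawn (fresh noise) up to max_retry times. */
SEXP C_cle_ensemble(SEXP enc_, SEXP y0_, SEXP dt_, SEXP st_, SEXP noise_,
                    SEXP policy_, SEXP nrep_, SEXP out_idx_, SEXP max_retry_)
{
    const double *enc = REAL(enc_);
    int ns = (int) enc[ENC_NSPEC];
    int nst = LENGTH(st_);
    int nrep = asInteger(nrep_);
    int oi = asInteger(out_idx_) - 1;
    int max_retry = asInteger(max_retry_);
    double dt = asReal(dt_);
    long steps_at[1024], nsteps;
    double rec[1024 * MAX_SPEC];
    SEXP out;
    int r, k, tries;

    if (ns > MAX_SPEC) error("too many species");
    if (nst > 1024) error("too many sample times");
    make_steps(REAL(st_), nst, dt, steps_at, &nsteps);

    out = PROTECT(allocMatrix(REALSXP, nrep, nst));
    GetRNGstate();
    for (r = 0; r < nrep; r++) {
        int bad = 1;
        for (tries = 0; tries <= max_retry && bad; tries++)
            bad = cle_one(enc, REAL(y0_), ns, dt, asReal(noise_),
                          asInteger(policy_), steps_at, nst, nsteps, rec);
        if (bad) {
            PutRNGstate();
            UNPROTECT(1);
            error("stochastic simulation diverged in replicate %d "
                  "after %d retries", r + 1, max_retry);
        }
        for (k = 0; k < nst; k++)
            REAL(out)[r + k * nrep] = rec[k + oi * nst];
    }
    PutRNGstate();
    UNPROTECT(1);
    return out;
}
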