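/* Compiled kernel for the metabolic network ODE right-hand side.
 *
 * The network (species, reactions, rate laws, effective velocities) is
 * packed into a flat double vector on the R side (see pack_model()) and
 * installed with C_pdacmet_set_model() before integration. deSolve then
 * calls pdacmet_derivs() without any per-call R overhead; reaction fluxes
 * are emitted through the `yout` slots so trajectories carry fluxes at the
 * requested output times.
 *
 * The algebra here must match rate_law_flux() in R/ratelaws.R exactly
 * (same factor ordering); the test suite asserts agreement to 1e-12.
 */

#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <math.h>

#define MAXSP 256

/* form codes */
#define F_MM_IRR   1
#define F_MM_REV   2
#define F_BIBI_REV 3
#define F_HALDANE  4
#define F_CARRIER  5
#define F_MA_REV   6
#define F_MA_IRR   7
#define F_MWC      8

/* modifier codes */
#define M_INH      1
#define M_ACT      2
#define M_COF      3
#define M_ALLO_INH 4
#define M_ALLO_ACT 5

static SEXP g_model_sexp = NULL;
static const double *g_model = NULL;

SEXP C_pdacmet_set_model(SEXP packed)
{
    if (g_model_sexp != NULL) {
        R_ReleaseObject(g_model_sexp);
        g_model_sexp = NULL;
    }
    g_model_sexp = packed;
    R_PreserveObject(g_model_sexp);
    g_model = REAL(packed);
    return R_NilValue;
}

/* evaluate the net flux of one reaction block at clipped concentrations c */
static double rx_flux(const double *m, int blk, const double *c)
{
    const double *b = m + blk;
    int form = (int) b[0];
    double vf = b[1], vr = b[2];
    int nsub = (int) b[3], npro = (int) b[4];
    const double *sub = b + 5;
    const double *pro = sub + nsub;
    const double *post = pro + npro;          /* nstoich, pairs... */
    int nst = (int) post[0];
    const double *par = post + 1 + 2 * nst + 1;
    int npar = (int) post[2 * nst + 1];
    const double *modv = par + npar;
    int nmod = (int) modv[0];
    const double *mods = modv + 1;            /* (type, idx, k) triplets */
    double v = 0.0;
    int i;

    switch (form) {
    case F_MM_IRR: {
        v = vf;
        for (i = 0; i < nsub; i++) {
            double S = c[(int) sub[i]];
            v *= S / (par[i] + S);
        }
        break;
    }
    case F_MM_REV: {
        double pa = 1.0, pb = 1.0, da = 1.0, db = 1.0;
        for (i = 0; i < nsub; i++) {
            double a = c[(int) sub[i]] / par[i];
            pa *= a; da *= (1.0 + a);
        }
        for (i = 0; i < npro; i++) {
            double p = c[(int) pro[i]] / par[nsub + i];
            pb *= p; db *= (1.0 + p);
        }
        v = (vf * pa - vr * pb) / (da + db - 1.0);
        break;
    }
    case F_BIBI_REV: {
        double A = c[(int) sub[0]], B = c[(int) sub[1]];
        double P = c[(int) pro[0]], Q = c[(int) pro[1]];
        double Kia = par[0], Kib = par[1], Kmb = par[2];
        double Kip = par[3], Kiq = par[4], Kmq = par[5];
        double KdAQ = par[6], KdBP = par[7];
        double fnum = vf * A * B / (Kia * Kmb);
        double rnum = vr * P * Q / (Kip * Kmq);
        double D = 1.0 + A / Kia + B / Kib + P / Kip + Q / Kiq +
            A * B / (Kia * Kmb) + P * Q / (Kip * Kmq) +
            A * Q / KdAQ + B * P / KdBP;
        v = (fnum - rnum) / D;
        break;
    }
    case F_HALDANE: {
        double PS = 1.0, PP = 1.0, ds = 1.0, dp = 1.0, KK = 1.0;
        double Keq = par[nsub + npro];
        for (i = 0; i < nsub; i++) {
            double S = c[(int) sub[i]];
            PS *= S; ds *= (1.0 + S / par[i]); KK *= par[i];
        }
        for (i = 0; i < npro; i++) {
            double P = c[(int) pro[i]];
            PP *= P; dp *= (1.0 + P / par[nsub + i]);
        }
        v = vf * (PS - PP / Keq) / (KK * (ds + dp - 1.0));
        break;
    }
    case F_CARRIER: {
        double S = c[(int) sub[0]], P = c[(int) pro[0]];
        double Kms = par[0], Kmp = par[1], Keq = par[2], alpha = par[3];
        double D = 1.0 + S / Kms + P / Kmp + alpha * S * P / (Kms * Kmp);
        v = vf * (S - P / Keq) / (Kms * D);
        break;
    }
    case F_MA_REV: {
        double pf = 1.0, pr = 1.0;
        for (i = 0; i < nsub; i++) pf *= pow(c[(int) sub[i]], par[i]);
        for (i = 0; i < npro; i++) pr *= pow(c[(int) pro[i]], par[nsub + i]);
        v = vf * pf - vr * pr;
        break;
    }
    case F_MA_IRR: {
        double pf = 1.0;
        for (i = 0; i < nsub; i++) pf *= pow(c[(int) sub[i]], par[i]);
        v = vf * pf;
        break;
    }
    case F_MWC: {
        double S1 = c[(int) sub[0]];
        double s1 = S1 / par[0];
        double n = par[nsub], L0 = par[nsub + 1], cc = par[nsub + 2];
        double L = L0;
        for (i = 0; i < nmod; i++) {
            int ty = (int) mods[3 * i];
            double x = c[(int) mods[3 * i + 1]];
            double k = mods[3 * i + 2];
            if (ty == M_ALLO_INH) L *= pow(1.0 + x / k, n);
            if (ty == M_ALLO_ACT) L /= pow(1.0 + x / k, n);
        }
        v = vf * s1 * pow(1.0 + s1, n - 1.0) /
            (pow(1.0 + s1, n) + L * pow(1.0 + cc * s1, n));
        for (i = 1; i < nsub; i++) {
            double S = c[(int) sub[i]];
            v *= S / (par[i] + S);
        }
        break;
    }
    default:
        error("pdacmet kernel: unknown rate-law form code %d", form);
    }

    for (i = 0; i < nmod; i++) {
        int ty = (int) mods[3 * i];
        double x = c[(int) mods[3 * i + 1]];
        double k = mods[3 * i + 2];
        if (ty == M_INH) v *= k / (k + x);
        else if (ty == M_ACT) v *= x / (k + x);
        else if (ty == M_COF) v *= x / (k + x);
        /* allo_* handled inside F_MWC */
    }
    return v;
}

static void eval_system(const double *m, double t, const double *y,
                        double *ydot, double *flux)
{
    int ns = (int) m[0];
    int nr = (int) m[1];
    int cellflag = (int) m[2];
    const double *gp = m + 3;                 /* 8 growth params */
    int i_atp = (int) m[11], i_glc = (int) m[12], i_gln = (int) m[13];
    const double *dyn = m + 14;               /* ns dynamic flags */
    const double *offs = m + 14 + ns;         /* nr block offsets */
    double c[MAXSP];
    int i, j;

    if (ns > MAXSP) error("pdacmet kernel: too many species");
    for (i = 0; i < ns; i++) {
        c[i] = y[i] > 0.0 ? y[i] : 0.0;
        ydot[i] = 0.0;
    }

    for (j = 0; j < nr; j++) {
        int blk = (int) offs[j];
        double v = rx_flux(m, blk, c);
        const double *b = m + blk;
        int nsub = (int) b[3], npro = (int) b[4];
        const double *post = b + 5 + nsub + npro;
        int nst = (int) post[0];
        for (i = 0; i < nst; i++) {
            int sp = (int) post[1 + 2 * i];
            if (dyn[sp] > 0.5)
                ydot[sp] += post[2 + 2 * i] * v;
        }
        if (flux) flux[j] = v;
    }

    if (cellflag) {
        double ATP = c[i_atp], GLC = c[i_glc], GLN = c[i_gln];
        double lambda = gp[0] * ATP / (gp[4] + ATP) +
                        gp[1] * GLC / (gp[5] + GLC) +
                        gp[2] * GLN / (gp[6] + GLN);
        double CN = y[ns] > 0.0 ? y[ns] : 0.0;
        ydot[ns] = lambda * (1.0 - CN / gp[7]) * CN - gp[3] * CN;
    }
}

/* deSolve entry point */
void pdacmet_derivs(int *neq, double *t, double *y, double *ydot,
                    double *yout, int *ip)
{
    int nr;
    if (g_model == NULL) error("pdacmet kernel: no model installed");
    nr = (int) g_model[1];
    if (ip[0] < nr) error("pdacmet kernel: nout too small");
    eval_system(g_model, *t, y, ydot, yout);
}

/* single-shot evaluation for tests/oracles: list(ydot, flux) */
SEXP C_pdacmet_eval(SEXP packed, SEXP t, SEXP y)
{
    const double *m = REAL(packed);
    int ns = (int) m[0], nr = (int) m[1];
    int cellflag = (int) m[2];
    int neq = ns + (cellflag ? 1 : 0);
    SEXP ydot = PROTECT(allocVector(REALSXP, neq));
    SEXP flux = PROTECT(allocVector(REALSXP, nr));
    SEXP out = PROTECT(allocVector(VECSXP, 2));
    if (LENGTH(y) < neq) error("state vector too short");
    eval_system(m, asReal(t), REAL(y), REAL(ydot), REAL(flux));
    SET_VECTOR_ELT(out, 0, ydot);
    SET_VECTOR_ELT(out, 1, flux);
    UNPROTECT(3);
    return out;
}

static const R_CallMethodDef callMethods[] = {
    {"C_pdacmet_set_model", (DL_FUNC) &C_pdacmet_set_model, 1},
    {"C_pdacmet_eval",      (DL_FUNC) &C_pdacmet_eval,      3},
    {NULL, NULL, 0}
};

void R_init_pdacmet(DllInfo *info)
{
    R_registerRoutines(info, NULL, callMethods, NULL, NULL);
    R_useDynamicSymbols(info, TRUE);
}
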