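/* Compiled core of the Hopf (Stuart-Landau) whole-brain model:
 *  - hopf_derivs / hopf_set_parms: right-hand side in the deSolve
 *    compiled-model convention (the cross-check integration route);
 *  - hopf_simulate: native adaptive Dormand-Prince RK45 integrator with
 *    cubic Hermite dense output onto a uniform sampling grid (the default
 *    route; the grid-search workloads run thousands of 14.5 s solves);
 *  - iir_filtfilt: zero-phase forward-backward IIR application (direct
 *    form II transposed, zero initial state; callers trim the edges);
 *  - pli_signmean: the PLI pair loop.
 *
 * Parameter pack layout (shared by both integration routes):
 *   pack = [N, K, lambda, C, omega[1..N], gain[1..N], W column-major N*N]
 * State layout: y[0..N-1] = Re(z), y[N..2N-1] = Im(z).
 */
#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <math.h>
#include <stdlib.h>
#include <string.h>

static double *par = NULL;
static int par_len = 0;

void hopf_set_parms(double *p, int *len)
{
    if (par != NULL) {
        free(par);
        par = NULL;
    }
    par_len = *len;
    par = (double *) malloc((size_t) par_len * sizeof(double));
    if (par == NULL)
        error("hopf_set_parms: allocation of %d doubles failed", par_len);
    memcpy(par, p, (size_t) par_len * sizeof(double));
}

static void hopf_rhs(int n2, double t, const double *y, double *ydot)
{
    const int N = n2 / 2;
    const double K = par[1];
    const double lambda = par[2];
    const double C = par[3];
    const double *omega = par + 4;
    const double *gain = par + 4 + N;
    const double *W = par + 4 + 2 * N;
    const double *x = y;
    const double *yi = y + N;

    for (int i = 0; i < N; i++) {
        double s = 0.0;
        const double *wcol = W + (size_t) i; /* row i; W symmetric */
        for (int j = 0; j < N; j++)
            s += wcol[(size_t) j * N] * x[j];
        const double r2 = x[i] * x[i] + yi[i] * yi[i];
        const double a = lambda - r2;
        ydot[i] = a * x[i] - omega[i] * yi[i] + gain[i] * K * tanh(C * s);
        ydot[N + i] = a * yi[i] + omega[i] * x[i];
    }
    (void) t;
}

void hopf_derivs(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
    if (par == NULL)
        error("hopf_derivs: parameters not initialised");
    hopf_rhs(*neq, *t, y, ydot);
    (void) yout; (void) ip;
}

/* Dormand-Prince RK45 Butcher tableau */
static const double DP_C[7] = {0., 1. / 5, 3. / 10, 4. / 5, 8. / 9, 1., 1.};
static const double DP_A[7][6] = {
    {0, 0, 0, 0, 0, 0},
    {1. / 5, 0, 0, 0, 0, 0},
    {3. / 40, 9. / 40, 0, 0, 0, 0},
    {44. / 45, -56. / 15, 32. / 9, 0, 0, 0},
    {19372. / 6561, -25360. / 2187, 64448. / 6561, -212. / 729, 0, 0},
    {9017. / 3168, -355. / 33, 46732. / 5247, 49. / 176, -5103. / 18656, 0},
    {35. / 384, 0, 500. / 1113, 125. / 192, -2187. / 6784, 11. / 84}
};
static const double DP_B5[7] =
    {35. / 384, 0, 500. / 1113, 125. / 192, -2187. / 6784, 11. / 84, 0};
static const double DP_E[7] = { /* 5th-order minus embedded 4th-order */
    71. / 57600, 0, -71. / 16695, 71. / 1920, -17253. / 339200,
    22. / 525, -1. / 40};

/* Integrate from times[0] to times[nt-1]; write the state at every output
 * time (cubic Hermite within accepted steps) into out (nt x n, column
 * major).  status: 0 ok, 1 non-finite state, 2 step-size underflow,
 * 3 max-steps exceeded; on failure times[0] reports the failure time. */
void hopf_simulate(double *y0, int *nPtr, double *times, int *ntPtr,
                   double *atolPtr, double *rtolPtr, double *hmaxPtr,
                   double *out, int *status)
{
    const int n = *nPtr, nt = *ntPtr;
    const double atol = *atolPtr, rtol = *rtolPtr;
    const double hmax = *hmaxPtr;
    const long maxSteps = 10000000L;
    double *y = (double *) R_alloc(n, sizeof(double));
    double *ytmp = (double *) R_alloc(n, sizeof(double));
    double *ynew = (double *) R_alloc(n, sizeof(double));
    double *k[7];
    for (int s = 0; s < 7; s++)
        k[s] = (double *) R_alloc(n, sizeof(double));

    if (par == NULL) { *status = 1; return; }
    memcpy(y, y0, n * sizeof(double));
    double t = times[0];
    const double tEnd = times[nt - 1];
    for (int i = 0; i < n; i++) out[(size_t) i * nt] = y[i];
    int iOut = 1;

    hopf_rhs(n, t, y, k[0]); /* FSAL: k[0] holds f(t, y) */
    double h = 1e-3;
    if (hmax > 0 && h > hmax) h = hmax;
    if (h > tEnd - t) h = tEnd - t;
    *status = 0;

    for (long step = 0; ; step++) {
        if (t >= tEnd - 1e-14) break;
        if (step >= maxSteps) { *status = 3; times[0] = t; return; }
        if (t + h > tEnd) h = tEnd - t;
        for (int s = 1; s < 7; s++) {
            for (int i = 0; i < n; i++) {
                double acc = 0.0;
                for (int q = 0; q < s; q++)
                    acc += DP_A[s][q] * k[q][i];
                ytmp[i] = y[i] + h * acc;
            }
            hopf_rhs(n, t + DP_C[s] * h, ytmp, k[s]);
        }
        double errsq = 0.0;
        int finite = 1;
        for (int i = 0; i < n; i++) {
            double acc = 0.0, eacc = 0.0;
            for (int s = 0; s < 7; s++) {
                acc += DP_B5[s] * k[s][i];
                eacc += DP_E[s] * k[s][i];
            }
            ynew[i] = y[i] + h * acc;
            if (!R_FINITE(ynew[i])) finite = 0;
            double sc = atol + rtol * fmax(fabs(y[i]), fabs(ynew[i]));
            double e = h * eacc / sc;
            errsq += e * e;
        }
        double err = sqrt(errsq / n);
        if (finite && err <= 1.0) {
            /* accept: cubic Hermite dense output on [t, t+h] */
            while (iOut < nt && times[iOut] <= t + h + 1e-14) {
                double th = (times[iOut] - t) / h;
                double h00 = (1 + 2 * th) * (1 - th) * (1 - th);
                double h10 = th * (1 - th) * (1 - th);
                double h01 = th * th * (3 - 2 * th);
                double h11 = th * th * (th - 1);
                for (int i = 0; i < n; i++)
                    out[(size_t) i * nt + iOut] =
                        h00 * y[i] + h10 * h * k[0][i] +
                        h01 * ynew[i] + h11 * h * k[6][i];
                iOut++;
            }
            t += h;
            memcpy(y, ynew, n * sizeof(double));
            memcpy(k[0], k[6], n * sizeof(double)); /* FSAL */
            double fac = 0.9 * pow(fmax(err, 1e-10), -0.2);
            h *= fmin(5.0, fmax(0.2, fac));
            if (hmax > 0 && h > hmax) h = hmax;
        } else {
            double fac = finite ? fmax(0.1, 0.9 * pow(err, -0.2)) : 0.25;
            h *= fac;
            if (h < 1e-12) { *status = 2; times[0] = t; return; }
        }
    }
    for (; iOut < nt; iOut++) /* trailing output times equal to tEnd */
        for (int i = 0; i < n; i++)
            out[(size_t) i * nt + iOut] = y[i];
}

/* Zero-phase IIR: direct form II transposed, forward then backward, zero
 * initial state, applied in place per column of x (T x ncol); b, a of
 * length nc with a normalised so a[0] = 1. */
void iir_filtfilt(double *x, int *TPtr, int *ncolPtr, double *b, double *a,
                  int *ncPtr)
{
    const int T = *TPtr, ncol = *ncolPtr, nc = *ncPtr;
    double *w = (double *) R_alloc(nc, sizeof(double));
    for (int c = 0; c < ncol; c++) {
        double *col = x + (size_t) c * T;
        for (int pass = 0; pass < 2; pass++) {
            memset(w, 0, nc * sizeof(double));
            int start = pass == 0 ? 0 : T - 1;
            int stepDir = pass == 0 ? 1 : -1;
            for (int m = 0, tIdx = start; m < T; m++, tIdx += stepDir) {
                double xin = col[tIdx];
                double yout = b[0] * xin + w[0];
                for (int q = 0; q < nc - 1; q++)
                    w[q] = b[q + 1] * xin + w[q + 1] - a[q + 1] * yout;
                col[tIdx] = yout;
            }
        }
    }
}

/* PLI pair loop: out[i, j] = | mean_t sign(sin(phi_i - phi_j)) | */
void pli_signmean(double *phi, int *TPtr, int *NPtr, double *out)
{
    const int T = *TPtr, N = *NPtr;
    double *S = (double *) R_alloc((size_t) T * N, sizeof(double));
    double *C = (double *) R_alloc((size_t) T * N, sizeof(double));
    for (size_t q = 0; q < (size_t) T * N; q++) {
        S[q] = sin(phi[q]);
        C[q] = cos(phi[q]);
    }
    for (int i = 0; i < N; i++) out[(size_t) i * N + i] = 0.0;
    for (int i = 0; i < N - 1; i++) {
        const double *Si = S + (size_t) i * T, *Ci = C + (size_t) i * T;
        for (int j = i + 1; j < N; j++) {
            const double *Sj = S + (size_t) j * T, *Cj = C + (size_t) j * T;
            double acc = 0.0;
            for (int tIdx = 0; tIdx < T; tIdx++) {
                double d = Si[tIdx] * Cj[tIdx] - Ci[tIdx] * Sj[tIdx];
                acc += (d > 0) - (d < 0);
            }
            double v = fabs(acc / T);
            out[(size_t) j * N + i] = v;
            out[(size_t) i * N + j] = v;
        }
    }
}

static const R_CMethodDef CEntries[] = {
    {"hopf_set_parms", (DL_FUNC) &hopf_set_parms, 2},
    {"hopf_derivs",    (DL_FUNC) &hopf_derivs,    6},
    {"hopf_simulate",  (DL_FUNC) &hopf_simulate,  9},
    {"iir_filtfilt",   (DL_FUNC) &iir_filtfilt,   6},
    {"pli_signmean",   (DL_FUNC) &pli_signmean,   4},
    {NULL, NULL, 0}
};

void R_init_hopfconn(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
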