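/* Mass-action right-hand side for the Drp1/Mff fission model, in the
 * deSolve compiled-model convention.
 *
 * State layout (length N + 3):
 *   y[0]      T   cytosolic Drp1 tetramers (or dimensionless z)
 *   y[1]      M   unbound Mff              (or dimensionless y)
 *   y[2+i-1]  C_i oligomer of size i, i = 1..N (or x_i)
 *   y[N+2]    running integral of the total fission rate (cumulative TF)
 *
 * The dimensionless system is the same vector field under the parameter
 * substitution k1 -> beta, k_m1 -> zeta, k_plus -> mu, k_minus -> 1,
 * a -> alpha; the R wrappers perform that mapping.
 */
#include <R.h>
#include <R_ext/Rdynload.h>

static double parms[8];
#define K1    parms[0]
#define KM1   parms[1]
#define KP    parms[2]
#define KM    parms[3]
#define AFIS  parms[4]
#define GAMMA parms[5]
#define ELL   parms[6]
#define NMAX  parms[7]

void fission_init(void (*odeparms)(int *, double *))
{
    int n = 8;
    odeparms(&n, parms);
}

void fission_derivs(int *neq, double *t, double *y, double *ydot,
                    double *yout, int *ip)
{
    const int N = (int) NMAX;
    const int ell = (int) ELL;
    const double T = y[0], M = y[1];
    const double *C = y + 2;        /* C[i-1] = C_i */
    double sum_ic_fis = 0.0;        /* sum i*C_i over fission-competent i */
    double sum_c_fis  = 0.0;        /* sum   C_i over fission-competent i */
    double sum_c3     = 0.0;        /* sum C_i, i = 3..N   */
    double sum_c2     = 0.0;        /* sum C_i, i = 2..N-1 */
    int i;

    for (i = 3; i <= N; i++)       sum_c3 += C[i - 1];
    for (i = 2; i <= N - 1; i++)   sum_c2 += C[i - 1];
    for (i = ell + 1; i <= N; i++) {
        sum_c_fis  += C[i - 1];
        sum_ic_fis += i * C[i - 1];
    }

    {
        const double flux = KM1 * C[0] - K1 * T * M + AFIS * sum_ic_fis;
        ydot[0] = GAMMA * flux;
        ydot[1] = flux;
    }
    ydot[2] = K1 * T * M - KM1 * C[0] + KM * (2.0 * C[1] + sum_c3)
              - KP * (2.0 * C[0] * C[0] + sum_c2 * C[0]);
    for (i = 2; i <= N - 1; i++) {
        const double fi = (i > ell) ? AFIS : 0.0;
        ydot[i + 1] = -KP * C[0] * (C[i - 1] - C[i - 2])
                      + KM * (C[i] - C[i - 1]) - fi * C[i - 1];
    }
    ydot[N + 1] = KP * C[N - 2] * C[0] - KM * C[N - 1] - AFIS * C[N - 1];
    ydot[N + 2] = AFIS * sum_c_fis;   /* d(cumTF)/dt = TFR */
}

static const R_CMethodDef cMethods[] = {
    {"fission_init",   (DL_FUNC) &fission_init,   1},
    {"fission_derivs", (DL_FUNC) &fission_derivs, 6},
    {NULL, NULL, 0}
};

void R_init_mitofission(DllInfo *dll)
{
    R_registerRoutines(dll, cMethods, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
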