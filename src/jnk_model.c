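/* Right-hand side of the single-cell JNK cascade model for deSolve's
 * compiled-model interface.
 *
 * Species (16):
 *   0 Z     inactive ZAK            8  M7pp  bis-phos MKK7 (active)
 *   1 Za    active ZAK              9  M7f   feedback-phos MKK7, unphos
 *   2 M4    unphos MKK4            10  M7fp  feedback-phos MKK7, mono
 *   3 M4p   mono-phos MKK4         11  M7fpp feedback-phos MKK7, bis (active, gain)
 *   4 M4pp  bis-phos MKK4 (active) 12  M7i   Akt-inhibited MKK7
 *   5 M4i   Akt-inhibited MKK4     13  J     unphos JNK
 *   6 M7    unphos MKK7            14  Jp    mono-phos JNK
 *   7 M7p   mono-phos MKK7         15  Jpp   bis-phos (active) JNK
 *
 * Kinase steps are distributive two-site Michaelis-Menten; constitutive
 * phosphatases are first order.  Active JNK converts every MKK7 phospho-form
 * to a feedback-marked variant whose catalytic output is multiplied by the
 * feedback gain.  Phospho-Akt drives MKK4/MKK7 into catalytically dead
 * inhibited states with first-order recovery.
 *
 * Parameter vector (21): kin kmz kpz k4 km4 p4 k7 km7 p7 k44 k77 kmj pj
 *                        kfb pfb gfb ka4 ka7 krec stim pakt
 */
#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

static double parms[21];
#define kin  parms[0]
#define kmz  parms[1]
#define kpz  parms[2]
#define k4   parms[3]
#define km4  parms[4]
#define p4   parms[5]
#define k7   parms[6]
#define km7  parms[7]
#define p7   parms[8]
#define k44  parms[9]
#define k77  parms[10]
#define kmj  parms[11]
#define pj   parms[12]
#define kfb  parms[13]
#define pfb  parms[14]
#define gfb  parms[15]
#define ka4  parms[16]
#define ka7  parms[17]
#define krec parms[18]
#define stim parms[19]
#define pakt parms[20]

void jnk_initmod(void (*odeparms)(int *, double *))
{
    int n = 21;
    odeparms(&n, parms);
}

void jnk_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    double Z = y[0], Za = y[1];
    double M4 = y[2], M4p = y[3], M4pp = y[4], M4i = y[5];
    double M7 = y[6], M7p = y[7], M7pp = y[8];
    double M7f = y[9], M7fp = y[10], M7fpp = y[11], M7i = y[12];
    double J = y[13], Jp = y[14], Jpp = y[15];

    double vz = kin * stim * Z / (kmz + Z);

    double v41 = k4 * Za * M4 / (km4 + M4);
    double v42 = k4 * Za * M4p / (km4 + M4p);
    /* Akt-driven sequestration of engaged (phosphorylated) MKK forms */
    double a4p = ka4 * pakt * M4p;
    double a4pp = ka4 * pakt * M4pp;

    double v71 = k7 * Za * M7 / (km7 + M7);
    double v72 = k7 * Za * M7p / (km7 + M7p);
    double v71f = k7 * Za * M7f / (km7 + M7f);
    double v72f = k7 * Za * M7fp / (km7 + M7fp);
    double a7p = ka7 * pakt * M7p;
    double a7pp = ka7 * pakt * M7pp;
    double a7fp = ka7 * pakt * M7fp;
    double a7fpp = ka7 * pakt * M7fpp;

    /* feedback marking of MKK7 by active JNK (mass action in Jpp) */
    double f0 = kfb * Jpp * M7;
    double f1 = kfb * Jpp * M7p;
    double f2 = kfb * Jpp * M7pp;

    /* active MKK7 output: feedback-marked bis-form amplified by gain */
    double mkk7eff = M7pp + gfb * M7fpp;
    double kcatj = k44 * M4pp + k77 * mkk7eff;
    double w1 = kcatj * J / (kmj + J);
    double w2 = kcatj * Jp / (kmj + Jp);

    ydot[0] = -vz + kpz * Za;
    ydot[1] = vz - kpz * Za;

    ydot[2] = -v41 + p4 * M4p + krec * M4i;
    ydot[3] = v41 - v42 - p4 * M4p + p4 * M4pp - a4p;
    ydot[4] = v42 - p4 * M4pp - a4pp;
    ydot[5] = a4p + a4pp - krec * M4i;

    ydot[6] = -v71 + p7 * M7p - f0 + pfb * M7f + krec * M7i;
    ydot[7] = v71 - v72 - p7 * M7p + p7 * M7pp - f1 + pfb * M7fp - a7p;
    ydot[8] = v72 - p7 * M7pp - f2 + pfb * M7fpp - a7pp;
    ydot[9] = -v71f + p7 * M7fp + f0 - pfb * M7f;
    ydot[10] = v71f - v72f - p7 * M7fp + p7 * M7fpp + f1 - pfb * M7fp - a7fp;
    ydot[11] = v72f - p7 * M7fpp + f2 - pfb * M7fpp - a7fpp;
    ydot[12] = a7p + a7pp + a7fp + a7fpp - krec * M7i;

    ydot[13] = -w1 + pj * Jp;
    ydot[14] = w1 - w2 - pj * Jp + pj * Jpp;
    ydot[15] = w2 - pj * Jpp;
}

static const R_CMethodDef cMethods[] = {
    {"jnk_initmod", (DL_FUNC) &jnk_initmod, 1},
    {"jnk_derivs",  (DL_FUNC) &jnk_derivs,  6},
    {NULL, NULL, 0}
};

void R_init_jnknoise(DllInfo *dll)
{
    R_registerRoutines(dll, cMethods, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
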