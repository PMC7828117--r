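/* Compiled right-hand side of the three-layer PK / PK-PD system, in the
 * deSolve compiled-code convention (initializer + derivative function).
 *
 * States (amounts in ng PTX-equivalent, canonical ordering):
 *   y[0..2] free drug   central, tumor, peripheral
 *   y[3..5] NP-bound    central, tumor, peripheral
 *   y[6..8] MSC-bound   central, tumor, peripheral
 *   y[9]    TV, tumor bioluminescence (1e6 photon/s); frozen when pd_on = 0
 *   y[10]   cumulative eliminated mass (ng), mass-balance audit
 *
 * With dynamic geometry the tumor volume is recomputed from TV through the
 * power calibration at every evaluation and used in all exchange terms.
 */
#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <math.h>

#define NPARMS 33
static double parms[NPARMS];

#define CLp    parms[0]
#define CLDp   parms[1]
#define Vcp    parms[2]
#define Vpp    parms[3]
#define Ep     parms[4]
#define Pp     parms[5]
#define Dp     parms[6]
#define CLn    parms[7]
#define CLDn   parms[8]
#define Vcn    parms[9]
#define Vpn    parms[10]
#define En     parms[11]
#define Pn     parms[12]
#define Dn     parms[13]
#define Krel   parms[14]
#define Kexo   parms[15]
#define Kct    parms[16]
#define Kcp    parms[17]
#define VT0    parms[18]
#define Rt0    parms[19]
#define Rcap   parms[20]
#define Rk     parms[21]
#define DYN    parms[22]
#define CAL_A  parms[23]
#define CAL_B  parms[24]
#define TVFLR  parms[25]
#define Kg0    parms[26]
#define KmaxP  parms[27]
#define IC50P  parms[28]
#define KmaxN  parms[29]
#define IC50N  parms[30]
#define Kmsc   parms[31]
#define PD_ON  parms[32]

void nanomsc_init(void (*odeparms)(int *, double *))
{
    int n = NPARMS;
    odeparms(&n, parms);
}

void nanomsc_derivs(int *neq, double *t, double *y, double *ydot,
                    double *yout, int *ip)
{
    double VT, Rt, TV = y[9];

    if (DYN > 0.5) {
        double tvc = TV > TVFLR ? TV : TVFLR;
        VT = CAL_A * pow(tvc, CAL_B);
        Rt = cbrt(3.0 * VT / (4.0 * M_PI));
    } else {
        VT = VT0;
        Rt = Rt0;
    }

    double exP = (2.0 * Pp * Rcap / (Rk * Rk) + 6.0 * Dp / (Rt * Rt)) * VT;
    double exN = (2.0 * Pn * Rcap / (Rk * Rk) + 6.0 * Dn / (Rt * Rt)) * VT;

    double CcP = y[0] / Vcp, CcN = y[3] / Vcn;
    double fluxP = exP * (CcP * Ep - y[1] / VT);
    double fluxN = exN * (CcN * En - y[4] / VT);
    double distP = CLDp * (y[2] / Vpp - CcP);
    double distN = CLDn * (y[5] / Vpn - CcN);

    /* MSC layer: unidirectional extravasation + release + exocytosis */
    ydot[6] = -(Kct + Kcp + Krel + Kexo) * y[6];
    ydot[7] = Kct * y[6] - (Krel + Kexo) * y[7];
    ydot[8] = Kcp * y[6] - (Krel + Kexo) * y[8];

    /* NP layer: own disposition - release + exocytosis gain from MSC */
    ydot[3] = distN - CLn * CcN - fluxN - Krel * y[3] + Kexo * y[6];
    ydot[4] = fluxN - Krel * y[4] + Kexo * y[7];
    ydot[5] = -distN - Krel * y[5] + Kexo * y[8];

    /* free-drug layer: own disposition + release gains from NP and MSC */
    ydot[0] = distP - CLp * CcP - fluxP + Krel * (y[3] + y[6]);
    ydot[1] = fluxP + Krel * (y[4] + y[7]);
    ydot[2] = -distP + Krel * (y[5] + y[8]);

    /* tumor growth with three parallel kill terms */
    if (PD_ON > 0.5) {
        double cP = y[1] / VT, cN = y[4] / VT, cM = y[7] / VT;
        if (cP < 0.0) cP = 0.0;
        if (cN < 0.0) cN = 0.0;
        if (cM < 0.0) cM = 0.0;
        double kill = KmaxP * cP / (IC50P + cP) + KmaxN * cN / (IC50N + cN)
                      + Kmsc * cM;
        ydot[9] = (Kg0 - kill) * TV;
    } else {
        ydot[9] = 0.0;
    }

    /* eliminated-mass accumulator */
    ydot[10] = CLp * CcP + CLn * CcN;

    if (ip[0] >= 1)
        yout[0] = VT;
}

void nanomsc_etd(double *, double *, int *, double *, int *, double *,
                 int *, double *, double *, double *, double *, double *);

static const R_CMethodDef cMethods[] = {
    {"nanomsc_init",   (DL_FUNC) &nanomsc_init,   1},
    {"nanomsc_derivs", (DL_FUNC) &nanomsc_derivs, 6},
    {"nanomsc_etd",    (DL_FUNC) &nanomsc_etd,    12},
    {NULL, NULL, 0}
};

void R_init_nanomsc(DllInfo *dll)
{
    R_registerRoutines(dll, cMethods, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
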