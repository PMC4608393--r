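/* Per-cell ODE right-hand side for the NF-kB activation model.
 *
 * State vector (15 species, time in minutes):
 *   0  L     extracellular ligand (ng/ml); depletes in sealed mode
 *   1  B     active receptor complex (fraction of the cell's receptors)
 *   2  T     active TRAF6 (fraction)
 *   3  IKKn  neutral IKK        (IKK pool is a closed cycle, total = 1)
 *   4  IKKa  active IKK
 *   5  IKKi  inactive IKK
 *   6  Im    IkBa mRNA
 *   7  I     free cytoplasmic IkBa
 *   8  In    free nuclear IkBa
 *   9  N     free cytoplasmic NF-kB
 *  10  Nn    free nuclear NF-kB
 *  11  NI    cytoplasmic NF-kB:IkBa complex
 *  12  NIn   nuclear NF-kB:IkBa complex
 *  13  Am    A20 mRNA
 *  14  A     A20 protein
 *
 * Total NF-kB (N + Nn + NI + NIn) is conserved exactly by construction.
 *
 * Parameter vector layout (see parmVector() on the R side):
 *   0 kb, 1 kdb, 2 kt, 3 kdt, 4 aT, 5 hill_n, 6 hill_K, 7 ka, 8 ki, 9 kr,
 *  10 aI, 11 c1, 12 c3, 13 c4, 14 c5, 15 d_ikba, 16 kin_i, 17 kex_i,
 *  18 a1, 19 a1n, 20 kin_n, 21 kex_c, 22 d_nic, 23 c6, 24 c1a, 25 c3a,
 *  26 c4a, 27 c5a, 28 kdep0, 29 kdep1, 30 kself, 31 R, 32 Ntot, 33 sealed
 */
#include <R.h>
#include <Rinternals.h>
#include <math.h>

#define NSTATE 15
#define NPARMS 34

static double parms[NPARMS];

void nfkb_initmod(void (*odeparms)(int *, double *))
{
    int n = NPARMS;
    odeparms(&n, parms);
}

static void nfkb_core(double t, const double *y, double *dy, const double *p)
{
    double L    = y[0] > 0.0 ? y[0] : 0.0;
    double B    = y[1];
    double T    = y[2] > 0.0 ? y[2] : 0.0;
    double IKKn = y[3], IKKa = y[4], IKKi = y[5];
    double Im   = y[6], I = y[7], In = y[8];
    double N    = y[9], Nn = y[10], NI = y[11], NIn = y[12];
    double Am   = y[13], A = y[14];

    double R = p[31];

    /* cooperative TRAF6 -> IKK activation (Hill) */
    double hill = 0.0;
    if (T > 0.0) {
        double Tn = pow(T, p[5]);
        double Kn = pow(p[6], p[5]);
        hill = Tn / (Kn + Tn);
    }

    /* sealed-chamber ligand depletion: chamber-level + receptor-scaled term */
    double depl = p[33] > 0.5 ? (p[28] + p[29] * R) : 0.0;

    double act   = p[7] * hill * IKKn;                 /* IKK activation   */
    double inact = p[8] * IKKa * (1.0 + p[10] * A);    /* A20-boosted off  */
    double bindc = p[18] * I * N;                      /* cyt sequestration */
    double bindn = p[19] * In * Nn;                    /* nuc sequestration */
    double rel   = (p[22] * IKKa + p[23]) * NI;        /* IkBa degradation in
                                                          complex frees NF-kB */

    dy[0]  = -depl * L;
    dy[1]  = p[0] * L * (1.0 - B) - p[1] * B;
    dy[2]  = (p[2] * R * B + p[30] * T * T) * (1.0 - T)
             - p[3] * T * (1.0 + p[4] * A);
    dy[3]  = p[9] * IKKi - act;
    dy[4]  = act - inact;
    dy[5]  = inact - p[9] * IKKi;
    dy[6]  = p[11] * Nn - p[12] * Im;
    dy[7]  = p[13] * Im - bindc - p[16] * I + p[17] * In
             - p[15] * IKKa * I - p[14] * I;
    dy[8]  = p[16] * I - p[17] * In - bindn;
    dy[9]  = rel - bindc - p[20] * N;
    dy[10] = p[20] * N - bindn;
    dy[11] = bindc + p[21] * NIn - rel;
    dy[12] = bindn - p[21] * NIn;
    dy[13] = p[24] * Nn - p[25] * Am;
    dy[14] = p[26] * Am - p[27] * A;
}

/* deSolve entry point */
void nfkb_derivs(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
    nfkb_core(*t, y, ydot, parms);
}

/* standalone .Call entry point so R-level code and tests can evaluate the
 * same right-hand side outside the integrator */
SEXP C_nfkb_rhs(SEXP ySEXP, SEXP tSEXP, SEXP pSEXP)
{
    if (LENGTH(ySEXP) != NSTATE)
        error("state vector must have %d elements", NSTATE);
    if (LENGTH(pSEXP) != NPARMS)
        error("parameter vector must have %d elements", NPARMS);
    SEXP out = PROTECT(allocVector(REALSXP, NSTATE));
    nfkb_core(asReal(tSEXP), REAL(ySEXP), REAL(out), REAL(pSEXP));
    UNPROTECT(1);
    return out;
}
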