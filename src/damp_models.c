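/* Compiled right-hand sides for the batch-culture mutagenesis models,
 * using the deSolve compiled-model interface.  The parameter vector and
 * state layouts mirror the R reference implementation in R/model_core.R:
 *
 * parms[0..18]  U1 M1 Ks I1 D1 O2 I2 D2 C1 C2 R1 S r O3 R2 Met1 CellVol
 *               molML GCperGen
 * parms[19]     variant code (A=1 .. K=11, coculture=12)
 * parms[20..34] U2 K2 ROSC ROSC2 kdiff C3 C3a C3G C3b C3c Kt kAhp kmAhp
 *               kKat kmKat
 *
 * mono state (11): eGlc iGlc dGTP DNA wtCell ROS odGTP mDNA mCell cytVol
 *                  ROSexternal
 * coculture state (20): eGlc | wt block (iGlc dGTP DNA wtCell ROS odGTP
 *                  mDNA mCell cytVol) | ROSexternal | Hpx- block (9)
 *
 * Derivatives are evaluated on the state clamped at zero, and uptake
 * fluxes are gated off once external glucose is exhausted (required for
 * the variant-B uptake law, which does not vanish at eGlc = 0).
 */

#include <R.h>
#include <R_ext/Rdynload.h>

#define N_PARMS 35

static double parms[N_PARMS];

void dampsim_initmod(void (*odeparms)(int *, double *))
{
    int n = N_PARMS;
    odeparms(&n, parms);
}

static double clamp0(double x) { return x > 0.0 ? x : 0.0; }

void dampsim_derivs_mono(int *neq, double *t, double *y, double *ydot,
                         double *yout, int *ip)
{
    const double U1 = parms[0], M1 = parms[1], Ks = parms[2], I1 = parms[3],
                 D1 = parms[4], O2 = parms[5], I2 = parms[6], D2 = parms[7],
                 C1 = parms[8], C2 = parms[9], R1 = parms[10], S = parms[11],
                 r = parms[12], O3 = parms[13], R2 = parms[14],
                 Met1 = parms[15], CellVol = parms[16], molML = parms[17],
                 GCperGen = parms[18];
    const int code = (int) parms[19];
    const double U2 = parms[20], K2 = parms[21], ROSC = parms[22],
                 ROSC2 = parms[23], kdiff = parms[24], C3 = parms[25],
                 C3a = parms[26], C3G = parms[27], C3b = parms[28],
                 C3c = parms[29], Kt = parms[30], kAhp = parms[31],
                 kmAhp = parms[32], kKat = parms[33], kmKat = parms[34];

    double eGlc = clamp0(y[0]), iGlc = clamp0(y[1]), dGTP = clamp0(y[2]),
           DNA = clamp0(y[3]), wt = clamp0(y[4]), ROS = clamp0(y[5]),
           od = clamp0(y[6]), mDNA = clamp0(y[7]), cytVol = clamp0(y[9]),
           ROSext = clamp0(y[10]);
    double uptake, ROSeff, oxid;

    if (eGlc <= 0.0)
        uptake = 0.0;
    else if (code == 2)
        /* the exhaustion factor (scale 1e-9 M, far below Ks) smoothly
         * shuts off the upregulated-importer flux, which unlike Monod
         * kinetics does not vanish at eGlc = 0 */
        uptake = U1 * wt * (U2 - eGlc) / (U2 - eGlc + K2)
                 * eGlc / (eGlc + 1e-9);
    else
        uptake = U1 * wt * eGlc / (eGlc + Ks);

    ROSeff = (code == 3) ? ROSC : ROS;
    oxid = dGTP * ROSeff * O2;

    ydot[0] = -uptake;
    ydot[1] = uptake / cytVol - Met1 * M1 * iGlc;
    ydot[2] = M1 * iGlc - I1 * dGTP - oxid;
    ydot[3] = I1 * dGTP + C2 * mDNA + S * mDNA + R1 * od - D1 * DNA;
    ydot[4] = (D1 * DNA + R2 * mDNA) * cytVol;

    switch (code) {
    case 3:  /* constant cytoplasmic peroxide: no ROS state */
        ydot[5] = 0.0;
        break;
    case 4:  /* D: external source, membrane diffusion */
        ydot[5] = kdiff * (ROSext - ROS) - oxid - O3 * ROS;
        break;
    case 5:  /* E: degradation gated by internal glucose */
        ydot[5] = M1 * r * iGlc - oxid - O3 * ROS * iGlc / (iGlc + C3);
        break;
    case 6:  /* F: degradation proportional to population density */
        ydot[5] = M1 * r * iGlc - oxid - ROS * (molML / GCperGen) * wt * C3a;
        break;
    case 11: /* K: separate Ahp/Kat Michaelis-Menten sinks + diffusion */
        ydot[5] = M1 * r * iGlc - oxid - kAhp * ROS / (ROS + kmAhp)
                  - kKat * ROS / (ROS + kmKat) - kdiff * (ROS - ROSext);
        break;
    default:
        ydot[5] = M1 * r * iGlc - oxid - O3 * ROS;
    }

    switch (code) {
    case 7:  /* G: MutT activity rises with internal glucose (no R1 sink);
              C3G sits just above the largest iGlc reached, keeping the
              up-regulation factor 1/(1 - iGlc/C3G) positive */
        ydot[6] = oxid - C1 * od / (1.0 - iGlc / C3G) - I2 * od;
        break;
    case 8:  /* H: MutT activity rises with odGTP */
        ydot[6] = oxid - C1 * od / (1.0 - od / C3b) - I2 * od;
        break;
    case 9:  /* I: MutT activity rises with ROS */
        ydot[6] = oxid - C1 * od / (1.0 - ROS / C3c) - I2 * od;
        break;
    case 10: /* J: Michaelis-Menten MutT kinetics */
        ydot[6] = oxid - C1 * od * od / (od + Kt) - I2 * od;
        break;
    default:
        ydot[6] = oxid - C1 * od - I2 * od - R1 * od;
    }

    ydot[7] = I2 * od - D2 * mDNA - C2 * mDNA - S * mDNA - R2 * mDNA;
    ydot[8] = D2 * mDNA * cytVol;
    ydot[9] = (D1 * DNA + R2 * mDNA) * cytVol * molML / GCperGen * CellVol;

    if (code == 4)
        ydot[10] = ROSC2 + cytVol / (1.0 - cytVol) * kdiff * (ROS - ROSext);
    else if (code == 11)
        ydot[10] = kdiff * (ROS - ROSext) * cytVol / (1.0 - cytVol);
    else
        ydot[10] = 0.0;
}

/* one metabolic block of the two-population model (model D kinetics);
 * O3b = 0 for the Hpx- block */
static void cocult_block(const double *b, double uptake, double O3b,
                         double ROSext, double *d)
{
    const double M1 = parms[1], I1 = parms[3], D1 = parms[4], O2 = parms[5],
                 I2 = parms[6], D2 = parms[7], C1 = parms[8], C2 = parms[9],
                 R1 = parms[10], S = parms[11], R2 = parms[14],
                 Met1 = parms[15], CellVol = parms[16], molML = parms[17],
                 GCperGen = parms[18], kdiff = parms[24];
    double iGlc = b[0], dGTP = b[1], DNA = b[2], ROS = b[4], od = b[5],
           mDNA = b[6], cytVol = b[8];
    double oxid = dGTP * ROS * O2;

    d[0] = uptake / cytVol - Met1 * M1 * iGlc;
    d[1] = M1 * iGlc - I1 * dGTP - oxid;
    d[2] = I1 * dGTP + C2 * mDNA + S * mDNA + R1 * od - D1 * DNA;
    d[3] = (D1 * DNA + R2 * mDNA) * cytVol;
    d[4] = -oxid - O3b * ROS - kdiff * (ROS - ROSext);
    d[5] = oxid - C1 * od - I2 * od - R1 * od;
    d[6] = I2 * od - D2 * mDNA - C2 * mDNA - S * mDNA - R2 * mDNA;
    d[7] = D2 * mDNA * cytVol;
    d[8] = (D1 * DNA + R2 * mDNA) * cytVol * molML / GCperGen * CellVol;
}

void dampsim_derivs_cocult(int *neq, double *t, double *y, double *ydot,
                           double *yout, int *ip)
{
    const double U1 = parms[0], Ks = parms[2], O3 = parms[13],
                 ROSC2 = parms[23], kdiff = parms[24];
    double s[20];
    double monod, upt_w, upt_h, free_vol;
    int i;

    for (i = 0; i < 20; i++) s[i] = clamp0(y[i]);

    monod = s[0] > 0.0 ? s[0] / (s[0] + Ks) : 0.0;
    upt_w = U1 * s[4] * monod;       /* s[4]  = wtCell      */
    upt_h = U1 * s[14] * monod;      /* s[14] = wtCell_hpx  */
    free_vol = 1.0 - s[9] - s[19];   /* 1 - cytVol - cytVol_hpx */

    ydot[0] = -upt_w - upt_h;
    cocult_block(s + 1, upt_w, O3, s[10], ydot + 1);
    ydot[10] = ROSC2
        + s[9] / free_vol * kdiff * (s[5] - s[10])
        + s[19] / free_vol * kdiff * (s[15] - s[10]);
    cocult_block(s + 11, upt_h, 0.0, s[10], ydot + 11);
}

static const R_CMethodDef cMethods[] = {
    {"dampsim_initmod",       (DL_FUNC) &dampsim_initmod,       1},
    {"dampsim_derivs_mono",   (DL_FUNC) &dampsim_derivs_mono,   6},
    {"dampsim_derivs_cocult", (DL_FUNC) &dampsim_derivs_cocult, 6},
    {NULL, NULL, 0}
};

void R_init_dampsim(DllInfo *dll)
{
    R_registerRoutines(dll, cMethods, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
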