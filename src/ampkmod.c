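/* Compiled right-hand side of the AMPK-mTORC1-ULK1-ATG model for
 * deSolve's compiled-model interface. Parameter vector layout (36):
 *  0 kaA   1 S     2 kiA   3 kiAU  4 kiAM  5 kamtor 6 kiM  7 kiMA
 *  8 kiMU  9 kaUA 10 kiU  11 kiUM 12 kaGU 13 kaG0  14 kiG 15 kiGM
 * 16 JaA  17 JiA  18 JaM  19 JiM  20 JaU  21 JiU   22 JaG 23 JiG
 * 24 AT   25 MT   26 UT   27 GT   28 w    29..35 edges a..g
 */
#include <R.h>

static double parms[36];

void ampk_initmod(void (*odeparms)(int *, double *))
{
    int n = 36;
    odeparms(&n, parms);
}

void ampk_derivs(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
    const double *p = parms;
    double A = y[0], M = y[1], U = y[2], G = y[3];
    double w = p[28];
    double ea = p[29], eb = p[30], ec = p[31], ed = p[32];
    double ee = p[33], ef = p[34], eg = p[35];

    ydot[0] = p[0] * p[1] * (p[24] - A) / (p[16] + p[24] - A) -
        (p[2] + eb * p[3] * U + w * p[4] * M) * A / (p[17] + A);
    ydot[1] = p[5] * (p[25] - M) / (p[18] + p[25] - M) -
        (p[6] + ee * p[7] * A + ed * p[8] * U) * M / (p[19] + M);
    ydot[2] = ea * p[9] * A * (p[26] - U) / (p[20] + p[26] - U) -
        (p[10] + ec * p[11] * M) * U / (p[21] + U);
    ydot[3] = (p[13] + eg * p[12] * U) * (p[27] - G) / (p[22] + p[27] - G) -
        (p[14] + ef * p[15] * M) * G / (p[23] + G);
}
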