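/* Reduced two-variable HN model: membrane potential and intracellular
 * [Na+] with instantaneous gating.  Compiled right-hand side for deSolve.
 *
 * State: y[0] V (V), y[1] Nai (M).
 * Units as in full_model.c.
 */
#include <R.h>
#include <math.h>

#define N_RED_PARMS 30

static double rp[N_RED_PARMS];
/* parameter order -- must match .reduced_parms_vector() on the R side:
   0 gNaPn 1 gNaP  2 gNaF  3 gh  4 gK2  5 glNa  6 glK
   7 Eh  8 EK  9 ElK  10 Imax  11 Naih  12 Nais  13 Nao  14 Cm  15 vF
   16 A_mNaPn 17 B_mNaPn  18 A_mNaP 19 B_mNaP  20 A_mNaF 21 B_mNaF
   22 A_hNaF 23 B_hNaF  24 Ah1_mh 25 Ah2_mh 26 B_mh  27 A_mK2 28 B_mK2
   29 enaK (Nernst slope) */

void hn_red_init(void (*odeparms)(int *, double *))
{
    int n = N_RED_PARMS;
    odeparms(&n, rp);
}

void hn_red_deriv(int *neq, double *t, double *y, double *ydot,
                  double *yout, int *ip)
{
    double V = y[0], Nai = y[1];
    double ENa = rp[29] * log(rp[13] / Nai);

    double mNaPn = 1.0 / (1.0 + exp(rp[16] * (V + rp[17])));
    double mNaP  = 1.0 / (1.0 + exp(rp[18] * (V + rp[19])));
    double mNaF  = 1.0 / (1.0 + exp(rp[20] * (V + rp[21])));
    double hNaF  = 1.0 / (1.0 + exp(rp[22] * (V + rp[23])));
    double mh    = 1.0 / (1.0 + 2.0 * exp(rp[24] * (V + rp[26]))
                              + exp(rp[25] * (V + rp[26])));
    double mK2   = 1.0 / (1.0 + exp(rp[27] * (V + rp[28])));

    double INaPn = rp[0] * mNaPn * (V - ENa);
    double INaP  = rp[1] * mNaP * (V - ENa);
    double INaF  = rp[2] * mNaF * mNaF * mNaF * hNaF * (V - ENa);
    double Ih    = rp[3] * mh * mh * (V - rp[7]);
    double IhNa  = (3.0 / 7.0) * Ih;
    double IhK   = (4.0 / 7.0) * Ih;
    double IK2   = rp[4] * mK2 * mK2 * (V - rp[8]);
    double IlNa  = rp[5] * (V - ENa);
    double IlK   = rp[6] * (V - rp[9]);
    double Ipump = rp[10] / (1.0 + exp((rp[11] - Nai) / rp[12]));

    ydot[0] = -(INaPn + INaP + Ipump + INaF + IhNa + IhK + IlNa + IlK + IK2)
            / rp[14];
    /* Eq. 4: native, h and leak Na+ fluxes included; pump x3 */
    ydot[1] = -(INaPn + INaP + 3.0 * Ipump + INaF + IhNa + IlNa) / rp[15];

    if (ip[0] >= 2) {
        yout[0] = INaP;
        yout[1] = Ipump;
    }
}
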