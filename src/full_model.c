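/* Full HN "virtual hybrid neuron": canonical single-compartment HN model
 * with dynamic-clamp style injected persistent Na+ and Na+/K+ pump currents
 * and intracellular Na+ bookkeeping.
 *
 * Compiled right-hand side for deSolve (lsoda).  State vector (16):
 *   y[0]  V      membrane potential (V)
 *   y[1]  Nai    intracellular [Na+] (M)
 *   y[2..15]     gating: mNaF hNaF mNaP mNaPn mK1 hK1 mK2 mKA hKA mh
 *                mCaF hCaF mCaS hCaS
 *
 * Units: V, s, nS, nA, nF, M (nS * V = nA; nA / nF = V/s).
 */
#include <R.h>
#include <math.h>

#define N_FULL_PARMS 23

static double fp[N_FULL_PARMS];
/* parameter order -- must match .full_parms_vector() on the R side:
   0 gNaF  1 gNaP  2 gNaPn 3 gK1  4 gK2  5 gKA  6 gh  7 gCaF  8 gCaS
   9 gleak 10 EK  11 Eh  12 ECa  13 Eleak 14 Imax 15 Imaxn
   16 Naih 17 Nais 18 Nao 19 Cm  20 vF  21 Iapp 22 enaK (Nernst slope) */

void hn_full_init(void (*odeparms)(int *, double *))
{
    int n = N_FULL_PARMS;
    odeparms(&n, fp);
}

/* one forcing channel: piecewise-constant stochastic current (nA) */
static double ffc[1];
void hn_full_forc(void (*odeforcs)(int *, double *))
{
    int n = 1;
    odeforcs(&n, ffc);
}

static double boltz(double A, double B, double V)
{
    return 1.0 / (1.0 + exp(A * (V + B)));
}

static double taug(double A, double B, double C, double D, double V)
{
    return C + D / (1.0 + exp(A * (V + B)));
}

void hn_full_deriv(int *neq, double *t, double *y, double *ydot,
                   double *yout, int *ip)
{
    double V = y[0], Nai = y[1];
    double mNaF = y[2], hNaF = y[3], mNaP = y[4], mNaPn = y[5];
    double mK1 = y[6], hK1 = y[7], mK2 = y[8], mKA = y[9], hKA = y[10];
    double mh = y[11], mCaF = y[12], hCaF = y[13], mCaS = y[14], hCaS = y[15];

    double ENa = fp[22] * log(fp[18] / Nai);

    double INaF  = fp[0] * mNaF * mNaF * mNaF * hNaF * (V - ENa);
    double INaP  = fp[1] * mNaP * (V - ENa);
    double INaPn = fp[2] * mNaPn * (V - ENa);
    double IK1   = fp[3] * mK1 * mK1 * hK1 * (V - fp[10]);
    double IK2   = fp[4] * mK2 * mK2 * (V - fp[10]);
    double IKA   = fp[5] * mKA * mKA * hKA * (V - fp[10]);
    double Ih    = fp[6] * mh * mh * (V - fp[11]);
    double ICaF  = fp[7] * mCaF * mCaF * hCaF * (V - fp[12]);
    double ICaS  = fp[8] * mCaS * mCaS * hCaS * (V - fp[12]);
    double Ileak = fp[9] * (V - fp[13]);
    double spump = 1.0 / (1.0 + exp((fp[16] - Nai) / fp[17]));
    double Ipump  = fp[14] * spump;
    double Ipumpn = fp[15] * spump;

    double Isum = INaF + INaP + INaPn + IK1 + IK2 + IKA + Ih + ICaF + ICaS
                + Ipump + Ipumpn + Ileak;

    ydot[0] = (-Isum + fp[21] + ffc[0]) / fp[19];
    /* Eq. 1 bookkeeping: leak and h Na+ fluxes deliberately excluded */
    ydot[1] = -(INaP + INaPn + INaF + 3.0 * Ipump + 3.0 * Ipumpn) / fp[20];

    ydot[2]  = (boltz(-150.0, 0.029, V) - mNaF) / 0.0001;
    {
        double tau_hNa = 0.004 + 0.02 / cosh(300.0 * (V + 0.0027))
                       + 0.006 / (1.0 + exp(500.0 * (V + 0.028)));
        ydot[3] = (boltz(500.0, 0.03, V) - hNaF) / tau_hNa;
    }
    ydot[4]  = (boltz(-120.0, 0.039, V) - mNaP)
             / taug(400.0, 0.057, 0.01, 0.2, V);
    ydot[5]  = (boltz(-120.0, 0.039, V) - mNaPn)
             / taug(400.0, 0.057, 0.01, 0.2, V);
    ydot[6]  = (boltz(-143.0, 0.021, V) - mK1)
             / taug(150.0, 0.016, 0.001, 0.011, V);
    ydot[7]  = (boltz(111.0, 0.028, V) - hK1)
             / taug(-143.0, 0.013, 0.5, 0.2, V);
    ydot[8]  = (boltz(-83.0, 0.02, V) - mK2)
             / taug(200.0, 0.035, 0.057, 0.043, V);
    ydot[9]  = (boltz(-130.0, 0.044, V) - mKA)
             / taug(200.0, 0.03, 0.005, 0.011, V);
    ydot[10] = (boltz(160.0, 0.063, V) - hKA)
             / taug(-300.0, 0.055, 0.026, 0.0085, V);
    {
        double fh = 1.0 / (1.0 + 2.0 * exp(180.0 * (V + 0.047))
                               + exp(500.0 * (V + 0.047)));
        ydot[11] = (fh - mh) / taug(-100.0, 0.073, 0.7, 1.7, V);
    }
    ydot[12] = (boltz(-600.0, 0.0467, V) - mCaF)
             / taug(-330.0, 0.0467, 0.011, 0.024, V);
    ydot[13] = (boltz(350.0, 0.055, V) - hCaF)
             / taug(270.0, 0.055, 0.06, 0.31, V);
    ydot[14] = (boltz(-420.0, 0.0472, V) - mCaS)
             / taug(-400.0, 0.0487, 0.005, 0.134, V);
    ydot[15] = (boltz(360.0, 0.055, V) - hCaS)
             / taug(-250.0, 0.043, 0.2, 5.25, V);

    if (ip[0] >= 4) {
        yout[0] = INaP;    /* injected persistent Na+ current  */
        yout[1] = Ipump;   /* injected pump current            */
        yout[2] = INaPn;   /* native persistent Na+ current    */
        yout[3] = Ipumpn;  /* native pump current              */
    }
}
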