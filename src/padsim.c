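/* Compiled right-hand sides for the deSolve integrators.
 *
 * Two models share the same membrane equations (Morris-Lecar-type V/w pair
 * plus a slow sodium-inactivation gate h applied to a fraction p of gNa):
 *  - padsim_deriv_memb:  single compartment under a list of stimuli
 *  - padsim_deriv_cable: chain of segments with ohmic axial coupling,
 *    GABA conductance over a contiguous segment range, current pulses at
 *    one segment (state interleaved V,w,h per segment -> bandwidth 3)
 *
 * Units throughout: mV, ms, uA/cm2, mS/cm2, uF/cm2.
 */
#include <R.h>
#include <R_ext/Rdynload.h>
#include <math.h>

#define MEMB_NPAR 20
#define MAX_STIM 16
#define MEMB_PLEN (MEMB_NPAR + 8 * MAX_STIM)
#define CABLE_PLEN 32

static double mp[MEMB_PLEN];
static double cp[CABLE_PLEN];

static double xinf(double V, double b, double g)
{
    return 0.5 * (1.0 + tanh((V - b) / g));
}

/* tau(V) = 1/cosh((V-b)/(2g)); rate uses phi*(xinf-x)/tau */
static double xtau(double V, double b, double g)
{
    return 1.0 / cosh((V - b) / (2.0 * g));
}

void padsim_init_memb(void (*odeparms)(int *, double *))
{
    int N = MEMB_PLEN;
    odeparms(&N, mp);
}

void padsim_init_cable(void (*odeparms)(int *, double *))
{
    int N = CABLE_PLEN;
    odeparms(&N, cp);
}

/* Stimulus records, 8 doubles each, starting at mp[MEMB_NPAR]:
 *  type 1 conductance step:    [1, gden, Erev, t_on, duration, -, -, -]
 *  type 2 conductance ramp:    [2, gden, Erev, t_on, hold, rise, -, -]
 *  type 3 synaptic waveform:   [3, gden, Erev, t_on, tau_rise, tau_decay, x, -]
 *  type 4 current step:        [4, Iden, -, t_on, duration, -, -, -]
 */
void padsim_deriv_memb(int *neq, double *t, double *y, double *ydot,
                       double *yout, int *ip)
{
    const double C = mp[0], gNa = mp[1], ENa = mp[2], bm = mp[3], gm = mp[4];
    const double gK = mp[5], EK = mp[6], phiw = mp[7], bw = mp[8], gw = mp[9];
    const double gl = mp[10], El = mp[11], p = mp[12];
    const double bh = mp[13], gh = mp[14], phih = mp[15];
    const double gNav = mp[16], bmv = mp[17], gmv = mp[18];
    const int nstim = (int) mp[19];
    const double V = y[0], w = y[1], h = y[2];
    double Isyn = 0.0, Istim = 0.0;

    for (int k = 0; k < nstim; k++) {
        const double *s = mp + MEMB_NPAR + 8 * k;
        const int type = (int) s[0];
        const double tt = *t - s[3];
        if (type == 4) {
            if (tt >= 0.0 && tt < s[4])
                Istim += s[1];
            continue;
        }
        double g = 0.0;
        if (type == 1) {
            if (tt >= 0.0 && tt < s[4])
                g = s[1];
        } else if (type == 2) {
            if (tt >= 0.0 && tt < s[5] + s[4])
                g = (tt < s[5]) ? s[1] * tt / s[5] : s[1];
        } else if (type == 3) {
            if (tt >= 0.0)
                g = s[1] * s[6] * (exp(-tt / s[5]) - exp(-tt / s[4]));
        }
        Isyn += g * (V - s[2]);
    }

    double INa = gNa * xinf(V, bm, gm) * (V - ENa) * (p * h + (1.0 - p));
    if (gNav > 0.0)
        INa += gNav * xinf(V, bmv, gmv) * (V - ENa);

    ydot[0] = (Istim - INa - gK * w * (V - EK) - gl * (V - El) - Isyn) / C;
    ydot[1] = phiw * (xinf(V, bw, gw) - w) / xtau(V, bw, gw);
    ydot[2] = phih * (xinf(V, bh, gh) - h) / xtau(V, bh, gh);
}

/* cp layout:
 *  0 n_segments, 1 n_compartments, 2 segs_per_compartment, 3 axial coupling
 *    (mS/cm2, between adjacent segment centres),
 *  4..19 membrane: C gNa ENa bm gm gK EK phiw bw gw gl El p bh gh phih,
 *  20 gGABA density, 21 E_GABA, 22 g t_on, 23 g duration,
 *  24 first GABA segment (1-based), 25 last GABA segment,
 *  26 stimulated segment (1-based), 27 pulse amplitude (uA/cm2),
 *  28 pulse duration, 29 first pulse onset, 30 pulse interval, 31 n pulses.
 */
void padsim_deriv_cable(int *neq, double *t, double *y, double *ydot,
                        double *yout, int *ip)
{
    const int N = (int) cp[0];
    const double Kax = cp[3];
    const double C = cp[4], gNa = cp[5], ENa = cp[6], bm = cp[7], gm = cp[8];
    const double gK = cp[9], EK = cp[10], phiw = cp[11], bw = cp[12],
                 gw = cp[13];
    const double gl = cp[14], El = cp[15], p = cp[16];
    const double bh = cp[17], gh = cp[18], phih = cp[19];
    const double gden = cp[20], Eg = cp[21];
    const int gon = (*t >= cp[22] && *t < cp[22] + cp[23]);
    const int glo = (int) cp[24] - 1, ghi = (int) cp[25] - 1;
    const int sseg = (int) cp[26] - 1;
    const double amp = cp[27], pdur = cp[28], pt0 = cp[29], pint = cp[30];
    const int npulse = (int) cp[31];

    int pulse_on = 0;
    for (int k = 0; k < npulse; k++) {
        double tt = *t - (pt0 + k * pint);
        if (tt >= 0.0 && tt < pdur) {
            pulse_on = 1;
            break;
        }
    }

    for (int j = 0; j < N; j++) {
        const double V = y[3 * j], w = y[3 * j + 1], h = y[3 * j + 2];
        double I = (pulse_on && j == sseg) ? amp : 0.0;
        double Ig = (gon && j >= glo && j <= ghi) ? gden * (V - Eg) : 0.0;
        double ax = 0.0;
        if (j > 0)
            ax += Kax * (y[3 * (j - 1)] - V);
        if (j < N - 1)
            ax += Kax * (y[3 * (j + 1)] - V);
        double INa = gNa * xinf(V, bm, gm) * (V - ENa) * (p * h + (1.0 - p));
        ydot[3 * j] = (I - INa - gK * w * (V - EK) - gl * (V - El) - Ig + ax)
                      / C;
        ydot[3 * j + 1] = phiw * (xinf(V, bw, gw) - w) / xtau(V, bw, gw);
        ydot[3 * j + 2] = phih * (xinf(V, bh, gh) - h) / xtau(V, bh, gh);
    }
}

static const R_CMethodDef cMethods[] = {
    {"padsim_init_memb",   (DL_FUNC) &padsim_init_memb,   1},
    {"padsim_init_cable",  (DL_FUNC) &padsim_init_cable,  1},
    {"padsim_deriv_memb",  (DL_FUNC) &padsim_deriv_memb,  6},
    {"padsim_deriv_cable", (DL_FUNC) &padsim_deriv_cable, 6},
    {NULL, NULL, 0}
};

void R_init_padsim(DllInfo *dll)
{
    R_registerRoutines(dll, cMethods, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
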