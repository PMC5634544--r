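/* Compiled right-hand sides for the energy allocation model, in the
 * deSolve compiled-model convention (initfunc + derivs).
 *
 * Parameter vector (set via ea_init):
 *   0 p_W   price of waking effort
 *   1 p_B1  proportionality constant of the investment price p_B = p_B1*BD
 *   2 m_C   circadian mean level
 *   3 A     circadian amplitude (half peak-to-trough)
 *   4 TSTd  total sleep time as a fraction of the day (TST_h/24)
 *   5 r_Ww  wake-phase rate to waking effort
 *   6 r_Bw  wake-phase rate to biological investment
 *   7 r_Ws  sleep-phase rate to waking effort
 *   8 r_Bs  sleep-phase rate to biological investment
 *
 * Time unit is days; the day is [0, 1], wake first, sleep from 1 - TSTd.
 * The switch time itself belongs to the sleep phase; TSTd = 0 means no
 * sleep phase at all. Integration is driven from R in two segments with a
 * breakpoint at the switch, so the discontinuity is never stepped over.
 */

#include <R.h>
#include <math.h>

static double p[9];

void ea_init(void (*odeparms)(int *, double *))
{
    int n = 9;
    odeparms(&n, p);
}

static void rates_at(double t, double *rW, double *rB)
{
    double ts = 1.0 - p[4];
    if (p[4] <= 0.0 || t < ts) {
        *rW = p[5];
        *rB = p[6];
    } else {
        *rW = p[7];
        *rB = p[8];
    }
}

/* circadian efficiency multiplier, period one day, peak mid-sleep */
static double circ(double t)
{
    return p[2] - p[3] * sin(2.0 * M_PI * (t - 0.25 + 0.5 * p[4]));
}

/* scalar reduction: dBD/dt depends only on t and BD */
void ea_deriv_bd(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
    double rW, rB;
    double BD = y[0];
    double C = circ(*t);

    rates_at(*t, &rW, &rB);
    ydot[0] = p[0] * rW + rB * (p[1] * BD - C * BD / (1.0 + BD * BD));
}

/* full (BR, BI) pair; BD = BR - BI */
void ea_deriv_pair(int *neq, double *t, double *y, double *ydot,
                   double *yout, int *ip)
{
    double rW, rB;
    double BD = y[0] - y[1];
    double C = circ(*t);

    rates_at(*t, &rW, &rB);
    ydot[0] = p[0] * rW + p[1] * BD * rB;
    ydot[1] = C * BD / (1.0 + BD * BD) * rB;
}
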