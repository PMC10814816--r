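/* Method-of-lines right-hand side for the 1-D reaction-diffusion
 * predator-prey model, in the deSolve compiled-model interface.
 *
 * State layout: interleaved (u_1, v_1, u_2, v_2, ...) over nx cells so
 * that the Jacobian is banded with half-bandwidth 2.  The grid is
 * cell-centred on (0, l*pi); Neumann (zero-flux) boundaries enter via
 * mirror ghost cells.  parms = (a, b, c, d, h, D0, 1/dx^2); with
 * 1/dx^2 = 0 (or nx = 1) the same code integrates the kinetic ODE.
 */
#include <R.h>

static double parms[7];
#define P_A    parms[0]
#define P_B    parms[1]
#define P_C    parms[2]
#define P_D    parms[3]
#define P_H    parms[4]
#define P_D0   parms[5]
#define P_DXI2 parms[6]

void thb_init(void (*odeparms)(int *, double *))
{
    int n = 7;
    odeparms(&n, parms);
}

void thb_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    const int nx = *neq / 2;
    for (int i = 0; i < nx; i++) {
        const int im = (i == 0) ? 0 : i - 1;
        const int ipl = (i == nx - 1) ? nx - 1 : i + 1;
        const double lapu = (y[2 * im] - 2.0 * y[2 * i] + y[2 * ipl]) * P_DXI2;
        const double lapv = (y[2 * im + 1] - 2.0 * y[2 * i + 1] + y[2 * ipl + 1]) * P_DXI2;
        /* densities below 1e-30 count as extinct in the reaction terms:
         * this freezes the exponential decay towards the origin well above
         * the underflow region (absolute error < 1e-30), while diffusion
         * (computed from the raw values) can still recolonize a cell */
        const double u = (y[2 * i] > 1e-30) ? y[2 * i] : 0.0;
        const double v = (y[2 * i + 1] > 1e-30) ? y[2 * i + 1] : 0.0;
        const double s = u + v;
        /* ratio-dependent predation, 0 at the origin */
        const double r = (u <= 0.0 || v <= 0.0 || s < 1e-300) ? 0.0 : u * v / s;
        ydot[2 * i] = P_D0 * lapu + P_A * u * (1.0 - u) * (u - P_B) - r;
        ydot[2 * i + 1] = lapv + P_C * r - (P_D + P_H) * v;
    }
}
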