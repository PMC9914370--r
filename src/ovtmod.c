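/* Compiled right-hand side of the nine-compartment tumor-immune system,
 * in the deSolve compiled-code calling convention. Parameter layout matches
 * the R-side table order (45 model constants) followed by the effective
 * dose rate s, blockade fraction u, and the CD8-proliferation form flag. */

#include <R.h>

static double p[48];

#define r_u     p[0]
#define K_t     p[1]
#define beta_t  p[2]
#define m_v     p[3]
#define delta_c p[4]
#define m_t     p[5]
#define delta_x p[6]
#define m_x     p[7]
#define d_u     p[8]
#define r_i     p[9]
#define a_t     p[10]
#define delta_z p[11]
#define d_i     p[12]
#define b_t     p[13]
#define gamma_v p[14]
#define delta_v p[15]
#define d_v     p[16]
#define a_v     p[17]
#define a_x     p[18]
#define h_x     p[19]
#define gamma_x p[20]
#define nu      p[21]
#define a_y     p[22]
#define h_y     p[23]
#define gamma_y p[24]
#define alpha_n p[25]
#define b_n     p[26]
#define alpha_x p[27]
#define b_x     p[28]
#define alpha_y p[29]
#define b_y     p[30]
#define gamma_c p[31]
#define r_x     p[32]
#define r_y     p[33]
#define gamma_w p[34]
#define p_v     p[35]
#define gamma_z p[36]
#define s_n     p[37]
#define r_n     p[38]
#define K_n     p[39]
#define m_n     p[40]
#define delta_n p[41]
#define zeta    p[42]
#define h_n     p[43]
#define gamma_n p[44]
#define DOSE_S  p[45]
#define BLOCK_U p[46]
#define X_SCALED p[47]

void ovt_initmod(void (*odeparms)(int *, double *))
{
    int n = 48;
    odeparms(&n, p);
}

static double nn(double x) { return x > 0 ? x : 0; } /* clamp undershoot */

void ovt_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    double Tu = nn(y[0]), Ti = nn(y[1]), V = nn(y[2]), X = nn(y[3]);
    double Y = nn(y[4]), C = nn(y[5]), W = nn(y[6]), Z = nn(y[7]);
    double N = nn(y[8]);
    double Tt = Tu + Ti;

    double infect = beta_t * Tu * V / (m_v + Tu);
    double cd8_kill = delta_x * X / (m_x + X);
    double prolif = a_x * Tt / (h_x + Tt);
    if (X_SCALED > 0.5) prolif *= X;
    double cfac = 1.0 + nu * W;
    double avNV = a_v * N * V;
    double oneu = 1.0 - BLOCK_U;

    ydot[0] = r_u * Tu * (1.0 - Tt / K_t) - infect
            - delta_c * Tu * C / (m_t + Tu) - cd8_kill * Tu - d_u * N * Tu;
    ydot[1] = r_i * Ti * (1.0 - Tt / K_t) + infect - a_t * Ti
            - cd8_kill * Ti - delta_c * Ti * C / (m_t + Ti)
            - delta_z * Z * Ti - d_i * N * Ti;
    ydot[2] = b_t * a_t * Ti - delta_v * V * Z - gamma_v * V
            - d_v * N * V + DOSE_S;
    ydot[3] = avNV + prolif - gamma_x * X;
    ydot[4] = avNV / cfac + a_y * Tt / ((h_y + Tt) * cfac) * C - gamma_y * Y;
    ydot[5] = alpha_n * Tt * N / (1.0 + b_n * W)
            + alpha_x * Tt * X / (1.0 + b_x * W)
            + alpha_y * Tt * Y / (1.0 + b_y * W) - gamma_c * C;
    ydot[6] = r_x * oneu * X + r_y * oneu * Y - gamma_w * W;
    ydot[7] = p_v * Ti - gamma_z * Z;
    ydot[8] = s_n + r_n * N * (1.0 - N / K_n) * (Ti / (Ti + m_n))
            + zeta * C * N / (C + h_n) - delta_n * Tt * N - gamma_n * N;
}
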