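/* Compiled right-hand side of the 14-state alloimmune model, used by the
 * deSolve integrators. Mirrors the reference R implementation in
 * R/model.R exactly (the test suite asserts agreement); exists because
 * the sweep experiments and evolutionary calibration run tens of
 * thousands of integrations.
 *
 * Parameter vector layout (0-based):
 *   [0..10]   printed Treg-equation constants:
 *             k_eR mu_R r_RG alpha_6 a_R gamma_2 r_R alpha_2 e_R mu_RN T_0
 *   [11..43]  supplementary rates, registry order (see R/parameters.R)
 *   [44]      G0_ref  (initial graft cells; scales immature-DC decay)
 *   [45..49]  D0 beta f_G f_LN f_N
 *   [50]      number of dose days nd
 *   [51..]    dose days t_i (MAXDOSES slots, padded with 0)
 */

#include <math.h>

#define MAXDOSES 64
#define NPARMS (51 + MAXDOSES)

static double parms[NPARMS];

void tregsim_initmod(void (*odeparms)(int *, double *))
{
    int N = NPARMS;
    odeparms(&N, parms);
}

static double clamp0(double x) { return x > 0.0 ? x : 0.0; }

/* saturating ratio with the 0-denominator convention of the R RHS */
static double sdiv(double num, double den) { return den > 0.0 ? num / den : 0.0; }

void tregsim_derivs(int *neq, double *t, double *y, double *ydot,
                    double *yout, int *ip)
{
    /* printed constants */
    const double k_eR = parms[0], mu_R = parms[1], r_RG = parms[2],
        alpha_6 = parms[3], a_R = parms[4], gamma_2 = parms[5],
        r_R = parms[6], alpha_2 = parms[7], e_R = parms[8],
        mu_RN = parms[9], T_0 = parms[10];
    /* supplementary rates (registry order) */
    const double *s = parms + 11;
    const double mu_IA = s[0], m_A = s[1], k_mp = s[2], k_mh = s[3],
        kappa_RA = s[4], e_A = s[5], mu_A = s[6], a_H = s[7], a_E = s[8],
        gamma_act = s[9], kappa_act = s[10], r_H = s[11], r_E = s[12],
        alpha_T = s[13], mu_TH = s[14], mu_TE = s[15], e_H = s[16],
        e_E = s[17], mu_THG = s[18], mu_TEG = s[19], a_M = s[20],
        gamma_M = s[21], kappa_Ma = s[22], mu_M = s[23], p_p = s[24],
        kappa_pa = s[25], mu_Cp = s[26], p_a = s[27], mu_Ca = s[28],
        k_GE = s[29], k_GM = s[30], kappa_k = s[31], kappa_ca = s[32];
    const double G0_ref = parms[44];
    const double D0 = parms[45], beta = parms[46], f_G = parms[47],
        f_LN = parms[48], f_N = parms[49];
    const int nd = (int) parms[50];

    /* states */
    const double T_H_LN = y[0], T_E_LN = y[1], T_R_LN = y[2],
        T_RN_LN = y[3], A_mat_LN = y[4], T_H_G = y[5], T_E_G = y[6],
        T_R_G = y[7], A_imm = y[8], A_mat_G = y[9], A_inf = y[10],
        C_p = y[11], C_a = y[12], G = y[13];

    /* dosing input D(t): sum of active exponential boluses */
    double D = 0.0;
    if (D0 > 0.0) {
        for (int i = 0; i < nd; i++) {
            double dt = *t - parms[51 + i];
            if (dt >= 0.0) D += exp(-beta * dt);
        }
        D *= D0;
    }

    const double cT_R_G = clamp0(T_R_G), cT_R_LN = clamp0(T_R_LN),
        cA_mat_LN = clamp0(A_mat_LN), cC_p = clamp0(C_p),
        cC_a = clamp0(C_a), cT_H_G = clamp0(T_H_G),
        cT_H_LN = clamp0(T_H_LN), cT_E_LN = clamp0(T_E_LN),
        cG = clamp0(G);

    const double phi = sdiv(cC_p, k_mp + cC_p) + sdiv(cT_H_G, k_mh + cT_H_G);
    const double sup_G = sdiv(kappa_RA, kappa_RA + cT_R_G);
    const double sup_LN = sdiv(kappa_act, kappa_act + cT_R_LN);
    const double mat_flux = m_A * phi * sup_G * A_imm;
    const double act_drive = sdiv(cA_mat_LN, gamma_act + cA_mat_LN);

    /* T_H_LN */
    ydot[0] = a_H * act_drive * sup_LN +
        r_H * T_H_LN * sdiv(cA_mat_LN, alpha_T + cT_H_LN) * sup_LN -
        (mu_TH + e_H) * T_H_LN;
    /* T_E_LN */
    ydot[1] = a_E * act_drive * sup_LN +
        r_E * T_E_LN * sdiv(cA_mat_LN, alpha_T + cT_E_LN) * sup_LN -
        (mu_TE + e_E) * T_E_LN;
    /* T_R_LN (printed equation) */
    ydot[2] = a_R * T_RN_LN * sdiv(cA_mat_LN, gamma_2 + cA_mat_LN) -
        mu_R * T_R_LN +
        r_R * T_R_LN * sdiv(T_E_LN + T_H_LN, alpha_2 + cT_R_LN) -
        e_R * T_R_LN + f_LN * D;
    /* T_RN_LN (printed equation) */
    ydot[3] = mu_RN * (T_0 - T_RN_LN) + f_N * D;
    /* A_mat_LN */
    ydot[4] = e_A * A_mat_G - mu_A * A_mat_LN;
    /* T_H_G */
    ydot[5] = e_H * T_H_LN - mu_THG * T_H_G;
    /* T_E_G */
    ydot[6] = e_E * T_E_LN - mu_TEG * T_E_G;
    /* T_R_G (printed equation) */
    ydot[7] = k_eR * T_R_LN - mu_R * T_R_G +
        r_RG * T_R_G * sdiv(T_E_G + T_H_G, alpha_6 + cT_R_G) + f_G * D;
    /* A_imm: decay scaled by remaining graft mass, plus maturation loss */
    ydot[8] = -mu_IA * (cG / G0_ref) * A_imm - mat_flux;
    /* A_mat_G */
    ydot[9] = mat_flux - (e_A + mu_A) * A_mat_G;
    /* A_inf */
    ydot[10] = a_M * sdiv(cC_p, gamma_M + cC_p) *
        sdiv(kappa_Ma, kappa_Ma + cC_a) - mu_M * A_inf;
    /* C_p */
    ydot[11] = p_p * (A_mat_G + A_inf + T_E_G + T_H_G) *
        sdiv(kappa_pa, kappa_pa + cC_a) - mu_Cp * C_p;
    /* C_a */
    ydot[12] = p_a * T_R_G - mu_Ca * C_a;
    /* G: destruction only, jointly suppressed by graft Tregs and C_a */
    {
        double suppress = sdiv(kappa_k, kappa_k + cT_R_G) *
            sdiv(kappa_ca, kappa_ca + cC_a);
        ydot[13] = -(k_GE * T_E_G + k_GM * A_inf) * G * suppress;
    }
}
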