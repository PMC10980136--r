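/* Compiled right-hand side of the multiscale PK/PD system, for use with
 * deSolve's compiled-model interface. The parameter vector layout must match
 * .rhs_param_order in R/model.R; the state layout matches .state_names.
 */
#include <R.h>
#include <math.h>

#define N_PARMS 47

static double parms[N_PARMS];

/* parameter indices (keep in sync with .rhs_param_order) */
#define P_VPL        0   /* plasma volume, mL */
#define P_PHI        1   /* tumor interstitial fraction */
#define P_NP_DIAM    2
#define P_NP_PORE    3
#define P_NP_PREF    4
#define P_NP_DEG     5
#define P_NP_CL      6
#define P_NP_PAYLOAD 7
#define P_NP_DIFF    8
#define P_TR_S       9
#define P_TR_LEN    10   /* micrometers */
#define P_TR_FC     11
#define P_TR_FT     12
#define P_TR_VC     13
#define P_TR_VT     14
#define P_MI_G0     15
#define P_MI_DM     16
#define P_MI_KM     17
#define P_MI_AML    18
#define P_MI_AAM    19
#define P_MI_EC50   20
#define P_MI_DAM    21
#define P_MI_KEXO   22
#define P_CK_GL     23
#define P_CK_DL     24
#define P_CK_KML    25
#define P_CK_P1EQ   26
#define P_CK_DP1    27
#define P_CK_KDPP   28
#define P_CK_KDA    29
#define P_CK_KDP    30
#define P_CK_DT     31
#define P_CK_KI     32
#define P_CK_ESC    33
#define P_CH_CL     34
#define P_CH_PERM   35
#define P_CH_DTU    36
#define P_CH_KILL   37
#define P_CH_IC50   38
#define P_CH_RC     39
#define P_IC_CL     40
#define P_IC_PERM   41
#define P_IC_DTU    42
#define P_IC_MWA    43
#define P_IC_MWP    44
#define P_GR_GAMMA  45
#define P_GR_K      46

void antimir_initmod(void (*odeparms)(int *, double *))
{
    int n = N_PARMS;
    odeparms(&n, parms);
}

void antimir_derivs(int *neq, double *t, double *y, double *ydot,
                    double *yout, int *ip)
{
    double s[16];
    int i;
    for (i = 0; i < 16; i++) s[i] = y[i] > 0 ? y[i] : 0.0;

    /* volume floored at one cell so transport terms stay finite */
    double v  = s[15] > 1e-9 ? s[15] : 1e-9;
    double vi = parms[P_PHI] * v;
    double vpl = parms[P_VPL];

    /* derived transport quantities */
    double hind = 1.0 - parms[P_NP_DIAM] / parms[P_NP_PORE];
    double p_np = parms[P_NP_PREF] * hind * hind;
    double len_cm = parms[P_TR_LEN] * 1e-4;
    double k_diff = parms[P_NP_DIFF] * (100.0 / parms[P_NP_DIAM]) /
        (len_cm * len_cm);
    double psv_np = p_np * parms[P_TR_S] * v;

    /* nanoparticles */
    double j_np = psv_np * (s[0] / vpl - s[1] / vi);
    ydot[0] = -(parms[P_NP_CL] + parms[P_NP_DEG]) * s[0] - j_np;
    ydot[1] = j_np - parms[P_NP_DEG] * s[1] - k_diff * s[1];

    /* intracellular anti-miR-155 */
    double rel = k_diff * s[1] * parms[P_NP_PAYLOAD];
    ydot[2] = parms[P_TR_FC] * rel / parms[P_TR_VC] - parms[P_MI_DAM] * s[2];
    ydot[3] = parms[P_TR_FT] * rel / parms[P_TR_VT] - parms[P_MI_DAM] * s[3];

    /* miR-155 */
    double mir_eq = parms[P_MI_G0] / parms[P_MI_DM];
    double g0_c = parms[P_MI_G0] - parms[P_MI_KEXO] * mir_eq;
    double hill_c = parms[P_MI_AAM] * s[2] / (parms[P_MI_EC50] + s[2]);
    double hill_t = parms[P_MI_AAM] * s[3] / (parms[P_MI_EC50] + s[3]);
    ydot[4] = g0_c + parms[P_MI_KEXO] * s[5] -
        parms[P_MI_DM] * (1.0 + hill_c) * s[4];
    ydot[5] = parms[P_MI_G0] - parms[P_MI_DM] * (1.0 + hill_t) * s[5];

    /* PD-L1 (miR-155-repressed) and PD-1 (constant turnover) */
    ydot[6] = parms[P_CK_GL] * parms[P_CK_KML] / (parms[P_CK_KML] + s[4]) -
        parms[P_CK_DL] * s[6];
    ydot[7] = parms[P_CK_GL] * parms[P_CK_KML] / (parms[P_CK_KML] + s[5]) -
        parms[P_CK_DL] * s[7];
    ydot[8] = parms[P_CK_DP1] * (parms[P_CK_P1EQ] - s[8]);

    /* cisplatin */
    double j_cis = parms[P_CH_PERM] * parms[P_TR_S] * v *
        (s[9] / vpl - s[10] / vi);
    ydot[9]  = -parms[P_CH_CL] * s[9] - j_cis;
    ydot[10] = j_cis - parms[P_CH_DTU] * s[10];
    double cis_conc = s[10] / vi;

    /* immune checkpoint inhibitors */
    double psv_ici = parms[P_IC_PERM] * parms[P_TR_S] * v;
    double j_ate = psv_ici * (s[11] / vpl - s[12] / vi);
    ydot[11] = -parms[P_IC_CL] * s[11] - j_ate;
    ydot[12] = j_ate - parms[P_IC_DTU] * s[12];
    double j_pem = psv_ici * (s[13] / vpl - s[14] / vi);
    ydot[13] = -parms[P_IC_CL] * s[13] - j_pem;
    ydot[14] = j_pem - parms[P_IC_DTU] * s[14];
    double ate_pm = s[12] / vi / parms[P_IC_MWA] * 1e12;
    double pem_pm = s[14] / vi / parms[P_IC_MWP] * 1e12;

    /* checkpoint occupancy: equilibrium PD-1:PD-L1 complex under
     * competitive antibody binding, then saturable escape */
    double L = 0.5 * (s[6] + s[7]);
    double P = s[8];
    double kd_eff = parms[P_CK_KDPP] *
        (1.0 + ate_pm / parms[P_CK_KDA]) *
        (1.0 + pem_pm / parms[P_CK_KDP]);
    double sum = L + P + kd_eff;
    double disc = sum * sum - 4.0 * L * P;
    double X = (sum - sqrt(disc > 0 ? disc : 0)) / 2.0;
    double psi = 1.0 - parms[P_CK_ESC] * X / (parms[P_CK_KI] + X);

    /* tumor volume */
    double prolif = 1.0 + (parms[P_MI_AML] - 1.0) * s[4] /
        (parms[P_MI_KM] + s[4]);
    double ic50_eff = parms[P_CH_IC50] *
        (1.0 + parms[P_CH_RC] * s[4] / (parms[P_MI_KM] + s[4]));
    double d_chemo = parms[P_CH_KILL] * cis_conc / (ic50_eff + cis_conc);
    ydot[15] = parms[P_GR_GAMMA] * prolif * v *
        (1.0 - v / parms[P_GR_K]) -
        d_chemo * v - parms[P_CK_DT] * psi * v;
}
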