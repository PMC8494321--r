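/* Compiled derivative core of the 17-state NVU model for deSolve.
 *
 * The parameter vector layout MUST match the order of nvu_parameters() in
 * R/nvu-parameters.R (90 model constants), followed by one extra slot:
 * parms[90] = pathway (1..4) selecting where the forced perturbation enters.
 * One forcing series is supplied: the filtered vasoactive signal v(t).
 *
 * The pure-R nvu_derivatives() is the reference implementation; the two are
 * cross-checked term-wise in the test suite.
 */
#include <R.h>
#include <math.h>

#define N_PARMS 91

static double parms[N_PARMS];
static double forc[1];

/* parameter accessors, order identical to nvu_parameters() */
#define J_Ks0      parms[0]
#define J_SKmax    parms[1]
#define k_Na       parms[2]
#define KKO_a      parms[3]
#define rho0       parms[4]
#define K_rho      parms[5]
#define delta_G    parms[6]
#define K_G        parms[7]
#define r_h        parms[8]
#define k_deg      parms[9]
#define J_max      parms[10]
#define K_I        parms[11]
#define K_act      parms[12]
#define Ca_er      parms[13]
#define V_pump     parms[14]
#define K_pump     parms[15]
#define P_leak     parms[16]
#define B_cyt      parms[17]
#define k_on       parms[18]
#define K_inh      parms[19]
#define J_trpv     parms[20]
#define Ca_p_half  parms[21]
#define kap_cap    parms[22]
#define tau_trpv   parms[23]
#define V_eet      parms[24]
#define Ca_eet_min parms[25]
#define k_eet      parms[26]
#define eet_shift  parms[27]
#define v3b        parms[28]
#define v4b        parms[29]
#define phi_bk     parms[30]
#define g_bk       parms[31]
#define E_bk       parms[32]
#define g_leak_a   parms[33]
#define E_leak_a   parms[34]
#define g_trpv     parms[35]
#define E_trpv     parms[36]
#define c_isk      parms[37]
#define C_astr     parms[38]
#define c_jbk      parms[39]
#define VR_pa      parms[40]
#define c_jkir     parms[41]
#define VR_ps      parms[42]
#define R_decay    parms[43]
#define K_p_min    parms[44]
#define c_cap      parms[45]
#define Ca_A_ref   parms[46]
#define R_cap      parms[47]
#define Ca_p_min   parms[48]
#define E_kir_coef parms[49]
#define K_smc_i    parms[50]
#define K_kir_half parms[51]
#define s_kir_k    parms[52]
#define tau_kir    parms[53]
#define g_kir      parms[54]
#define v1s        parms[55]
#define v2s        parms[56]
#define g_ca       parms[57]
#define v_ca       parms[58]
#define v4s        parms[59]
#define v5s        parms[60]
#define v6s        parms[61]
#define Ca3        parms[62]
#define Ca4        parms[63]
#define phi_n      parms[64]
#define g_k        parms[65]
#define v_K        parms[66]
#define g_l        parms[67]
#define v_l        parms[68]
#define v_kv1      parms[69]
#define v_kv2      parms[70]
#define g_kv       parms[71]
#define C_smc      parms[72]
#define V_smc_ref  parms[73]
#define rho_ca     parms[74]
#define alpha_ca   parms[75]
#define k_ca       parms[76]
#define Ca_m       parms[77]
#define q_psi      parms[78]
#define k_w        parms[79]
#define k_y        parms[80]
#define s_y        parms[81]
#define omega_ref  parms[82]
#define p_t        parms[83]
#define k_pas      parms[84]
#define x_pas0     parms[85]
#define k_act      parms[86]
#define x_act0     parms[87]
#define eta_v      parms[88]
#define trpv_strain_gain parms[89]
#define PATHWAY    parms[90]

void nvu_initmod(void (*odeparms)(int *, double *)) {
  int N = N_PARMS;
  odeparms(&N, parms);
}

void nvu_initforc(void (*odeforcs)(int *, double *)) {
  int N = 1;
  odeforcs(&N, forc);
}

void nvu_derivs_c(int *neq, double *t, double *y, double *ydot,
                  double *yout, int *ip) {
  const double K_s = y[0], IP3 = y[1], Ca_A = y[2], h = y[3], ss = y[4],
               EET = y[5], n_bk = y[6], Vk = y[7], K_p = y[8], Ca_p = y[9],
               k = y[10], V_smc = y[11], n = y[12], Ca_smc = y[13],
               omega = y[14], yy = y[15], x = y[16];

  const double v = forc[0];
  const int pw = (int)PATHWAY;
  const double v1 = (pw == 1) ? v : 0.0;
  const double v2 = (pw == 2) ? v : 0.0;
  const double v3 = (pw == 3) ? v : 0.0;
  const double v4 = (pw == 4) ? v : 0.0;

  /* synaptic space */
  const double J_uptake = J_SKmax * k_Na * K_s / (K_s + KKO_a);
  ydot[0] = J_Ks0 + v1 - J_uptake;

  /* astrocyte IP3 */
  const double rho = rho0 * K_s / (K_s + K_rho);
  const double G = (rho + delta_G) / (K_G + rho + delta_G);
  ydot[1] = r_h * G - k_deg * IP3;

  /* astrocyte ER calcium */
  const double m_inf = IP3 / (IP3 + K_I);
  const double c_inf = Ca_A / (Ca_A + K_act);
  const double gate = m_inf * c_inf * h;
  const double J_ip3r = J_max * gate * gate * gate * (1.0 - Ca_A / Ca_er);
  const double J_pump = V_pump * Ca_A * Ca_A / (Ca_A * Ca_A + K_pump * K_pump);
  const double J_erleak = P_leak * (1.0 - Ca_A / Ca_er);
  ydot[2] = B_cyt * (J_ip3r + J_erleak - J_pump) + J_trpv * ss;
  ydot[3] = k_on * (K_inh - (Ca_A + K_inh) * h);

  /* TRPV4 gating */
  const double strain = trpv_strain_gain * (x - x_act0) / x_act0;
  const double s_inf = 1.0 / (1.0 + exp((Ca_p - Ca_p_half) / kap_cap - strain));
  ydot[4] = (s_inf - ss) / tau_trpv;

  /* EET and BK */
  const double ca_ex = Ca_A - Ca_eet_min;
  ydot[5] = V_eet * (ca_ex > 0.0 ? ca_ex : 0.0) - k_eet * EET;
  const double nbk_inf = 0.5 * (1.0 + tanh((Vk + eet_shift * EET - v3b) / v4b));
  ydot[6] = phi_bk * (nbk_inf - n_bk);

  /* astrocyte membrane */
  const double I_bk = g_bk * n_bk * (Vk - E_bk);
  const double I_leak_a = g_leak_a * (Vk - E_leak_a);
  const double I_trpv = g_trpv * ss * (Vk - E_trpv);
  const double I_sk = -c_isk * J_uptake;
  ydot[7] = (-I_bk - I_leak_a - I_trpv - I_sk + v2) / C_astr;

  /* perivascular space */
  const double E_kir = E_kir_coef * log(K_p / K_smc_i);
  const double k_inf = 1.0 / (1.0 + exp(-(K_p - K_kir_half) / s_kir_k));
  const double I_kir_pvs = g_kir * k * (V_smc_ref - E_kir);
  ydot[8] = c_jbk * I_bk / VR_pa + c_jkir * I_kir_pvs / VR_ps -
            R_decay * (K_p - K_p_min) + v3;
  ydot[9] = c_cap * (Ca_A - Ca_A_ref) - R_cap * (Ca_p - Ca_p_min);

  /* SMC KIR gating */
  ydot[10] = (k_inf - k) / tau_kir;

  /* SMC membrane */
  const double m_inf_s = 0.5 * (1.0 + tanh((V_smc - v1s) / v2s));
  const double I_ca = g_ca * m_inf_s * (V_smc - v_ca);
  const double v3s = -(v5s / 2.0) * tanh((Ca_smc - Ca3) / Ca4) + v6s;
  const double n_inf_s = 0.5 * (1.0 + tanh((V_smc - v3s) / v4s));
  const double lam_n = phi_n * cosh((V_smc - v3s) / (2.0 * v4s));
  const double I_k = g_k * n * (V_smc - v_K);
  const double I_l = g_l * (V_smc - v_l);
  const double I_kir = g_kir * k * (V_smc - E_kir);
  const double p_inf = 0.5 * (1.0 + tanh((V_smc - v_kv1) / v_kv2));
  const double I_kv = g_kv * p_inf * (V_smc - v_K);
  ydot[11] = (-I_l - I_k - I_ca - I_kir - I_kv + v4) / C_smc;
  ydot[12] = lam_n * (n_inf_s - n);
  ydot[13] = rho_ca * (-alpha_ca * I_ca - k_ca * Ca_smc);

  /* contraction and wall mechanics */
  const double caq = pow(Ca_smc > 0.0 ? Ca_smc : 0.0, q_psi);
  const double psi = caq / (caq + pow(Ca_m, q_psi));
  ydot[14] = k_w * (psi - omega);
  ydot[15] = k_y * (1.0 - s_y * (omega - omega_ref) - yy);
  const double T_pr = p_t * x;
  const double T_pas = k_pas * (x - x_pas0);
  const double T_act = k_act * omega * yy * (x / x_act0);
  ydot[16] = (T_pr - T_pas - T_act) / eta_v;
}

/* direct evaluation entry point (for cross-checking against the R reference
 * implementation): copies the parameter vector and forcing value into the
 * module statics and evaluates the derivative once */
void nvu_derivs_direct(double *y, double *p, double *v, double *ydot) {
  int i, neq = 17, ip = 0;
  double t = 0.0, yout = 0.0;
  for (i = 0; i < N_PARMS; i++) parms[i] = p[i];
  forc[0] = v[0];
  nvu_derivs_c(&neq, &t, y, ydot, &yout, &ip);
}
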