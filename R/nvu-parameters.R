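#' Default parameter set for the neurovascular-unit model
#'
#' Returns the full named parameter vector of the 17-state lumped
#' neurovascular unit (NVU): synaptic space, astrocyte, perivascular space and
#' arteriolar smooth-muscle cell (SMC), plus the Kelvin-Voigt vessel-wall
#' mechanics. The compartmental structure follows the bidirectional
#' astrocyte-microvessel model lineage of Witthoft & Karniadakis (2012),
#' Farr & David (2011) and Gonzalez-Fernandez & Ermentrout (1994); individual
#' constants are lineage values or design values chosen for a ~10 um cortical
#' arteriole operating at a stable resting point. Each entry carries a
#' provenance tag (see [nvu_parameter_table()]).
#'
#' Unit system (kept native throughout the model; conversions happen only at
#' I/O): time s, potential mV, conductance nS, current pA, capacitance nF,
#' potassium mM, calcium/IP3/EET uM, circumference um.
#'
#' @param ... named overrides of individual parameters.
#' @return named numeric vector with class `"nvu_parameters"`.
#' @export
#' @examples
#' p <- nvu_parameters()
#' p[["R_decay"]]
nvu_parameters <- function(...) {
  p <- c(
    ## -- synaptic space ------------------------------------------------
    J_Ks0    = 0.725926, # baseline K+ flux released into the synaptic space (mM/s)
    J_SKmax  = 5.6,      # maximum astrocytic K+ uptake flux (mM/s)
    k_Na     = 0.5,      # Na-dependent scaling of the uptake flux (dimensionless)
    KKO_a    = 10,       # half-saturation of synaptic K+ uptake (mM)
    ## -- astrocyte: IP3 / G-protein cascade ---------------------------
    rho0     = 1,        # maximal receptor occupancy driven by synaptic K+ (-)
    K_rho    = 8,        # synaptic K+ at half receptor occupancy (mM)
    delta_G  = 0.001235, # background G-protein activation (-)
    K_G      = 8.82,     # G-protein activation scale (-)
    r_h      = 4.8,      # maximal IP3 production rate (uM/s)
    k_deg    = 1.25,     # IP3 degradation rate (1/s)
    ## -- astrocyte: ER calcium (Li-Rinzel kinetics) --------------------
    J_max    = 800,      # maximal IP3R channel flux (uM/s)
    K_I      = 0.03,     # IP3 affinity of the IP3R (uM)
    K_act    = 0.17,     # Ca activation affinity of the IP3R (uM)
    Ca_er    = 400,      # effective ER calcium content scale (uM)
    V_pump   = 20,       # maximal SERCA pump rate (uM/s)
    K_pump   = 0.24,     # SERCA half-activation (uM)
    P_leak   = 0.26,     # ER leak permeability (uM/s)
    B_cyt    = 0.0244,   # cytosolic free-calcium buffering fraction (-)
    k_on     = 2,        # IP3R inactivation binding rate (1/(uM s))
    K_inh    = 0.1,      # Ca inhibition affinity of the IP3R gate (uM)
    ## -- astrocyte: TRPV4 / EET / BK ----------------------------------
    J_trpv   = 0.03,      # Ca influx per unit TRPV4 open probability (uM/s)
    Ca_p_half = 1600,    # perivascular Ca at half TRPV4 inhibition (uM)
    kap_cap  = 150,      # TRPV4 inhibition slope (uM)
    tau_trpv = 0.9,      # TRPV4 gating time constant (s)
    V_eet    = 72,       # EET production rate above threshold (1/s)
    Ca_eet_min = 0.05,   # Ca threshold for EET production (uM)
    k_eet    = 7.2,      # EET degradation rate (1/s)
    eet_shift = 2,       # depolarizing shift of BK activation per EET (mV/uM)
    v3b      = -60,      # BK half-activation potential (mV)
    v4b      = 12,       # BK activation slope (mV)
    phi_bk   = 0.1,      # effective BK endfoot signalling rate (1/s)
    ## -- astrocyte membrane -------------------------------------------
    g_bk     = 0.8,      # BK conductance (nS)
    E_bk     = -95,      # K+ reversal at the endfoot (mV)
    g_leak_a = 1.0,      # astrocyte leak conductance (nS)
    E_leak_a = -82,      # astrocyte leak reversal (mV)
    g_trpv   = 0.06,     # TRPV4 conductance (nS)
    E_trpv   = 0,        # TRPV4 reversal (nonselective cation) (mV)
    c_isk    = 0.6,      # electrogenic uptake current per unit K+ flux (pA/(mM/s))
    C_astr   = 0.01,     # astrocyte membrane capacitance (nF)
    ## -- perivascular space -------------------------------------------
    c_jbk    = 2.0,      # K+ flux per unit BK current (mM/s per pA)
    VR_pa    = 5,        # volume ratio perivascular space : astrocyte (-)
    c_jkir   = 0.5,      # K+ flux per unit KIR current (mM/s per pA)
    VR_ps    = 5,        # volume ratio perivascular space : SMC (-)
    R_decay  = 0.15,     # perivascular K+ clearance rate (1/s)
    K_p_min  = 3,        # resting perivascular K+ concentration (mM)
    c_cap    = 50,       # perivascular Ca influx per astrocytic Ca excess (1/s)
    Ca_A_ref = 0.1,      # astrocytic Ca reference for endfoot Ca release (uM)
    R_cap    = 0.5,      # perivascular Ca clearance rate (1/s)
    Ca_p_min = 1495,     # resting perivascular Ca concentration (uM)
    ## -- SMC: KIR channel ----------------------------------------------
    E_kir_coef = 26.7,   # Nernst slope for the KIR reversal (mV)
    K_smc_i  = 140,      # SMC intracellular K+ (mM)
    K_kir_half = 12,     # perivascular K+ at half KIR activation (mM)
    s_kir_k  = 2,        # KIR activation slope in perivascular K+ (mM)
    tau_kir  = 0.1,      # KIR gating time constant (s)
    g_kir    = 0.3,      # KIR conductance (nS)
    ## -- SMC: membrane and calcium (Morris-Lecar-type kinetics) --------
    v1s      = -22.5,    # Ca channel half-activation (mV)
    v2s      = 25,       # Ca channel activation slope (mV)
    g_ca     = 0.157,    # Ca channel conductance (nS)
    v_ca     = 80,       # Ca reversal potential (mV)
    v4s      = 14.5,     # K channel activation slope (mV)
    v5s      = 8,        # Ca-dependent shift amplitude of K activation (mV)
    v6s      = -15,      # K channel half-activation offset (mV)
    Ca3      = 0.4,      # Ca at half shift (uM)
    Ca4      = 0.15,     # shift slope in Ca (uM)
    phi_n    = 2.664,    # K channel gating rate (1/s)
    g_k      = 0.314,    # Ca-gated K conductance (nS)
    v_K      = -90,      # K+ reversal in the SMC (mV)
    g_l      = 0.0785,   # SMC leak conductance (nS)
    v_l      = -67,      # SMC leak reversal (mV)
    v_kv1    = -25,      # voltage-gated K (KV) half-activation (mV)
    v_kv2    = 15,       # KV activation slope (mV)
    g_kv     = 0.10,     # KV conductance (nS)
    C_smc    = 0.0196,   # SMC membrane capacitance (nF)
    V_smc_ref = -45,     # SMC reference potential for the perivascular KIR flux (mV)
    rho_ca   = 1,        # cytosolic Ca buffering factor (-)
    alpha_ca = 0.18,    # Ca influx per unit Ca current (uM/(s pA))
    k_ca     = 1.35,     # SMC Ca extrusion rate (1/s)
    ## -- contraction and vessel-wall mechanics -------------------------
    Ca_m     = 0.6,     # Ca at half cross-bridge activation (uM)
    q_psi    = 4,        # Hill exponent of cross-bridge activation (-)
    k_w      = 0.5,      # cross-bridge cycling rate (1/s)
    k_y      = 0.5,      # contractile-element relaxation rate (1/s)
    s_y      = 0.8,      # contractile shortening per unit cross-bridge excess (-)
    omega_ref = 0.29,   # reference tone for contractile-element rest length (-)
    p_t      = 0.05,     # transmural pressure tension coefficient (tension/um)
    k_pas    = 0.1,      # passive wall stiffness (tension/um)
    x_pas0   = 50,       # unstressed wall circumference (um)
    k_act    = 6.36,      # maximal active tension (tension)
    x_act0   = 62.8,     # optimal circumference for active tension (um)
    eta_v    = 0.4,      # wall viscosity (tension s/um)
    ## -- coupling switches ---------------------------------------------
    trpv_strain_gain = 0 # vessel-strain feedback onto TRPV4 (0 = nested cascade)
  )
  ov <- list(...)
  if (length(ov)) {
    ov <- unlist(ov)
    bad <- setdiff(names(ov), names(p))
    if (length(bad)) {
      stop("unresolved parameter symbol(s): ", paste(bad, collapse = ", "))
    }
    p[names(ov)] <- ov
  }
  if (any(p[c("C_astr", "C_smc", "VR_pa", "VR_ps", "R_decay", "tau_trpv",
              "tau_kir", "eta_v", "k_deg", "k_eet", "k_ca")] <= 0)) {
    stop("capacitances, volume ratios, decay rates and time constants must be strictly positive")
  }
  class(p) <- c("nvu_parameters", class(p))
  p
}

#' Parameter provenance table
#'
#' A data frame listing every model constant, its unit, and whether its value
#' is a literature value from the source-model lineage or a design value set
#' for this implementation's operating point.
#'
#' @return data.frame with columns `symbol`, `value`, `unit`, `provenance`.
#' @export
nvu_parameter_table <- function() {
  p <- nvu_parameters()
  lineage <- c("delta_G", "K_G", "r_h", "k_deg", "K_I", "K_act", "V_pump",
               "K_pump", "B_cyt", "k_on", "K_inh", "V_eet", "k_eet",
               "E_kir_coef", "v1s", "v2s", "g_ca", "v_ca", "v4s", "v5s",
               "v6s", "Ca3", "Ca4", "phi_n", "g_k", "v_K", "g_l", "v_l",
               "C_smc", "Ca_m")
  units <- rep("see ?nvu_parameters", length(p))
  data.frame(
    symbol = names(unclass(p)),
    value = as.numeric(p),
    provenance = ifelse(names(unclass(p)) %in% lineage,
                        "lineage-default", "design"),
    stringsAsFactors = FALSE
  )
}

# canonical state ordering used everywhere (derivatives, C core, linearizer)
.nvu_state_names <- c("K_s", "IP3", "Ca_A", "h", "ss", "EET", "n_bk", "Vk",
                      "K_p", "Ca_p", "k", "V_smc", "n", "Ca_smc", "omega",
                      "yy", "x")

#' State labels of the NVU model
#'
#' @return character vector of the 17 state symbols, in canonical order:
#'   synaptic potassium, astrocytic IP3/calcium/gating/TRPV4/EET/BK/potential,
#'   perivascular potassium and calcium, SMC KIR gating, potential, K gating,
#'   calcium, cross-bridge fraction, contractile length, circumference.
#' @export
nvu_state_names <- function() .nvu_state_names
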