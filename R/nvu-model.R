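#' Time derivatives of the 17-state neurovascular-unit model
#'
#' Reference (pure R) implementation of the lumped NVU dynamics. The system is
#' a feedforward cascade of four compartments -- synaptic space, astrocyte,
#' perivascular space, arteriolar smooth-muscle cell -- terminating in the
#' vessel-wall mechanics whose state `x` is the mean circumference. tDCS acts
#' through at most one of four additive perturbations:
#' \describe{
#'   \item{dJKs}{extra K+ flux into the synaptic space (pathway 1, mM/s)}
#'   \item{dIT}{extra astrocytic transmembrane current (pathway 2, pA)}
#'   \item{dKT}{extra perivascular K+ flux (pathway 3, mM/s)}
#'   \item{dIKV}{extra SMC voltage-gated channel current (pathway 4, pA)}
#' }
#' Injected currents are divided by the respective membrane capacitance, so a
#' perturbation `dIT = eps` adds exactly `eps / C_astr` to `dVk/dt`.
#'
#' A fast C implementation of the same equations drives [nvu_simulate()]; the
#' two are cross-checked in the test suite.
#'
#' @param state named numeric vector of the 17 states (see [nvu_state_names()]).
#' @param t time (s); the autonomous system ignores it.
#' @param params parameter vector from [nvu_parameters()].
#' @param perturbation named numeric vector with entries among
#'   `dJKs`, `dIT`, `dKT`, `dIKV`; missing entries are zero.
#' @return named numeric vector of the 17 time derivatives, in native units
#'   per second.
#' @export
#' @examples
#' p <- nvu_parameters()
#' eq <- nvu_find_equilibrium(p)
#' max(abs(nvu_derivatives(eq$state, 0, p)))
nvu_derivatives <- function(state, t = 0, params = nvu_parameters(),
                            perturbation = c(dJKs = 0, dIT = 0, dKT = 0, dIKV = 0)) {
  if (length(state) != 17L) {
    stop("the NVU system has exactly 17 state variables; got ", length(state))
  }
  s <- as.numeric(state)
  names(s) <- .nvu_state_names
  p <- as.list(unclass(params))
  v <- c(dJKs = 0, dIT = 0, dKT = 0, dIKV = 0)
  v[names(perturbation)] <- perturbation

  with(c(p, as.list(s)), {
    ## synaptic space ---------------------------------------------------
    J_uptake <- J_SKmax * k_Na * K_s / (K_s + KKO_a)
    dK_s <- J_Ks0 + v[["dJKs"]] - J_uptake

    ## astrocyte: IP3 production driven by synaptic activity -------------
    rho <- rho0 * K_s / (K_s + K_rho)
    G <- (rho + delta_G) / (K_G + rho + delta_G)
    dIP3 <- r_h * G - k_deg * IP3

    ## astrocyte: ER calcium ---------------------------------------------
    m_inf <- IP3 / (IP3 + K_I)
    c_inf <- Ca_A / (Ca_A + K_act)
    J_ip3r <- J_max * (m_inf * c_inf * h)^3 * (1 - Ca_A / Ca_er)
    J_pump <- V_pump * Ca_A^2 / (Ca_A^2 + K_pump^2)
    J_erleak <- P_leak * (1 - Ca_A / Ca_er)
    dCa_A <- B_cyt * (J_ip3r + J_erleak - J_pump) + J_trpv * ss
    dh <- k_on * (K_inh - (Ca_A + K_inh) * h)

    ## astrocyte: TRPV4 gating (perivascular Ca inhibits; optional strain
    ## feedback from the vessel, zero by default to keep the pathway nesting)
    strain <- trpv_strain_gain * (x - x_act0) / x_act0
    s_inf <- 1 / (1 + exp((Ca_p - Ca_p_half) / kap_cap - strain))
    dss <- (s_inf - ss) / tau_trpv

    ## astrocyte: EET and BK ---------------------------------------------
    dEET <- V_eet * max(Ca_A - Ca_eet_min, 0) - k_eet * EET
    nbk_inf <- 0.5 * (1 + tanh((Vk + eet_shift * EET - v3b) / v4b))
    dn_bk <- phi_bk * (nbk_inf - n_bk)

    ## astrocyte membrane potential ---------------------------------------
    I_bk <- g_bk * n_bk * (Vk - E_bk)
    I_leak_a <- g_leak_a * (Vk - E_leak_a)
    I_trpv <- g_trpv * ss * (Vk - E_trpv)
    I_sk <- -c_isk * J_uptake  # electrogenic K+ uptake: inward (depolarizing)
    dVk <- (-I_bk - I_leak_a - I_trpv - I_sk + v[["dIT"]]) / C_astr

    ## perivascular space -------------------------------------------------
    E_kir <- E_kir_coef * log(K_p / K_smc_i)
    k_inf <- 1 / (1 + exp(-(K_p - K_kir_half) / s_kir_k))
    I_kir_pvs <- g_kir * k * (V_smc_ref - E_kir)
    dK_p <- c_jbk * I_bk / VR_pa + c_jkir * I_kir_pvs / VR_ps -
      R_decay * (K_p - K_p_min) + v[["dKT"]]
    dCa_p <- c_cap * (Ca_A - Ca_A_ref) - R_cap * (Ca_p - Ca_p_min)

    ## SMC: KIR gating (driven by perivascular K+) ------------------------
    dk <- (k_inf - k) / tau_kir

    ## SMC membrane -------------------------------------------------------
    m_inf_s <- 0.5 * (1 + tanh((V_smc - v1s) / v2s))
    I_ca <- g_ca * m_inf_s * (V_smc - v_ca)
    v3s <- -(v5s / 2) * tanh((Ca_smc - Ca3) / Ca4) + v6s
    n_inf_s <- 0.5 * (1 + tanh((V_smc - v3s) / v4s))
    lam_n <- phi_n * cosh((V_smc - v3s) / (2 * v4s))
    I_k <- g_k * n * (V_smc - v_K)
    I_l <- g_l * (V_smc - v_l)
    I_kir <- g_kir * k * (V_smc - E_kir)
    p_inf <- 0.5 * (1 + tanh((V_smc - v_kv1) / v_kv2))
    I_kv <- g_kv * p_inf * (V_smc - v_K)
    dV_smc <- (-I_l - I_k - I_ca - I_kir - I_kv + v[["dIKV"]]) / C_smc
    dn <- lam_n * (n_inf_s - n)
    dCa_smc <- rho_ca * (-alpha_ca * I_ca - k_ca * Ca_smc)

    ## contraction and wall mechanics --------------------------------------
    psi <- Ca_smc^q_psi / (Ca_smc^q_psi + Ca_m^q_psi)
    domega <- k_w * (psi - omega)
    dyy <- k_y * (1 - s_y * (omega - omega_ref) - yy)
    T_pr <- p_t * x
    T_pas <- k_pas * (x - x_pas0)
    T_act <- k_act * omega * yy * (x / x_act0)
    dx <- (T_pr - T_pas - T_act) / eta_v

    d <- c(dK_s, dIP3, dCa_A, dh, dss, dEET, dn_bk, dVk, dK_p, dCa_p,
           dk, dV_smc, dn, dCa_smc, domega, dyy, dx)
    names(d) <- .nvu_state_names
    if (any(!is.finite(d))) {
      stop("non-finite derivative in equation(s): ",
           paste(.nvu_state_names[!is.finite(d)], collapse = ", "))
    }
    d
  })
}

# direct call into the compiled derivative core (cross-checked against
# nvu_derivatives in the test suite)
.nvu_derivs_compiled <- function(state, params, v = 0, pathway = 1) {
  out <- .C("nvu_derivs_direct", as.double(state),
            as.double(c(as.numeric(unclass(params)), pathway)),
            as.double(v), ydot = double(17), PACKAGE = "nvucvr")
  d <- out$ydot
  names(d) <- .nvu_state_names
  d
}

#' Baseline state guess within physiological ranges
#'
#' @param params parameter vector.
#' @return named state vector suitable as a Newton starting point.
#' @export
nvu_initial_guess <- function(params = nvu_parameters()) {
  s <- c(K_s = 3.5, IP3 = 0.13, Ca_A = 0.12, h = 0.46, ss = 0.67, EET = 0.68,
         n_bk = 0.05, Vk = -79, K_p = 4.95, Ca_p = 1497, k = 0.029,
         V_smc = -40.7, n = 0.036, Ca_smc = 0.48, omega = 0.29, yy = 1, x = 63.2)
  s
}

#' Find the baseline operating point of the NVU model
#'
#' Locates the unforced equilibrium by damped Newton iteration on the full
#' 17-dimensional system with a central-finite-difference Jacobian. If Newton
#' fails to converge, the routine falls back to a long unforced settling
#' simulation; if the settled trajectory still cycles, the temporal mean of
#' the cycle is returned and flagged as an oscillatory baseline.
#'
#' @param params parameter vector from [nvu_parameters()].
#' @param guess starting state; default [nvu_initial_guess()].
#' @param tol infinity-norm tolerance on the derivative residual.
#' @param max_iter maximum Newton iterations.
#' @return list with elements `state` (the operating point), `residual`
#'   (max abs derivative), `strategy` (`"newton"` or `"settling"`), and
#'   `oscillatory` (logical flag).
#' @export
nvu_find_equilibrium <- function(params = nvu_parameters(),
                                 guess = nvu_initial_guess(params),
                                 tol = 1e-9, max_iter = 100) {
  f <- function(s) nvu_derivatives(s, 0, params)
  s <- as.numeric(guess)
  scale <- pmax(abs(s), 1e-3)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    r <- f(s)
    if (max(abs(r)) < tol) { converged <- TRUE; break }
    J <- .fd_jacobian(f, s, scale)
    step <- tryCatch(solve(J, -r), error = function(e) NULL)
    if (is.null(step)) break
    lam <- 1
    r0 <- sqrt(sum(r^2))
    repeat {
      s_new <- s + lam * step
      r_new <- tryCatch(f(s_new), error = function(e) rep(Inf, 17))
      if (sqrt(sum(r_new^2)) < r0 || lam < 1e-4) break
      lam <- lam / 2
    }
    s <- s_new
  }
  oscillatory <- FALSE
  strategy <- "newton"
  if (!converged) {
    ## settle the unforced system for 300 s and inspect the tail
    traj <- nvu_simulate(guess, params, stimulus = NULL, pathway = 1,
                         t_span = c(0, 300), dt_out = 0.1)
    tail_idx <- traj$time >= 200
    tail_states <- traj$state[tail_idx, , drop = FALSE]
    s <- colMeans(tail_states)
    amp <- apply(tail_states, 2, function(z) diff(range(z)))
    oscillatory <- any(amp / pmax(abs(s), 1e-6) > 1e-4)
    strategy <- "settling"
  }
  names(s) <- .nvu_state_names
  probs <- c("h", "ss", "n_bk", "k", "n", "omega")
  bad <- s[probs] < -1e-6 | s[probs] > 1 + 1e-6
  if (any(bad)) {
    stop("equilibrium probability state outside [0,1]: ",
         paste(probs[bad], collapse = ", "))
  }
  s[probs] <- pmin(pmax(s[probs], 0), 1)
  res <- max(abs(f(s)))
  list(state = s, residual = res, strategy = strategy,
       oscillatory = oscillatory)
}

# central finite-difference Jacobian with per-component scaled steps
.fd_jacobian <- function(f, x, scale = pmax(abs(x), 1e-3), rel_step = 1e-6) {
  n <- length(x)
  f0 <- f(x)
  J <- matrix(0, length(f0), n)
  for (j in seq_len(n)) {
    hj <- rel_step * scale[j]
    xp <- x; xp[j] <- x[j] + hj
    xm <- x; xm[j] <- x[j] - hj
    J[, j] <- (f(xp) - f(xm)) / (2 * hj)
  }
  J
}

#' Simulate the nonlinear NVU model under a tDCS stimulus
#'
#' Integrates the 17-state system with a stiff implicit solver (`deSolve`
#' backward-differentiation formulas) using the compiled derivative core.
#' The stimulus current is first passed through the first-order vasoactive
#' filter ([vasoactive_signal()]) and the filtered signal perturbs the state
#' selected by `pathway`.
#'
#' @param initial named state vector (e.g. from [nvu_find_equilibrium()]).
#' @param params parameter vector.
#' @param stimulus a `stimulus_waveform` (see [tdcs_trapezoid()]), or `NULL`
#'   for the unforced system.
#' @param pathway integer 1-4: injection at synaptic K+, astrocyte membrane,
#'   perivascular K+, or SMC membrane.
#' @param gain lead-field gain applied to the filtered stimulus.
#' @param tau vasoactive filter time constant (s).
#' @param t_span length-2 numeric, simulation window (s).
#' @param dt_out output sampling interval (s).
#' @param rtol,atol solver tolerances (recorded in the result).
#' @param state_bound abort threshold: integration stops with an error if any
#'   state magnitude exceeds this bound (instability guard).
#' @return list of class `"nvu_trajectory"`: `time`, `state` (matrix with one
#'   column per state), `stimulus` (filtered perturbation at output times),
#'   `pathway`, `rtol`, `atol`.
#' @export
nvu_simulate <- function(initial, params = nvu_parameters(), stimulus = NULL,
                         pathway = 1, gain = 1, tau = 0.02,
                         t_span = c(0, 150), dt_out = 0.1,
                         rtol = 1e-8, atol = 1e-10, state_bound = 1e6) {
  stopifnot(length(initial) == 17L, pathway %in% 1:4)
  times <- seq(t_span[1], t_span[2], by = dt_out)
  if (is.null(stimulus)) {
    v <- cbind(times, 0)
  } else {
    vs <- vasoactive_signal(stimulus, vasoactive_filter(K = gain, tau = tau))
    ## forcing interpolated linearly by the solver; extend flat past the ends
    v <- cbind(vs$time, vs$signal)
    if (max(vs$time) < t_span[2]) {
      v <- rbind(v, c(t_span[2], vs$signal[length(vs$signal)]))
    }
    if (min(vs$time) > t_span[1]) v <- rbind(c(t_span[1], 0), v)
  }
  parms <- c(as.numeric(unclass(params)), pathway)
  y0 <- as.numeric(initial)
  names(y0) <- .nvu_state_names
  out <- deSolve::ode(
    y = y0, times = times, func = "nvu_derivs_c", parms = parms,
    dllname = "nvucvr", initfunc = "nvu_initmod", initforc = "nvu_initforc",
    forcings = list(v), method = "bdf", rtol = rtol, atol = atol,
    maxsteps = 50000
  )
  if (attr(out, "istate")[1] < 0) {
    stop("NVU integration failed at t = ", max(out[, 1]))
  }
  state <- out[, -1, drop = FALSE]
  if (any(abs(state) > state_bound)) {
    stop("NVU simulation unstable: a state exceeded ", state_bound)
  }
  vi <- stats::approx(v[, 1], v[, 2], xout = times, rule = 2)$y
  structure(list(time = times, state = state, stimulus = vi,
                 pathway = pathway, rtol = rtol, atol = atol),
            class = "nvu_trajectory")
}

#' @export
print.nvu_trajectory <- function(x, ...) {
  cat("NVU trajectory: pathway", x$pathway, "|", length(x$time), "samples,",
      "t =", min(x$time), "-", max(x$time), "s\n")
  cat("  circumference range:",
      format(range(x$state[, "x"]), digits = 6), "um\n")
  invisible(x)
}

#' Export a trajectory as a delimited table
#'
#' Writes time, the 17 states and the filtered stimulus as tab-separated text.
#'
#' @param traj an `nvu_trajectory`.
#' @param file output path.
#' @export
write_trajectory <- function(traj, file) {
  df <- data.frame(time = traj$time, traj$state, stimulus = traj$stimulus)
  utils::write.table(df, file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}
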