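#' Jacobian linearization of the NVU model at its operating point
#'
#' Linearizes the full 17-state nonlinear system around a baseline operating
#' point by central finite differences with per-state scaled steps, and builds
#' the per-pathway input and circumference output maps:
#' the input column B has a single structural nonzero at the pathway's
#' injection state (synaptic K+ for pathway 1, astrocyte potential for 2,
#' perivascular K+ for 3, SMC potential for 4; potentials are scaled by the
#' inverse membrane capacitance because the injected quantity is a current),
#' and the output row C selects the circumference deviation.
#'
#' The whole-system Jacobian is used rather than a literal compartment-by-
#' compartment linearization: at a shared operating point the two are
#' mathematically identical, and the compartment structure is retained as
#' state-label metadata.
#'
#' @param params parameter vector from [nvu_parameters()].
#' @param x0 equilibrium state (see [nvu_find_equilibrium()]); checked.
#' @param pathway integer 1-4.
#' @param equilibrium_tol maximum allowed derivative residual at `x0`.
#' @param rel_step relative finite-difference step.
#' @return a [linear_model()] whose input is the filtered perturbation signal
#'   v_i(t) and output the circumference deviation (um).
#' @export
#' @examples
#' p <- nvu_parameters()
#' eq <- nvu_find_equilibrium(p)
#' m3 <- nvu_linearize(p, eq$state, pathway = 3)
nvu_linearize <- function(params, x0, pathway, equilibrium_tol = 1e-6,
                          rel_step = 1e-6) {
  stopifnot(pathway %in% 1:4, length(x0) == 17L)
  r0 <- nvu_derivatives(x0, 0, params)
  if (max(abs(r0)) > equilibrium_tol) {
    stop("x0 is not an equilibrium (residual ", format(max(abs(r0))),
         " > ", equilibrium_tol, "); run nvu_find_equilibrium first")
  }
  f <- function(s) nvu_derivatives(s, 0, params)
  scale <- pmax(abs(as.numeric(x0)), 1e-3)
  A <- .fd_jacobian(f, as.numeric(x0), scale, rel_step)
  ## entries this small are finite-difference noise on structural zeros of
  ## the compartmental cascade (the smallest genuine coupling is ~1e-5 of
  ## the largest entry); zeroing them preserves the exact nesting structure
  A[abs(A) < 1e-8 * max(abs(A))] <- 0
  kappa <- kappa(A, exact = FALSE)
  if (kappa > 1e12) {
    warning("ill-conditioned Jacobian (condition number ", format(kappa), ")")
  }
  B <- matrix(0, 17, 1)
  inj <- switch(pathway,
    `1` = c(which(.nvu_state_names == "K_s"), 1),
    `2` = c(which(.nvu_state_names == "Vk"), 1 / params[["C_astr"]]),
    `3` = c(which(.nvu_state_names == "K_p"), 1),
    `4` = c(which(.nvu_state_names == "V_smc"), 1 / params[["C_smc"]])
  )
  B[inj[1], 1] <- inj[2]
  C <- matrix(0, 1, 17)
  C[1, which(.nvu_state_names == "x")] <- 1
  linear_model(A, B, C, state_labels = .nvu_state_names,
               operating_point = x0, pathway = pathway)
}

#' Cascade the vasoactive input filter with a pathway model
#'
#' Builds the full stimulus-to-circumference model: the first-order filter
#' K/(tau s + 1) in series with the pathway state-space model. Adds exactly
#' one state (and one pole).
#'
#' @param model a `linear_model` from [nvu_linearize()] (input = perturbation).
#' @param K lead-field gain.
#' @param tau filter time constant (s).
#' @return a `linear_model` with n+1 states whose input is the raw stimulus.
#' @export
cascade_with_filter <- function(model, K = 1, tau = 0.02) {
  if (tau <= 0) stop("tau must be strictly positive")
  n <- nrow(model$A)
  A <- rbind(cbind(model$A, model$B), matrix(c(rep(0, n), -1 / tau), 1))
  B <- matrix(c(rep(0, n), K / tau), ncol = 1)
  C <- cbind(model$C, 0)
  linear_model(A, B, C, state_labels = c(model$state_labels, "v_filter"),
               free_mask = model$free_mask,
               operating_point = model$operating_point,
               pathway = model$pathway)
}

#' Transfer function of a state-space model
#'
#' Poles are the eigenvalues of A; zeros are the finite generalized
#' eigenvalues of the Rosenbrock system pencil (QZ algorithm); the gain is
#' fixed by matching the resolvent frequency response at a probe point. Near
#' pole-zero cancellations are removed at a configurable relative tolerance.
#'
#' @param model a `linear_model`.
#' @param cancel_tol relative pole-zero distance below which a pair is
#'   cancelled (minimality tolerance).
#' @return a [rational_tf()].
#' @export
to_transfer_function <- function(model, cancel_tol = 1e-7) {
  ## exact structural reduction first: the pencil separates finite from
  ## infinite zeros much more cleanly without the uncontrollable /
  ## unobservable block
  model <- .structural_kalman(model)
  poles <- eigen(model$A, only.values = TRUE)$values
  pz <- cpp_pencil_zeros(model$A, model$B, model$C, model$D)
  ## infinite zeros come out with beta ~ 0; the finite transmission zeros
  ## separate cleanly by |beta| when the pencil is built on the original
  ## (unbalanced) realization
  finite <- abs(pz$beta) > 1e-7 * max(abs(pz$beta))
  zeros <- (pz$alpha / pz$beta)[finite]
  out <- .cancel_pairs(zeros, poles, cancel_tol)
  ## gain: match |G| at a probe point away from all roots
  s0 <- 1i * exp(mean(log(pmax(abs(c(out$poles, 1)), 1e-6))))
  G0 <- freqresp(model, Im(s0))
  base <- exp(sum(log(s0 - out$zeros)) - sum(log(s0 - out$poles)))
  gain <- Re(G0 / base)
  rational_tf(out$zeros, out$poles, gain)
}

# remove zero/pole pairs closer than tol (relative)
.cancel_pairs <- function(zeros, poles, tol) {
  zs <- as.complex(zeros); ps <- as.complex(poles)
  keep_z <- rep(TRUE, length(zs)); keep_p <- rep(TRUE, length(ps))
  for (i in seq_along(zs)) {
    if (!keep_z[i]) next
    d <- abs(zs[i] - ps) / pmax(abs(ps), 1)
    j <- which(keep_p & d < tol)
    if (length(j)) { keep_z[i] <- FALSE; keep_p[j[1]] <- FALSE }
  }
  list(zeros = zs[keep_z], poles = ps[keep_p])
}

#' Serialize a linear model to JSON
#'
#' Plain-text state-space record with state labels and an operating-point
#' hash for provenance.
#'
#' @param model a `linear_model`.
#' @param file output path; if `NULL` the JSON string is returned.
#' @export
write_linear_model <- function(model, file = NULL) {
  op <- model$operating_point
  rec <- list(
    A = unclass(model$A), B = unclass(model$B), C = unclass(model$C),
    D = unclass(model$D), state_labels = model$state_labels,
    free_mask = model$free_mask, pathway = model$pathway,
    operating_point = as.numeric(op),
    operating_point_hash = if (is.null(op)) NA_character_ else
      sprintf("%08x", sum(strtoi(charToRaw(paste(format(op, digits = 12),
                                                 collapse = ",")), 16L)))
  )
  js <- jsonlite::toJSON(rec, digits = NA, auto_unbox = TRUE)
  if (is.null(file)) return(js)
  writeLines(js, file)
  invisible(file)
}
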