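#' Trapezoidal tDCS stimulus waveform
#'
#' Builds the sampled current waveform of a tDCS session: linear ramp-up,
#' plateau, linear ramp-down. The default session shape is 2 mA held for
#' 10 minutes total with 30 s ramps.
#'
#' @param amplitude peak current (mA).
#' @param ramp_up,plateau,ramp_down segment durations (s), all non-negative.
#' @param onset stimulation start time (s).
#' @param rate sampling rate (Hz), > 0.
#' @param t_end optional end of the sampled record (s); defaults to the end of
#'   the ramp-down.
#' @param normalized if `TRUE`, scale the peak to 1.
#' @return object of class `"stimulus_waveform"`: list with `time`, `current`,
#'   `rate`, and the generating parameters.
#' @export
#' @examples
#' stim <- tdcs_trapezoid(2, 30, 540, 30)
#' max(stim$current)  # 2 mA
tdcs_trapezoid <- function(amplitude = 2, ramp_up = 30, plateau = 540,
                           ramp_down = 30, onset = 0, rate = 10,
                           t_end = NULL, normalized = FALSE) {
  if (any(c(ramp_up, plateau, ramp_down) < 0)) {
    stop("ramp and plateau durations must be non-negative")
  }
  if (rate <= 0) stop("sampling rate must be positive")
  dur <- ramp_up + plateau + ramp_down
  if (is.null(t_end)) t_end <- onset + dur
  time <- seq(0, t_end, by = 1 / rate)
  tt <- time - onset
  cur <- numeric(length(time))
  if (ramp_up > 0) {
    i <- tt > 0 & tt < ramp_up
    cur[i] <- amplitude * tt[i] / ramp_up
  }
  i <- tt >= ramp_up & tt <= ramp_up + plateau
  cur[i] <- amplitude
  if (ramp_down > 0) {
    i <- tt > ramp_up + plateau & tt < dur
    cur[i] <- amplitude * (dur - tt[i]) / ramp_down
  }
  if (normalized && amplitude != 0) cur <- cur / amplitude
  structure(list(time = time, current = cur, rate = rate,
                 amplitude = amplitude, ramp_up = ramp_up, plateau = plateau,
                 ramp_down = ramp_down, onset = onset,
                 normalized = normalized),
            class = "stimulus_waveform")
}

#' @export
print.stimulus_waveform <- function(x, ...) {
  cat("tDCS stimulus:", x$amplitude, "mA,", x$ramp_up, "s ramp-up,",
      x$plateau, "s plateau,", x$ramp_down, "s ramp-down @", x$rate, "Hz",
      if (x$normalized) "(normalized)" else "", "\n")
  invisible(x)
}

#' Analytic area of a trapezoidal waveform
#'
#' @param stim a `stimulus_waveform`.
#' @return the closed-form integral amplitude * (plateau + (ramp_up +
#'   ramp_down)/2), in mA s.
#' @export
trapezoid_area <- function(stim) {
  a <- if (stim$normalized && stim$amplitude != 0) 1 else stim$amplitude
  a * (stim$plateau + (stim$ramp_up + stim$ramp_down) / 2)
}

#' First-order vasoactive filter
#'
#' The lead-field gain and membrane time constant of the first-order transfer
#' function K / (tau s + 1): a unity-DC-gain low-pass scaled by K, mapping
#' scalp current to the compartmental perturbation signal. Default time
#' constant 20 ms (passive membrane).
#'
#' @param K dimensionless lead-field gain.
#' @param tau time constant (s), > 0.
#' @return object of class `"vasoactive_filter"`.
#' @export
vasoactive_filter <- function(K = 1, tau = 0.02) {
  if (tau <= 0) stop("tau must be strictly positive")
  structure(list(K = K, tau = tau), class = "vasoactive_filter")
}

#' Apply the vasoactive filter to a stimulus waveform
#'
#' Filters the sampled stimulus through K / (tau s + 1) using the exact
#' zero-order-hold discretization at the stimulus sampling rate: within each
#' sample the input is held constant and the state update is
#' `v[k+1] = a v[k] + K (1-a) u[k]`, `a = exp(-dt/tau)`. With tau = 20 ms at
#' 10 Hz a naive Euler step would distort the transient, the ZOH step is exact
#' for piecewise-constant input.
#'
#' @param stimulus a `stimulus_waveform`.
#' @param filt a `vasoactive_filter`.
#' @return list with `time`, `signal` (the perturbation series v_i(t)),
#'   `K`, `tau`.
#' @export
#' @examples
#' stim <- tdcs_trapezoid(1, 0, 10, 0, rate = 100)
#' v <- vasoactive_signal(stim, vasoactive_filter(1, 0.02))
vasoactive_signal <- function(stimulus, filt = vasoactive_filter()) {
  dt <- 1 / stimulus$rate
  a <- exp(-dt / filt$tau)
  u <- stimulus$current
  n <- length(u)
  v <- numeric(n)
  b <- filt$K * (1 - a)
  for (i in seq_len(n - 1)) v[i + 1] <- a * v[i] + b * u[i]
  list(time = stimulus$time, signal = v, K = filt$K, tau = filt$tau)
}
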