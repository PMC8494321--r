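#' Specification of a synthetic fNIRS cohort
#'
#' Defines the study conditions the generator emulates: 11 subjects, two
#' regions (targeted / nontargeted) recorded for 600 s of stimulation after a
#' 120 s baseline at 10 Hz. Each subject's ground-truth vessel response is
#' simulated from the nonlinear NVU model under the subject's true pathway and
#' lead-field gain, mapped linearly to total hemoglobin (blood volume is
#' proportional to circumference for small changes), split into
#' anti-correlated oxy/deoxy components, and contaminated with systemic
#' sinusoids (Mayer ~0.1 Hz, respiration ~0.25 Hz, cardiac ~1 Hz), slow drift
#' and white noise. A fixed fraction of subjects (default 3/11) is generated
#' under a common-drive regime -- positively coupled oxy/deoxy with an
#' initial-dip vessel transient -- and must fail the anti-correlation QC.
#'
#' @param n_subjects cohort size (default 11).
#' @param seed integer seed (mandatory; all randomness derives from it).
#' @param pathway_truth named integer vector: true pathway per region.
#' @param gain_meanlog,gain_sdlog log-normal lead-field gain distribution.
#'   Pathway 4 gains are negated (a net hyperpolarizing SMC perturbation, so
#'   the nontargeted response is also a dilation).
#' @param noise_sd white measurement noise per channel (uM).
#' @param mayer_amp,resp_amp,cardiac_amp systemic sinusoid amplitudes (uM).
#' @param drift_amp linear drift over the record (uM end-to-end).
#' @param antiphase_sd amplitude (sd, uM) of the shared anti-phase
#'   oxy/deoxy component carrying the anti-correlation.
#' @param lambda_split deoxy share of the tHb split (oxy gets 1 - lambda).
#'   The default -0.2 encodes the differential neurovascular response: oxy-Hb
#'   rises while deoxy-Hb falls, their sum remaining the tHb ground truth.
#' @param nontargeted_gain_scale multiplier on the nontargeted-region gain
#'   (the contralateral response is weaker than under the stimulation site).
#' @param dip_fraction fraction of common-drive / initial-dip subjects.
#' @param dip_amp amplitude of the initial-dip transient (uM).
#' @param n_channels analysis channels per region.
#' @param n_background additional montage channels per hemisphere that carry
#'   systemic physiology and the anti-phase component but no evoked response
#'   (the spatial PCA sees the full montage, as in a 16-channel recording).
#' @param baseline,duration pre-onset and stimulation durations (s).
#' @param rate sampling rate (Hz).
#' @param params NVU parameters (defaults [nvu_parameters()]).
#' @return object of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_subjects = 11, seed,
                        pathway_truth = c(targeted = 3, nontargeted = 4),
                        gain_meanlog = log(0.02), gain_sdlog = 0.2,
                        noise_sd = 0.1, mayer_amp = 2.0, resp_amp = 0.3,
                        cardiac_amp = 0.4, drift_amp = 0.3,
                        antiphase_sd = 0.15, lambda_split = -0.2,
                        nontargeted_gain_scale = 0.25,
                        dip_fraction = 3 / 11, dip_amp = 0.6,
                        n_channels = 4, n_background = 12,
                        baseline = 120, duration = 600,
                        rate = 10, params = nvu_parameters()) {
  if (missing(seed)) stop("a seed is mandatory for reproducibility")
  stopifnot(n_subjects >= 1, dip_fraction >= 0, dip_fraction <= 1,
            all(c(noise_sd, mayer_amp, resp_amp, cardiac_amp) >= 0))
  n_dip <- round(dip_fraction * n_subjects)
  ## common-drive subjects at fixed positions spread over the cohort
  dip_ids <- if (n_dip > 0) {
    unique(round(seq(3, n_subjects, length.out = n_dip)))
  } else integer(0)
  eq <- nvu_find_equilibrium(params)
  structure(list(
    n_subjects = n_subjects, seed = as.integer(seed),
    pathway_truth = pathway_truth, gain_meanlog = gain_meanlog,
    gain_sdlog = gain_sdlog, noise_sd = noise_sd, mayer_amp = mayer_amp,
    resp_amp = resp_amp, cardiac_amp = cardiac_amp, drift_amp = drift_amp,
    antiphase_sd = antiphase_sd, lambda_split = lambda_split,
    nontargeted_gain_scale = nontargeted_gain_scale,
    dip_ids = dip_ids, dip_amp = dip_amp, n_channels = n_channels,
    n_background = n_background,
    baseline = baseline, duration = duration, rate = rate,
    params = params, equilibrium = eq), class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("synthetic cohort:", x$n_subjects, "subjects, pathways (",
      paste(names(x$pathway_truth), x$pathway_truth, collapse = ", "),
      "), seed", x$seed, "\n")
  cat("  common-drive subjects:", paste(x$dip_ids, collapse = ", "), "\n")
  invisible(x)
}

# band-limited (0.01-0.1 Hz) unit-sd noise series
.bandlimited_noise <- function(n, rate, sd_target) {
  w <- stats::rnorm(n + 600 * rate)
  f <- bandpass(w, rate = rate, low = 0.01, high = 0.1)
  f <- f[seq_len(n) + 300 * rate]
  f / stats::sd(f) * sd_target
}

#' Generate one synthetic subject (both regions)
#'
#' Simulates the subject's ground-truth circumference response with the
#' nonlinear NVU model (the subject's true pathway and gain per region), maps
#' it to tHb, splits it into oxy/deoxy channels and adds systemic
#' contamination and noise. Ground-truth labels (true pathway, gain, the
#' noiseless tHb series, QC class) are embedded in the record metadata, which
#' the fitting modules never read.
#'
#' @param spec a `cohort_spec`.
#' @param subject_id integer in 1..n_subjects.
#' @return a [subject_record()].
#' @export
generate_subject <- function(spec, subject_id) {
  set.seed(spec$seed * 1009L + subject_id)
  rate <- spec$rate
  t_total <- spec$baseline + spec$duration
  n <- t_total * rate + 1
  tt <- (seq_len(n) - 1) / rate
  is_dip <- subject_id %in% spec$dip_ids
  stim <- tdcs_trapezoid(2, 30, spec$duration - 60, 30, onset = spec$baseline,
                         rate = rate, t_end = t_total)
  ## systemic physiology is shared across regions and channels (a global
  ## spatial mode, which the rank-1 PCA removal is meant to capture)
  phases <- stats::runif(3, 0, 2 * pi)
  systemic <- spec$mayer_amp * sin(2 * pi * 0.1 * tt + phases[1]) +
    spec$resp_amp * sin(2 * pi * 0.25 * tt + phases[2]) +
    spec$cardiac_amp * sin(2 * pi * 1.0 * tt + phases[3]) +
    spec$drift_amp * (tt / max(tt) - 0.5)
  regions <- list()
  bg_oxy <- list(); bg_deoxy <- list()
  meta <- list(subject_id = subject_id, common_drive = is_dip,
               truth = list())
  for (nm in names(spec$pathway_truth)) {
    pw <- spec$pathway_truth[[nm]]
    gain <- stats::rlnorm(1, spec$gain_meanlog, spec$gain_sdlog)
    if (nm == "nontargeted") gain <- gain * spec$nontargeted_gain_scale
    if (pw == 4) gain <- -gain
    traj <- nvu_simulate(spec$equilibrium$state, spec$params, stim,
                         pathway = pw, gain = gain / 2,
                         t_span = c(0, t_total), dt_out = 1 / rate,
                         rtol = 1e-7, atol = 1e-9)
    ## stimulus peaks at 2 mA; gain/2 keeps the per-unit-stimulus convention
    x_dev <- traj$state[, "x"] - spec$equilibrium$state[["x"]]
    thb_ground <- x_dev  # 1 uM per um: linear small-signal volume map
    if (is_dip) {
      ## initial-dip: negative early vascular transient on the vessel drive
      f1 <- vasoactive_signal(stim, vasoactive_filter(1, 5))$signal
      f2 <- vasoactive_signal(stim, vasoactive_filter(1, 25))$signal
      dipw <- f1 - f2  # fast-minus-slow: an early transient that relaxes
      pk <- max(abs(dipw))
      if (pk > 0) thb_ground <- thb_ground - spec$dip_amp * dipw / pk
    }
    ## shared anti-phase component (region-specific)
    s_anti <- .bandlimited_noise(n, rate, spec$antiphase_sd)
    lam <- spec$lambda_split
    nc <- spec$n_channels
    oxy <- matrix(0, n, nc); deoxy <- matrix(0, n, nc)
    for (ch in seq_len(nc)) {
      eps_o <- stats::rnorm(n, 0, spec$noise_sd)
      eps_d <- stats::rnorm(n, 0, spec$noise_sd)
      if (!is_dip) {
        oxy[, ch] <- 30 + (1 - lam) * thb_ground + s_anti + systemic + eps_o
        deoxy[, ch] <- 10 + lam * thb_ground - s_anti + systemic + eps_d
      } else {
        ## common-drive regime: both chromophores rise together and ride the
        ## same slow drive (no differential response)
        oxy[, ch] <- 30 + 0.5 * thb_ground + s_anti + systemic + eps_o
        deoxy[, ch] <- 10 + 0.5 * thb_ground + 0.8 * s_anti + systemic + eps_d
      }
    }
    regions[[nm]] <- list(oxy = oxy, deoxy = deoxy)
    ## background montage channels on the same hemisphere: systemic and the
    ## regional anti-phase component, no evoked response
    if (spec$n_background > 0) {
      nb <- spec$n_background
      oxy_b <- matrix(0, n, nb); deoxy_b <- matrix(0, n, nb)
      for (ch in seq_len(nb)) {
        oxy_b[, ch] <- 30 + s_anti + systemic + stats::rnorm(n, 0, spec$noise_sd)
        deoxy_b[, ch] <- 10 - s_anti + systemic + stats::rnorm(n, 0, spec$noise_sd)
      }
      bg_oxy[[nm]] <- oxy_b; bg_deoxy[[nm]] <- deoxy_b
    }
    meta$truth[[nm]] <- list(pathway = pw, gain = gain,
                             thb_ground = thb_ground)
  }
  background <- if (spec$n_background > 0) {
    list(oxy = do.call(cbind, bg_oxy), deoxy = do.call(cbind, bg_deoxy))
  } else NULL
  subject_record(paste0("S", sprintf("%02d", subject_id)), regions,
                 background = background,
                 rate = rate, stim_onset = spec$baseline,
                 baseline_window = spec$baseline, meta = meta)
}

#' Generate the full synthetic cohort
#'
#' @param spec a `cohort_spec`.
#' @return list of [subject_record()]s with a `manifest` attribute (seeds and
#'   ground-truth labels as a data.frame).
#' @export
generate_cohort <- function(spec) {
  recs <- lapply(seq_len(spec$n_subjects), function(i) {
    generate_subject(spec, i)
  })
  manifest <- do.call(rbind, lapply(recs, function(r) {
    data.frame(subject = r$subject_id,
               region = names(r$meta$truth),
               pathway = vapply(r$meta$truth, `[[`, numeric(1), "pathway"),
               gain = vapply(r$meta$truth, `[[`, numeric(1), "gain"),
               common_drive = r$meta$common_drive,
               row.names = NULL)
  }))
  attr(recs, "manifest") <- manifest
  recs
}

#' Simulated input/output dataset from a transfer function
#'
#' Noisy response of a stable transfer function to a stimulus, for exercising
#' the fixed-order estimation and reduction tools.
#'
#' @param tf a stable `rational_tf`.
#' @param stimulus a `stimulus_waveform`.
#' @param snr signal-to-noise power ratio (`Inf` = noiseless).
#' @param seed integer seed.
#' @return list with `input`, `output`, `clean`, `dt`, `noise_sd`.
#' @export
generate_tf_dataset <- function(tf, stimulus, snr = Inf, seed = 1) {
  set.seed(seed)
  dt <- 1 / stimulus$rate
  u <- stimulus$current
  y <- lsim_foh(tf, u, dt)
  sd_n <- if (is.finite(snr)) stats::sd(y) / sqrt(snr) else 0
  list(input = u, output = y + stats::rnorm(length(y), 0, sd_n), clean = y,
       dt = dt, noise_sd = sd_n)
}
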