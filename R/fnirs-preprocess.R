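#' Subject fNIRS record
#'
#' Container for one subject's per-region oxy-/deoxy-hemoglobin channel
#' series. Channels are stored as a named list of regions, each a list with
#' matrices `oxy` and `deoxy` (rows = samples, columns = channels, uM).
#'
#' @param subject_id identifier.
#' @param regions named list (`targeted`, `nontargeted`), each a list with
#'   `oxy` and `deoxy` matrices of equal dimensions.
#' @param background optional list with `oxy`/`deoxy` matrices of additional
#'   montage channels that carry no analyzed response; they participate in
#'   the spatial PCA but not in the regional averages.
#' @param rate sampling rate (Hz).
#' @param stim_onset stimulation onset (s into the record).
#' @param baseline_window length of the pre-onset baseline (s).
#' @param meta optional list of generator metadata (ground-truth labels).
#' @return object of class `"subject_record"`.
#' @export
subject_record <- function(subject_id, regions, background = NULL, rate = 10,
                           stim_onset = 120, baseline_window = 120,
                           meta = list()) {
  for (rg in c(regions, if (!is.null(background)) list(background))) {
    if (!all(dim(rg$oxy) == dim(rg$deoxy))) {
      stop("oxy and deoxy channel matrices must have equal dimensions")
    }
  }
  if (baseline_window > stim_onset) {
    stop("baseline window must lie entirely before the stimulation onset")
  }
  structure(list(subject_id = subject_id, regions = regions,
                 background = background, rate = rate,
                 stim_onset = stim_onset, baseline_window = baseline_window,
                 meta = meta),
            class = "subject_record")
}

#' @export
print.subject_record <- function(x, ...) {
  n <- nrow(x$regions[[1]]$oxy)
  cat("subject_record", x$subject_id, ":", length(x$regions), "regions,",
      ncol(x$regions[[1]]$oxy), "channels,", n / x$rate, "s @", x$rate, "Hz\n")
  invisible(x)
}

#' Total hemoglobin from oxy/deoxy channels
#'
#' tHb = oxy-Hb + deoxy-Hb per channel; the regional series is the mean over
#' the region's channels.
#'
#' @param record a `subject_record`.
#' @param region region name (default all regions).
#' @return named list of regional tHb series (or a single series if `region`
#'   is given).
#' @export
compute_thb <- function(record, region = NULL) {
  one <- function(rg) {
    if (!all(dim(rg$oxy) == dim(rg$deoxy))) stop("channel length mismatch")
    rowMeans(rg$oxy + rg$deoxy)
  }
  if (!is.null(region)) return(one(record$regions[[region]]))
  lapply(record$regions, one)
}

#' Zero-phase band-pass filter
#'
#' Order-3 Butterworth band-pass applied forward-backward (zero phase). The
#' default band is the neurovascular-coupling band 0.01-0.05 Hz.
#'
#' @param series numeric vector.
#' @param rate sampling rate (Hz); must exceed twice the upper edge.
#' @param low,high band edges (Hz).
#' @param order Butterworth order (default 3).
#' @return filtered series.
#' @export
bandpass <- function(series, rate = 10, low = 0.01, high = 0.05, order = 3) {
  if (high >= rate / 2) stop("band edge above the Nyquist frequency")
  if (low <= 0 || low >= high) stop("require 0 < low < high")
  ## the mean is removed first: the high-pass kills DC anyway, and a large
  ## offset would otherwise produce severe forward-backward edge transients
  series <- series - mean(series)
  ## two cascaded designs (high-pass then low-pass) are better conditioned at
  ## very low normalized cutoffs than a single narrow band-pass design
  hp <- signal::butter(order, low / (rate / 2), type = "high")
  lp <- signal::butter(order, high / (rate / 2), type = "low")
  y <- signal::filtfilt(hp, series)
  signal::filtfilt(lp, y)
}

#' Baseline subtraction and maximum normalization
#'
#' Subtracts the pre-onset baseline mean and divides by the maximum absolute
#' post-onset value, so the response extremum maps to +1 (or -1 for
#' initial-dip records, flagged via the `negative_peak` attribute).
#'
#' @param series numeric vector.
#' @param rate sampling rate (Hz).
#' @param onset stimulation onset (s into the series).
#' @param baseline_window baseline length (s) immediately before onset
#'   (>= 10 s).
#' @return normalized series with attributes `scale` (the normalization
#'   factor), `negative_peak` and `degenerate` (constant series: subtraction
#'   only, flagged).
#' @export
baseline_normalize <- function(series, rate = 10, onset = 120,
                               baseline_window = 120) {
  if (baseline_window < 10) stop("baseline window must be at least 10 s")
  if (all(series == 0)) stop("all-zero series cannot be normalized")
  i_on <- round(onset * rate) + 1
  i_b0 <- i_on - round(baseline_window * rate)
  if (i_b0 < 1) stop("baseline window extends before the record start")
  base <- mean(series[i_b0:(i_on - 1)])
  y <- series - base
  post <- y[i_on:length(y)]
  m <- max(abs(post))
  if (m == 0) {
    return(structure(y, scale = NA_real_, negative_peak = FALSE,
                     degenerate = TRUE))
  }
  peak <- post[which.max(abs(post))]
  structure(y / m, scale = m, negative_peak = peak < 0, degenerate = FALSE)
}

#' Oxy/deoxy anti-correlation quality control
#'
#' Pearson correlation between the regional oxy and deoxy series over the QC
#' window; the record passes if r < -0.5 (clear anti-correlation indicating a
#' neurovascular rather than systemic origin).
#'
#' @param record a `subject_record`.
#' @param region region name.
#' @param window QC window (s) starting at the stimulation onset
#'   (default 600 s).
#' @param threshold pass threshold (default -0.5).
#' @return list with `r` and `pass`; constant input gives an NA `r`, fail,
#'   with a `reason`.
#' @export
anticorrelation_qc <- function(record, region = "targeted", window = 600,
                               threshold = -0.5) {
  rg <- record$regions[[region]]
  rate <- record$rate
  i0 <- round(record$stim_onset * rate) + 1
  i1 <- min(i0 + round(window * rate) - 1, nrow(rg$oxy))
  if ((i1 - i0 + 1) / rate < window) {
    stop("record too short for the ", window, " s QC window")
  }
  oxy <- rowMeans(rg$oxy)[i0:i1]
  deoxy <- rowMeans(rg$deoxy)[i0:i1]
  if (stats::sd(oxy) == 0 || stats::sd(deoxy) == 0) {
    return(list(r = NA_real_, pass = FALSE, reason = "constant series"))
  }
  r <- stats::cor(oxy, deoxy)
  list(r = r, pass = r < threshold)
}

#' PCA removal of systemic components
#'
#' Identifies the spatial principal components explaining the most covariance
#' across channels and subtracts the projection onto the leading
#' `n_components` (default 1), removing globally shared systemic physiology
#' (e.g. Mayer waves) while preserving channel-specific signals.
#'
#' @param channels numeric matrix (rows = samples, columns = channels).
#' @param n_components number of spatial components to remove (0 = identity).
#' @param basis_rows optional row indices used to estimate the spatial
#'   components (e.g. the pre-stimulation baseline, so the evoked response
#'   does not contribute to the removed subspace); the projection is then
#'   applied to the whole record. Default: all rows.
#' @return cleaned matrix (channel means restored).
#' @export
pca_systemic_removal <- function(channels, n_components = 1,
                                 basis_rows = NULL) {
  channels <- as.matrix(channels)
  if (ncol(channels) < 2) stop("need at least 2 channels")
  if (n_components >= ncol(channels)) {
    stop("n_components must be smaller than the channel count")
  }
  if (n_components == 0) return(channels)
  ## center at the basis-window means so the basis block is properly
  ## centered and the estimated components reflect its covariance only
  mu <- if (is.null(basis_rows)) colMeans(channels) else
    colMeans(channels[basis_rows, , drop = FALSE])
  Xc <- sweep(channels, 2, mu)
  Xb <- if (is.null(basis_rows)) Xc else Xc[basis_rows, , drop = FALSE]
  pc <- stats::prcomp(Xb, center = FALSE, scale. = FALSE)
  V <- pc$rotation[, seq_len(n_components), drop = FALSE]
  cleaned <- Xc - Xc %*% V %*% t(V)
  sweep(cleaned, 2, mu, `+`)
}

#' Ensemble average of aligned series
#'
#' @param series_list list of equal-length numeric vectors with aligned
#'   onsets.
#' @return list with `mean`, `sd` (pointwise) and `n`.
#' @export
ensemble_average <- function(series_list) {
  if (!length(series_list)) stop("empty cohort")
  len <- vapply(series_list, length, integer(1))
  if (length(unique(len)) != 1) stop("series lengths differ")
  M <- do.call(cbind, series_list)
  list(mean = rowMeans(M),
       sd = if (ncol(M) > 1) apply(M, 1, stats::sd) else rep(0, nrow(M)),
       n = ncol(M))
}

#' Full fNIRS preprocessing chain for one subject
#'
#' Fixed, logged stage order: tHb construction -> PCA systemic removal (on the
#' pooled channel set) -> zero-phase band-pass -> baseline subtraction and
#' maximum normalization -> anti-correlation QC. Returns the per-region
#' normalized tHb plus the QC report.
#'
#' @param record a `subject_record`.
#' @param low,high analysis band (Hz).
#' @param n_components PCA components to remove (default 1).
#' @param qc_window anti-correlation QC window (s).
#' @return list with per-region `thb` (normalized series), `qc` (per-region
#'   r/pass), `stages` (the stage log) and `record` metadata.
#' @export
preprocess_subject <- function(record, low = 0.01, high = 0.05,
                               n_components = 1, qc_window = 600) {
  rate <- record$rate
  ## PCA across the pooled channels of the full montage (regions plus any
  ## background channels); the spatial basis is estimated on the pre-onset
  ## baseline so the evoked response does not contribute to the removed
  ## subspace
  pool <- c(record$regions,
            if (!is.null(record$background)) list(record$background))
  oxy_all <- do.call(cbind, lapply(pool, `[[`, "oxy"))
  deoxy_all <- do.call(cbind, lapply(pool, `[[`, "deoxy"))
  if (n_components > 0) {
    bl <- seq_len(max(2, round(record$stim_onset * rate)))
    oxy_all <- pca_systemic_removal(oxy_all, n_components, basis_rows = bl)
    deoxy_all <- pca_systemic_removal(deoxy_all, n_components,
                                      basis_rows = bl)
  }
  ## reassemble per-region records
  cleaned <- record
  j <- 0
  for (nm in names(record$regions)) {
    nc <- ncol(record$regions[[nm]]$oxy)
    cleaned$regions[[nm]]$oxy <- oxy_all[, j + seq_len(nc), drop = FALSE]
    cleaned$regions[[nm]]$deoxy <- deoxy_all[, j + seq_len(nc), drop = FALSE]
    j <- j + nc
  }
  thb_raw <- compute_thb(cleaned)
  thb <- lapply(thb_raw, function(s) {
    f <- bandpass(s, rate = rate, low = low, high = high)
    baseline_normalize(f, rate = rate, onset = record$stim_onset,
                       baseline_window = record$baseline_window)
  })
  qc <- lapply(names(record$regions), function(nm) {
    anticorrelation_qc(cleaned, region = nm, window = qc_window)
  })
  names(qc) <- names(record$regions)
  list(subject_id = record$subject_id, thb = thb, qc = qc,
       stages = c("thb", "pca_removal", "bandpass", "baseline_normalize",
                  "qc"),
       rate = rate, stim_onset = record$stim_onset, meta = record$meta)
}

#' Read/write the long-format fNIRS table
#'
#' Delimited long-format exchange: columns `time`, `subject`, `region`,
#' `channel`, `oxy`, `deoxy`.
#'
#' @param records list of `subject_record`s.
#' @param file path.
#' @name fnirs_io
#' @export
write_fnirs_table <- function(records, file) {
  rows <- list()
  for (rec in records) {
    for (nm in names(rec$regions)) {
      rg <- rec$regions[[nm]]
      t <- (seq_len(nrow(rg$oxy)) - 1) / rec$rate
      for (ch in seq_len(ncol(rg$oxy))) {
        rows[[length(rows) + 1]] <- data.frame(
          time = t, subject = rec$subject_id, region = nm, channel = ch,
          oxy = rg$oxy[, ch], deoxy = rg$deoxy[, ch])
      }
    }
  }
  df <- do.call(rbind, rows)
  utils::write.table(df, file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname fnirs_io
#' @param rate,stim_onset,baseline_window record metadata (not stored in the
#'   table).
#' @export
read_fnirs_table <- function(file, rate = 10, stim_onset = 120,
                             baseline_window = 120) {
  df <- utils::read.table(file, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  out <- list()
  for (sid in unique(df$subject)) {
    ds <- df[df$subject == sid, ]
    regions <- list()
    for (nm in unique(ds$region)) {
      dr <- ds[ds$region == nm, ]
      chs <- sort(unique(dr$channel))
      oxy <- sapply(chs, function(ch) dr$oxy[dr$channel == ch])
      deoxy <- sapply(chs, function(ch) dr$deoxy[dr$channel == ch])
      regions[[nm]] <- list(oxy = as.matrix(oxy), deoxy = as.matrix(deoxy))
    }
    out[[as.character(sid)]] <- subject_record(
      sid, regions, rate = rate, stim_onset = stim_onset,
      baseline_window = baseline_window)
  }
  out
}
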