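#' Hankel singular values of a stable linear model
#'
#' @param model a `linear_model` (asymptotically stable).
#' @return non-increasing, non-negative numeric vector.
#' @export
hankel_singular_values <- function(model) {
  .balance_factors(model)$hsv
}

.assert_stable <- function(A) {
  ev <- eigen(A, only.values = TRUE)$values
  if (max(Re(ev)) >= 0) {
    stop("model is not asymptotically stable (max Re(pole) = ",
         format(max(Re(ev))), "); split marginal modes before reduction")
  }
  invisible(ev)
}

# square-root balancing: gramian factors, Hankel singular values and the
# balancing transformation
.balance_factors <- function(model) {
  A <- model$A
  .assert_stable(A)
  P <- cpp_lyap(A, model$B %*% t(model$B))
  Q <- cpp_lyap(t(A), t(model$C) %*% model$C)
  sq <- function(M) {
    e <- eigen((M + t(M)) / 2, symmetric = TRUE)
    e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
  }
  S <- sq(P); R <- sq(Q)
  sv <- svd(R %*% S)
  list(hsv = sv$d, S = S, R = R, U = sv$u, V = sv$v)
}

#' Balanced-truncation model reduction
#'
#' Discards the states contributing least to the input-output behaviour, as
#' measured by the Hankel singular values, using the square-root balancing
#' algorithm. The H-infinity error of the reduced model is bounded by twice
#' the sum of the discarded singular values; the bound and the DC-gain error
#' are returned in the report.
#'
#' @param model a stable `linear_model`.
#' @param order retained order; if `NULL`, chosen from `tol`.
#' @param tol relative Hankel-singular-value threshold (default 1e-7) used
#'   when `order` is `NULL`.
#' @return list with `model` (the reduced `linear_model`) and `report`
#'   (class `"reduction_report"`: `hsv`, `order`, `error_bound`,
#'   `dc_gain_error`).
#' @export
balanced_truncate <- function(model, order = NULL, tol = 1e-7) {
  bf <- .balance_factors(model)
  hsv <- bf$hsv
  n <- length(hsv)
  ## numerical rank: states with hsv ~ 0 cannot be balanced (uncontrollable
  ## or unobservable) and are always dropped
  rank_max <- sum(hsv > max(hsv) * 1e-12)
  r <- if (is.null(order)) sum(hsv > max(hsv) * tol) else order
  r <- min(r, rank_max)
  if (r < 1) stop("requested order leaves no dynamic states")
  s_half <- 1 / sqrt(hsv[seq_len(r)])
  T_r <- bf$S %*% bf$V[, seq_len(r), drop = FALSE] %*% diag(s_half, r)
  Ti_r <- diag(s_half, r) %*% t(bf$U[, seq_len(r), drop = FALSE]) %*% bf$R
  Ar <- Ti_r %*% model$A %*% T_r
  Br <- Ti_r %*% model$B
  Cr <- model$C %*% T_r
  red <- linear_model(Ar, Br, Cr, model$D,
                      state_labels = paste0("b", seq_len(r)),
                      free_mask = model$free_mask,
                      operating_point = model$operating_point,
                      pathway = model$pathway)
  bound <- if (r < n) 2 * sum(hsv[(r + 1):n]) else 0
  report <- structure(
    list(hsv = hsv, order = r, error_bound = bound,
         dc_gain_error = abs(dc_gain(red) - dc_gain(model))),
    class = "reduction_report")
  list(model = red, report = report)
}

#' @export
print.reduction_report <- function(x, ...) {
  cat("balanced truncation: retained order", x$order, "of", length(x$hsv),
      "| H-inf error bound", format(x$error_bound, digits = 4),
      "| DC-gain error", format(x$dc_gain_error, digits = 4), "\n")
  invisible(x)
}

#' Balanced minimal realization
#'
#' Removes uncontrollable and unobservable states exactly (structural Kalman
#' decomposition on the sparsity graph), then truncates any remaining
#' numerically negligible states at a tiny relative Hankel-singular-value
#' threshold.
#'
#' @param model a stable `linear_model`.
#' @param tol relative Hankel threshold (default 1e-12).
#' @return reduced `linear_model`.
#' @export
minimal_realization <- function(model, tol = 1e-12) {
  m <- .structural_kalman(model)
  if (nrow(m$A) == 0) stop("model has no reachable and observable states")
  balanced_truncate(m, order = NULL, tol = tol)$model
}

# exact structural Kalman reduction: drop states that are not reachable from
# the input support or not co-reachable to the output support in the sparsity
# graph of A; for a deviation model these states are identically zero or
# never read, so the principal submatrix realization is exact
.structural_kalman <- function(model) {
  Aad <- model$A != 0
  reach <- function(adj, start) {
    seen <- start
    frontier <- start
    while (length(frontier)) {
      nxt <- which(apply(adj[, frontier, drop = FALSE], 1, any))
      frontier <- setdiff(nxt, seen)
      seen <- union(seen, frontier)
    }
    seen
  }
  rc <- reach(Aad, which(rowSums(abs(model$B)) > 0))
  ro <- reach(t(Aad), which(colSums(abs(model$C)) > 0))
  keep <- sort(intersect(rc, ro))
  linear_model(model$A[keep, keep, drop = FALSE],
               model$B[keep, , drop = FALSE],
               model$C[, keep, drop = FALSE], model$D,
               state_labels = model$state_labels[keep],
               free_mask = model$free_mask,
               operating_point = model$operating_point,
               pathway = model$pathway)
}

#' Reference minimal-realization transfer functions of the four pathways
#'
#' The package's reference parameterization of the nested pathway transfer
#' functions from the reduced grey-box analysis, in factored form. The four
#' are nested: each higher pathway multiplies additional zero/pole factors
#' onto the one below it, so the pole/zero counts are 11/3, 10/3, 8/2 and 6/1
#' for pathways 1-4. They initialize fixed-order estimation and provide the
#' normalized impulse-response timing analysis.
#'
#' @param pathway integer 1-4.
#' @return a [rational_tf()] with unit leading gain.
#' @export
#' @examples
#' tf4 <- reference_pathway_tf(4)
#' length(tf4$poles)  # 6
reference_pathway_tf <- function(pathway) {
  stopifnot(pathway %in% 1:4)
  ## complex pair from s^2 + 9.804 s + 95.24
  re <- -9.804 / 2
  im <- sqrt(95.24 - re^2)
  tf4 <- rational_tf(zeros = -2.962,
                     poles = c(-9.594e6, -20.69, -3.3, -0.2446,
                               complex(real = re, imaginary = im),
                               complex(real = re, imaginary = -im)),
                     gain = 1, label = "TF4")
  if (pathway == 4) return(tf4)
  tf3 <- tf_series(rational_tf(zeros = -2.371e7,
                               poles = c(-2.974e4, -1), gain = 1), tf4)
  tf3$label <- "TF3"
  if (pathway == 3) return(tf3)
  tf2 <- tf_series(rational_tf(zeros = -46.5,
                               poles = c(-1.966, -15.08), gain = 1), tf3)
  tf2$label <- "TF2"
  if (pathway == 2) return(tf2)
  tf1 <- tf_series(rational_tf(zeros = complex(0), poles = -0.4, gain = 1), tf2)
  tf1$label <- "TF1"
  tf1
}

#' Peak time of the normalized impulse response
#'
#' Simulates the impulse response by matrix-exponential stepping, normalizes
#' the peak magnitude to 1, and returns the time of the global maximum refined
#' by quadratic interpolation around the discrete peak.
#'
#' @param tf a stable `rational_tf`.
#' @param horizon simulation horizon (s).
#' @param dt sampling interval (s), default 1 ms.
#' @return numeric peak time (s), with attributes `peak` (signed peak before
#'   normalization) and `boundary` (TRUE if the maximum sits at the horizon,
#'   which also raises a warning).
#' @export
#' @examples
#' # (s+a)^-2 peaks at t = 1/a
#' impulse_peak_time(rational_tf(poles = c(-1, -1), gain = 1), horizon = 10)
impulse_peak_time <- function(tf, horizon = 30, dt = 1e-3) {
  if (max(Re(tf$poles)) >= 0) stop("impulse_peak_time requires a stable system")
  ir <- impulse_response(tf, horizon, dt)
  i <- which.max(abs(ir$h))
  boundary <- i == length(ir$h)
  if (boundary) {
    warning("impulse response still growing at the horizon; peak at boundary")
  }
  tpk <- ir$time[i]
  if (i > 1 && i < length(ir$h)) {
    ## quadratic refinement on |h|
    y1 <- abs(ir$h[i - 1]); y2 <- abs(ir$h[i]); y3 <- abs(ir$h[i + 1])
    denom <- y1 - 2 * y2 + y3
    if (abs(denom) > 0) tpk <- tpk + dt * 0.5 * (y1 - y3) / denom
  }
  structure(tpk, peak = ir$h[i], boundary = boundary)
}

#' Fixed-order transfer-function estimation (output error)
#'
#' Fits a rational transfer function of fixed pole/zero counts to sampled
#' input/output data by Levenberg-Marquardt minimization of the simulation
#' error. Poles are parameterized in a stability-preserving form (real poles
#' as -exp(theta); complex pairs by log natural frequency and log damping), so
#' every candidate during the search is stable. The initial parameterization
#' is taken from `init` (typically a nested reference pathway model, reduced
#' to the requested order by balanced truncation).
#'
#' @param input,output numeric series at sampling interval `dt`.
#' @param n_poles,n_zeros requested orders, `n_zeros < n_poles`.
#' @param init a `rational_tf` initial model, or `NULL` for a generic
#'   low-pass start.
#' @param dt sampling interval (s).
#' @param prefilter optional function applied to the simulated response before
#'   the error is formed (see [pem_fit()]); when given, `input` may be longer
#'   than `output` (the prefilter crops to the measured window).
#' @param max_iter Levenberg-Marquardt iteration cap.
#' @return list with `tf` (fitted `rational_tf`), `mse` (mean squared
#'   simulation error), `gof` (chi-square goodness of fit, the residual sum
#'   of squares normalized by the output sum of squares about its mean),
#'   `rss`, `n_free`, `converged`.
#' @export
tf_estimate <- function(input, output, n_poles, n_zeros, init = NULL,
                        dt = 0.1, prefilter = NULL, max_iter = 30) {
  stopifnot(n_zeros < n_poles)
  if (is.null(prefilter)) stopifnot(length(input) == length(output))
  if (is.null(init)) {
    init <- rational_tf(zeros = -seq_len(n_zeros),
                        poles = -0.5 * seq_len(n_poles), gain = 1)
  }
  init <- .match_order(init, n_poles, n_zeros)
  par0 <- .tf_to_par(init)
  simfun <- function(tf) {
    yhat <- lsim_foh(tf, input, dt)
    if (!is.null(prefilter)) yhat <- prefilter(yhat)
    yhat
  }
  resid_fun <- function(par) {
    tf <- .par_to_tf(par, par0$structure)
    yhat <- tryCatch(simfun(tf), error = function(e) rep(1e6, length(output)))
    output - yhat
  }
  fit <- minpack.lm::nls.lm(par = par0$par, fn = resid_fun,
                            control = minpack.lm::nls.lm.control(
                              maxiter = max_iter, ptol = 1e-10))
  tf <- .par_to_tf(fit$par, par0$structure)
  yhat <- simfun(tf)
  rss <- sum((output - yhat)^2)
  tss <- sum((output - mean(output))^2)
  n_free <- length(fit$par)
  list(tf = tf, mse = rss / length(output), gof = rss / tss, rss = rss,
       n_free = n_free, prediction = yhat,
       converged = fit$info %in% 1:4)
}

# bring a tf to the requested order: balanced truncation for poles, then pad
# or drop zeros (dropped from the fastest end, gain-compensated)
.match_order <- function(tf, n_poles, n_zeros) {
  if (length(tf$poles) != n_poles) {
    ss <- .tf_to_ss(tf)
    m <- linear_model(ss$A, ss$B, ss$C, ss$D)
    tf <- to_transfer_function(balanced_truncate(m, order = n_poles)$model)
  }
  z <- tf$zeros[order(abs(tf$zeros))]
  g <- tf$gain
  while (length(z) > n_zeros) {
    zi <- z[length(z)]
    g <- g * Re(-zi)  # preserve DC contribution of the dropped factor
    z <- z[-length(z)]
  }
  while (length(z) < n_zeros) z <- c(z, -10 * max(abs(z), 1))
  rational_tf(z, tf$poles, g, label = tf$label)
}

# pack a tf into an unconstrained parameter vector (stability-preserving)
.tf_to_par <- function(tf) {
  pg <- .group_conjugates(tf$poles)
  par <- numeric(0); structure <- list(npairs = 0, nreal = 0)
  pairs <- Filter(function(p) length(p) == 2, pg)
  reals <- Filter(function(p) length(p) == 1, pg)
  for (p in pairs) {
    wn <- abs(p[1]); zeta <- -Re(p[1]) / wn
    par <- c(par, log(wn), log(max(zeta, 1e-3)))
  }
  for (p in reals) par <- c(par, log(max(-Re(p[1]), 1e-8)))
  structure$npairs <- length(pairs); structure$nreal <- length(reals)
  zr <- Re(tf$zeros)
  structure$nzeros <- length(zr)
  c_par <- c(par, zr, tf$gain)
  list(par = c_par, structure = structure)
}

.par_to_tf <- function(par, structure) {
  i <- 1; poles <- complex(0)
  for (k in seq_len(structure$npairs)) {
    wn <- exp(par[i]); zeta <- exp(par[i + 1]); i <- i + 2
    if (zeta < 1) {
      re <- -zeta * wn; im <- wn * sqrt(1 - zeta^2)
      poles <- c(poles, complex(real = re, imaginary = im),
                 complex(real = re, imaginary = -im))
    } else {
      d <- wn * sqrt(zeta^2 - 1)
      poles <- c(poles, as.complex(-zeta * wn + d), as.complex(-zeta * wn - d))
    }
  }
  for (k in seq_len(structure$nreal)) {
    poles <- c(poles, as.complex(-exp(par[i]))); i <- i + 1
  }
  zeros <- as.complex(par[seq(i, length.out = structure$nzeros)])
  gain <- par[length(par)]
  rational_tf(zeros, poles, gain)
}

#' Chi-square difference test for nested fixed-order models
#'
#' Compares a sequence of nested output-error fits (as returned by
#' [tf_estimate()]) and selects the lowest-order model whose fit is not
#' significantly worse than the next larger one. The difference statistic is
#' `(RSS_small - RSS_large) / (RSS_large / (N - k_large))` on
#' `k_large - k_small` degrees of freedom.
#'
#' @param fits list of `tf_estimate` results, any order.
#' @param n_samples number of data samples.
#' @param alpha significance level (default 0.05).
#' @return list with `selected` (index into `fits` of the chosen model) and
#'   `table` (data.frame: n_free, rss, gof, p_next).
#' @export
compare_nested <- function(fits, n_samples, alpha = 0.05) {
  k <- vapply(fits, function(f) f$n_free, numeric(1))
  o <- order(k)
  fits_o <- fits[o]
  m <- length(fits_o)
  p_next <- rep(NA_real_, m)
  sel <- m
  for (i in seq_len(m - 1)) {
    small <- fits_o[[i]]; large <- fits_o[[i + 1]]
    dfree <- large$n_free - small$n_free
    stat <- max(small$rss - large$rss, 0) /
      (large$rss / (n_samples - large$n_free))
    p_next[i] <- stats::pchisq(stat, df = max(dfree, 1), lower.tail = FALSE)
  }
  ## walk from the smallest model upward; stop at the first model not
  ## significantly improved upon by the next larger one
  sel <- m
  for (i in seq_len(m - 1)) {
    if (p_next[i] > alpha) { sel <- i; break }
  }
  tab <- data.frame(
    n_free = k[o],
    rss = vapply(fits_o, function(f) f$rss, numeric(1)),
    gof = vapply(fits_o, function(f) f$gof, numeric(1)),
    p_next = p_next
  )
  list(selected = o[sel], table = tab)
}
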