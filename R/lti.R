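#' Linear state-space model container
#'
#' Continuous-time state-space quadruple (A, B, C, D) with state labels, an
#' identifiable-parameter mask and the operating point it was linearized at.
#'
#' @param A,B,C,D system matrices; `D` defaults to zero.
#' @param state_labels character vector of state symbols.
#' @param free_mask character vector naming the identifiable parameters the
#'   prediction-error fit may adjust (see [pem_fit()]); default gain and rate.
#' @param operating_point the state vector the model was linearized at.
#' @param pathway integer 1-4 or `NA`.
#' @return object of class `"linear_model"`.
#' @export
linear_model <- function(A, B, C, D = matrix(0, nrow(C), ncol(B)),
                         state_labels = NULL, free_mask = c("gain", "rate"),
                         operating_point = NULL, pathway = NA_integer_) {
  A <- as.matrix(A); B <- as.matrix(B); C <- as.matrix(C); D <- as.matrix(D)
  n <- nrow(A)
  stopifnot(ncol(A) == n, nrow(B) == n, ncol(C) == n,
            nrow(D) == nrow(C), ncol(D) == ncol(B))
  if (is.null(state_labels)) state_labels <- paste0("x", seq_len(n))
  ev <- eigen(A, only.values = TRUE)$values
  if (any(!is.finite(ev))) stop("state matrix has non-finite eigenvalues")
  structure(list(A = A, B = B, C = C, D = D, state_labels = state_labels,
                 free_mask = free_mask, operating_point = operating_point,
                 pathway = pathway),
            class = "linear_model")
}

#' @export
print.linear_model <- function(x, ...) {
  ev <- eigen(x$A, only.values = TRUE)$values
  cat("linear_model:", nrow(x$A), "states,", ncol(x$B), "input(s),",
      nrow(x$C), "output(s)\n")
  cat("  pathway:", x$pathway, "| max Re(pole):",
      format(max(Re(ev)), digits = 4), "\n")
  invisible(x)
}

#' Rational transfer function in zero-pole-gain form
#'
#' Stores the factored (zeros/poles/gain) representation -- numerically robust
#' at wide pole spreads -- together with expanded polynomial coefficients in
#' descending powers of s.
#'
#' @param zeros,poles complex vectors (complex values must come in conjugate
#'   pairs so the coefficients are real).
#' @param gain real scalar: G(s) = gain * prod(s - z) / prod(s - p).
#' @param label optional name.
#' @return object of class `"rational_tf"` with fields `zeros`, `poles`,
#'   `gain`, `num`, `den`, `label`.
#' @export
rational_tf <- function(zeros = complex(0), poles, gain = 1, label = NULL) {
  if (length(zeros) > length(poles)) {
    stop("denominator degree must be at least the numerator degree")
  }
  num <- Re(.poly_from_roots(zeros)) * gain
  den <- Re(.poly_from_roots(poles))
  structure(list(zeros = as.complex(zeros), poles = as.complex(poles),
                 gain = gain, num = num, den = den, label = label),
            class = "rational_tf")
}

#' @export
print.rational_tf <- function(x, ...) {
  cat("rational_tf", if (!is.null(x$label)) paste0("[", x$label, "]") else "",
      ": ", length(x$poles), " poles, ", length(x$zeros), " zeros, gain ",
      format(x$gain, digits = 6), "\n", sep = "")
  invisible(x)
}

# monic polynomial coefficients (descending powers) from roots
.poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (ri in r) p <- c(p, 0) - c(0, p * ri)
  p
}

#' Frequency response of a transfer function or state-space model
#'
#' Evaluated in factored form for `rational_tf` (stable at wide pole spreads)
#' and through the resolvent `C (sI - A)^-1 B + D` for `linear_model`.
#'
#' @param sys a `rational_tf` or `linear_model`.
#' @param w angular frequencies (rad/s).
#' @return complex vector of G(jw).
#' @export
freqresp <- function(sys, w) {
  s <- 1i * w
  if (inherits(sys, "rational_tf")) {
    vapply(s, function(si) {
      lg <- sum(log(si - sys$zeros)) - sum(log(si - sys$poles))
      sys$gain * exp(lg)
    }, complex(1))
  } else if (inherits(sys, "linear_model")) {
    n <- nrow(sys$A)
    vapply(s, function(si) {
      (sys$C %*% solve(diag(si, n) - sys$A, sys$B) + sys$D)[1, 1]
    }, complex(1))
  } else stop("unsupported system type")
}

#' DC gain
#' @param sys a `rational_tf` or `linear_model`.
#' @return steady-state gain G(0).
#' @export
dc_gain <- function(sys) {
  if (inherits(sys, "rational_tf")) {
    Re(sys$gain * prod(-sys$zeros) / prod(-sys$poles))
  } else {
    (-sys$C %*% solve(sys$A, sys$B) + sys$D)[1, 1]
  }
}

#' Series interconnection of two transfer functions
#' @param f,g `rational_tf` objects; returns g(s) f(s).
#' @return `rational_tf`.
#' @export
tf_series <- function(f, g) {
  rational_tf(c(f$zeros, g$zeros), c(f$poles, g$poles), f$gain * g$gain,
              label = paste(c(f$label, g$label), collapse = " * "))
}

# zpk -> state-space as a cascade of first/second-order sections.
# Real poles give 1x1 sections, conjugate pairs 2x2; zeros are distributed
# over sections (at most as many as the section's poles). Numerically robust
# for the wide pole spreads of the composed pathway transfer functions.
.tf_to_ss <- function(tf) {
  stopifnot(length(tf$zeros) <= length(tf$poles))
  grp <- .group_conjugates(tf$poles)
  zg <- .group_conjugates(tf$zeros)
  # flatten zeros into a queue, pairs first so they land in 2x2 sections
  zqueue <- zg[order(!vapply(zg, function(z) length(z) == 2L, logical(1)))]
  A <- matrix(0, 0, 0); B <- matrix(0, 0, 1); C <- matrix(0, 1, 0)
  D <- matrix(1, 1, 1)
  take_zeros <- function(k) {
    out <- list()
    while (k > 0 && length(zqueue)) {
      cand <- zqueue[[1]]
      if (length(cand) <= k) {
        out <- c(out, list(cand)); zqueue <<- zqueue[-1]; k <- k - length(cand)
      } else break
    }
    unlist(lapply(out, identity))
  }
  # order pole groups: pairs first (so paired zeros can be placed), fast last
  grp <- grp[order(!vapply(grp, function(p) length(p) == 2L, logical(1)),
                   -vapply(grp, function(p) max(abs(p)), numeric(1)))]
  for (pg in grp) {
    zz <- take_zeros(length(pg))
    if (length(pg) == 1L) {
      p <- Re(pg)
      if (length(zz) == 1L) {        # (s - z)/(s - p): D=1, C=(p - z)... G = 1 + (p-z)/(s-p)? check
        z <- Re(zz)
        sec <- list(A = matrix(p, 1, 1), B = matrix(1, 1, 1),
                    C = matrix(p - z, 1, 1), D = matrix(1, 1, 1))
      } else {
        sec <- list(A = matrix(p, 1, 1), B = matrix(1, 1, 1),
                    C = matrix(1, 1, 1), D = matrix(0, 1, 1))
      }
    } else {
      a <- Re(.poly_from_roots(pg))  # s^2 + a1 s + a0
      if (length(zz) == 2L) {
        b <- Re(.poly_from_roots(zz))
        # (s^2+b1 s+b0)/(s^2+a1 s+a0) = 1 + ((b1-a1)s + (b0-a0))/den
        sec <- list(A = rbind(c(0, 1), c(-a[3], -a[2])),
                    B = rbind(0, 1),
                    C = cbind(b[3] - a[3], b[2] - a[2]),
                    D = matrix(1, 1, 1))
      } else if (length(zz) == 1L) {
        z <- Re(zz)
        sec <- list(A = rbind(c(0, 1), c(-a[3], -a[2])),
                    B = rbind(0, 1), C = cbind(-z, 1), D = matrix(0, 1, 1))
      } else {
        sec <- list(A = rbind(c(0, 1), c(-a[3], -a[2])),
                    B = rbind(0, 1), C = cbind(1, 0), D = matrix(0, 1, 1))
      }
    }
    ## series: previous system (A,B,C,D) feeding section (sec)
    n1 <- nrow(A); n2 <- nrow(sec$A)
    A <- rbind(cbind(A, matrix(0, n1, n2)),
               cbind(sec$B %*% C, sec$A))
    B <- rbind(B, sec$B %*% D)
    C <- cbind(sec$D %*% C, sec$C)
    D <- sec$D %*% D
  }
  if (length(zqueue)) stop("could not distribute zeros over pole sections")
  list(A = A, B = B * tf$gain, C = C, D = D * tf$gain)
}

# group complex-conjugate roots: returns list of length-1 (real) or
# length-2 (conjugate pair) root sets
.group_conjugates <- function(r, tol = 1e-8) {
  out <- list(); used <- rep(FALSE, length(r))
  for (i in seq_along(r)) {
    if (used[i]) next
    if (abs(Im(r[i])) < tol * max(1, abs(r[i]))) {
      out[[length(out) + 1]] <- Re(r[i]); used[i] <- TRUE
    } else {
      j <- which(!used & seq_along(r) != i &
                   abs(r - Conj(r[i])) < 1e-6 * max(1, abs(r[i])))
      if (!length(j)) stop("complex root without conjugate partner")
      j <- j[1]
      out[[length(out) + 1]] <- c(r[i], r[j]); used[c(i, j)] <- TRUE
    }
  }
  out
}

#' Simulate a continuous-time linear system with first-order-hold input
#'
#' Exact discretization for piecewise-linear input (first-order hold) via the
#' Van Loan augmented matrix exponential, appropriate for the piecewise-linear
#' trapezoid stimulus at 10 Hz.
#'
#' @param sys `linear_model`, `rational_tf`, or a bare list with A, B, C, D.
#' @param u input samples.
#' @param dt sampling interval (s).
#' @param x0 initial state (default zero).
#' @return numeric vector of output samples (same length as `u`).
#' @export
lsim_foh <- function(sys, u, dt, x0 = NULL) {
  ss <- if (inherits(sys, "rational_tf")) .tf_to_ss(sys) else sys
  A <- ss$A; B <- as.matrix(ss$B); C <- ss$C; D <- ss$D
  n <- nrow(A)
  M <- rbind(cbind(A, B, matrix(0, n, 1)),
             cbind(matrix(0, 1, n), 0, 1),
             matrix(0, 1, n + 2))
  E <- .expm(M * dt)
  F1 <- E[1:n, 1:n, drop = FALSE]
  H0 <- E[1:n, n + 1, drop = FALSE]
  H1 <- E[1:n, n + 2, drop = FALSE]
  x <- if (is.null(x0)) numeric(n) else as.numeric(x0)
  N <- length(u)
  y <- numeric(N)
  Dn <- as.numeric(D)
  for (k in seq_len(N)) {
    y[k] <- as.numeric(C %*% x) + Dn * u[k]
    if (k < N) x <- as.numeric(F1 %*% x + H0 * u[k] + H1 * (u[k + 1] - u[k]) / dt)
  }
  y
}

#' Impulse response of a linear system
#'
#' Computed by matrix-exponential stepping of a section-cascade realization:
#' the state starts at B and is propagated by expm(A dt). Strictly proper
#' systems only.
#'
#' @param sys `rational_tf` or `linear_model`/list with A, B, C.
#' @param t_end horizon (s).
#' @param dt sampling interval (s).
#' @return list with `time` and `h`.
#' @export
impulse_response <- function(sys, t_end, dt = 1e-3) {
  ss <- if (inherits(sys, "rational_tf")) .tf_to_ss(sys) else sys
  if (any(abs(ss$D) > 0)) stop("impulse response requires a strictly proper system")
  A <- ss$A
  E <- .expm(A * dt)
  nsteps <- floor(t_end / dt)
  x <- as.numeric(ss$B)
  h <- numeric(nsteps + 1)
  Cm <- ss$C
  h[1] <- as.numeric(Cm %*% x)
  for (k in seq_len(nsteps)) {
    x <- as.numeric(E %*% x)
    h[k + 1] <- as.numeric(Cm %*% x)
  }
  list(time = seq(0, by = dt, length.out = nsteps + 1), h = h)
}

# matrix exponential (Ward's balanced Pade approximation via the Matrix
# package; robust on stiff non-normal cascade matrices)
.expm <- function(M) as.matrix(Matrix::expm(Matrix::Matrix(M)))
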