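# shared, lazily-computed objects reused across test files
.ctx <- new.env(parent = emptyenv())

test_ctx <- function() {
  if (is.null(.ctx$params)) {
    .ctx$params <- nvu_parameters()
    .ctx$eq <- nvu_find_equilibrium(.ctx$params)
    .ctx$models <- lapply(1:4, function(pw) {
      nvu_linearize(.ctx$params, .ctx$eq$state, pw)
    })
  }
  .ctx
}

# a 150 s fitting stimulus at 10 Hz (30 s ramp, then steady)
fit_stimulus <- function() tdcs_trapezoid(1, 30, 120, 0, onset = 0, rate = 10,
                                          t_end = 150)

# random stable state-space model for reduction tests
random_stable_model <- function(n = 10) {
  A <- matrix(stats::rnorm(n * n), n) / sqrt(n)
  shift <- max(Re(eigen(A, only.values = TRUE)$values)) + 0.3
  A <- A - diag(n) * shift
  linear_model(A, matrix(stats::rnorm(n), n), matrix(stats::rnorm(n), 1))
}
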