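test_that("the system has exactly 17 state derivatives with the canonical labels", {
  ctx <- test_ctx()
  d <- nvu_derivatives(ctx$eq$state, 0, ctx$params)
  expect_length(d, 17L)
  expect_identical(names(d), nvu_state_names())
  expect_error(nvu_derivatives(ctx$eq$state[-1], 0, ctx$params), "17 state")
})

test_that("equilibrium is a fixed point, idempotent, and attracts nearby guesses", {
  ctx <- test_ctx()
  expect_equal(ctx$eq$strategy, "newton")
  expect_lt(ctx$eq$residual, 1e-8)
  d <- nvu_derivatives(ctx$eq$state, 0, ctx$params)
  expect_lt(max(abs(d)), 1e-6)
  ## feeding the equilibrium back converges immediately to the same state
  eq2 <- nvu_find_equilibrium(ctx$params, guess = ctx$eq$state)
  expect_equal(as.numeric(eq2$state), as.numeric(ctx$eq$state), tolerance = 1e-10)
  ## +-5% perturbed guess lands on the same equilibrium
  set.seed(3)
  guess <- ctx$eq$state * (1 + stats::runif(17, -0.05, 0.05))
  eq3 <- nvu_find_equilibrium(ctx$params, guess = guess)
  expect_equal(as.numeric(eq3$state), as.numeric(ctx$eq$state), tolerance = 1e-6)
})

test_that("compiled and reference derivative implementations agree term-wise", {
  ## the C core used by the integrator is an independent translation of the
  ## equations; compare elementwise on 100 random perturbed states, with and
  ## without pathway perturbations
  ctx <- test_ctx()
  set.seed(42)
  pert_names <- c("dJKs", "dIT", "dKT", "dIKV")
  for (i in 1:100) {
    s <- ctx$eq$state * (1 + stats::runif(17, -0.2, 0.2))
    pw <- sample(1:4, 1)
    v <- stats::rnorm(1, 0, 0.01)
    pert <- stats::setNames(v, pert_names[pw])
    dR <- nvu_derivatives(s, 0, ctx$params, pert)
    dC <- nvucvr:::.nvu_derivs_compiled(s, ctx$params, v, pw)
    expect_equal(as.numeric(dC), as.numeric(dR), tolerance = 1e-10)
  }
})

test_that("pathway perturbations are additive at the documented injection sites", {
  ctx <- test_ctx()
  base <- nvu_derivatives(ctx$eq$state, 0, ctx$params)
  eps <- 1e-3
  ## astrocytic transmembrane current adds eps / C_astr to dVk/dt
  d2 <- nvu_derivatives(ctx$eq$state, 0, ctx$params, c(dIT = eps))
  expect_equal(d2[["Vk"]] - base[["Vk"]], eps / ctx$params[["C_astr"]],
               tolerance = 1e-10)
  expect_equal(d2[-8], base[-8], tolerance = 1e-12)
  ## synaptic, perivascular and SMC injections analogous
  d1 <- nvu_derivatives(ctx$eq$state, 0, ctx$params, c(dJKs = eps))
  expect_equal(d1[["K_s"]] - base[["K_s"]], eps, tolerance = 1e-10)
  d3 <- nvu_derivatives(ctx$eq$state, 0, ctx$params, c(dKT = eps))
  expect_equal(d3[["K_p"]] - base[["K_p"]], eps, tolerance = 1e-10)
  d4 <- nvu_derivatives(ctx$eq$state, 0, ctx$params, c(dIKV = eps))
  expect_equal(d4[["V_smc"]] - base[["V_smc"]], eps / ctx$params[["C_smc"]],
               tolerance = 1e-10)
})

test_that("unforced simulation stays at the fixed point", {
  ctx <- test_ctx()
  tr <- nvu_simulate(ctx$eq$state, ctx$params, stimulus = NULL,
                     t_span = c(0, 150), dt_out = 0.1)
  expect_lt(max(abs(tr$state[, "x"] - ctx$eq$state[["x"]])), 1e-4)
})

test_that("stimulated trajectories show an initial transient for every pathway", {
  ctx <- test_ctx()
  stim <- tdcs_trapezoid(2, 30, 120, 0, onset = 0, rate = 10, t_end = 150)
  for (pw in 1:4) {
    g <- if (pw == 4) -0.01 else 0.01
    tr <- nvu_simulate(ctx$eq$state, ctx$params, stim, pathway = pw, gain = g,
                       t_span = c(0, 150), dt_out = 0.1)
    dev <- tr$state[, "x"] - ctx$eq$state[["x"]]
    expect_gt(max(abs(dev)), 1e-3)          # the vessel responds
    expect_lt(max(abs(dev)) / ctx$eq$state[["x"]], 0.2)  # and stays bounded
    ## dilation for these gain signs
    expect_gt(dev[length(dev)], 0)
  }
})

test_that("trajectories converge under solver-tolerance refinement", {
  ctx <- test_ctx()
  stim <- tdcs_trapezoid(2, 30, 60, 0, onset = 0, rate = 10, t_end = 100)
  t1 <- nvu_simulate(ctx$eq$state, ctx$params, stim, pathway = 3, gain = 0.02,
                     t_span = c(0, 100), dt_out = 0.1, rtol = 1e-6, atol = 1e-8)
  t2 <- nvu_simulate(ctx$eq$state, ctx$params, stim, pathway = 3, gain = 0.02,
                     t_span = c(0, 100), dt_out = 0.1, rtol = 5e-7, atol = 5e-9)
  rel <- max(abs(t1$state[, "x"] - t2$state[, "x"])) /
    max(abs(t2$state[, "x"] - ctx$eq$state[["x"]]))
  expect_lt(rel, 1e-3)
})

test_that("parameter construction validates symbols and positivity", {
  expect_error(nvu_parameters(not_a_symbol = 1), "unresolved parameter")
  expect_error(nvu_parameters(C_astr = -1), "strictly positive")
  tab <- nvu_parameter_table()
  expect_true(all(tab$provenance %in% c("lineage-default", "design")))
  expect_equal(nrow(tab), length(unclass(nvu_parameters())))
})

test_that("trajectory export writes a complete delimited table", {
  ctx <- test_ctx()
  tr <- nvu_simulate(ctx$eq$state, ctx$params, stimulus = NULL,
                     t_span = c(0, 5), dt_out = 0.5)
  f <- tempfile(fileext = ".tsv")
  write_trajectory(tr, f)
  df <- read.table(f, header = TRUE, sep = "\t")
  expect_equal(dim(df), c(11, 19))  # time + 17 states + stimulus
  expect_equal(df$x, unname(tr$state[, "x"]), tolerance = 1e-9)
})
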