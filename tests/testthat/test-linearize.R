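test_that("input columns have a single structural nonzero at the injection site", {
  ctx <- test_ctx()
  sites <- c("K_s", "Vk", "K_p", "V_smc")
  scales <- c(1, 1 / ctx$params[["C_astr"]], 1, 1 / ctx$params[["C_smc"]])
  for (pw in 1:4) {
    m <- ctx$models[[pw]]
    nz <- which(m$B != 0)
    expect_length(nz, 1L)
    expect_equal(m$state_labels[nz], sites[pw])
    expect_equal(m$B[nz, 1], scales[pw])
    ## output selects the circumference deviation
    expect_equal(which(m$C != 0), which(nvu_state_names() == "x"))
    expect_true(all(m$D == 0))
  }
})

test_that("linearization refuses a non-equilibrium operating point", {
  ctx <- test_ctx()
  bad <- ctx$eq$state * 1.2
  expect_error(nvu_linearize(ctx$params, bad, 1), "not an equilibrium")
})

test_that("all pathway models are asymptotically stable", {
  ctx <- test_ctx()
  for (pw in 1:4) {
    ev <- eigen(ctx$models[[pw]]$A, only.values = TRUE)$values
    expect_lt(max(Re(ev)), 0)
  }
})

test_that("Jacobian is robust to finite-difference step halving", {
  ctx <- test_ctx()
  m1 <- nvu_linearize(ctx$params, ctx$eq$state, 3, rel_step = 1e-6)
  m2 <- nvu_linearize(ctx$params, ctx$eq$state, 3, rel_step = 5e-7)
  e1 <- sort(Re(eigen(m1$A, only.values = TRUE)$values))
  e2 <- sort(Re(eigen(m2$A, only.values = TRUE)$values))
  expect_lt(max(abs(e1 - e2) / pmax(abs(e2), 1e-6)), 1e-4)
})

test_that("a 1-state model converts to the exact transfer function", {
  m <- linear_model(matrix(-1), matrix(1), matrix(1))
  tf <- to_transfer_function(m)
  expect_equal(Re(tf$poles), -1)
  expect_length(tf$zeros, 0L)
  expect_equal(tf$gain, 1, tolerance = 1e-12)
})

test_that("pathway transfer functions match the resolvent on a log grid", {
  ctx <- test_ctx()
  w <- 10^seq(-3, 3, length.out = 30)
  for (pw in 1:4) {
    tf <- to_transfer_function(ctx$models[[pw]])
    G <- freqresp(ctx$models[[pw]], w)
    expect_lt(max(abs(freqresp(tf, w) - G) / abs(G)), 1e-8)
  }
})

test_that("pathway nesting: downstream poles are subsets of upstream poles", {
  ctx <- test_ctx()
  tfs <- lapply(1:4, function(pw) to_transfer_function(ctx$models[[pw]]))
  for (pair in list(c(4, 3), c(3, 2), c(2, 1))) {
    p_lo <- tfs[[pair[1]]]$poles
    p_hi <- tfs[[pair[2]]]$poles
    d <- vapply(p_lo, function(p) min(abs(p - p_hi)) / max(abs(p), 1),
                numeric(1))
    expect_lt(max(d), 1e-6)
  }
})

test_that("small-signal error decreases first-order in amplitude (all pathways)", {
  ctx <- test_ctx()
  stim <- tdcs_trapezoid(2, 30, 120, 0, onset = 0, rate = 10, t_end = 150)
  for (pw in 1:4) {
    errs <- vapply(c(0.02, 0.01), function(eps) {
      tr <- nvu_simulate(ctx$eq$state, ctx$params, stim, pathway = pw,
                         gain = eps, t_span = c(0, 150), dt_out = 0.1,
                         rtol = 1e-9, atol = 1e-11)
      ynl <- tr$state[, "x"] - ctx$eq$state[["x"]]
      ylin <- pem_simulate(ctx$models[[pw]], stim$current, gain = eps)
      sqrt(sum((ynl - ylin)^2) / sum(ylin^2))
    }, numeric(1))
    ## halving the amplitude roughly halves the relative error
    expect_lt(errs[2], 0.65 * errs[1])
  }
})

test_that("cascading the input filter adds exactly one state and one pole", {
  ctx <- test_ctx()
  m3 <- ctx$models[[3]]
  casc <- cascade_with_filter(m3, K = 1, tau = 0.02)
  expect_equal(nrow(casc$A), nrow(m3$A) + 1L)
  tf_m <- to_transfer_function(m3)
  tf_c <- to_transfer_function(casc)
  expect_equal(length(tf_c$poles), length(tf_m$poles) + 1L)
  expect_equal(length(tf_c$zeros), length(tf_m$zeros))
  ## DC gain preserved (unity-DC filter)
  expect_equal(dc_gain(casc), dc_gain(m3), tolerance = 1e-9)
  expect_error(cascade_with_filter(m3, tau = -1), "positive")
})

test_that("linear model serialization round-trips through JSON", {
  ctx <- test_ctx()
  js <- write_linear_model(ctx$models[[2]])
  rec <- jsonlite::fromJSON(js)
  expect_equal(rec$pathway, 2)
  expect_equal(matrix(rec$A, 17, 17), unclass(ctx$models[[2]]$A),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(rec$state_labels, nvu_state_names())
  expect_true(nzchar(rec$operating_point_hash))
})
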