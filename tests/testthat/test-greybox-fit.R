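test_that("the AIC score follows the normalized log-MSE form", {
  expect_equal(aic_score(1, 0, 1500), 0)
  ## doubling the parameter count at fixed mse raises the score by 2*dk/N
  expect_equal(aic_score(0.01, 8, 1500) - aic_score(0.01, 4, 1500),
               2 * 4 / 1500)
  ## monotone in mse at fixed n_free
  expect_lt(aic_score(0.01, 2, 1500), aic_score(0.02, 2, 1500))
  expect_warning(a0 <- aic_score(0, 2, 100), "-Inf")
  expect_identical(a0, -Inf)
  expect_error(aic_score(-1, 0, 10), "non-negative")
  ## ranking agrees with an independently coded criterion on a 4-way case
  mses <- c(0.02, 0.05, 0.011, 0.03)
  ks <- c(2, 2, 2, 2)
  ours <- vapply(1:4, function(i) aic_score(mses[i], ks[i], 1500), numeric(1))
  oracle <- log10(mses) + 2 * ks / 1500  # direct formula, written separately
  expect_equal(order(ours), order(oracle))
})

test_that("fitting the model to its own response returns the initialization", {
  ctx <- test_ctx()
  stim <- fit_stimulus()
  y <- pem_simulate(ctx$models[[3]], stim$current, gain = 0.05, rate = 1)
  ## an exactly self-generated series can reach mse == 0 (AIC -Inf warning)
  fit <- suppressWarnings(pem_fit(ctx$models[[3]], stim$current, y))
  expect_lt(fit$mse, 1e-12)
  expect_equal(unname(coef(fit)[["gain"]]), 0.05, tolerance = 1e-4)
  expect_equal(unname(coef(fit)[["rate"]]), 1, tolerance = 1e-3)
  expect_true(fit$converged)
  expect_equal(fit$n_free, 2L)
  ## gain-only variant
  fit1 <- suppressWarnings(pem_fit(ctx$models[[3]], stim$current, y,
                                   free = "gain"))
  expect_equal(fit1$n_free, 1L)
  expect_lt(fit1$mse, 1e-12)
})

test_that("white measurement noise is recovered as the fit MSE", {
  ctx <- test_ctx()
  stim <- fit_stimulus()
  y0 <- pem_simulate(ctx$models[[3]], stim$current, gain = 0.02)
  sigma <- 0.1 * stats::sd(y0)
  ok <- 0
  for (s in 1:20) {
    set.seed(s)
    y <- y0 + stats::rnorm(length(y0), 0, sigma)
    fit <- pem_fit(ctx$models[[3]], stim$current, y)
    if (abs(fit$mse - sigma^2) / sigma^2 < 0.2) ok <- ok + 1
  }
  expect_gte(ok, 18)
})

test_that("parameter estimates cover the truth at the nominal CI rate", {
  ctx <- test_ctx()
  stim <- fit_stimulus()
  y0 <- pem_simulate(ctx$models[[3]], stim$current, gain = 0.02, rate = 1)
  sigma <- 0.1 * stats::sd(y0)
  cov_g <- 0; cov_r <- 0; n_rep <- 30
  for (s in seq_len(n_rep)) {
    set.seed(1000 + s)
    y <- y0 + stats::rnorm(length(y0), 0, sigma)
    fit <- pem_fit(ctx$models[[3]], stim$current, y)
    sm <- summary(fit)
    if (sm$ci["gain", 1] <= 0.02 && 0.02 <= sm$ci["gain", 2]) cov_g <- cov_g + 1
    if (sm$ci["rate", 1] <= 1 && 1 <= sm$ci["rate", 2]) cov_r <- cov_r + 1
  }
  expect_gte(cov_g / n_rep, 0.8)
  expect_gte(cov_r / n_rep, 0.8)
})

test_that("normalized MSE is invariant to consistent scaling of the raw series", {
  ctx <- test_ctx()
  stim <- fit_stimulus()
  set.seed(77)
  raw <- 5 + pem_simulate(ctx$models[[3]], stim$current, gain = 0.02) +
    stats::rnorm(1501, 0, 0.005)
  norm1 <- baseline_normalize(c(rep(5, 200), raw), rate = 10, onset = 20,
                              baseline_window = 20)
  norm2 <- baseline_normalize(c(rep(5, 200), raw) * 7.3, rate = 10,
                              onset = 20, baseline_window = 20)
  y1 <- as.numeric(norm1)[201:1701]
  y2 <- as.numeric(norm2)[201:1701]
  f1 <- pem_fit(ctx$models[[3]], stim$current, y1)
  f2 <- pem_fit(ctx$models[[3]], stim$current, y2)
  expect_equal(f1$mse, f2$mse, tolerance = 1e-10)
  expect_equal(f1$aic, f2$aic, tolerance = 1e-8)
})

test_that("residual diagnostics report whiteness correctly", {
  ## i.i.d. Gaussian residuals stay inside the 99% bands at ~99% of lags
  frac <- replicate(100, {
    r <- stats::rnorm(1500)
    d <- residual_diagnostics(r, lags = 25)
    d$whiteness_acf
  })
  expect_gte(mean(frac >= 0.95), 0.95)
  ## residuals equal to the input: unit cross-correlation at lag zero
  u <- stats::rnorm(500)
  d <- residual_diagnostics(u, input = u, lags = 25)
  expect_equal(d$ccf[d$ccf_lag == 0], 1, tolerance = 1e-10)
  expect_gt(abs(d$ccf[d$ccf_lag == 0]), d$band)
  ## constant residuals: autocorrelation 1 at every lag
  dc <- residual_diagnostics(rep(2, 100), lags = 10)
  expect_true(all(dc$acf == 1))
  expect_error(residual_diagnostics(rnorm(10)), "at least 50")
})

test_that("fit methods expose prediction, residuals, coefficients and simulation", {
  ctx <- test_ctx()
  stim <- fit_stimulus()
  set.seed(5)
  y <- pem_simulate(ctx$models[[2]], stim$current, gain = 0.03) +
    stats::rnorm(1501, 0, 0.01)
  fit <- pem_fit(ctx$models[[2]], stim$current, y, region = "targeted")
  expect_length(predict(fit), length(y))
  expect_equal(predict(fit) + residuals(fit), y, tolerance = 1e-12)
  expect_named(coef(fit), c("gain", "rate", "tau"))
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_length(sims, 3)
  expect_equal(length(sims[[1]]), length(y))
  expect_output(print(fit), "pathway 2")
  expect_output(print(summary(fit)), "estimate")
})

test_that("cohort summary statistics reproduce direct calculations", {
  set.seed(8)
  tab <- expand.grid(subject = 1:6, region = c("targeted", "nontargeted"),
                     pathway = 1:4)
  tab$mse <- stats::runif(nrow(tab), 0.01, 0.1)
  tab$aic <- log10(tab$mse) + 2 * 2 / 1500
  s <- summarize_fits(tab)
  expect_equal(nrow(s), 8)
  row <- s[s$pathway == 2 & s$region == "targeted", ]
  sel <- tab$pathway == 2 & tab$region == "targeted"
  expect_equal(row$mse_median, stats::median(tab$mse[sel]))
  expect_equal(row$aic_mean, mean(tab$aic[sel]))
  expect_equal(row$mse_sd, stats::sd(tab$mse[sel]))
})
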