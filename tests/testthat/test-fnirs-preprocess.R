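make_record <- function(oxy_t, deoxy_t, oxy_nt = oxy_t, deoxy_nt = deoxy_t,
                        rate = 10, stim_onset = 120) {
  subject_record(
    "S01",
    regions = list(
      targeted = list(oxy = as.matrix(oxy_t), deoxy = as.matrix(deoxy_t)),
      nontargeted = list(oxy = as.matrix(oxy_nt), deoxy = as.matrix(deoxy_nt))),
    rate = rate, stim_onset = stim_onset, baseline_window = stim_onset)
}

test_that("tHb is the oxy/deoxy sum averaged over channels", {
  n <- 7300
  rec <- make_record(matrix(2, n, 2), matrix(1, n, 2))
  thb <- compute_thb(rec)
  expect_equal(unique(thb$targeted), 3)
  ## exact cancellation
  x <- matrix(stats::rnorm(n * 2), n, 2)
  rec2 <- make_record(x, -x)
  expect_true(all(abs(compute_thb(rec2)$targeted) < 1e-12))
  expect_error(subject_record("a", list(r = list(oxy = matrix(0, 5, 1),
                                                 deoxy = matrix(0, 4, 1)))),
               "equal dimensions")
})

test_that("band-pass keeps the passband, rejects cardiac and removes DC", {
  rate <- 10
  t <- seq(0, 1200, by = 1 / rate)
  mid <- seq(2000, length(t) - 2000)
  ## 0.03 Hz passband tone preserved within 5%
  y1 <- bandpass(sin(2 * pi * 0.03 * t), rate = rate)
  expect_equal(max(abs(y1[mid])), 1, tolerance = 0.05)
  ## 1 Hz cardiac tone attenuated by >= 20 dB
  y2 <- bandpass(sin(2 * pi * 1 * t), rate = rate)
  expect_lt(max(abs(y2[mid])), 0.1)
  ## DC eliminated
  y3 <- bandpass(rep(4, length(t)), rate = rate)
  expect_lt(max(abs(y3)), 1e-8)
  ## zero phase: a band-limited pulse peak does not move
  pulse <- exp(-(t - 600)^2 / (2 * 15^2))
  y4 <- bandpass(pulse, rate = rate)
  expect_lt(abs(t[which.max(y4)] - 600), 2)
  expect_error(bandpass(y3, rate = 10, high = 6), "Nyquist")
})

test_that("baseline normalization maps the response extremum to one", {
  rate <- 10
  base <- rep(2, 1200)
  ramp <- seq(0, 5, length.out = 1000)
  y <- baseline_normalize(c(base, ramp), rate = rate, onset = 120,
                          baseline_window = 60)
  expect_equal(max(as.numeric(y)), 1)
  expect_false(attr(y, "negative_peak"))
  expect_equal(attr(y, "scale"), 3)  # max post-onset deviation from baseline 2
  ## negative extremum (initial dip) flagged
  y2 <- baseline_normalize(c(base, 2 - ramp), rate = rate, onset = 120,
                           baseline_window = 60)
  expect_true(attr(y2, "negative_peak"))
  expect_equal(min(as.numeric(y2)), -1)
  ## constant series: subtraction only, degenerate flag
  y3 <- baseline_normalize(rep(3, 2000), rate = rate, onset = 120,
                           baseline_window = 60)
  expect_true(attr(y3, "degenerate"))
  expect_true(all(as.numeric(y3) == 0))
  expect_error(baseline_normalize(rep(0, 100)), "all-zero")
  expect_error(baseline_normalize(rep(1, 2000), baseline_window = 5),
               "at least 10")
})

test_that("anti-correlation QC passes r=-1, fails r=+1 and flags constants", {
  n <- 7301
  s <- sin(2 * pi * 0.02 * seq(0, 730, by = 0.1)) + 0.01 * stats::rnorm(n)
  rec_anti <- make_record(matrix(s, n, 1), matrix(-s, n, 1))
  q1 <- anticorrelation_qc(rec_anti, "targeted")
  expect_lt(q1$r, -0.99)
  expect_true(q1$pass)
  rec_pos <- make_record(matrix(s, n, 1), matrix(s, n, 1))
  q2 <- anticorrelation_qc(rec_pos, "targeted")
  expect_gt(q2$r, 0.99)
  expect_false(q2$pass)
  rec_const <- make_record(matrix(1, n, 1), matrix(s, n, 1))
  q3 <- anticorrelation_qc(rec_const, "targeted")
  expect_true(is.na(q3$r))
  expect_false(q3$pass)
  expect_match(q3$reason, "constant")
  short <- make_record(matrix(s[1:100], 100, 1), matrix(s[1:100], 100, 1),
                       stim_onset = 0)
  expect_error(anticorrelation_qc(short, "targeted"), "too short")
})

test_that("PCA removal eliminates a rank-1 common mode exactly", {
  set.seed(10)
  n <- 2000
  common <- sin(2 * pi * 0.1 * (1:n) / 10)
  unique_part <- matrix(stats::rnorm(n * 6, sd = 1e-4), n, 6)
  X <- unique_part + common            # same loading on all channels
  cleaned <- pca_systemic_removal(X, 1)
  ## the common mode is gone to numerical precision
  resid_common <- stats::lm.fit(cbind(1, common), rowMeans(cleaned))$coefficients[2]
  expect_lt(abs(resid_common), 1e-6)
  ## identity when nothing is removed
  expect_equal(pca_systemic_removal(X, 0), X)
  expect_error(pca_systemic_removal(X, 6), "smaller")
  expect_error(pca_systemic_removal(X[, 1, drop = FALSE], 1), "2 channels")
})

test_that("ensemble averaging is exact and converges at the root-n rate", {
  s1 <- sin(seq(0, 10, by = 0.01))
  ea1 <- ensemble_average(list(s1))
  expect_equal(ea1$mean, s1)
  expect_true(all(ea1$sd == 0))
  ea2 <- ensemble_average(list(s1, -s1))
  expect_lt(max(abs(ea2$mean)), 1e-12)
  expect_error(ensemble_average(list()), "empty")
  expect_error(ensemble_average(list(s1, s1[-1])), "lengths differ")
  ## LLN: noise around a template shrinks ~ 1/sqrt(n)
  set.seed(3)
  noisy <- function(n) lapply(seq_len(n), function(i) s1 + stats::rnorm(length(s1)))
  err4 <- sqrt(mean((ensemble_average(noisy(4))$mean - s1)^2))
  err64 <- sqrt(mean((ensemble_average(noisy(64))$mean - s1)^2))
  expect_lt(err64, err4 / 2)
})

test_that("the subject pipeline is deterministic and logs its stage order", {
  spec <- cohort_spec(n_subjects = 2, seed = 31)
  rec <- generate_subject(spec, 1)
  p1 <- preprocess_subject(rec)
  p2 <- preprocess_subject(rec)
  expect_identical(p1$thb, p2$thb)
  expect_identical(p1$qc, p2$qc)
  expect_equal(p1$stages,
               c("thb", "pca_removal", "bandpass", "baseline_normalize", "qc"))
})

test_that("linear filtering and ensemble averaging commute", {
  set.seed(4)
  series <- lapply(1:5, function(i) stats::rnorm(3000))
  a <- bandpass(ensemble_average(series)$mean, rate = 10)
  b <- ensemble_average(lapply(series, bandpass, rate = 10))$mean
  expect_lt(max(abs(a - b)), 1e-9)
})

test_that("the long-format table round-trips through disk", {
  spec <- cohort_spec(n_subjects = 2, seed = 32, n_background = 0)
  recs <- generate_cohort(spec)
  f <- tempfile(fileext = ".tsv")
  write_fnirs_table(recs, f)
  back <- read_fnirs_table(f, rate = 10, stim_onset = 120,
                           baseline_window = 120)
  expect_length(back, 2)
  r1 <- back[[recs[[1]]$subject_id]]
  expect_equal(r1$regions$targeted$oxy, recs[[1]]$regions$targeted$oxy,
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(r1$regions$nontargeted$deoxy,
               recs[[1]]$regions$nontargeted$deoxy,
               tolerance = 1e-6, ignore_attr = TRUE)
})
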