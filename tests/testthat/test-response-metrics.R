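test_that("cosine fit recovers pure cosines with the lag phase convention", {
  t <- 0:149
  cf0 <- cosine_fit(cos(2 * pi * t / 10), 10)
  expect_equal(cf0$r, 1, tolerance = 1e-9)
  expect_equal(cf0$ph, 0, tolerance = 1e-9)
  cf1 <- cosine_fit(cos(2 * pi * t / 10 - pi / 2), 10)
  expect_equal(cf1$ph, pi / 2, tolerance = 1e-9)
  expect_equal(cf1$amplitude, 1, tolerance = 1e-9)
})

test_that("cosine fit matches the brute-force phase grid search", {
  set.seed(421)
  for (i in 1:5) {
    x <- rnorm(150)
    cf <- cosine_fit(x, 10)
    gs <- grid_search_cosine(x, 10, n_phase = 3600)
    expect_lt(abs(cf$r - gs$r), 1e-6)
    expect_lt(abs(cf$amplitude - 2 * Mod(naive_dft(x, 15)) / 150), 1e-10)
  }
})

test_that("cosine fit coherence is unsigned and invariant to positive affine maps", {
  set.seed(422)
  x <- rnorm(80)
  cf <- cosine_fit(x, 10)
  cf2 <- cosine_fit(3.7 * x + 11, 10)
  expect_equal(cf$r, cf2$r, tolerance = 1e-9)
  expect_gte(cf$r, 0)
  expect_lte(cf$r, 1)
  # zero-variance series is flagged degenerate
  cfz <- cosine_fit(rep(4, 40), 10)
  expect_equal(cfz$r, 0)
  expect_true(cfz$degenerate)
})

test_that("trial averaging is the pointwise mean", {
  tm <- segment_trials(rep(c(1, 2, 3, 4, 5), 4), 5)
  expect_equal(trial_average(tm), c(1, 2, 3, 4, 5))
  x <- rnorm(10)
  tm2 <- structure(rbind(x, -x), tr = 1.5, condition = NULL,
                   class = c("trial_matrix", "matrix"))
  expect_equal(trial_average(tm2), rep(0, 10))
})

test_that("amplitude_std is the population sd and is homogeneous", {
  x <- cos(2 * pi * (0:9) / 10)
  expect_equal(amplitude_std(x), enum_pop_sd(x), tolerance = 1e-12)
  expect_equal(amplitude_std(rep(0, 10)), 0)
  expect_equal(amplitude_std(-2.5 * x), 2.5 * amplitude_std(x), tolerance = 1e-12)
})

test_that("Fourier trial metrics match the naive DFT and amplitude convention", {
  x <- 1.0 * cos(2 * pi * (0:9) / 10)
  f <- fourier_trial_metrics(x)
  expect_equal(f$amplitude, 1, tolerance = 1e-12)
  expect_equal(f$phase, 0, tolerance = 1e-12)
  expect_equal(fourier_trial_metrics(rep(3, 10))$amplitude, 0, tolerance = 1e-12)
  set.seed(423)
  y <- rnorm(10)
  fy <- fourier_trial_metrics(y)
  d <- naive_dft(y, 1)
  expect_lt(abs(fy$amplitude - 2 * Mod(d) / 10), 1e-10)
  expect_lt(abs(fy$phase - ((-Arg(d)) %% (2 * pi))), 1e-10)
})

test_that("Fourier amplitude never exceeds sqrt(2) x the std amplitude", {
  set.seed(424)
  for (i in 1:20) {
    x <- rnorm(10)
    expect_lte(fourier_trial_metrics(x)$amplitude,
               sqrt(2) * amplitude_std(x) + 1e-12)
  }
  # equality for a single harmonic
  x <- cos(2 * pi * (0:9) / 10 - 1)
  expect_equal(fourier_trial_metrics(x)$amplitude / amplitude_std(x), sqrt(2),
               tolerance = 1e-9)
})

test_that("exponential eccentricity bins have the documented edges", {
  b <- make_eccentricity_bins(0.2, 70, 12)
  expect_length(b$edges, 13)
  expect_equal(b$edges[1], 0.2)
  expect_equal(b$edges[13], 70)
  ratios <- b$edges[-1] / b$edges[-13]
  expect_equal(ratios, rep(350^(1 / 12), 12), tolerance = 1e-9)
  b1 <- make_eccentricity_bins(0.2, 70, 1)
  expect_equal(b1$edges, c(0.2, 70))
})

test_that("bin assignment is half-open with a closed last bin", {
  b <- make_eccentricity_bins(0.2, 70, 12)
  expect_equal(assign_bins(c(0.2, 70), b), c(1L, 12L))
  expect_true(is.na(suppressMessages(assign_bins(0.1, b))))
  expect_true(is.na(suppressMessages(assign_bins(71, b))))
})

test_that("phase converts to latency in seconds", {
  expect_equal(phase_to_seconds(pi, 15), 7.5)
  expect_equal(phase_to_seconds(0, 15), 0)
})

test_that("inverted and standard bins differ by ~180 deg; balanced bins cancel", {
  p <- protocol_config(runs_per_condition = 1)
  cp <- list(high = list(noise = noise_spec(), amplitude = 1),
             low = list(noise = noise_spec(), amplitude = 1))
  vm <- default_voxel_meta(8)
  vm$phase_group <- rep(c("standard", "foveal_inverted"), each = 4)
  ses <- generate_session(p, cp, vm, physio = FALSE, n_background = 0, seed = 2)
  pp <- preprocess_session(ses, gsr = FALSE)
  ph_std <- fourier_trial_metrics(trial_average(condition_trials(pp, "all", 1:4)))$phase
  ph_inv <- fourier_trial_metrics(trial_average(condition_trials(pp, "all", 5:8)))$phase
  d <- abs((((ph_inv - ph_std) + pi) %% (2 * pi)) - pi)
  expect_lt(abs(d - pi), 0.2)
  # equal mixture of the two groups destructively interferes
  amp_all <- amplitude_std(trial_average(condition_trials(pp, "all")))
  amp_std <- amplitude_std(trial_average(condition_trials(pp, "all", 1:4)))
  expect_lt(amp_all, 0.02 * amp_std)
})
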