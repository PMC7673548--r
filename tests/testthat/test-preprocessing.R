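test_that("first-trial discard leaves the documented volume counts", {
  m <- matrix(rnorm(3 * 160), nrow = 3)
  out <- discard_first_trial(m, 10)
  expect_equal(ncol(out), 150L)
  expect_equal(attr(out, "volumes_discarded"), 10L)
  # stimulus-free style run: 164 volumes, 14 discarded
  m2 <- matrix(rnorm(2 * 164), nrow = 2)
  expect_equal(ncol(discard_first_trial(m2, 14)), 150L)
  # zero-volume discard is the identity
  expect_equal(discard_first_trial(m, 0)[, ], m[, ])
  expect_error(discard_first_trial(m[, 1:5, drop = FALSE], 10), "shorter")
})

test_that("normalization divides by the mean then standardizes", {
  m <- rbind(c(1, 3), c(2, 6))
  out <- normalize_run(m, mode = "none")
  expect_equal(out[1, ], c(0.5, 1.5))  # hand arithmetic: mean 2
  out2 <- normalize_run(matrix(rnorm(200, mean = 100), nrow = 2))
  expect_equal(apply(out2, 1, function(x) sqrt(mean((x - mean(x))^2))),
               c(1, 1), tolerance = 1e-9)
  expect_equal(rowMeans(out2), c(0, 0), tolerance = 1e-12)
})

test_that("degenerate voxels are excluded from normalization with a warning", {
  m <- rbind(rep(5, 10), rnorm(10, mean = 50), rep(-1, 10))
  expect_warning(out <- normalize_run(m), "excluded")
  expect_equal(nrow(out), 1L)
  expect_equal(attr(out, "excluded_voxels"), c(1L, 3L))
})

test_that("global regression leaves residuals orthogonal to the regressor", {
  set.seed(411)
  m <- matrix(rnorm(20 * 100), nrow = 20)
  out <- regress_global(m)
  g <- attr(out, "global")
  cors <- apply(out, 1, cor, y = g)
  expect_true(all(abs(cors) < 1e-8))
  # a voxel equal to the global mean is annihilated
  g0 <- colMeans(m)
  m2 <- rbind(g0, m)
  out2 <- regress_global(m2, global = g0)
  expect_lt(max(abs(out2[1, ])), 1e-10)
})

test_that("voxels orthogonal to a zero-mean global pass through unchanged", {
  n <- 100
  g <- sin(2 * pi * (1:n) / 10)
  v1 <- cos(2 * pi * (1:n) / 10)     # orthogonal to g over whole cycles
  v2 <- sin(2 * pi * (1:n) / 5)
  out <- regress_global(rbind(v1, v2), global = g)
  expect_equal(out[1, ], v1, tolerance = 1e-10)
  expect_equal(out[2, ], v2, tolerance = 1e-10)
})

test_that("constant global falls back to intercept-only with a warning", {
  m <- matrix(rnorm(40), nrow = 2)
  expect_warning(out <- regress_global(m, global = rep(2, 20)), "constant")
  expect_equal(rowMeans(out), c(0, 0), tolerance = 1e-12)
})

test_that("segmentation arithmetic and exclusion bookkeeping", {
  runs <- replicate(3, matrix(rnorm(4 * 150), nrow = 4), simplify = FALSE)
  tm <- concatenate_and_segment(runs, 10)
  expect_equal(dim(tm), c(45L, 10L))
  keep <- rep(TRUE, 45); keep[c(3, 17)] <- FALSE
  tm2 <- concatenate_and_segment(runs, 10, keep_trials = keep)
  expect_equal(nrow(tm2), 43L)
  expect_error(concatenate_and_segment(runs, 7), "multiple")
})

test_that("segmentation then re-concatenation reproduces the series", {
  x <- rnorm(120)
  tm <- segment_trials(x, 10)
  expect_equal(as.numeric(t(tm)), x)
})

test_that("z-scoring is idempotent", {
  z <- function(x) (x - mean(x)) / sqrt(mean((x - mean(x))^2))
  x <- rnorm(50, 3, 7)
  expect_equal(z(z(x)), z(x), tolerance = 1e-12)
})

test_that("GSR removes most of the injected global pulse component", {
  ses <- generate_session(seed = 77)
  pn <- preprocess_session(ses, gsr = FALSE)
  pg <- preprocess_session(ses)
  k_pre <- session_pulse_kernel(pn)
  k_post <- session_pulse_kernel(pg)
  expect_gt(1 - k_post$amplitude / k_pre$amplitude, 0.8)
})

test_that("GSR leaves foveal and peripheral bin amplitudes nearly intact", {
  ses <- generate_session(seed = 78)
  pn <- preprocess_session(ses, gsr = FALSE)
  pg <- preprocess_session(ses)
  bins <- make_eccentricity_bins()
  amp <- function(p) vapply(suppressWarnings(bin_and_average(p, bins, "all")),
                            function(tm) amplitude_std(trial_average(tm)),
                            numeric(1))
  a_pre <- amp(pn); a_post <- amp(pg)
  rel <- (a_post - a_pre) / a_pre
  # bin 4 straddles the foveal/peripheral phase boundary: near-total
  # destructive interference makes its relative amplitude ill-conditioned
  expect_lt(max(abs(rel[-4])), 0.15)
})
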