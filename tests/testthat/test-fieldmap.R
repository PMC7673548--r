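test_that("pRF size formula and its guards", {
  expect_equal(prf_sigma(1, 1), 0.2)
  expect_equal(prf_sigma(1, 2), 0.2 * 2^0.7)
  expect_equal(prf_sigma(3, 3), max(0.2 * 3 * 3^0.7, 0.05))
  # the floor protects point pRFs at the fovea
  expect_equal(prf_sigma(0, 1), 0.05)
  expect_error(prf_sigma(-1, 1), ">= 0")
  expect_error(prf_sigma(1, 4), "roi")
})

test_that("complex response encodes coherence as modulus and phase as argument", {
  expect_equal(complex_response(1, 0), 1 + 0i)
  expect_equal(complex_response(0.5, pi / 2), 0.5i, tolerance = 1e-12)
  set.seed(471)
  co <- runif(20); ph <- runif(20, 0, 2 * pi)
  z <- complex_response(co, ph)
  expect_equal(Mod(z), co, tolerance = 1e-12)
  expect_equal(Arg(z) %% (2 * pi), ph, tolerance = 1e-10)
  expect_error(complex_response(-0.1, 0), ">= 0")
})

test_that("a single voxel projects to a peak at its pRF center with constant phase", {
  # sum mode: coherence follows the gaussian weight, peaking at the center
  fm <- project_field(complex_response(1, 1.2), prf_x = 3, prf_y = -2,
                      sigma = 1.5, grid_n = 49, extent_deg = 6, mode = "sum")
  peak <- which(fm$coherence == max(fm$coherence, na.rm = TRUE), arr.ind = TRUE)
  expect_equal(fm$x[peak[2]], 3, tolerance = 0.26)
  expect_equal(fm$y[peak[1]], -2, tolerance = 0.26)
  ok <- fm$coherence > 1e-6 & !is.na(fm$phase)
  expect_true(all(abs(fm$phase[ok] - 1.2) < 1e-9))
  # mean mode: a lone voxel's normalized response is constant wherever
  # weights exist, and the phase map is constant everywhere
  fm2 <- project_field(complex_response(1, 1.2), prf_x = 3, prf_y = -2,
                       sigma = 1.5, grid_n = 49, extent_deg = 6)
  expect_true(all(abs(fm2$coherence[!fm2$empty] - 1) < 1e-12))
  expect_true(all(abs(fm2$phase[!fm2$empty] - 1.2) < 1e-9))
})

test_that("co-located antiphase voxels cancel at their center", {
  fm <- project_field(complex_response(c(1, 1), c(0, pi)), prf_x = c(0, 0),
                      prf_y = c(0, 0), sigma = c(1, 1), grid_n = 21,
                      extent_deg = 2)
  center <- fm$coherence[11, 11]
  expect_lt(center, 1e-10)
})

test_that("phase rotation and coherence scaling act exactly on the maps", {
  set.seed(472)
  n <- 15
  co <- runif(n, 0.2, 1); ph <- runif(n, 0, 2 * pi)
  px <- runif(n, -3, 3); py <- runif(n, -3, 3); sg <- runif(n, 0.5, 2)
  f0 <- project_field(complex_response(co, ph), px, py, sg, grid_n = 15,
                      extent_deg = 4)
  f1 <- project_field(complex_response(co, ph + 0.7), px, py, sg, grid_n = 15,
                      extent_deg = 4)
  expect_equal((f1$phase - f0$phase) %% (2 * pi), matrix(0.7, 15, 15),
               tolerance = 1e-9)
  f2 <- project_field(complex_response(2 * co, ph), px, py, sg, grid_n = 15,
                      extent_deg = 4)
  expect_equal(f2$coherence, 2 * f0$coherence, tolerance = 1e-9)
})

test_that("uniform-phase input gives a constant phase map wherever weights exist", {
  set.seed(473)
  n <- 30
  fm <- project_field(complex_response(runif(n, 0.5, 1), rep(2, n)),
                      runif(n, -5, 5), runif(n, -5, 5), runif(n, 1, 2),
                      grid_n = 25, extent_deg = 6)
  expect_true(all(abs(fm$phase[!fm$empty] - 2) < 1e-9))
})

test_that("localizer-style input concentrates the map at the stimulus location", {
  set.seed(474)
  n <- 300
  r <- sqrt(runif(n)) * 10
  th <- runif(n, 0, 2 * pi)
  px <- r * cos(th); py <- r * sin(th)
  roi <- sample(1:3, n, replace = TRUE)
  d <- sqrt((px - 3.54)^2 + (py + 3.54)^2)
  co <- ifelse(d < 1, 1, 0)  # stimulus-driven voxels only
  fm <- project_field(complex_response(co, rep(0.8, n)), px, py,
                      prf_sigma(r, roi), grid_n = 61, extent_deg = 12)
  cen <- field_centroid(fm)
  expect_lt(sqrt((cen["x"] - 3.54)^2 + (cen["y"] + 3.54)^2), 1)
})

test_that("sum mode differs from mean mode by per-pixel weight normalization", {
  fm_m <- project_field(complex_response(c(1, 1), c(0, 0)), c(-1, 1), c(0, 0),
                        c(1, 1), grid_n = 11, extent_deg = 2, mode = "mean")
  fm_s <- project_field(complex_response(c(1, 1), c(0, 0)), c(-1, 1), c(0, 0),
                        c(1, 1), grid_n = 11, extent_deg = 2, mode = "sum")
  # hand oracle at the central pixel: both voxels at distance 1, weight
  # exp(-1/2) each; the weighted mean of two unit responses is 1
  expect_equal(fm_m$coherence[6, 6], 1, tolerance = 1e-12)
  expect_equal(fm_s$coherence[6, 6], 2 * exp(-0.5), tolerance = 1e-12)
  expect_lte(max(fm_m$coherence), 1 + 1e-12)  # mean mode bounded by max co
})
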