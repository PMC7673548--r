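test_that("zero-noise trial train has equal impulses at exact multiples of trial_len", {
  p <- protocol_config()
  tt <- generate_trial_train(p, noise_spec(), amplitude = 1.3)
  expect_equal(sum(tt$train > 0), 16L)
  expect_equal(which(tt$train > 0),
               as.integer(round((0:15) * 15 / p$fine_dt)) + 1L)
  expect_true(all(tt$train[tt$train > 0] == 1.3))
  expect_equal(tt$jitter_s, rep(0, 16))
})

test_that("default protocol yields 16 impulses in a 240 s / 160 volume run", {
  p <- protocol_config()
  expect_equal(run_duration(p), 240)
  expect_equal(run_volumes(p), 160L)
  tt <- generate_trial_train(p, noise_spec(temporal_jitter_sd = 1))
  expect_length(tt$onset_s, 16)
})

test_that("recorded temporal jitter matches its generating distribution", {
  set.seed(401)
  p <- protocol_config()
  js <- unlist(replicate(625, {  # 625 x 16 = 10,000 trials
    generate_trial_train(p, noise_spec(temporal_jitter_sd = 1))$jitter_s
  }, simplify = FALSE))
  expect_lt(abs(sd(js) - 1), 0.03)
  expect_lt(abs(mean(js)), 4 / sqrt(length(js)))
})

test_that("amplitude jitter is zero-mean, bounded, and recorded", {
  set.seed(402)
  p <- protocol_config()
  amps <- unlist(replicate(300, {
    generate_trial_train(p, noise_spec(amp_jitter_sd = 0.5), amplitude = 1)$amplitude
  }, simplify = FALSE))
  expect_true(all(amps > 0 & amps < 2))
  expect_lt(abs(mean(amps) - 1), 0.01)
})

test_that("onset jitter escaping the run is clamped and flagged", {
  set.seed(403)
  p <- protocol_config(trials_per_run = 2, trial_len = 15)
  tt <- generate_trial_train(p, noise_spec(temporal_jitter_sd = 40))
  expect_true(all(tt$onset_s >= 0 & tt$onset_s < run_duration(p)))
  expect_true(any(tt$clamped))
})

test_that("noiseless session is the periodic template, sign-flipped at the fovea", {
  p <- protocol_config(runs_per_condition = 1)
  cp <- list(high = list(noise = noise_spec(), amplitude = 1),
             low = list(noise = noise_spec(), amplitude = 1))
  vm <- default_voxel_meta(6)
  ses <- generate_session(p, cp, vm, physio = FALSE, n_background = 0, seed = 1)
  expect_equal(ncol(ses$runs[[1]]$data), 160L)
  std <- which(vm$phase_group == "standard")[1]
  inv <- which(vm$phase_group == "foveal_inverted")[1]
  expect_equal(ses$runs[[1]]$data[std, ], ses$ground_truth$template)
  expect_equal(ses$runs[[1]]$data[inv, ], -ses$ground_truth$template)
  # periodicity after the first trial: shifting by one trial matches
  x <- ses$runs[[1]]$data[std, ]
  expect_equal(x[21:160], x[11:150], tolerance = 1e-12)
})

test_that("sessions are bit-for-bit reproducible under a seed", {
  s1 <- generate_session(tiny_protocol(), voxel_meta = default_voxel_meta(8),
                         n_background = 16, seed = 99)
  s2 <- generate_session(tiny_protocol(), voxel_meta = default_voxel_meta(8),
                         n_background = 16, seed = 99)
  expect_identical(s1$runs[[1]]$data, s2$runs[[1]]$data)
  expect_identical(s1$ground_truth$trials, s2$ground_truth$trials)
  expect_identical(s1$physio[[1]]$peak_times, s2$physio[[1]]$peak_times)
})

test_that("ground truth has one row per trial across all runs", {
  ses <- generate_session(tiny_protocol(), voxel_meta = default_voxel_meta(4),
                          n_background = 0, physio = FALSE, seed = 3)
  expect_equal(nrow(ses$ground_truth$trials), 4L * 4L)  # 4 trials x 4 runs
})

test_that("spectrally synthesized noise has a 1/f power slope", {
  set.seed(404)
  slopes <- replicate(30, {
    x <- one_over_f_noise(1024, 1)
    P <- Mod(fft(x))[2:512]^2
    f <- 1:511
    keep <- f >= 5 & f <= 50  # one decade
    unname(coef(lm(log(P[keep]) ~ log(f[keep])))[2])
  })
  expect_lt(abs(mean(slopes) + 1), 0.15)
})

test_that("mismatched condition labels are rejected", {
  cp <- condition_params_default()
  expect_error(generate_session(tiny_protocol(), cp["high"]), "both")
})

test_that("pupil generator: constant at tonic baseline when phasic and noise are off", {
  par <- pupil_params_default()
  par$phasic <- c(high = 0, low = 0)
  par$noise_sd <- 0
  par$blink_rate_hz <- 0
  pup <- generate_pupil_session(n_trials = 3, params = par, seed = 5)
  expect_true(all(pup$high$pupil == par$tonic[["high"]]))
  expect_true(all(pup$low$pupil == par$tonic[["low"]]))
})

test_that("pupil traces run at 500 Hz with 2,000 samples per 4 s window", {
  pup <- generate_pupil_session(n_trials = 4, seed = 6)
  expect_equal(pup$high$fs, 500)
  seg <- segment_pupil_trials(remove_blinks(pup$high), window_ms = 4000)
  expect_equal(ncol(seg$samples), 2000L)
})

test_that("tonic estimator recovers the generative condition offset", {
  set.seed(405)
  pup <- generate_pupil_session(n_trials = 200)
  s <- pupil_condition_summary(pup)
  truth <- pup$params$tonic[["high"]] - pup$params$tonic[["low"]]
  expect_lt(abs((s$tonic[s$condition == "high"] - s$tonic[s$condition == "low"]) -
                  truth), 0.02)
})
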