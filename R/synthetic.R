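#' Per-trial impulse train on the fine grid
#'
#' Places one impulse per trial at `(k-1) * trial_len + jitter_k`, where
#' `jitter_k ~ N(0, temporal_jitter_sd)`, rounded to the fine grid and clamped
#' to the run. Impulse height is the mean amplitude plus bounded sigmoidal
#' amplitude noise, `amplitude + (2/(1 + exp(-x)) - 1)` with
#' `x ~ N(0, amp_jitter_sd)`: zero-mean, strictly inside (-1, 1), and added
#' to (not scaling) the trial's response amplitude. Exact jitters and
#' realized amplitudes are returned as ground truth.
#'
#' @param protocol a [protocol_config()].
#' @param noise a [noise_spec()]; only the jitter fields are used here.
#' @param amplitude mean trial amplitude (impulse height at zero jitter).
#' @return list with `train` (fine-grid impulse series), and per-trial
#'   `onset_s`, `jitter_s`, `amplitude`, `clamped`.
#' @export
generate_trial_train <- function(protocol, noise = noise_spec(), amplitude = 1) {
  stopifnot(inherits(protocol, "protocol_config"), inherits(noise, "noise_spec"))
  n_fine <- as.integer(round(run_duration(protocol) / protocol$fine_dt))
  k <- seq_len(protocol$trials_per_run)
  nominal <- (k - 1) * protocol$trial_len
  jitter <- if (noise$temporal_jitter_sd > 0)
    stats::rnorm(length(k), 0, noise$temporal_jitter_sd) else numeric(length(k))
  onset <- nominal + jitter
  hi <- run_duration(protocol) - protocol$fine_dt
  clamped <- onset < 0 | onset > hi
  onset <- pmin(pmax(onset, 0), hi)
  amp <- if (noise$amp_jitter_sd > 0)
    amplitude + (sigmoid_amp(stats::rnorm(length(k), 0, noise$amp_jitter_sd)) - 1)
  else rep(amplitude, length(k))
  train <- numeric(n_fine)
  idx <- as.integer(round(onset / protocol$fine_dt)) + 1L
  for (i in seq_along(idx)) train[idx[i]] <- train[idx[i]] + amp[i]
  list(train = train, onset_s = onset, jitter_s = onset - nominal,
       amplitude = amp, clamped = clamped)
}

# sample a fine-grid series at volume acquisition times 0, tr, 2*tr, ...
downsample_to_tr <- function(x, protocol) {
  step <- as.integer(round(protocol$tr / protocol$fine_dt))
  x[seq(1L, length(x), by = step)][seq_len(run_volumes(protocol))]
}

#' Default early-visual-cortex voxel metadata
#'
#' A deterministic grid of pRF centers: eccentricities geometrically spaced
#' over `ecc_range` (matching the roughly uniform voxel counts of exponential
#' eccentricity bins), polar angles spread by the golden angle, ROI labels
#' cycling V1/V2/V3. Voxels with pRF center eccentricity below `foveal_cut`
#' degrees form the `foveal_inverted` phase group: their task response is
#' multiplied by -1, emulating the phase-inverted foveal subpopulation.
#'
#' @param n_voxels number of EVC voxels.
#' @param ecc_range eccentricity range in degrees.
#' @param foveal_cut eccentricity (deg) below which voxels are inverted.
#' @return data.frame with columns `voxel_id`, `eccentricity_deg`, `roi`,
#'   `prf_x_deg`, `prf_y_deg`, `phase_group`.
#' @export
default_voxel_meta <- function(n_voxels = 48, ecc_range = c(0.2, 70),
                               foveal_cut = 1) {
  stopifnot(n_voxels >= 1, ecc_range[1] > 0, ecc_range[2] > ecc_range[1])
  ecc <- exp(seq(log(ecc_range[1]), log(ecc_range[2]), length.out = n_voxels))
  ecc <- pmin(pmax(ecc, ecc_range[1]), ecc_range[2])  # guard fp drift at the ends
  ang <- (seq_len(n_voxels) - 1) * 2.399963  # golden angle, radians
  data.frame(
    voxel_id = seq_len(n_voxels),
    eccentricity_deg = ecc,
    roi = rep_len(1:3, n_voxels),
    prf_x_deg = ecc * cos(ang),
    prf_y_deg = ecc * sin(ang),
    phase_group = ifelse(ecc < foveal_cut, "foveal_inverted", "standard"),
    stringsAsFactors = FALSE)
}

#' Default reward-condition parameters
#'
#' The generative reward effect is higher mean response amplitude together
#' with lower temporal jitter on high-reward runs; ongoing 1/f noise and
#' amplitude jitter are shared between conditions. Heart rate is given a
#' tonic offset and a larger trial-locked bump under high reward.
#'
#' @return named list with `high` and `low` entries, each carrying a
#'   [noise_spec()], a mean `amplitude` (z-units), and heart-rate parameters
#'   `hr_offset_bpm` / `hr_bump_bpm`.
#' @export
condition_params_default <- function() {
  list(
    high = list(noise = noise_spec(independent_sd = 0.5, amp_jitter_sd = 0.3,
                                   temporal_jitter_sd = 0.5),
                amplitude = 1.2, hr_offset_bpm = 3, hr_bump_bpm = 0.25),
    low = list(noise = noise_spec(independent_sd = 0.5, amp_jitter_sd = 0.3,
                                  temporal_jitter_sd = 1.0),
               amplitude = 1.0, hr_offset_bpm = 0, hr_bump_bpm = 0.15))
}

#' Default pulse-to-BOLD kernel injected by the generator
#'
#' A hemodynamic-shaped lagged filter mapping instantaneous heart rate
#' (beats/min, mean-centered) to a globally shared BOLD component, sampled on
#' the TR grid over lags `0..max_lag` seconds.
#'
#' @param tr repetition time (s).
#' @param max_lag kernel support (s), a multiple of `tr`.
#' @param gain peak kernel weight in z-units per beat/min.
#' @return list with `lags_s` and `weights`.
#' @export
default_pulse_kernel <- function(tr = 1.5, max_lag = 30, gain = 0.07) {
  lags <- seq(0, max_lag, by = tr)
  # strongly biphasic: little DC gain, so slow heart-rate drifts and the
  # trial-locked bump transmit weakly while mid-frequency fluctuations pass
  w <- gamma_lobe(lags, 4, 1.5) - 0.5 * gamma_lobe(lags, 12, 2)
  list(lags_s = lags, weights = gain * w / max(w))
}

# heart-rate trace, pulse peak times, and the shared BOLD component for one
# run; the trial-locked bump follows nominal (unjittered) trial onsets
generate_physio_run <- function(protocol, cond_par, pulse_kernel,
                                hr_baseline = 60, hr_fs = 50,
                                hr_noise_sd = 3, hr_white_sd = 0.8) {
  dur <- run_duration(protocol)
  t <- seq(0, dur - 1 / hr_fs, by = 1 / hr_fs)
  u <- t %% protocol$trial_len
  bump <- cond_par$hr_bump_bpm * gamma_lobe(u, 2, 0.8)
  hr <- hr_baseline + cond_par$hr_offset_bpm + bump +
    one_over_f_noise(length(t), hr_noise_sd) +
    stats::rnorm(length(t), 0, hr_white_sd)
  hr <- pmax(hr, 40)
  # pulse peaks at unit crossings of the integrated instantaneous rate
  phase <- cumsum(hr / 60) / hr_fs
  n_beats <- floor(max(phase))
  peak_times <- stats::approx(phase, t, xout = seq_len(n_beats))$y
  # anti-aliased heart rate on the TR grid: mean within each TR window
  win <- as.integer(round(protocol$tr * hr_fs))
  nv <- run_volumes(protocol)
  hr_tr <- colMeans(matrix(hr[seq_len(win * nv)], nrow = win))
  comp <- convolve_causal(hr_tr - mean(hr_tr), pulse_kernel$weights)
  list(peak_times = peak_times, hr_fs = hr_fs, hr_true = hr_tr,
       injected_kernel = pulse_kernel, pulse_component = comp)
}

#' Generate a synthetic fMRI session
#'
#' Builds `2 * runs_per_condition` runs (alternating high/low reward). Trial
#' timing and amplitude jitter are drawn once per run and shared by all
#' voxels (they model trial-level neural variability); the jittered impulse
#' train is convolved with the double-gamma IRF on the fine grid, sampled at
#' the TR, scaled by the voxel gain, and sign-flipped for the
#' `foveal_inverted` phase group. Each voxel then receives independent 1/f
#' noise; a heart-rate-driven component (injected pulse kernel convolved with
#' the run's instantaneous heart rate) is added with equal weight to every
#' voxel; optional white measurement noise last.
#'
#' The synthetic "scanned volume" additionally contains `n_background`
#' non-ROI voxels standing in for the non-retinotopic tissue in the imaged
#' field of view: they carry the global pulse component, 1/f noise, and a
#' task-entrained response whose phase is randomized per voxel (task-related
#' activity is widespread but phase-heterogeneous outside the ROI, so it
#' largely cancels in the global mean). They are used only when computing
#' the global mean signal.
#'
#' @param protocol a [protocol_config()].
#' @param condition_params list with `high`/`low` entries as in
#'   [condition_params_default()].
#' @param voxel_meta EVC voxel metadata, see [default_voxel_meta()].
#' @param irf an [irf_spec()].
#' @param physio logical; add the heart-rate-driven global component?
#' @param n_background number of non-ROI scanned-volume voxels.
#' @param gain per-voxel response gain (scalar or per-voxel vector).
#' @param seed optional integer seed (full session is reproducible).
#' @return a `taskbold_session`: list with `runs` (each `data` voxel x volume,
#'   `background`, `condition`), `voxel_meta`, `physio` per run,
#'   `ground_truth`, and the `protocol`.
#' @export
generate_session <- function(protocol = protocol_config(),
                             condition_params = condition_params_default(),
                             voxel_meta = default_voxel_meta(),
                             irf = irf_spec("A"),
                             physio = TRUE, n_background = 6 * nrow(voxel_meta),
                             gain = 1, seed = NULL) {
  stopifnot(nrow(voxel_meta) >= 1)
  if (!all(c("high", "low") %in% names(condition_params)))
    stop("`condition_params` must provide both 'high' and 'low' conditions")
  if (!is.null(seed)) set.seed(seed)
  nvox <- nrow(voxel_meta)
  gain <- rep_len(gain, nvox)
  sgn <- ifelse(voxel_meta$phase_group == "foveal_inverted", -1, 1)
  # support one sample short of two trials, so every post-discard trial sees
  # exactly one previous trial's tail and the zero-noise run is exactly
  # periodic after the first trial
  kernel <- make_irf(irf, protocol$fine_dt,
                     duration = 2 * protocol$trial_len - protocol$fine_dt)
  pulse_kernel <- default_pulse_kernel(protocol$tr)
  conditions <- rep(c("high", "low"), protocol$runs_per_condition)
  nv <- run_volumes(protocol)
  # per-voxel circular phase shifts (in volumes) for the background task
  # response: equally spaced over one trial cycle, so the summed background
  # response cancels at the trial frequency and all its harmonics
  bg_shift <- rep_len(seq_len(trial_volumes(protocol)) - 1L, n_background)

  runs <- vector("list", length(conditions))
  physio_l <- vector("list", length(conditions))
  gt <- vector("list", length(conditions))
  for (r in seq_along(conditions)) {
    cond <- conditions[r]
    par <- condition_params[[cond]]
    tt <- generate_trial_train(protocol, par$noise, par$amplitude)
    sig <- downsample_to_tr(convolve_causal(tt$train, kernel), protocol)
    if (physio) {
      ph <- generate_physio_run(protocol, par, pulse_kernel)
      pulse <- ph$pulse_component
    } else {
      ph <- NULL
      pulse <- numeric(nv)
    }
    mat <- matrix(0, nrow = nvox, ncol = nv)
    for (v in seq_len(nvox)) {
      x <- sgn[v] * gain[v] * sig + pulse
      if (par$noise$independent_sd > 0)
        x <- x + one_over_f_noise(nv, par$noise$independent_sd)
      if (par$noise$measurement_sd > 0)
        x <- x + stats::rnorm(nv, 0, par$noise$measurement_sd)
      mat[v, ] <- x
    }
    bg <- NULL
    if (n_background > 0) {
      bg <- matrix(0, nrow = n_background, ncol = nv)
      for (v in seq_len(n_background)) {
        sh <- bg_shift[v]
        shifted <- if (sh == 0) sig else c(sig[(sh + 1):nv], sig[1:sh])
        x <- mean(gain) * shifted + pulse
        if (par$noise$independent_sd > 0)
          x <- x + one_over_f_noise(nv, par$noise$independent_sd)
        if (par$noise$measurement_sd > 0)
          x <- x + stats::rnorm(nv, 0, par$noise$measurement_sd)
        bg[v, ] <- x
      }
    }
    runs[[r]] <- list(data = mat, background = bg, condition = cond)
    physio_l[r] <- list(ph)  # keep the slot even when physio is disabled
    gt[[r]] <- data.frame(run = r, trial = seq_len(protocol$trials_per_run),
                          condition = cond, onset_s = tt$onset_s,
                          jitter_s = tt$jitter_s, amplitude = tt$amplitude,
                          clamped = tt$clamped)
  }
  template <- downsample_to_tr(
    convolve_causal(generate_trial_train(protocol, noise_spec(), 1)$train,
                    kernel), protocol)
  structure(list(runs = runs, voxel_meta = voxel_meta, physio = physio_l,
                 ground_truth = list(trials = do.call(rbind, gt),
                                     condition_params = condition_params,
                                     irf = irf, gain = gain,
                                     template = template,
                                     pulse_kernel = pulse_kernel),
                 protocol = protocol),
            class = "taskbold_session")
}

#' Default pupil-trace parameters
#'
#' Tonic (trial baseline) and phasic (trial-evoked dilation) amplitudes per
#' reward condition, in arbitrary pupillometer units; both are larger on
#' high-reward runs. The phasic waveform is gamma-shaped, peaking about 1 s
#' after trial onset and back at baseline by 4 s. Blinks occur at Poisson
#' times and black out 100-300 ms of samples.
#'
#' @return named list of generator parameters.
#' @export
pupil_params_default <- function() {
  list(tonic = c(high = 1.3, low = 1.0),
       phasic = c(high = 0.45, low = 0.30),
       phasic_trial_cv = 0.1, noise_sd = 0.05,
       blink_rate_hz = 0.1, fs = 500, trial_len_s = 6)
}

#' Generate synthetic pupil traces for both reward conditions
#'
#' Produces one continuous 500 Hz trace per condition: tonic baseline plus a
#' gamma-shaped phasic dilation locked to each trial onset (peak ~1 s,
#' returning to baseline by 4 s), gaussian sample noise, and flagged blink
#' dropouts.
#'
#' @param n_trials trials per condition.
#' @param params see [pupil_params_default()].
#' @param seed optional integer seed.
#' @return list with one `pupil_trace` per condition (`time_s`, `pupil`,
#'   `blink`, `trial_onsets_s`, `fs`) and the ground-truth `params`.
#' @export
generate_pupil_session <- function(n_trials = 40, params = pupil_params_default(),
                                   seed = NULL) {
  stopifnot(n_trials >= 1, params$trial_len_s >= 4)
  if (!is.null(seed)) set.seed(seed)
  fs <- params$fs
  one_cond <- function(cond) {
    dur <- n_trials * params$trial_len_s
    n <- as.integer(dur * fs)
    t <- (seq_len(n) - 1) / fs
    onsets <- (seq_len(n_trials) - 1) * params$trial_len_s
    u <- t %% params$trial_len_s
    wave <- gamma_lobe(u, 1, 0.25)          # peak 1 s, ~0 beyond 3 s
    amp <- params$phasic[[cond]] *
      pmax(1 + stats::rnorm(n_trials, 0, params$phasic_trial_cv), 0)
    trial_idx <- pmin(floor(t / params$trial_len_s) + 1, n_trials)
    x <- params$tonic[[cond]] + amp[trial_idx] * wave +
      stats::rnorm(n, 0, params$noise_sd)
    blink <- logical(n)
    n_blinks <- stats::rpois(1, params$blink_rate_hz * dur)
    if (n_blinks > 0) {
      starts <- stats::runif(n_blinks, 0, dur)
      lens <- stats::runif(n_blinks, 0.1, 0.3)
      for (b in seq_len(n_blinks)) {
        i0 <- max(1L, as.integer(starts[b] * fs))
        i1 <- min(n, as.integer((starts[b] + lens[b]) * fs))
        blink[i0:i1] <- TRUE
        x[i0:i1] <- 0  # dropout: recorded value is meaningless during a blink
      }
    }
    structure(list(time_s = t, pupil = x, blink = blink,
                   trial_onsets_s = onsets, fs = fs,
                   trial_len_s = params$trial_len_s),
              class = "pupil_trace")
  }
  list(high = one_cond("high"), low = one_cond("low"), params = params)
}
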