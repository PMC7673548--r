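#' High-pass filter a run in the Fourier domain
#'
#' Removes the DC component and every discrete Fourier component whose period
#' exceeds `cutoff_s`. The Fourier basis is periodic over the run, so an
#' exactly task-periodic signal (whose energy sits at harmonics of the trial
#' frequency) passes through unchanged — drift removal never distorts the
#' response of interest.
#'
#' @param series numeric vector (one run, one voxel/ROI).
#' @param tr repetition time (s).
#' @param cutoff_s period cutoff in seconds (default 120 s; the 15 s task
#'   frequency is far above it).
#' @return filtered series.
#' @export
highpass_filter <- function(series, tr = 1.5, cutoff_s = 120) {
  n <- length(series)
  stopifnot(n >= 4, tr > 0, cutoff_s > 0)
  X <- stats::fft(series)
  freq_idx <- c(0:(n %/% 2), if (n %% 2 == 0) (n %/% 2 - 1):1 else (n %/% 2):1)
  period <- n * tr / pmax(freq_idx, 1e-12)
  X[freq_idx == 0 | period > cutoff_s] <- 0
  Re(stats::fft(X, inverse = TRUE)) / n
}

#' Configuration of a noise-source sweep
#'
#' One sweep varies a single noise source (task-independent 1/f noise,
#' per-trial amplitude jitter, or per-trial temporal jitter) across ordered
#' levels, the first of which is always zero noise. Default level grids span
#' negligible to severe: independent sd `{0, .2, .4, .8, 1.6, 3.2}` z,
#' amplitude jitter sd `{0, .25, .5, 1, 2, 4}`, temporal jitter sd
#' `{0, .5, 1, 2, 3, 4}` s.
#'
#' @param noise_type `"independent"`, `"amplitude"`, or `"temporal"`.
#' @param irf_variant `"A"` or `"B"`.
#' @param levels ordered noise levels; `levels[1]` must be 0.
#' @param runs_per_level runs simulated at each level (default 100).
#' @param protocol a [protocol_config()] (16 trials of 10 timepoints by
#'   default).
#' @param highpass_cutoff_s high-pass period cutoff (s).
#' @param seed optional integer seed.
#' @return object of class `sweep_config`.
#' @export
sweep_config <- function(noise_type = c("independent", "amplitude", "temporal"),
                         irf_variant = c("A", "B"), levels = NULL,
                         runs_per_level = 100,
                         protocol = protocol_config(),
                         highpass_cutoff_s = 120, seed = NULL) {
  noise_type <- match.arg(noise_type)
  irf_variant <- match.arg(irf_variant)
  levels <- levels %||% switch(noise_type,
    independent = c(0, 0.2, 0.4, 0.8, 1.6, 3.2),
    amplitude = c(0, 0.25, 0.5, 1, 2, 4),
    temporal = c(0, 0.5, 1, 2, 3, 4))
  stopifnot(runs_per_level >= 1, length(levels) >= 2)
  if (levels[1] != 0) stop("levels[1] must be zero noise")
  structure(list(noise_type = noise_type, irf_variant = irf_variant,
                 levels = levels, runs_per_level = as.integer(runs_per_level),
                 protocol = protocol, highpass_cutoff_s = highpass_cutoff_s,
                 seed = seed),
            class = "sweep_config")
}

#' Run a noise-source sweep
#'
#' For each level: simulate `runs_per_level` single-voxel runs with only the
#' configured noise source active, discard the first trial of each run,
#' high-pass filter, concatenate all runs of the level, segment into trials,
#' and compute the mean trial, the time-point variability curve, and the
#' response amplitude (std of the mean trial) normalized to level 1.
#'
#' @param cfg a [sweep_config()].
#' @return object of class `sweep_result`: per level, `mean_trial` (matrix,
#'   levels x timepoints), `var_curve` (same shape), `amplitude` and
#'   `norm_amplitude` vectors, plus the `cfg`.
#' @export
run_sweep <- function(cfg) {
  stopifnot(inherits(cfg, "sweep_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  protocol <- cfg$protocol
  tv <- trial_volumes(protocol)
  # one sample short of two trials: post-discard zero-noise trials are then
  # exactly identical, so level 1 has exactly zero variability
  kernel <- make_irf(irf_spec(cfg$irf_variant), protocol$fine_dt,
                     duration = 2 * protocol$trial_len - protocol$fine_dt)
  nl <- length(cfg$levels)
  mean_trial <- matrix(0, nl, tv)
  var_curve <- matrix(0, nl, tv)
  amplitude <- numeric(nl)
  for (li in seq_len(nl)) {
    lev <- cfg$levels[li]
    ns <- switch(cfg$noise_type,
      independent = noise_spec(independent_sd = lev),
      amplitude = noise_spec(amp_jitter_sd = lev),
      temporal = noise_spec(temporal_jitter_sd = lev))
    runs <- vector("list", cfg$runs_per_level)
    for (r in seq_len(cfg$runs_per_level)) {
      tt <- generate_trial_train(protocol, ns, amplitude = 1)
      x <- downsample_to_tr(convolve_causal(tt$train, kernel), protocol)
      if (ns$independent_sd > 0)
        x <- x + one_over_f_noise(length(x), ns$independent_sd)
      x <- discard_first_trial(x, tv)
      runs[[r]] <- highpass_filter(x, protocol$tr, cfg$highpass_cutoff_s)
    }
    tm <- concatenate_and_segment(runs, tv, tr = protocol$tr)
    mt <- trial_average(tm)
    mean_trial[li, ] <- mt
    var_curve[li, ] <- timepoint_variability(tm)$curve
    amplitude[li] <- amplitude_std(mt)
  }
  structure(list(levels = cfg$levels, mean_trial = mean_trial,
                 var_curve = var_curve, amplitude = amplitude,
                 norm_amplitude = amplitude / amplitude[1], cfg = cfg),
            class = "sweep_result")
}

#' Flatness of a variability curve
#'
#' `(max - min) / mean`: near 0 for the flat curves produced by
#' task-independent noise, large for the response-shaped curves produced by
#' amplitude or temporal jitter.
#'
#' @param variability_curve per-timepoint sd values with positive mean.
#' @return unitless flatness index.
#' @export
flatness_index <- function(variability_curve) {
  m <- mean(variability_curve)
  if (!is.finite(m) || m <= 0) stop("variability curve must have positive mean")
  (max(variability_curve) - min(variability_curve)) / m
}

#' Rank candidate noise sources for an observed variability profile
#'
#' Compares an observed signature (time-point variability curve plus the
#' response amplitude relative to a low-noise baseline) against
#' sweep-derived signatures of the three noise sources. For each source the
#' level whose mean variability best matches the observation is selected and
#' a distance over three features is computed: curve flatness, curve shape
#' (root-mean-square difference of the mean-normalized curves, which is
#' stable even when a reference curve is flat), and the amplitude ratio.
#' Smaller score = better match.
#'
#' @param var_curve observed per-timepoint variability curve.
#' @param amp_change observed amplitude divided by the zero-noise/baseline
#'   amplitude.
#' @param sweeps named list of `sweep_result`s for `independent`,
#'   `amplitude`, and `temporal` (e.g. from [run_sweep()]).
#' @return object of class `noise_signature`: data.frame `scores` ranked
#'   best-first with feature columns, and `degenerate` flag (all-zero
#'   observed variability).
#' @export
classify_noise_signature <- function(var_curve, amp_change, sweeps) {
  stopifnot(all(c("independent", "amplitude", "temporal") %in% names(sweeps)))
  if (mean(var_curve) < 1e-10)
    return(structure(list(scores = NULL, degenerate = TRUE),
                     class = "noise_signature"))
  obs_flat <- flatness_index(var_curve)
  rows <- lapply(c("independent", "amplitude", "temporal"), function(ty) {
    sw <- sweeps[[ty]]
    lv <- 2:length(sw$levels)  # skip the zero-noise level
    pick <- lv[which.min(abs(rowMeans(sw$var_curve[lv, , drop = FALSE]) -
                               mean(var_curve)))]
    ref_curve <- sw$var_curve[pick, ]
    shape_rmse <- sqrt(mean((var_curve / mean(var_curve) -
                               ref_curve / mean(ref_curve))^2))
    data.frame(noise_type = ty,
               flatness_diff = abs(obs_flat - flatness_index(ref_curve)),
               shape_mismatch = shape_rmse,
               amp_diff = abs(amp_change - sw$norm_amplitude[pick]),
               level = sw$levels[pick])
  })
  sc <- do.call(rbind, rows)
  sc$score <- sqrt(sc$flatness_diff^2 + sc$shape_mismatch^2 + sc$amp_diff^2)
  sc <- sc[order(sc$score), ]
  rownames(sc) <- NULL
  structure(list(scores = sc, degenerate = FALSE), class = "noise_signature")
}
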