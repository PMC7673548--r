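#' Trial-to-trial variability at each timepoint
#'
#' The population std across trials is computed separately for each of the
#' trial's timepoints and then averaged across timepoints, yielding the mean
#' time-point variability. Task-independent noise produces a flat curve;
#' amplitude or temporal jitter produce curves shaped like the response.
#'
#' @param tm a `trial_matrix` with at least 2 trials.
#' @return list with `curve` (per-timepoint sd) and `mean`.
#' @export
timepoint_variability <- function(tm) {
  if (nrow(tm) < 2) stop("time-point variability needs >= 2 trials")
  curve <- apply(tm, 2, pop_sd)
  list(curve = curve, mean = mean(curve))
}

#' Trial-to-trial variability of response amplitude
#'
#' Each trial receives an amplitude estimate (the population std of its
#' timepoints); amplitude variability is the population std of those
#' per-trial amplitudes.
#'
#' @param tm a `trial_matrix` with at least 2 trials.
#' @return scalar sd of per-trial amplitudes (z-units).
#' @export
amplitude_variability <- function(tm) {
  if (nrow(tm) < 2) stop("amplitude variability needs >= 2 trials")
  pop_sd(apply(tm, 1, pop_sd))
}

#' Circular standard deviation of a set of angles
#'
#' `sqrt(-2 * log(Rbar))` where `Rbar` is the modulus of the mean unit
#' phasor. Zero iff all angles coincide modulo 2*pi; if `Rbar` is 0 (e.g.
#' antipodal angles) the statistic is unbounded and `Inf` is returned with a
#' warning.
#'
#' @param angles radians.
#' @return circular sd in radians.
#' @export
circular_std <- function(angles) {
  stopifnot(length(angles) >= 1)
  rbar <- Mod(mean(exp(1i * angles)))
  if (rbar < 1e-15) {
    warning("mean resultant length is 0; circular std is unbounded")
    return(Inf)
  }
  if (rbar > 1) rbar <- 1  # numerical guard
  sqrt(-2 * log(rbar))
}

#' Trial-to-trial variability of response timing
#'
#' Each trial's phase at one cycle per trial is extracted with
#' [fourier_trial_metrics()]; temporal variability is the circular std of
#' those phases. Trials whose one-cycle Fourier amplitude is numerically
#' zero carry no phase and are excluded with a warning.
#'
#' @param tm a `trial_matrix` with at least 2 trials.
#' @param amp_tol amplitude below which a trial's phase is undefined.
#' @return circular sd in radians.
#' @export
temporal_variability <- function(tm, amp_tol = 1e-12) {
  if (nrow(tm) < 2) stop("temporal variability needs >= 2 trials")
  f <- apply(tm, 1, function(x) unlist(fourier_trial_metrics(x)))
  ok <- f["amplitude", ] > amp_tol
  if (!all(ok)) {
    warning(sum(!ok), " trial(s) with zero one-cycle amplitude excluded")
    if (sum(ok) < 2) stop("fewer than 2 trials with a defined phase")
  }
  circular_std(f["phase", ok])
}

#' All three variability measures for one condition
#'
#' @param tm a `trial_matrix`.
#' @return object of class `variability_summary`: list with
#'   `timepoint_var_curve`, `timepoint_var_mean`, `amp_var`, `temporal_var`,
#'   `n_trials`.
#' @export
variability_summary <- function(tm) {
  tv <- timepoint_variability(tm)
  structure(list(timepoint_var_curve = tv$curve,
                 timepoint_var_mean = tv$mean,
                 amp_var = amplitude_variability(tm),
                 temporal_var = temporal_variability(tm),
                 n_trials = nrow(tm)),
            class = "variability_summary")
}
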