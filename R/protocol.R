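#' Scan protocol configuration
#'
#' Describes the timing of a periodic-task fMRI session: one volume every
#' `tr` seconds, trials of `trial_len` seconds (an integer number of volumes),
#' `trials_per_run` trials per run. The generator realizes trial onsets on a
#' fine grid of `fine_dt` seconds so that sub-TR onset jitter survives
#' downsampling to the TR grid.
#'
#' @param tr repetition time in seconds (volume spacing).
#' @param trial_len trial duration in seconds; must be an integer multiple of
#'   `tr` (10 volumes per trial at defaults).
#' @param trials_per_run number of trials per run (16 by default, giving
#'   160 volumes / 240 s runs).
#' @param runs_per_condition number of runs per reward condition in a session.
#' @param n_participants group size used by pipeline-level helpers.
#' @param fine_dt step of the fine grid used for impulse trains and IRF
#'   convolution; `tr` must be an integer multiple of it.
#' @param seed optional integer seed recorded with the protocol.
#' @return an object of class `protocol_config`.
#' @export
protocol_config <- function(tr = 1.5, trial_len = 15, trials_per_run = 16,
                            runs_per_condition = 6, n_participants = 14,
                            fine_dt = tr / 10, seed = NULL) {
  stopifnot(tr > 0, trial_len > 0, trials_per_run >= 1,
            runs_per_condition >= 1, n_participants >= 1, fine_dt > 0)
  if (abs(trial_len / tr - round(trial_len / tr)) > 1e-9)
    stop("`trial_len` must be an integer multiple of `tr`")
  if (abs(tr / fine_dt - round(tr / fine_dt)) > 1e-9)
    stop("`tr` must be an integer multiple of `fine_dt`")
  structure(list(tr = tr, trial_len = trial_len,
                 trials_per_run = as.integer(trials_per_run),
                 runs_per_condition = as.integer(runs_per_condition),
                 n_participants = as.integer(n_participants),
                 fine_dt = fine_dt, seed = seed),
            class = "protocol_config")
}

#' @rdname protocol_config
#' @param protocol a `protocol_config`.
#' @export
trial_volumes <- function(protocol) as.integer(round(protocol$trial_len / protocol$tr))

#' @rdname protocol_config
#' @export
run_volumes <- function(protocol) protocol$trials_per_run * trial_volumes(protocol)

#' @rdname protocol_config
#' @export
run_duration <- function(protocol) protocol$trials_per_run * protocol$trial_len

#' Noise specification for the session generator
#'
#' Three dissociable noise sources plus optional white sensor noise:
#' * `independent_sd`: scale (z-units) of 1/f ongoing fluctuations added
#'   independently to every voxel, unrelated to the task;
#' * `amp_jitter_sd`: sd of the gaussian passed through the bounded sigmoid
#'   `2/(1+exp(-x))` that multiplies each trial's response amplitude
#'   (mean 1 by symmetry, strictly positive);
#' * `temporal_jitter_sd`: sd (seconds) of the gaussian jitter added to each
#'   trial's onset time;
#' * `measurement_sd`: white gaussian sensor noise (z-units), default 0.
#'
#' With every field 0 the generator reproduces the noiseless periodic
#' template exactly.
#'
#' @param independent_sd,amp_jitter_sd,temporal_jitter_sd,measurement_sd
#'   nonnegative scalars, see above.
#' @return an object of class `noise_spec`.
#' @export
noise_spec <- function(independent_sd = 0, amp_jitter_sd = 0,
                       temporal_jitter_sd = 0, measurement_sd = 0) {
  vals <- c(independent_sd, amp_jitter_sd, temporal_jitter_sd, measurement_sd)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("all noise scales must be finite and >= 0")
  structure(list(independent_sd = independent_sd,
                 amp_jitter_sd = amp_jitter_sd,
                 temporal_jitter_sd = temporal_jitter_sd,
                 measurement_sd = measurement_sd),
            class = "noise_spec")
}

# population (divide-by-n) standard deviation, the convention used for all
# amplitude measures in the package
pop_sd <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) return(NA_real_)
  sqrt(mean((x - mean(x))^2))
}
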