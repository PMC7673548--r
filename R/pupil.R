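#' Invalidate blink neighborhoods in a pupil trace
#'
#' Every flagged blink sample plus `pad_samples` samples on each side (three
#' samples, i.e. 6 ms at 500 Hz, by default) is marked invalid; padding is
#' clipped at the trace bounds. Values of valid samples are never changed —
#' invalid samples are simply excluded from downstream means and stds (an
#' optional linear-interpolation mode is available but off by default).
#'
#' @param trace a `pupil_trace` (list with `pupil`, `blink`, ...).
#' @param pad_samples samples to invalidate on each side of a blink.
#' @param interpolate replace invalid samples by linear interpolation instead
#'   of excluding them.
#' @return the trace with a logical `valid` field (and interpolated `pupil`
#'   values if requested).
#' @export
remove_blinks <- function(trace, pad_samples = 3, interpolate = FALSE) {
  stopifnot(!is.null(trace$blink), pad_samples >= 0)
  n <- length(trace$blink)
  invalid <- trace$blink
  idx <- which(trace$blink)
  if (length(idx) > 0 && pad_samples > 0) {
    for (d in seq_len(pad_samples)) {
      invalid[pmax(idx - d, 1L)] <- TRUE
      invalid[pmin(idx + d, n)] <- TRUE
    }
  }
  trace$valid <- !invalid
  if (interpolate && any(invalid) && any(!invalid)) {
    ok <- which(!invalid)
    trace$pupil <- stats::approx(ok, trace$pupil[ok], xout = seq_len(n),
                                 rule = 2)$y
    trace$valid <- rep(TRUE, n)
  }
  trace
}

#' Segment a pupil trace into per-trial windows
#'
#' Each trial is the first `window_ms` milliseconds from its onset (2,000
#' samples at 500 Hz for the default 4,000 ms window). Trials extending past
#' the end of the trace are dropped with a message, as are trials without a
#' behavioral response when `keep_trials` is provided, and trials with no
#' valid samples at all.
#'
#' @param trace a `pupil_trace`, ideally after [remove_blinks()].
#' @param window_ms analysis window per trial (> 0).
#' @param keep_trials optional logical per trial.
#' @return list with `samples` (trials x window matrix) and `valid` (same
#'   shape, logical).
#' @export
segment_pupil_trials <- function(trace, window_ms = 4000, keep_trials = NULL) {
  stopifnot(window_ms > 0)
  fs <- trace$fs
  w <- as.integer(round(window_ms / 1000 * fs))
  if (is.null(trace$valid)) trace$valid <- rep(TRUE, length(trace$pupil))
  onsets <- trace$trial_onsets_s
  if (!is.null(keep_trials)) {
    stopifnot(length(keep_trials) == length(onsets))
    onsets <- onsets[keep_trials]
  }
  starts <- as.integer(round(onsets * fs)) + 1L
  ok <- starts + w - 1L <= length(trace$pupil)
  if (!all(ok)) message(sum(!ok), " trial(s) dropped: window exceeds the trace")
  starts <- starts[ok]
  samples <- t(vapply(starts, function(s) trace$pupil[s:(s + w - 1L)], numeric(w)))
  valid <- t(vapply(starts, function(s) trace$valid[s:(s + w - 1L)], logical(w)))
  all_invalid <- rowSums(valid) == 0
  if (any(all_invalid)) {
    warning(sum(all_invalid), " fully invalid trial(s) dropped")
    samples <- samples[!all_invalid, , drop = FALSE]
    valid <- valid[!all_invalid, , drop = FALSE]
  }
  list(samples = samples, valid = valid, fs = fs)
}

#' Tonic pupil size
#'
#' Per trial, the mean of valid samples within the first `window_ms`
#' milliseconds (25 samples at 500 Hz by default — the pre-response
#' baseline); the condition-level value is the mean across trials. Trials
#' with no valid sample in the window are excluded from the average.
#'
#' @param trials output of [segment_pupil_trials()].
#' @param window_ms baseline window (ms).
#' @return list with `per_trial` values and the across-trial `mean`.
#' @export
tonic_size <- function(trials, window_ms = 50) {
  w <- as.integer(round(window_ms / 1000 * trials$fs))
  stopifnot(w >= 1)
  per_trial <- vapply(seq_len(nrow(trials$samples)), function(i) {
    v <- trials$valid[i, seq_len(w)]
    if (!any(v)) return(NA_real_)
    mean(trials$samples[i, seq_len(w)][v])
  }, numeric(1))
  list(per_trial = per_trial, mean = mean(per_trial, na.rm = TRUE))
}

#' Phasic pupil size
#'
#' Per trial, the population std of the valid samples across the whole
#' analysis window (the trial-evoked modulation); the condition-level value
#' is the mean across trials. A constant trial legitimately returns 0.
#'
#' @param trials output of [segment_pupil_trials()].
#' @return list with `per_trial` values and the across-trial `mean`.
#' @export
phasic_size <- function(trials) {
  per_trial <- vapply(seq_len(nrow(trials$samples)), function(i) {
    v <- trials$valid[i, ]
    if (sum(v) < 2) return(NA_real_)
    pop_sd(trials$samples[i, v])
  }, numeric(1))
  list(per_trial = per_trial, mean = mean(per_trial, na.rm = TRUE))
}

#' Tonic and phasic summaries for a two-condition pupil session
#'
#' Convenience wrapper: blink removal, segmentation, tonic and phasic
#' quantification for each condition of a [generate_pupil_session()] result
#' (or any compatible pair of traces).
#'
#' @param pupil_session list with `high` and `low` `pupil_trace`s.
#' @param window_ms analysis window (ms).
#' @return data.frame with one row per condition: `tonic`, `phasic`,
#'   `n_trials`; per-trial values in attribute `per_trial`.
#' @export
pupil_condition_summary <- function(pupil_session, window_ms = 4000) {
  per_trial <- list()
  rows <- lapply(c("high", "low"), function(cond) {
    tr <- remove_blinks(pupil_session[[cond]])
    seg <- segment_pupil_trials(tr, window_ms = window_ms)
    tonic <- tonic_size(seg)
    phasic <- phasic_size(seg)
    per_trial[[cond]] <<- list(tonic = tonic$per_trial, phasic = phasic$per_trial)
    data.frame(condition = cond, tonic = tonic$mean, phasic = phasic$mean,
               n_trials = nrow(seg$samples))
  })
  out <- do.call(rbind, rows)
  attr(out, "per_trial") <- per_trial
  out
}
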