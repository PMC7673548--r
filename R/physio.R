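#' Instantaneous heart rate from pulse-oximeter peaks
#'
#' The reciprocal of each inter-peak interval defines the rate over that
#' interval (`60/dt` beats/min), anchored at the interval midpoint and
#' linearly interpolated between midpoints; outside the anchored range (but
#' within `[first_peak, last_peak]`) the nearest rate is held constant.
#' Intervals shorter than `min_interval_s` are physiologically implausible at
#' rest and flagged as artifacts.
#'
#' @param peak_times strictly increasing pulse peak times (s), length >= 3.
#' @param min_interval_s artifact threshold for inter-peak intervals.
#' @return object of class `hr_trace`: `anchor_t`, `rate_bpm`, time range,
#'   and `artifact` flags per interval.
#' @export
instantaneous_hr <- function(peak_times, min_interval_s = 0.25) {
  stopifnot(length(peak_times) >= 3)
  if (any(diff(peak_times) <= 0)) stop("peak times must be strictly increasing")
  dt <- diff(peak_times)
  structure(list(anchor_t = peak_times[-length(peak_times)] + dt / 2,
                 rate_bpm = 60 / dt,
                 range = range(peak_times),
                 artifact = dt < min_interval_s),
            class = "hr_trace")
}

#' Evaluate a heart-rate trace on a query grid
#'
#' @param hr an `hr_trace` from [instantaneous_hr()].
#' @param times query times (s); values outside `[first_peak, last_peak]`
#'   return `NA`.
#' @return rate in beats/min at each query time.
#' @export
hr_at <- function(hr, times) {
  out <- stats::approx(hr$anchor_t, hr$rate_bpm, xout = times, rule = 2)$y
  out[times < hr$range[1] | times > hr$range[2]] <- NA_real_
  out
}

# heart rate on the TR grid: mean of a dense evaluation within each volume's
# acquisition window (anti-aliasing for the 50 Hz-derived trace)
hr_resample_tr <- function(hr, protocol, sub = 30) {
  nv <- run_volumes(protocol)
  tq <- (seq_len(nv * sub) - 0.5) * protocol$tr / sub
  v <- hr_at(hr, tq)
  # pad ends with nearest defined rate so partial coverage at run edges works
  v <- stats::approx(tq[!is.na(v)], v[!is.na(v)], xout = tq, rule = 2)$y
  colMeans(matrix(v, nrow = sub))
}

#' Trial-locked heart-rate response
#'
#' Resamples a heart-rate trace to the TR grid, segments it into trials, and
#' averages, yielding the mean trial heart-rate curve and the run-mean rate.
#'
#' @param hr an `hr_trace`.
#' @param protocol a [protocol_config()].
#' @return list with `mean_trial` (bpm per trial timepoint), `mean_rate`
#'   (bpm), and the TR-grid series `rate_tr`.
#' @export
hr_trial_response <- function(hr, protocol) {
  if (hr$range[2] - hr$range[1] < run_duration(protocol) - 2 * protocol$trial_len)
    stop("heart-rate trace does not cover the run")
  rate_tr <- hr_resample_tr(hr, protocol)
  tm <- segment_trials(rate_tr, trial_volumes(protocol), tr = protocol$tr)
  list(mean_trial = trial_average(tm), mean_rate = mean(rate_tr),
       rate_tr = rate_tr)
}

#' Lagged pulse-to-BOLD kernel by finite-impulse-response regression
#'
#' Least-squares FIR weights over lags `0..max_lag_s` of the mean-centered
#' heart rate predicting the mean-centered BOLD series. Runs are treated
#' separately when building the design (lagged predictors never cross run
#' boundaries) and stacked before solving. Kernel amplitude is the
#' population std of the weights.
#'
#' @param bold_runs list of numeric vectors (BOLD series per run, TR grid),
#'   or a single vector.
#' @param hr_runs matching list of heart-rate series (bpm, TR grid).
#' @param tr repetition time (s).
#' @param max_lag_s kernel support in seconds (a multiple of `tr`).
#' @return object of class `pulse_kernel`: `lags_s`, `weights`, `amplitude`.
#' @export
pulse_to_bold_kernel <- function(bold_runs, hr_runs, tr = 1.5, max_lag_s = 30) {
  if (!is.list(bold_runs)) bold_runs <- list(bold_runs)
  if (!is.list(hr_runs)) hr_runs <- list(hr_runs)
  stopifnot(length(bold_runs) == length(hr_runs))
  L <- as.integer(round(max_lag_s / tr))
  Xs <- list(); ys <- list()
  for (r in seq_along(bold_runs)) {
    y <- bold_runs[[r]]; h <- hr_runs[[r]]
    stopifnot(length(y) == length(h))
    h <- h - mean(h); y <- y - mean(y)
    if (pop_sd(h) < 1e-12) stop("constant heart rate: singular design")
    n <- length(y)
    if (n <= L + 1) stop("run shorter than the kernel support")
    X <- sapply(0:L, function(l) h[(L + 1 - l):(n - l)])
    Xs[[r]] <- X; ys[[r]] <- y[(L + 1):n]
  }
  X <- do.call(rbind, Xs); y <- unlist(ys)
  w <- qr.coef(qr(X), y)
  w[!is.finite(w)] <- 0
  structure(list(lags_s = (0:L) * tr, weights = as.numeric(w),
                 amplitude = pop_sd(w)),
            class = "pulse_kernel")
}

#' Session-level pulse kernel, per condition then averaged
#'
#' Estimates the FIR kernel separately for high- and low-reward runs of a
#' session (BOLD = mean across the given voxels) and averages the two
#' kernels, mirroring per-condition estimation followed by averaging.
#'
#' @param session a (possibly preprocessed) `taskbold_session` whose runs
#'   still align with the per-run `physio` entries.
#' @param voxels EVC voxel rows to average for the BOLD series.
#' @param max_lag_s kernel support (s).
#' @return a `pulse_kernel` (averaged weights), with per-condition kernels in
#'   attribute `by_condition`.
#' @export
session_pulse_kernel <- function(session, voxels = NULL, max_lag_s = 30) {
  voxels <- voxels %||% seq_len(nrow(session$voxel_meta))
  tr <- session$protocol$tr
  discarded <- if (!is.null(session$preproc) && session$preproc$discard)
    session$preproc$trial_volumes else 0L
  per_cond <- lapply(c("high", "low"), function(cond) {
    sel <- which(vapply(session$runs, function(r) r$condition == cond, logical(1)))
    bold <- lapply(sel, function(r)
      colMeans(session$runs[[r]]$data[voxels, , drop = FALSE]))
    hrs <- lapply(sel, function(r) {
      hr <- instantaneous_hr(session$physio[[r]]$peak_times)
      rate <- hr_resample_tr(hr, session$protocol)
      if (discarded > 0) rate <- rate[-seq_len(discarded)]
      rate
    })
    pulse_to_bold_kernel(bold, hrs, tr = tr, max_lag_s = max_lag_s)
  })
  w <- (per_cond[[1]]$weights + per_cond[[2]]$weights) / 2
  structure(list(lags_s = per_cond[[1]]$lags_s, weights = w,
                 amplitude = pop_sd(w)),
            class = "pulse_kernel",
            by_condition = stats::setNames(per_cond, c("high", "low")))
}
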