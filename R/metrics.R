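#' Best-fitting cosine at the task frequency
#'
#' Least-squares fit of `A * cos(2*pi*t/period - ph)` (plus an intercept) to a
#' series, with `t` in volumes. The coherence `r` is the Pearson correlation
#' between the series and the fitted cosine, which for a least-squares fit is
#' always in `[0, 1]` — coherence is unsigned, the sign of the response lives
#' in the phase. Phase follows the lag convention: larger phase = later
#' response; `phase/(2*pi) * period` converts to a latency in volumes.
#'
#' When the series length is an integer multiple of the period, the fit is
#' identical to the normalized discrete Fourier coefficient at the task
#' frequency.
#'
#' @param series numeric vector.
#' @param period task period in volumes (10 at defaults).
#' @return an object of class `cosine_fit`: list with `r`, `ph` (radians in
#'   `[0, 2*pi)`), `amplitude`, `period`, and `degenerate` (zero-variance
#'   input flag; `ph` is `NA` then).
#' @export
cosine_fit <- function(series, period) {
  n <- length(series)
  stopifnot(n >= 4, period > 0)
  if (abs(n / period - round(n / period)) > 1e-9)
    stop("series length must be an integer multiple of `period`")
  if (pop_sd(series) < 1e-14)
    return(structure(list(r = 0, ph = NA_real_, amplitude = 0,
                          period = period, degenerate = TRUE),
                     class = "cosine_fit"))
  t <- seq_len(n) - 1
  cc <- cos(2 * pi * t / period)
  ss <- sin(2 * pi * t / period)
  # columns are orthogonal to the intercept over whole cycles
  a <- 2 * sum(series * cc) / n
  b <- 2 * sum(series * ss) / n
  amp <- sqrt(a^2 + b^2)
  ph <- atan2(b, a) %% (2 * pi)
  fitted <- a * cc + b * ss
  r <- if (amp < 1e-14) 0 else stats::cor(series, fitted)
  structure(list(r = r, ph = ph, amplitude = amp, period = period,
                 degenerate = FALSE), class = "cosine_fit")
}

#' Mean trial time series
#'
#' @param tm a `trial_matrix` (trials x timepoints).
#' @return numeric vector: pointwise mean across trials.
#' @export
trial_average <- function(tm) {
  stopifnot(nrow(tm) >= 1)
  colMeans(tm)
}

#' Response amplitude as the std of the mean trial
#'
#' Population standard deviation of the trial-averaged time series: the
#' amplitude of a fixed waveform, not a sample estimate of a distribution.
#'
#' @param mean_trial numeric vector (the trial-averaged response).
#' @param type `"population"` (default) or `"sample"`.
#' @return scalar amplitude in z-units.
#' @export
amplitude_std <- function(mean_trial, type = c("population", "sample")) {
  type <- match.arg(type)
  stopifnot(length(mean_trial) >= 2)
  if (type == "population") pop_sd(mean_trial) else stats::sd(mean_trial)
}

#' Fourier amplitude and phase at one cycle per trial
#'
#' Takes the discrete Fourier component at the trial frequency (index 1; index
#' 0 is DC — the paper's "second component"). Amplitude is normalized as
#' `2*|X_1|/N`, so a pure cosine of amplitude A returns A; the phase is
#' reported in the lag convention (`A*cos(2*pi*k/N - ph)` has phase `ph`),
#' mapped to `[0, 2*pi)`. `phase/(2*pi) * trial_len` is the response latency
#' in seconds.
#'
#' @param mean_trial numeric vector of length >= 4 (one value per timepoint).
#' @return list with `amplitude` and `phase`.
#' @export
fourier_trial_metrics <- function(mean_trial) {
  n <- length(mean_trial)
  stopifnot(n >= 4)
  x1 <- stats::fft(mean_trial)[2]
  list(amplitude = 2 * Mod(x1) / n,
       phase = (-Arg(x1)) %% (2 * pi))
}

#' Convert a response phase to a latency in seconds
#'
#' @param ph phase in radians (lag convention).
#' @param trial_len trial duration in seconds.
#' @return latency in seconds within the trial.
#' @export
phase_to_seconds <- function(ph, trial_len = 15) (ph %% (2 * pi)) / (2 * pi) * trial_len

#' Exponentially spaced eccentricity bins
#'
#' Bin width grows exponentially with eccentricity so that roughly equal
#' numbers of voxels fall in each bin: edges `e_i = min * (max/min)^(i/n)`,
#' half-open `[e_i, e_(i+1))` with the last bin closed. Defaults reproduce
#' the 12 bins spanning 0.2 to 70 degrees.
#'
#' @param min_deg,max_deg eccentricity range in degrees.
#' @param n_bins number of bins.
#' @return object of class `ecc_bins`: list with `edges` (length
#'   `n_bins + 1`) and `n_bins`.
#' @export
make_eccentricity_bins <- function(min_deg = 0.2, max_deg = 70, n_bins = 12) {
  stopifnot(min_deg > 0, max_deg > min_deg, n_bins >= 1)
  i <- 0:n_bins
  structure(list(edges = min_deg * (max_deg / min_deg)^(i / n_bins),
                 n_bins = as.integer(n_bins)),
            class = "ecc_bins")
}

#' Assign voxels to eccentricity bins
#'
#' @param eccentricity vector of pRF center eccentricities (deg).
#' @param bins an [make_eccentricity_bins()] result.
#' @return integer bin index per voxel; `NA` (with a message) for voxels
#'   outside the binned range.
#' @export
assign_bins <- function(eccentricity, bins) {
  idx <- findInterval(eccentricity, bins$edges, rightmost.closed = TRUE)
  out <- ifelse(idx >= 1 & idx <= bins$n_bins, idx, NA_integer_)
  if (anyNA(out))
    message(sum(is.na(out)), " voxel(s) outside the eccentricity range; unbinned")
  out
}

#' Per-bin trial matrices for one condition
#'
#' Voxel series are averaged within each eccentricity bin, concatenated
#' across the condition's runs, and segmented into trials. Empty bins are
#' omitted with a warning.
#'
#' @param session a preprocessed session.
#' @param bins an [make_eccentricity_bins()] result.
#' @param condition `"high"`, `"low"`, or `"all"`.
#' @return named list of `trial_matrix` objects (`bin01`, `bin02`, ...), with
#'   the bin assignment in attribute `bin_of_voxel`.
#' @export
bin_and_average <- function(session, bins, condition = "all") {
  b <- assign_bins(session$voxel_meta$eccentricity_deg, bins)
  out <- list()
  for (k in seq_len(bins$n_bins)) {
    vox <- which(!is.na(b) & b == k)
    if (length(vox) == 0) {
      warning("bin ", k, " is empty; omitted")
      next
    }
    out[[sprintf("bin%02d", k)]] <- condition_trials(session, condition, voxels = vox)
  }
  attr(out, "bin_of_voxel") <- b
  attr(out, "edges") <- bins$edges
  out
}
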