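#' Discard the first trial of a run
#'
#' The opening trial is removed to let the longitudinal magnetization and the
#' hemodynamic response reach steady state: a 160-volume run with 10-volume
#' trials becomes 150 volumes (15 cycles). Stimulus-free runs discard 14 of
#' 164 volumes through the same operation.
#'
#' @param data voxel x volume matrix (or a numeric vector for one voxel).
#' @param n_volumes number of leading volumes to drop.
#' @return matrix/vector with the leading columns removed; the count removed
#'   is recorded in attribute `volumes_discarded`.
#' @export
discard_first_trial <- function(data, n_volumes) {
  vec <- is.null(dim(data))
  if (vec) data <- matrix(data, nrow = 1)
  n_volumes <- as.integer(n_volumes)
  stopifnot(n_volumes >= 0)
  if (ncol(data) <= n_volumes)
    stop("run shorter than the number of volumes to discard")
  out <- data[, if (n_volumes > 0) -seq_len(n_volumes) else TRUE, drop = FALSE]
  if (vec) out <- drop(out)
  attr(out, "volumes_discarded") <- n_volumes
  out
}

#' Normalize a run to z-units
#'
#' Each voxel's time series is divided by its temporal mean (converting
#' arbitrary scanner intensity to fractional signal change) and then
#' standardized. `mode = "center-scale"` (default) subtracts the mean and
#' divides by the population sd; `"divide-only"` divides by the sd without
#' centering, the literal reading of "converted to z-score values by dividing
#' by the std"; `"none"` stops after mean-division (all downstream effects
#' also hold without z-scoring). Voxels with nonpositive mean or zero
#' variance are excluded and reported in attribute `excluded_voxels` with a
#' warning.
#'
#' @param data voxel x volume matrix of raw intensities.
#' @param mode z-scoring mode, see above.
#' @return normalized matrix (possibly with rows dropped).
#' @export
normalize_run <- function(data, mode = c("center-scale", "divide-only", "none")) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(data))
  mu <- rowMeans(data)
  out <- data / mu
  sds <- apply(out, 1, pop_sd)
  bad <- !is.finite(mu) | mu <= 0 | sds < 1e-12
  if (any(bad)) {
    warning(sum(bad), " voxel(s) excluded (nonpositive mean or zero variance)")
    out <- out[!bad, , drop = FALSE]
    sds <- sds[!bad]
  }
  out <- switch(mode,
    "center-scale" = (out - rowMeans(out)) / sds,
    "divide-only" = out / sds,
    "none" = out)
  attr(out, "excluded_voxels") <- which(bad)
  attr(out, "zscore_mode") <- mode
  out
}

#' Regress out the global mean signal
#'
#' Ordinary least squares projection of each voxel onto an intercept and the
#' mean time series over the entire scanned volume, removing the shared
#' physiological component; the residual of every voxel is orthogonal to the
#' global mean. If the global signal is constant the regression falls back to
#' the intercept alone with a warning.
#'
#' @param data voxel x volume matrix (the series to clean).
#' @param global global mean series; defaults to `colMeans(data)`. Pass the
#'   whole-volume mean explicitly when `data` holds only an ROI.
#' @return residual matrix; the regressor is kept in attribute `global`.
#' @export
regress_global <- function(data, global = NULL) {
  stopifnot(is.matrix(data), nrow(data) >= 2 || !is.null(global))
  g <- global %||% colMeans(data)
  stopifnot(length(g) == ncol(data))
  gc <- g - mean(g)
  if (sqrt(mean(gc^2)) < 1e-12) {
    warning("constant global signal; regressing on intercept only")
    out <- data - rowMeans(data)
  } else {
    beta <- (data %*% gc) / sum(gc^2)
    out <- data - rowMeans(data) - beta %*% rbind(gc)
  }
  attr(out, "global") <- g
  out
}

#' Cut a series into a trials x timepoints matrix
#'
#' @param series numeric vector whose length is a multiple of `trial_volumes`.
#' @param trial_volumes timepoints per trial.
#' @param tr repetition time (s), stored on the result.
#' @param condition optional condition label stored on the result.
#' @return a `trial_matrix`: trials x timepoints matrix with attributes
#'   `tr` and `condition`.
#' @export
segment_trials <- function(series, trial_volumes, tr = 1.5, condition = NULL) {
  trial_volumes <- as.integer(trial_volumes)
  stopifnot(trial_volumes >= 1)
  if (length(series) %% trial_volumes != 0L)
    stop("series length is not a multiple of `trial_volumes`")
  tm <- matrix(series, ncol = trial_volumes, byrow = TRUE)
  structure(tm, tr = tr, condition = condition, class = c("trial_matrix", "matrix"))
}

#' Concatenate runs of one condition and segment into trials
#'
#' Runs are reduced to a single series each (by averaging across the supplied
#' voxel rows), concatenated in order, and cut into trials. Trials flagged as
#' non-response are dropped when `keep_trials` is provided.
#'
#' @param runs list of voxel x volume matrices (or numeric vectors), all with
#'   the same length; typically already preprocessed and first-trial-trimmed.
#' @param trial_volumes timepoints per trial.
#' @param tr repetition time (s).
#' @param condition label stored on the result.
#' @param keep_trials optional logical vector, one entry per concatenated
#'   trial; `FALSE` trials (e.g. no behavioral response) are excluded.
#' @return a `trial_matrix`.
#' @export
concatenate_and_segment <- function(runs, trial_volumes, tr = 1.5,
                                    condition = NULL, keep_trials = NULL) {
  series <- unlist(lapply(runs, function(r) {
    if (is.null(dim(r))) as.numeric(r) else colMeans(r)
  }), use.names = FALSE)
  tm <- segment_trials(series, trial_volumes, tr = tr, condition = condition)
  if (!is.null(keep_trials)) {
    stopifnot(length(keep_trials) == nrow(tm))
    tm <- structure(tm[keep_trials, , drop = FALSE], tr = tr,
                    condition = condition, class = c("trial_matrix", "matrix"))
  }
  tm
}

#' Preprocess a synthetic session
#'
#' Applies, per run and in this order: first-trial discard, mean-division plus
#' z-scoring, and global signal regression, where the global mean is computed
#' over the entire scanned volume (EVC plus background voxels) after
#' z-scoring. Background voxels are carried along so later stages can reuse
#' the global regressor.
#'
#' @param session a `taskbold_session` from [generate_session()].
#' @param gsr regress out the global mean signal?
#' @param zscore_mode passed to [normalize_run()]; note the generator already
#'   emits z-unit data, so mean-division is skipped for synthetic input.
#' @param discard drop the first trial of every run?
#' @return the session with processed `runs[[i]]$data`, class
#'   `taskbold_session_preproc`.
#' @export
preprocess_session <- function(session, gsr = TRUE,
                               zscore_mode = "center-scale", discard = TRUE) {
  stopifnot(inherits(session, "taskbold_session"))
  tv <- trial_volumes(session$protocol)
  for (r in seq_along(session$runs)) {
    run <- session$runs[[r]]
    dat <- run$data
    bg <- run$background
    if (discard) {
      dat <- discard_first_trial(dat, tv)
      if (!is.null(bg)) bg <- discard_first_trial(bg, tv)
    }
    # synthetic data are generated in z-like units around 0, so plain
    # standardization stands in for the mean-division + z-score pair
    zstd <- function(m) {
      if (zscore_mode == "none") return(m)
      sds <- apply(m, 1, pop_sd)
      sds[sds < 1e-12] <- 1
      if (zscore_mode == "divide-only") m / sds else (m - rowMeans(m)) / sds
    }
    dat <- zstd(dat)
    if (!is.null(bg)) bg <- zstd(bg)
    if (gsr) {
      g <- colMeans(rbind(dat, bg))
      dat <- regress_global(dat, global = g)
      if (!is.null(bg)) bg <- regress_global(bg, global = g)
    }
    session$runs[[r]]$data <- dat
    session$runs[[r]]$background <- bg
  }
  session$preproc <- list(gsr = gsr, zscore_mode = zscore_mode,
                          discard = discard, trial_volumes = tv)
  class(session) <- c("taskbold_session_preproc", class(session))
  session
}

#' Trial matrix for one condition of a preprocessed session
#'
#' Averages the selected voxels, concatenates the condition's runs, and
#' segments into trials.
#'
#' @param session a preprocessed session.
#' @param condition `"high"`, `"low"`, or `"all"`.
#' @param voxels integer indices of EVC voxels to average (default: all).
#' @return a `trial_matrix`.
#' @export
condition_trials <- function(session, condition = c("high", "low", "all"),
                             voxels = NULL) {
  condition <- match.arg(condition)
  voxels <- voxels %||% seq_len(nrow(session$voxel_meta))
  sel <- vapply(session$runs, function(r)
    condition == "all" || r$condition == condition, logical(1))
  runs <- lapply(session$runs[sel], function(r) r$data[voxels, , drop = FALSE])
  concatenate_and_segment(runs, trial_volumes(session$protocol),
                          tr = session$protocol$tr, condition = condition)
}
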