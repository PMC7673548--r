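#' Pipeline configuration
#'
#' One configuration object drives the full chain: simulate, preprocess,
#' response metrics, variability, permutation inference, physiology, pupil.
#' A single global seed fans out into independent per-stage and
#' per-participant sub-seeds, so toggling one stage never changes another
#' stage's randomness. The object round-trips through JSON unchanged.
#'
#' @param n_participants synthetic group size.
#' @param seed global integer seed.
#' @param n_perm permutations for the inference stage.
#' @param runs_per_condition runs per reward condition per participant.
#' @param n_voxels EVC voxels per participant.
#' @param pupil_trials pupil trials per condition.
#' @param stages named logical list toggling `permtest`, `physio`, `pupil`,
#'   `fieldmap`.
#' @param out optional output directory for tab-separated report tables.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(n_participants = 14, seed = 1, n_perm = 1000,
                            runs_per_condition = 5, n_voxels = 48,
                            pupil_trials = 40,
                            stages = list(permtest = TRUE, physio = TRUE,
                                          pupil = TRUE, fieldmap = FALSE),
                            out = NULL) {
  structure(list(n_participants = as.integer(n_participants),
                 seed = as.integer(seed), n_perm = as.integer(n_perm),
                 runs_per_condition = as.integer(runs_per_condition),
                 n_voxels = as.integer(n_voxels),
                 pupil_trials = as.integer(pupil_trials),
                 stages = stages, out = out),
            class = "pipeline_config")
}

#' Serialize / restore a pipeline configuration
#'
#' @param cfg a [pipeline_config()].
#' @param path JSON file path.
#' @return `read_pipeline_config()` returns the restored `pipeline_config`.
#' @export
write_pipeline_config <- function(cfg, path) {
  writeLines(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, null = "null"),
             path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::fromJSON(path)
  pipeline_config(n_participants = x$n_participants, seed = x$seed,
                  n_perm = x$n_perm, runs_per_condition = x$runs_per_condition,
                  n_voxels = x$n_voxels, pupil_trials = x$pupil_trials,
                  stages = as.list(x$stages), out = x$out)
}

# deterministic fan-out of the global seed into sub-stream seeds (< 2^31)
derive_seeds <- function(seed, n, stage) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed + 7919L * match(stage, c("simulate", "pupil", "permtest")))
  sample.int(.Machine$integer.max - 1L, n)
}

# the statistic functions exposed to the permutation stage; each maps a
# trials x timepoints submatrix to a scalar
pipeline_statistics <- function() {
  list(
    amp_std = function(m) amplitude_std(colMeans(m)),
    fourier_amp = function(m) fourier_trial_metrics(colMeans(m))$amplitude,
    fourier_phase = function(m) fourier_trial_metrics(colMeans(m))$phase,
    tp_var = function(m) timepoint_variability(m)$mean,
    amp_var = function(m) amplitude_variability(m),
    temp_var = function(m) suppressWarnings(temporal_variability(m)))
}

#' Run the full analysis pipeline on synthetic data
#'
#' Simulates `n_participants` sessions with the default reward structure
#' (high reward: higher mean amplitude, lower temporal jitter), preprocesses
#' them, computes the amplitude/latency and variability measures per
#' condition, and (per stage toggles) runs group permutation tests, the
#' physiological analyses, and the pupil analyses.
#'
#' @param cfg a [pipeline_config()].
#' @return object of class `pipeline_report`: `measures` (long data.frame,
#'   participant x condition x measure), `perm` (statistic, observed
#'   difference, p), optional `physio` and `pupil` tables, and `provenance`.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  stopifnot(inherits(cfg, "pipeline_config"))
  seeds <- derive_seeds(cfg$seed, cfg$n_participants, "simulate")
  protocol <- protocol_config(runs_per_condition = cfg$runs_per_condition,
                              n_participants = cfg$n_participants)
  stats_fns <- pipeline_statistics()
  measures <- list(); perm_data <- list(); physio_rows <- list()
  for (i in seq_len(cfg$n_participants)) {
    ses <- generate_session(protocol,
                            voxel_meta = default_voxel_meta(cfg$n_voxels),
                            physio = isTRUE(cfg$stages$physio),
                            seed = seeds[i])
    pp <- preprocess_session(ses)
    tms <- list(high = condition_trials(pp, "high"),
                low = condition_trials(pp, "low"))
    for (cond in names(tms)) {
      tm <- tms[[cond]]
      mt <- trial_average(tm)
      vs <- suppressWarnings(variability_summary(tm))
      fo <- fourier_trial_metrics(mt)
      measures[[length(measures) + 1L]] <- data.frame(
        participant = i, condition = cond,
        amp_std = amplitude_std(mt), fourier_amp = fo$amplitude,
        fourier_phase = fo$phase, tp_var = vs$timepoint_var_mean,
        amp_var = vs$amp_var, temp_var = vs$temporal_var)
    }
    both <- rbind(tms$high, tms$low)
    perm_data[[i]] <- list(values = both,
                           labels = rep(c("high", "low"),
                                        c(nrow(tms$high), nrow(tms$low))))
    if (isTRUE(cfg$stages$physio)) {
      hr_means <- vapply(c("high", "low"), function(cond) {
        sel <- which(vapply(pp$runs, function(r) r$condition == cond, logical(1)))
        mean(vapply(sel, function(r) {
          hr_trial_response(instantaneous_hr(pp$physio[[r]]$peak_times),
                            protocol)$mean_rate
        }, numeric(1)))
      }, numeric(1))
      kern <- session_pulse_kernel(pp)
      physio_rows[[i]] <- data.frame(participant = i,
                                     hr_high_bpm = hr_means[["high"]],
                                     hr_low_bpm = hr_means[["low"]],
                                     kernel_amplitude = kern$amplitude)
    }
  }
  report <- list(measures = do.call(rbind, measures))
  if (isTRUE(cfg$stages$permtest)) {
    pseeds <- derive_seeds(cfg$seed, length(stats_fns), "permtest")
    rows <- Map(function(name, fn, s) {
      pr <- suppressWarnings(group_permutation_test(
        perm_data, fn, n_perm = cfg$n_perm, sidedness = "two", seed = s))
      data.frame(statistic = name, observed_diff = pr$observed_diff, p = pr$p)
    }, names(stats_fns), stats_fns, as.list(pseeds))
    report$perm <- do.call(rbind, unname(rows))
  }
  if (isTRUE(cfg$stages$physio))
    report$physio <- do.call(rbind, physio_rows)
  if (isTRUE(cfg$stages$pupil)) {
    pup_seed <- derive_seeds(cfg$seed, 1, "pupil")
    pup <- generate_pupil_session(n_trials = cfg$pupil_trials, seed = pup_seed)
    report$pupil <- pupil_condition_summary(pup)
  }
  report$provenance <- list(seed = cfg$seed, config = unclass(cfg),
                            package_version = as.character(utils::packageVersion("taskbold")))
  class(report) <- "pipeline_report"
  if (!is.null(cfg$out)) {
    dir.create(cfg$out, recursive = TRUE, showWarnings = FALSE)
    for (nm in intersect(names(report), c("measures", "perm", "physio", "pupil")))
      utils::write.table(report[[nm]], file.path(cfg$out, paste0(nm, ".tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("taskbold pipeline report\n")
  agg <- stats::aggregate(cbind(amp_std, tp_var, amp_var, temp_var) ~ condition,
                          data = x$measures, FUN = mean)
  cat("\nGroup means by condition:\n")
  print(agg, row.names = FALSE)
  if (!is.null(x$perm)) {
    cat("\nPermutation tests (two-sided, high - low):\n")
    print(x$perm, row.names = FALSE)
  }
  if (!is.null(x$pupil)) {
    cat("\nPupil summaries:\n")
    print(x$pupil, row.names = FALSE)
  }
  invisible(x)
}
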