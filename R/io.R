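#' Write a session bundle to disk
#'
#' One directory per session: each run's voxel x volume matrix as a flat
#' little-endian float64 binary file with a sidecar text header (shape,
#' dtype, TR, condition); voxel metadata and trial ground truth as
#' tab-separated tables; per-run physiology as tab-separated
#' `(time_s, value)` following the BIDS physio convention plus a peak-event
#' list; pupil traces (when present) as `(time_s, pupil, blink_flag)`.
#'
#' @param session a `taskbold_session`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_mat <- function(m, base, condition) {
    con <- file(paste0(base, ".bin"), "wb")
    writeBin(as.numeric(t(m)), con, size = 8, endian = "little")
    close(con)
    writeLines(c(
      sprintf("shape\t%d\t%d", nrow(m), ncol(m)),
      "dtype\tfloat64_le",
      sprintf("tr_s\t%g", session$protocol$tr),
      sprintf("condition\t%s", condition)),
      paste0(base, ".hdr"))
  }
  for (r in seq_along(session$runs)) {
    run <- session$runs[[r]]
    base <- file.path(dir, sprintf("run%02d", r))
    write_mat(run$data, paste0(base, "_bold"), run$condition)
    if (!is.null(run$background))
      write_mat(run$background, paste0(base, "_background"), run$condition)
    ph <- session$physio[[r]]
    if (!is.null(ph)) {
      utils::write.table(
        data.frame(peak_time_s = ph$peak_times),
        paste0(base, "_pulse_peaks.tsv"),
        sep = "\t", row.names = FALSE, quote = FALSE)
    }
  }
  utils::write.table(session$voxel_meta, file.path(dir, "voxel_meta.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(session$ground_truth$trials,
                     file.path(dir, "ground_truth_trials.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  proto <- session$protocol
  writeLines(jsonlite::toJSON(proto[!vapply(proto, is.null, logical(1))],
                              auto_unbox = TRUE),
             file.path(dir, "protocol.json"))
  invisible(dir)
}

#' Read a session bundle written by [write_session()]
#'
#' Restores run matrices, conditions, voxel metadata, trial ground truth, and
#' pulse peak times. Generator-internal ground truth (templates, injected
#' kernels) is not serialized.
#'
#' @param dir bundle directory.
#' @return a `taskbold_session`.
#' @export
read_session <- function(dir) {
  proto <- jsonlite::fromJSON(file.path(dir, "protocol.json"))
  protocol <- protocol_config(tr = proto$tr, trial_len = proto$trial_len,
                              trials_per_run = proto$trials_per_run,
                              runs_per_condition = proto$runs_per_condition,
                              n_participants = proto$n_participants,
                              fine_dt = proto$fine_dt)
  read_mat <- function(base) {
    fields <- strsplit(readLines(paste0(base, ".hdr")), "\t")
    names(fields) <- vapply(fields, `[`, "", 1)
    shp <- as.integer(fields$shape[2:3])
    con <- file(paste0(base, ".bin"), "rb")
    vals <- readBin(con, numeric(), n = prod(shp), size = 8, endian = "little")
    close(con)
    list(data = matrix(vals, nrow = shp[1], byrow = TRUE),
         condition = fields$condition[2])
  }
  hdrs <- sort(list.files(dir, pattern = "_bold\\.hdr$", full.names = TRUE))
  runs <- list(); physio <- list()
  for (i in seq_along(hdrs)) {
    base <- sub("\\.hdr$", "", hdrs[i])
    m <- read_mat(base)
    bg_base <- sub("_bold$", "_background", base)
    bg <- if (file.exists(paste0(bg_base, ".hdr"))) read_mat(bg_base)$data
          else NULL
    runs[[i]] <- list(data = m$data, background = bg, condition = m$condition)
    pkf <- paste0(sub("_bold$", "", base), "_pulse_peaks.tsv")
    physio[i] <- if (file.exists(pkf))
      list(list(peak_times = utils::read.delim(pkf)$peak_time_s, hr_fs = 50))
    else list(NULL)
  }
  vm <- utils::read.delim(file.path(dir, "voxel_meta.tsv"),
                          stringsAsFactors = FALSE)
  gtf <- file.path(dir, "ground_truth_trials.tsv")
  gt <- if (file.exists(gtf)) utils::read.delim(gtf) else NULL
  structure(list(runs = runs, voxel_meta = vm, physio = physio,
                 ground_truth = list(trials = gt), protocol = protocol),
            class = "taskbold_session")
}

#' Write a pupil trace as tab-separated text
#'
#' @param trace a `pupil_trace`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pupil_trace <- function(trace, path) {
  utils::write.table(
    data.frame(time_s = trace$time_s, pupil = trace$pupil,
               blink_flag = as.integer(trace$blink)),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a tab-separated pupil trace
#'
#' @param path file with columns `time_s`, `pupil`, `blink_flag`.
#' @param trial_onsets_s trial onset times (s), not stored in the sample file.
#' @return a `pupil_trace`.
#' @export
read_pupil_trace <- function(path, trial_onsets_s = numeric(0)) {
  d <- utils::read.delim(path)
  fs <- 1 / stats::median(diff(d$time_s))
  structure(list(time_s = d$time_s, pupil = d$pupil,
                 blink = d$blink_flag > 0, trial_onsets_s = trial_onsets_s,
                 fs = round(fs)),
            class = "pupil_trace")
}

#' Convert an event-list blink table to a per-sample mask
#'
#' @param trace a `pupil_trace` (its `blink` field is replaced).
#' @param events data.frame with `start_s` and `end_s` columns.
#' @return the trace with the rebuilt blink mask.
#' @export
apply_blink_events <- function(trace, events) {
  blink <- logical(length(trace$time_s))
  for (i in seq_len(nrow(events)))
    blink <- blink | (trace$time_s >= events$start_s[i] &
                        trace$time_s <= events$end_s[i])
  trace$blink <- blink
  trace
}
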