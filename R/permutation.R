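#' Group-level label-permutation test
#'
#' For each participant the reward labels are shuffled across trials, the
#' statistic is recomputed per condition, and the high minus low differences
#' are averaged across participants; repeating this `n_perm` times builds the
#' null distribution of group-mean differences. The one-sided p-value is the
#' fraction of permutations with a null difference at least as large as the
#' observed one ("greater"); the two-sided p-value doubles the smaller tail
#' fraction, capped at 1. The raw fraction is floored at `1/n_perm`, the
#' minimum reportable p. An add-one correction `(b+1)/(n+1)` is available by
#' flag but off by default.
#'
#' @param data list of participants; each a list with `values` (trial-level
#'   numeric vector, or a trials x timepoints matrix) and `labels`
#'   (`"high"`/`"low"` per trial; both labels must be present).
#' @param statistic function mapping the values of one condition's trials
#'   (vector, or matrix with trials in rows) to a scalar.
#' @param n_perm number of permutations (values below 100 trigger a warning).
#' @param sidedness `"one"` (greater) or `"two"`.
#' @param add_one use the `(b+1)/(n+1)` estimator instead of the plain
#'   fraction.
#' @param seed optional integer seed.
#' @return object of class `perm_result`: `observed_diff`, `null_diffs`,
#'   `p`, `sidedness`, `n_perm`.
#' @export
group_permutation_test <- function(data, statistic, n_perm = 10000,
                                   sidedness = c("one", "two"),
                                   add_one = FALSE, seed = NULL) {
  sidedness <- match.arg(sidedness)
  n_perm <- as.integer(n_perm)
  if (n_perm < 100) warning("n_perm < 100 gives a very coarse p-value")
  if (!is.null(seed)) set.seed(seed)
  subset_vals <- function(v, keep) {
    if (is.null(dim(v))) v[keep] else v[keep, , drop = FALSE]
  }
  part_diff <- function(v, labels, who) {
    s_hi <- statistic(subset_vals(v, labels == "high"))
    s_lo <- statistic(subset_vals(v, labels == "low"))
    if (!is.finite(s_hi) || !is.finite(s_lo))
      stop("statistic returned a non-finite value for participant ", who)
    s_hi - s_lo
  }
  for (i in seq_along(data)) {
    lab <- data[[i]]$labels
    if (!all(c("high", "low") %in% lab))
      stop("participant ", i, " is missing one of the condition labels")
  }
  observed <- mean(vapply(seq_along(data), function(i)
    part_diff(data[[i]]$values, data[[i]]$labels, i), numeric(1)))
  null_diffs <- vapply(seq_len(n_perm), function(p) {
    mean(vapply(seq_along(data), function(i) {
      lab <- sample(data[[i]]$labels)
      part_diff(data[[i]]$values, lab, i)
    }, numeric(1)))
  }, numeric(1))
  frac <- function(b) {
    if (add_one) (b + 1) / (n_perm + 1) else max(b / n_perm, 1 / n_perm)
  }
  p_greater <- frac(sum(null_diffs >= observed))
  if (sidedness == "one") {
    p <- p_greater
  } else {
    p_less <- frac(sum(null_diffs <= observed))
    p <- min(1, 2 * min(p_greater, p_less))
  }
  structure(list(observed_diff = observed, null_diffs = null_diffs, p = p,
                 sidedness = sidedness, n_perm = n_perm, add_one = add_one),
            class = "perm_result")
}

#' @export
print.perm_result <- function(x, ...) {
  cat(sprintf("Group permutation test (%s-sided, %d permutations)\n",
              x$sidedness, x$n_perm))
  cat(sprintf("  observed high-low difference: %.6g\n", x$observed_diff))
  cat(sprintf("  p = %.4g\n", x$p))
  invisible(x)
}

#' Paired t test convenience wrapper
#'
#' Off-the-shelf paired comparison of per-participant condition means (used
#' for behavioral accuracy in the original protocol); provided for
#' completeness, the permutation test is the primary inference tool.
#'
#' @param high,low per-participant paired values.
#' @return the `htest` object from [stats::t.test()].
#' @export
paired_t_test <- function(high, low) stats::t.test(high, low, paired = TRUE)
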