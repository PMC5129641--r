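# Trapezoidal rule on an irregular grid.
trapezoid <- function(t, y) {
  sum(diff(t) * (head(y, -1) + tail(y, -1)) / 2)
}

#' Trapezoidal AUC of a VAS time course
#'
#' Reduces one subject-period-outcome series to its area under the curve
#' over the full 0-7 h span by the trapezoidal rule, including the baseline
#' point at t = 0 as the first node. No baseline subtraction is applied
#' here: baseline adjustment happens once, as the ANCOVA covariate.
#'
#' @param times Times in hours, strictly increasing, starting at 0. Checked
#'   against `grid` (default the 11-point measurement grid); a series with
#'   missing timepoints is an error — no silent interpolation. Pass
#'   `grid = NULL` to accept any valid grid.
#' @param scores Scores in mm, in \[0, 100\].
#' @param grid Expected measurement grid, or `NULL`.
#' @return AUC in mm*hr (0 to 700 on the canonical grid).
#' @export
#' @examples
#' compute_auc(vas_time_grid(), rep(100, 11)) # 700
compute_auc <- function(times, scores, grid = vas_time_grid()) {
  stopifnot(is.numeric(times), is.numeric(scores),
            length(times) == length(scores))
  if (length(times) < 2 || any(diff(times) <= 0) || times[1] != 0) {
    stop("`times` must be strictly increasing and start at 0.", call. = FALSE)
  }
  if (!is.null(grid) && !isTRUE(all.equal(times, grid))) {
    stop("Series does not match the measurement grid; missing or extra ",
         "timepoints are not interpolated.", call. = FALSE)
  }
  if (anyNA(scores) || any(scores < 0 | scores > 100)) {
    stop("`scores` must lie in [0, 100] with no missing values.",
         call. = FALSE)
  }
  trapezoid(times, scores)
}

#' Count binary symptom reports
#'
#' Counts the post-baseline timepoints (t > 0) at which the score reaches
#' `threshold`, emulating the trial's secondary binary-scale outcome (number
#' of times a symptom was reported over the 10 post-dose assessments).
#'
#' @inheritParams compute_auc
#' @param threshold Threshold in mm (>= 0).
#' @return Integer count in 0..(number of post-baseline points).
#' @export
binarize <- function(times, scores, threshold = 5) {
  stopifnot(length(times) == length(scores), threshold >= 0)
  sum(scores[times > 0] >= threshold)
}

#' Reduce a long trial table to per-subject-period outcome records
#'
#' Collapses each subject-period-outcome VAS series to one record carrying
#' the baseline score (t = 0), the trapezoidal AUC, and the binary report
#' count. Subjects lacking a complete crossover (both periods, full
#' 11-point series for every outcome present) are excluded from the output
#' and reported via a message and the `"excluded_subjects"` attribute,
#' mirroring the exclusion of participants lost to crossover.
#'
#' @param trial A long trial table ([simulate_trial()] or
#'   [read_trial_table()]).
#' @param binary_threshold Threshold in mm for [binarize()]; defaults to the
#'   simulating parameters' threshold when present, else 5.
#' @return A tibble of records: `subject`, `group`, `period`, `received`,
#'   `told`, `outcome`, `baseline_mm`, `auc_mm_hr`, `binary_count`.
#' @export
#' @examples
#' trial <- simulate_trial(generative_params(), n_per_group = 2, seed = 1)
#' reduce_trial(trial)
reduce_trial <- function(trial, binary_threshold = NULL) {
  if (is.null(binary_threshold)) {
    p <- attr(trial, "params")
    binary_threshold <- if (!is.null(p)) p$binary_threshold else 5
  }
  cols <- c("subject", "group", "period", "received", "told", "outcome",
            "time_h", "score_mm")
  if (!all(cols %in% names(trial))) {
    stop("Trial table must have columns: ", paste(cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(trial) == 0) {
    warning("Empty trial table; returning zero records.", call. = FALSE)
    return(tibble::tibble(
      subject = integer(), group = integer(), period = integer(),
      received = character(), told = character(), outcome = character(),
      baseline_mm = numeric(), auc_mm_hr = numeric(), binary_count = integer()
    ))
  }
  key <- paste(trial$subject, trial$period, trial$outcome, trial$time_h)
  if (anyDuplicated(key)) {
    stop("Duplicate (subject, period, outcome, time_h) rows in trial table.",
         call. = FALSE)
  }

  grid <- vas_time_grid()
  n_t <- length(grid)
  trial <- dplyr::arrange(trial, .data$outcome, .data$subject, .data$period,
                          .data$time_h)
  # contiguous (outcome, subject, period) runs after sorting
  id <- paste(trial$outcome, trial$subject, trial$period, sep = "\r")
  n <- length(id)
  first <- c(TRUE, id[-1] != id[-n])
  grp <- cumsum(first)
  ng <- grp[n]
  sizes <- tabulate(grp, nbins = ng)
  if (any(sizes != n_t) ||
      !isTRUE(all.equal(trial$time_h, rep(grid, ng)))) {
    per_grp_ok <- sizes == n_t
    if (all(per_grp_ok)) {
      match_grid <- trial$time_h == rep(grid, ng)
      per_grp_ok <- as.vector(rowsum(as.numeric(match_grid), grp)) == n_t
    }
    bad <- unique(trial$subject[first][!per_grp_ok])
    stop("Incomplete VAS series (missing timepoints) for subject(s): ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  }
  scores <- matrix(trial$score_mm, nrow = n_t)
  d <- diff(grid)
  w <- c(d / 2, 0) + c(0, d / 2)  # trapezoid weights
  recs <- tibble::tibble(
    outcome = trial$outcome[first],
    subject = trial$subject[first],
    group = trial$group[first],
    period = trial$period[first],
    received = trial$received[first],
    told = trial$told[first],
    baseline_mm = scores[1, ],
    auc_mm_hr = as.vector(w %*% scores),
    binary_count = as.integer(
      colSums(scores[-1, , drop = FALSE] >= binary_threshold)
    )
  )

  # a complete crossover = both periods present for every simulated outcome
  n_outcomes <- length(unique(recs$outcome))
  per_subj <- dplyr::count(recs, .data$subject)
  incomplete <- per_subj$subject[per_subj$n < 2L * n_outcomes]
  if (length(incomplete)) {
    message(length(incomplete),
            " subject(s) without a complete crossover excluded: ",
            paste(utils::head(incomplete, 10), collapse = ", "),
            if (length(incomplete) > 10) ", ..." else "")
    recs <- recs[!recs$subject %in% incomplete, ]
  }
  out <- dplyr::select(
    dplyr::arrange(recs, .data$outcome, .data$subject, .data$period),
    "subject", "group", "period", "received", "told", "outcome",
    "baseline_mm", "auc_mm_hr", "binary_count"
  )
  attr(out, "excluded_subjects") <- incomplete
  attr(out, "binary_threshold") <- binary_threshold
  out
}
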