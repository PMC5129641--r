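#' Read / write a long-format trial table
#'
#' The interchange format is a tidy CSV with one row per
#' subject-period-outcome-timepoint and header
#' `subject,group,period,received,told,outcome,time_h,score_mm`.
#' `received` is `"H"` or `"P"`; `told` is `"H"`, `"P"`, or `"U"`; `period`
#' is 1 or 2; `score_mm` lies in \[0, 100\]. Reading validates the schema
#' and reports offending row numbers; duplicate
#' (subject, period, outcome, time_h) keys are an error.
#'
#' @param path CSV file path.
#' @param trial A long trial table (e.g. from [simulate_trial()]).
#' @return `read_trial_table()` returns a validated tibble;
#'   `write_trial_table()` returns `path` invisibly.
#' @export
read_trial_table <- function(path) {
  cols <- c("subject", "group", "period", "received", "told", "outcome",
            "time_h", "score_mm")
  tbl <- readr::read_csv(path, col_types = readr::cols(
    subject = readr::col_integer(),
    group = readr::col_integer(),
    period = readr::col_integer(),
    received = readr::col_character(),
    told = readr::col_character(),
    outcome = readr::col_character(),
    time_h = readr::col_double(),
    score_mm = readr::col_double()
  ))
  missing_cols <- setdiff(cols, names(tbl))
  if (length(missing_cols)) {
    stop("Missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  validate_trial_table(tbl)
  tbl
}

#' @rdname read_trial_table
#' @export
write_trial_table <- function(trial, path) {
  cols <- c("subject", "group", "period", "received", "told", "outcome",
            "time_h", "score_mm")
  stopifnot(all(cols %in% names(trial)))
  readr::write_csv(trial[cols], path)
  invisible(path)
}

#' @keywords internal
validate_trial_table <- function(tbl) {
  fail <- function(what, rows) {
    stop(what, " in row(s): ",
         paste(utils::head(rows, 10), collapse = ", "),
         if (length(rows) > 10) ", ..." else "", call. = FALSE)
  }
  bad <- which(is.na(tbl$score_mm) | tbl$score_mm < 0 | tbl$score_mm > 100)
  if (length(bad)) fail("score_mm outside [0, 100]", bad)
  bad <- which(!tbl$received %in% received_levels())
  if (length(bad)) fail("Unknown `received` label", bad)
  bad <- which(!tbl$told %in% told_levels())
  if (length(bad)) fail("Unknown `told` label", bad)
  bad <- which(!tbl$period %in% c(1L, 2L))
  if (length(bad)) fail("`period` must be 1 or 2", bad)
  bad <- which(tbl$told == "U" & tbl$group != 3L)
  if (length(bad)) fail("told = \"U\" occurs only in group 3", bad)
  key <- paste(tbl$subject, tbl$period, tbl$outcome, tbl$time_h)
  bad <- which(duplicated(key))
  if (length(bad)) fail("Duplicate (subject, period, outcome, time_h) key", bad)
  invisible(tbl)
}

#' Run the full decomposition pipeline on one simulated trial
#'
#' Convenience orchestration: simulate a trial ([simulate_trial()]), reduce
#' it to outcome records ([reduce_trial()]), estimate the six effects per
#' outcome ([estimate_all()]), and complete the decomposition
#' ([decompose_effects()]). The resolved configuration (parameters, sample
#' size, dropout, seed) is attached as attribute `"config"` so a report can
#' be regenerated exactly.
#'
#' @inheritParams simulate_trial
#' @return A `bp_decomposition` (see [decompose_effects()]) with the
#'   records available as attribute `"records"`.
#' @export
#' @examples
#' rep <- run_report(n_per_group = 24, seed = 7)
#' rep$metrics
run_report <- function(params = generative_params(), n_per_group = 160,
                       dropout = 0, seed = 1, outcomes = NULL) {
  trial <- simulate_trial(params, n_per_group = n_per_group,
                          dropout = dropout, seed = seed, outcomes = outcomes)
  recs <- reduce_trial(trial)
  eff <- estimate_all(recs)
  out <- decompose_effects(eff)
  attr(out, "records") <- recs
  attr(out, "config") <- list(
    n_per_group = n_per_group, dropout = dropout, seed = seed,
    outcomes = outcomes %||% params$effects$outcome,
    lambda = params$lambda, sigma_subject = params$sigma_subject,
    sigma_resid = params$sigma_resid,
    binary_threshold = params$binary_threshold,
    effects = as.data.frame(params$effects)
  )
  out
}

#' Write a decomposition report to a directory
#'
#' Writes `effects.csv`, `comparisons.csv`, `metrics.csv` and, when the
#' report carries a resolved configuration, `config.json` — enough to
#' regenerate the report exactly.
#'
#' @param report A `bp_decomposition`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "bp_decomposition"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(report$effects, file.path(dir, "effects.csv"))
  readr::write_csv(report$comparisons, file.path(dir, "comparisons.csv"))
  readr::write_csv(report$metrics, file.path(dir, "metrics.csv"))
  cfg <- attr(report, "config")
  if (!is.null(cfg)) {
    jsonlite::write_json(cfg, file.path(dir, "config.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(dir)
}
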