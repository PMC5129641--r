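#' Experimental conditions of the hybrid balanced-placebo design
#'
#' A condition is a (received, told) pair: what a participant actually
#' receives (`"H"` = hydroxyzine/active drug, `"P"` = placebo) crossed with
#' what they are told they receive (`"H"`, `"P"`, or `"U"` = unknown, i.e.
#' a 50/50 chance of either). The hybrid design uses exactly six cells:
#' the four balanced-placebo cells H/H, H/P, P/H, P/P plus the two
#' conventional randomized placebo-controlled (RPCT) cells H/U and P/U.
#' The "told unknown" cells occur only in group 3.
#'
#' @return A tibble with columns `received`, `told`, `condition` (the
#'   `"received/told"` label) and `group` (the randomization group in which
#'   the cell occurs).
#' @export
#' @examples
#' trial_conditions()
trial_conditions <- function() {
  tibble::tibble(
    received = c("H", "H", "P", "P", "H", "P"),
    told     = c("H", "P", "H", "P", "U", "U"),
    group    = c(1L, 1L, 2L, 2L, 3L, 3L)
  ) |>
    dplyr::mutate(condition = condition_label(.data$received, .data$told)) |>
    dplyr::select("received", "told", "condition", "group")
}

#' @keywords internal
condition_label <- function(received, told) paste(received, told, sep = "/")

#' Canonical condition factor levels, reference cell (P/P) first.
#' @keywords internal
condition_levels <- function() c("P/P", "H/H", "H/P", "P/H", "H/U", "P/U")

received_levels <- function() c("H", "P")
told_levels <- function() c("H", "P", "U")

#' Enumerate the six crossover assignments
#'
#' Each randomization slot is one of six two-period crossover assignments:
#' group 1 receives drug in both periods and is told drug in one period and
#' placebo in the other (both period orders); group 2 receives placebo in
#' both periods with the same told crossover; group 3 receives drug in one
#' period and placebo in the other, told "unknown" both times. Within an
#' assignment the two periods therefore differ only in `told` (groups 1-2)
#' or only in `received` (group 3).
#'
#' @return A tibble with one row per assignment and columns `assignment`
#'   (1-6), `group`, `period1_received`, `period1_told`, `period2_received`,
#'   `period2_told`.
#' @export
#' @examples
#' enumerate_assignments()
enumerate_assignments <- function() {
  tibble::tibble(
    assignment       = 1:6,
    group            = c(1L, 1L, 2L, 2L, 3L, 3L),
    period1_received = c("H", "H", "P", "P", "H", "P"),
    period1_told     = c("H", "P", "P", "H", "U", "U"),
    period2_received = c("H", "H", "P", "P", "P", "H"),
    period2_told     = c("P", "H", "H", "P", "U", "U")
  )
}

#' Generate a block-randomization schedule
#'
#' Allocates `n_slots` participants to the six crossover assignments in
#' permuted blocks. Each complete block contains every assignment the same
#' number of times, so for any prefix of whole blocks the assignment counts
#' are balanced; a trailing partial block is a random subset of a permuted
#' block. The schedule is deterministic given `seed`.
#'
#' @param n_slots Number of participants (slots) to randomize.
#' @param block_size Block size; must be a positive multiple of 6 so that a
#'   block holds whole sets of the six assignments. Default 6.
#' @param seed Integer seed for the block permutations.
#' @return A tibble with one row per slot: `slot`, `assignment`, `group`,
#'   `period1_received`, `period1_told`, `period2_received`, `period2_told`;
#'   `block_size` and `seed` are attached as attributes.
#' @export
#' @examples
#' sched <- generate_schedule(12, block_size = 6, seed = 1)
#' table(sched$assignment)
generate_schedule <- function(n_slots, block_size = 6, seed = 1) {
  if (!is.numeric(n_slots) || length(n_slots) != 1 || is.na(n_slots) ||
      n_slots < 1 || n_slots != as.integer(n_slots)) {
    stop("`n_slots` must be a positive integer.", call. = FALSE)
  }
  if (!is.numeric(block_size) || length(block_size) != 1 ||
      is.na(block_size) || block_size < 6 || block_size %% 6 != 0) {
    stop("`block_size` must be a positive multiple of 6.", call. = FALSE)
  }
  n_slots <- as.integer(n_slots)
  block_size <- as.integer(block_size)

  n_blocks <- ceiling(n_slots / block_size)
  base_block <- rep(1:6, each = block_size %/% 6L)
  order <- withr::with_seed(seed, {
    unlist(lapply(seq_len(n_blocks), function(b) sample(base_block)))
  })
  order <- order[seq_len(n_slots)]

  assignments <- enumerate_assignments()
  sched <- assignments[order, ]
  sched <- dplyr::mutate(sched, slot = dplyr::row_number(), .before = 1)
  attr(sched, "block_size") <- block_size
  attr(sched, "seed") <- seed
  sched
}

#' Write / read a randomization schedule as CSV
#'
#' @param schedule A schedule tibble from [generate_schedule()].
#' @param path File path.
#' @return `read_schedule()` returns the schedule tibble; `write_schedule()`
#'   returns `path` invisibly.
#' @export
write_schedule <- function(schedule, path) {
  cols <- c("slot", "group", "period1_received", "period1_told",
            "period2_received", "period2_told")
  stopifnot(all(cols %in% names(schedule)))
  readr::write_csv(schedule[cols], path)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  sched <- readr::read_csv(path, col_types = readr::cols(
    slot = readr::col_integer(),
    group = readr::col_integer(),
    period1_received = readr::col_character(),
    period1_told = readr::col_character(),
    period2_received = readr::col_character(),
    period2_told = readr::col_character()
  ))
  bad <- !(sched$period1_received %in% received_levels()) |
    !(sched$period2_received %in% received_levels()) |
    !(sched$period1_told %in% told_levels()) |
    !(sched$period2_told %in% told_levels())
  if (any(bad)) {
    stop("Invalid condition labels in schedule rows: ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  }
  sched
}
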