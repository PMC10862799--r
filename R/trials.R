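# Trial-table interchange: one row per trial, comma-separated, fixed header,
# seconds as decimal floats, missing values as empty cells.

trial_columns <- c("participant", "phase", "session", "trial_index",
                   "coherence", "correct_side", "has_deadline", "deadline_s",
                   "choice", "rt_s", "outcome", "points_delta")

#' Validate a trial table
#'
#' Checks the per-row invariants of a trial record table: completed trials
#' (outcome `correct`/`error`) must carry a choice and a reaction time in
#' (0, 5] s; cancelled trials must carry a deadline and no reaction time; the
#' points delta must be +1 for correct, -1 for error and 0 otherwise; and the
#' enum columns must hold legal values.
#'
#' @param trials A data frame with the trial-table columns.
#' @param line_offset Added to row indices when reporting offending rows
#'   (use 1 so that reported numbers are file line numbers under a header).
#' @return The validated data frame, invisibly. Errors describe all offending
#'   rows.
#' @export
validate_trials <- function(trials, line_offset = 0) {
  missing_cols <- setdiff(trial_columns, names(trials))
  if (length(missing_cols))
    stop("trial table schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  bad <- function(cond) which(cond %in% TRUE)
  problems <- list(
    "phase not in {I, II, III}" = bad(!trials$phase %in% c("I", "II", "III")),
    "session < 1" = bad(!(trials$session >= 1)),
    "trial_index < 1" = bad(!(trials$trial_index >= 1)),
    "|coherence| > 0.512" = bad(!(abs(trials$coherence) <= 0.512)),
    "correct_side not in {left, right}" =
      bad(!trials$correct_side %in% c("left", "right")),
    "outcome not in {correct, error, canceled, aborted}" =
      bad(!trials$outcome %in% c("correct", "error", "canceled", "aborted")),
    "choice not in {left, right, none}" =
      bad(!(trials$choice %in% c("left", "right", "none") | is.na(trials$choice))),
    "completed trial without choice" =
      bad(trials$outcome %in% c("correct", "error") &
            !trials$choice %in% c("left", "right")),
    "completed trial without rt_s in (0, 5]" =
      bad(trials$outcome %in% c("correct", "error") &
            !(!is.na(trials$rt_s) & trials$rt_s > 0 & trials$rt_s <= 5)),
    "canceled trial without deadline" =
      bad(trials$outcome == "canceled" & !(trials$has_deadline %in% TRUE)),
    "canceled trial with rt_s present" =
      bad(trials$outcome == "canceled" & !is.na(trials$rt_s)),
    "points_delta inconsistent with outcome" =
      bad(trials$points_delta !=
            ifelse(trials$outcome == "correct", 1L,
                   ifelse(trials$outcome == "error", -1L, 0L)))
  )
  problems <- problems[vapply(problems, length, 1L) > 0]
  if (length(problems)) {
    msg <- vapply(seq_along(problems), function(i) {
      rows <- problems[[i]] + line_offset
      sprintf("%s (row%s %s)", names(problems)[i],
              if (length(rows) > 1) "s" else "",
              paste(head(rows, 10), collapse = ", "))
    }, "")
    stop("trial table validation error:\n  ", paste(msg, collapse = "\n  "))
  }
  invisible(trials)
}

#' Read a trial table from CSV
#'
#' @param path Path to a comma-separated trial table with the fixed header
#'   written by [write_trials()]. Empty cells are missing values.
#' @return A validated data frame of trial records.
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop("trial file not found: ", path)
  header <- strsplit(readLines(path, n = 1), ",", fixed = TRUE)[[1]]
  missing_cols <- setdiff(trial_columns, header)
  if (length(missing_cols))
    stop("trial table schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  df <- read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                 colClasses = c(participant = "character", phase = "character",
                                correct_side = "character",
                                choice = "character", outcome = "character"))
  df <- df[trial_columns]
  df$has_deadline <- as.logical(df$has_deadline)
  validate_trials(df, line_offset = 1)
  df
}

#' Write a trial table to CSV
#'
#' Columns are written in a fixed order; missing values become empty cells
#' (never `"0"`), so that [read_trials()] recovers the records exactly.
#'
#' @param trials A valid data frame of trial records.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  if (nrow(trials) > 0) validate_trials(trials)
  missing_cols <- setdiff(trial_columns, names(trials))
  if (length(missing_cols))
    stop("trial table schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  ok <- tryCatch({
    write.csv(trials[trial_columns], path, row.names = FALSE, na = "",
              quote = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("could not write trial table to ", path, ": ",
                        conditionMessage(ok))
  invisible(path)
}

#' Completed standard trials
#'
#' Keeps completed (correct or error) trials without a provisional deadline,
#' preserving order. Deadline trials are excluded from all model fits because
#' the deadline truncates their reaction times; aborted and cancelled trials
#' carry no decision.
#'
#' @param trials A data frame of trial records.
#' @return The filtered data frame.
#' @export
filter_standard_trials <- function(trials) {
  keep <- trials$outcome %in% c("correct", "error") & !(trials$has_deadline %in% TRUE)
  trials[keep, , drop = FALSE]
}
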