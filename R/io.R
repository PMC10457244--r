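#' Construct a force-plate recording
#'
#' A recording holds uniformly sampled force (`fx`, `fy`, `fz`, in N), moment
#' (`mx`, `my`, `mz`, in N·m) and binary trigger channels (`trig_*`) plus a
#' time column in seconds. The sample rate is implied by the time step and
#' validated on construction.
#'
#' @param data A data frame with columns `time`, `fx`, `fy`, `fz`, `mx`,
#'   `my`, `mz` and zero or more `trig_*` columns.
#' @param axis_map An [axis_map()] naming which moment channels control AP
#'   and ML sway.
#' @param block_id Optional block label.
#'
#' @return An object of class `fp_recording`: a list with elements `data`
#'   (tibble), `sample_rate` (Hz), `axis_map`, `block_id`.
#' @export
fp_recording <- function(data, axis_map = swaybins::axis_map(),
                         block_id = NA_character_) {
  data <- tibble::as_tibble(data)
  required <- c("time", "fx", "fy", "fz", "mx", "my", "mz")
  missing <- setdiff(required, names(data))
  if (length(missing) > 0) {
    stop("recording is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(names(data)) > 0) {
    stop("recording has duplicate column names", call. = FALSE)
  }
  extra <- setdiff(names(data), required)
  bad <- extra[!startsWith(extra, "trig_")]
  if (length(bad) > 0) {
    stop("unrecognised recording column(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(data) < 2) {
    stop("recording needs at least 2 samples to define a sample rate",
         call. = FALSE)
  }
  if (!all(vapply(data, function(col) all(is.finite(col)), logical(1)))) {
    stop("recording channels must be finite", call. = FALSE)
  }
  steps <- diff(data$time)
  if (any(steps <= 0)) {
    stop("time must be strictly increasing", call. = FALSE)
  }
  dt <- steps[1]
  if (any(abs(steps - dt) > 1e-9)) {
    stop("non-uniform sampling: time steps deviate by more than 1e-9 s",
         call. = FALSE)
  }
  sample_rate <- 1 / dt
  for (ch in c(axis_map$ap_control, axis_map$ml_control)) {
    if (!ch %in% names(data)) {
      stop("axis_map channel `", ch, "` not present in recording",
           call. = FALSE)
    }
  }
  structure(list(data = data, sample_rate = sample_rate,
                 axis_map = axis_map, block_id = block_id),
            class = "fp_recording")
}

#' @export
print.fp_recording <- function(x, ...) {
  cat(sprintf("<fp_recording> %d samples @ %g Hz (%.2f s), channels: %s\n",
              nrow(x$data), x$sample_rate,
              nrow(x$data) / x$sample_rate,
              paste(setdiff(names(x$data), "time"), collapse = ", ")))
  invisible(x)
}

#' Trigger channel names of a recording
#' @param rec An `fp_recording`.
#' @return Character vector of `trig_*` column names.
#' @export
trigger_channels <- function(rec) {
  stopifnot(inherits(rec, "fp_recording"))
  grep("^trig_", names(rec$data), value = TRUE)
}

#' Read / write a force-plate recording (TSV dialect)
#'
#' Recordings are stored as plain tab-separated text with a header row naming
#' the columns (`time`, `fx`, `fy`, `fz`, `mx`, `my`, `mz`, `trig_*`), `.` as
#' decimal separator, full double precision. The sample rate is inferred from
#' the time column.
#'
#' @param path File path.
#' @param axis_map An [axis_map()] validated against the columns.
#' @param block_id Optional block label attached to the recording.
#' @return `read_recording()` returns an `fp_recording`;
#'   `write_recording()` returns `path` invisibly.
#' @export
read_recording <- function(path, axis_map = swaybins::axis_map(),
                           block_id = NA_character_) {
  data <- utils::read.delim(path, check.names = FALSE)
  fp_recording(data, axis_map = axis_map, block_id = block_id)
}

#' @rdname read_recording
#' @param rec An `fp_recording`.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "fp_recording"))
  df <- as.data.frame(rec$data)
  # format() at 17 significant digits keeps the roundtrip bit-faithful
  for (nm in names(df)) df[[nm]] <- sprintf("%.17g", df[[nm]])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.trial_required_cols <- c(
  "participant", "block", "trial_index", "fixation_onset_s",
  "target_onset_s", "response_onset_s", "rt_ms", "congruency",
  "prev_congruency", "target_side", "response_side", "correct"
)
.trial_flag_cols <- c("error", "post_error", "slow_rt", "unresponsive",
                      "first_in_block")

#' Read / write a trial-event table (CSV)
#'
#' One row per trial, keyed by `(participant, block, trial_index)`, with
#' event times in seconds, condition codes, correctness, and logical
#' exclusion flags. Unknown condition codes are rejected.
#'
#' @param path File path.
#' @return `read_trial_table()` returns a tibble; `write_trial_table()`
#'   returns `path` invisibly.
#' @export
read_trial_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  missing <- setdiff(.trial_required_cols, names(df))
  if (length(missing) > 0) {
    stop("trial table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  check_codes <- function(col, allowed) {
    vals <- df[[col]][!is.na(df[[col]])]
    bad <- setdiff(unique(vals), allowed)
    if (length(bad) > 0) {
      stop(sprintf("unknown %s code(s): %s", col, paste(bad, collapse = ", ")),
           call. = FALSE)
    }
  }
  check_codes("congruency", .congruency_levels)
  check_codes("prev_congruency", c(.congruency_levels, "undefined"))
  check_codes("target_side", .side_levels)
  check_codes("response_side", c(.side_levels, "none"))
  df$correct <- as.logical(df$correct)
  for (fl in intersect(.trial_flag_cols, names(df))) {
    df[[fl]] <- as.logical(df[[fl]])
  }
  out <- tibble::as_tibble(df)
  dup <- out |>
    dplyr::count(.data$participant, .data$block, .data$trial_index) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop("duplicate (participant, block, trial_index) keys in trial table",
         call. = FALSE)
  }
  dplyr::arrange(out, .data$participant, .data$block, .data$trial_index)
}

#' @rdname read_trial_table
#' @param trials A trial tibble as produced by [segment_and_label()] or
#'   [sample_behavior()].
#' @export
write_trial_table <- function(trials, path) {
  df <- as.data.frame(trials)
  num <- vapply(df, is.double, logical(1))
  for (nm in names(df)[num]) df[[nm]] <- sprintf("%.17g", df[[nm]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}
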