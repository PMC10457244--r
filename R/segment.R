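#' Segment a recording into labelled trials
#'
#' Turns decoded trigger events into a trial table: one row per fixation
#' onset, with previous-trial congruency computed within the block (undefined
#' for the first trial, flagged `first_in_block`), the trial duration (from
#' fixation onset to the next fixation onset, or to the end of the nominal
#' trial envelope for the last trial), and sample indices delimiting the
#' trial segment in the recording.
#'
#' Correctness and response side are not carried by the trigger lines; they
#' are merged from `behavior` (the behavioural log of the experiment) by
#' `trial_index`. Without a behavioural table every responded trial is
#' assumed correct, with the response on the instructed side (the target side
#' on congruent trials, the opposite side on incongruent trials).
#'
#' @param rec An [fp_recording()].
#' @param events Decoded events from [decode_trigger_events()].
#' @param behavior Optional tibble with columns `trial_index`, `correct`,
#'   `response_side` for this block.
#' @param config An [analysis_config()]; supplies the trial-duration cutoff.
#' @param participant,block Labels stamped onto the rows.
#'
#' @return A trial tibble ordered by `trial_index`.
#' @export
segment_and_label <- function(rec, events, behavior = NULL,
                              config = analysis_config(),
                              participant = 1L, block = 1L) {
  stopifnot(inherits(rec, "fp_recording"))
  n_ev <- nrow(events)
  if (n_ev == 0) {
    return(empty_trial_table())
  }
  if (is.unsorted(events$fixation_onset_s, strictly = TRUE)) {
    stop("structure error: fixation onsets not strictly increasing",
         call. = FALSE)
  }
  end_of_pulse <- ifelse(events$responded, events$response_onset_s,
                         events$target_onset_s + 1.5)
  if (any(end_of_pulse[-n_ev] > events$fixation_onset_s[-1] + 1e-9)) {
    stop("structure error: overlapping trials", call. = FALSE)
  }
  # envelope after the response: feedback (350 ms) + blank (200 ms)
  envelope_s <- 0.55
  trial_end <- c(events$fixation_onset_s[-1], end_of_pulse[n_ev] + envelope_s)
  t0 <- rec$data$time[1]
  fs <- rec$sample_rate
  idx <- function(t) as.integer(round((t - t0) * fs)) + 1L

  trials <- tibble::tibble(
    participant = participant,
    block = block,
    trial_index = seq_len(n_ev),
    fixation_onset_s = events$fixation_onset_s,
    target_onset_s = events$target_onset_s,
    response_onset_s = events$response_onset_s,
    rt_ms = events$rt_ms,
    congruency = events$congruency,
    prev_congruency = dplyr::lag(events$congruency, default = "undefined"),
    target_side = events$target_side,
    responded = events$responded,
    duration_s = trial_end - events$fixation_onset_s,
    first_in_block = seq_len(n_ev) == 1L,
    seg_start = idx(events$fixation_onset_s),
    seg_end = pmin(idx(trial_end), nrow(rec$data))
  )
  if (any(trials$seg_start < 1)) {
    stop("structure error: trial segment precedes recording start",
         call. = FALSE)
  }

  if (!is.null(behavior)) {
    beh <- behavior[, c("trial_index", "correct", "response_side")]
    trials <- dplyr::left_join(trials, beh, by = "trial_index")
  } else {
    instructed <- ifelse(trials$congruency == "congruent",
                         trials$target_side,
                         ifelse(trials$target_side == "left", "right", "left"))
    trials$correct <- ifelse(trials$responded, TRUE, NA)
    trials$response_side <- ifelse(trials$responded, instructed, "none")
  }
  label_trial_flags(trials, config)
}

empty_trial_table <- function() {
  tibble::tibble(
    participant = integer(), block = integer(), trial_index = integer(),
    fixation_onset_s = numeric(), target_onset_s = numeric(),
    response_onset_s = numeric(), rt_ms = numeric(),
    congruency = character(), prev_congruency = character(),
    target_side = character(), responded = logical(), duration_s = numeric(),
    first_in_block = logical(), seg_start = integer(), seg_end = integer(),
    correct = logical(), response_side = character(),
    unresponsive = logical(), error = logical(), post_error = logical(),
    slow_rt = logical()
  )
}

#' Label behavioural exclusion flags
#'
#' Adds (or recomputes) the flag columns `unresponsive` (no response, or
#' trial duration above `trial_max_s`), `error` (incorrect response),
#' `post_error` (correct response immediately following an incorrect
#' response within the same block; a trial following an unresponsive trial is
#' not flagged), and `slow_rt` (correct response with `rt_ms >= rt_max_ms`).
#'
#' @param trials A trial tibble.
#' @param config An [analysis_config()].
#' @return The tibble with flag columns added.
#' @export
label_trial_flags <- function(trials, config = analysis_config()) {
  trials <- dplyr::arrange(trials, .data$participant, .data$block,
                           .data$trial_index)
  responded <- if ("responded" %in% names(trials)) trials$responded
               else !is.na(trials$rt_ms)
  # A trial with no response runs to the timeout, so its full duration
  # (fixation + timeout + feedback + blank) surpasses the 2 s envelope;
  # responded trials beyond the envelope are the slow-RT category instead.
  unresponsive <- !responded
  if ("duration_s" %in% names(trials)) {
    no_rt <- is.na(trials$rt_ms)
    unresponsive <- unresponsive |
      (no_rt & !is.na(trials$duration_s) &
         trials$duration_s > config$trial_max_s)
  }
  error <- !unresponsive & !is.na(trials$correct) & !trials$correct
  prev_error <- logical(nrow(trials))
  key <- interaction(trials$participant, trials$block, drop = TRUE)
  for (g in levels(key)) {
    rows <- which(key == g)
    e <- error[rows]
    prev_error[rows] <- c(FALSE, e[-length(e)])
  }
  post_error <- !unresponsive & !error & prev_error
  slow <- !unresponsive & !error & !is.na(trials$rt_ms) &
    trials$rt_ms >= config$rt_max_ms
  trials$unresponsive <- unresponsive
  trials$error <- error
  trials$post_error <- post_error
  trials$slow_rt <- slow
  trials
}

#' Apply the behavioural exclusion rules
#'
#' Removes trials in a fixed precedence order, counting each trial once
#' under its first matching reason: `unresponsive` (no response or total
#' duration above 2 s), `error` (incorrect response), `post_error` (correct
#' response immediately following an error), `slow_rt` (correct response
#' with RT at or above the cutoff). When `config$subset_rule` is
#' `"post_congruent_only"`, the sway-analysis subset additionally keeps only
#' retained trials whose previous trial was congruent.
#'
#' @param trials A trial tibble (flags are recomputed via
#'   [label_trial_flags()]).
#' @param config An [analysis_config()].
#'
#' @return A list of class `exclusion_result` with elements `trials` (all
#'   trials plus a `reason` column), `retained` (trials surviving all rules),
#'   `sway_trials` (retained trials after the subset rule), and `summary`
#'   (tibble of reason, count, proportion of all trials).
#' @export
apply_exclusions <- function(trials, config = analysis_config()) {
  reasons <- c("unresponsive", "error", "post_error", "slow_rt")
  if (nrow(trials) == 0) {
    summary <- tibble::tibble(reason = c(reasons, "retained"),
                              count = 0L, proportion = 0)
    out <- list(trials = trials, retained = trials, sway_trials = trials,
                summary = summary)
    class(out) <- "exclusion_result"
    return(out)
  }
  trials <- label_trial_flags(trials, config)
  reason <- rep("retained", nrow(trials))
  for (r in rev(reasons)) reason[trials[[r]]] <- r
  trials$reason <- reason
  counts <- vapply(c(reasons, "retained"),
                   function(r) sum(reason == r), integer(1))
  summary <- tibble::tibble(
    reason = names(counts),
    count = unname(counts),
    proportion = unname(counts) / nrow(trials)
  )
  retained <- trials[reason == "retained", , drop = FALSE]
  sway <- retained
  if (config$subset_rule == "post_congruent_only") {
    sway <- sway[sway$prev_congruency == "congruent", , drop = FALSE]
  }
  out <- list(trials = trials, retained = retained, sway_trials = sway,
              summary = summary)
  class(out) <- "exclusion_result"
  out
}

#' @export
print.exclusion_result <- function(x, ...) {
  cat("<exclusion_result>\n")
  print(x$summary)
  invisible(x)
}

#' Write an exclusion summary as CSV
#' @param excl An `exclusion_result`.
#' @param path File path.
#' @export
write_exclusion_summary <- function(excl, path) {
  utils::write.csv(as.data.frame(excl$summary), path, row.names = FALSE)
  invisible(path)
}
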