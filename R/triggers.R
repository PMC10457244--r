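#' Decode trigger pulses into trial events
#'
#' The experimental control software marks trial phases with binary pulse
#' channels recorded alongside the force-plate signals: one fixation channel
#' (high during each 200 ms fixation period) and four condition channels
#' (`trig_congruent_left`, `trig_congruent_right`, `trig_incongruent_left`,
#' `trig_incongruent_right`), exactly one of which is high from target onset
#' to response onset. Channels are thresholded per channel at
#' `threshold_fraction` of their low-to-high range, so analog noise on a
#' nominally binary line is tolerated.
#'
#' A condition pulse with no falling edge before the end of the recording,
#' or one whose width reaches the response timeout, marks an unresponsive
#' trial (no response event is emitted).
#'
#' @param rec An [fp_recording()] with a `trig_fixation` channel and the four
#'   condition channels.
#' @param threshold_fraction Fraction of each channel's range used as the
#'   high/low threshold (default 0.5).
#' @param timeout_s Response timeout encoded by the experiment (default
#'   1.5 s); condition pulses at least this wide count as unresponsive.
#'
#' @return A tibble with one row per decoded trial, ordered by target onset:
#'   `fixation_onset_s`, `target_onset_s`, `response_onset_s` (`NA` when
#'   unresponsive), `rt_ms`, `congruency`, `target_side`, `responded`.
#' @export
decode_trigger_events <- function(rec, threshold_fraction = 0.5,
                                  timeout_s = 1.5) {
  stopifnot(inherits(rec, "fp_recording"))
  cond_names <- c(
    congruent_left = "trig_congruent_left",
    congruent_right = "trig_congruent_right",
    incongruent_left = "trig_incongruent_left",
    incongruent_right = "trig_incongruent_right"
  )
  needed <- c("trig_fixation", unname(cond_names))
  missing <- setdiff(needed, names(rec$data))
  if (length(missing) > 0) {
    stop("recording lacks trigger channel(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  time <- rec$data$time
  dt <- 1 / rec$sample_rate

  binarize <- function(x) {
    rng <- range(x)
    if (diff(rng) < 1e-6) return(rep(FALSE, length(x)))
    x > rng[1] + threshold_fraction * diff(rng)
  }
  high <- lapply(rec$data[needed], binarize)

  overlap <- Reduce(`+`, high[unname(cond_names)])
  if (any(overlap > 1)) {
    stop("ambiguous triggers: two condition channels simultaneously high",
         call. = FALSE)
  }

  runs <- function(h) {
    # (onset index, offset index) pairs; offset NA when high at series end
    d <- diff(c(FALSE, h))
    on <- which(d == 1)
    off <- which(d == -1)
    if (length(off) < length(on)) off <- c(off, NA_integer_)
    list(on = on, off = off)
  }

  fix_on <- runs(high$trig_fixation)$on
  pulses <- list()
  for (key in names(cond_names)) {
    r <- runs(high[[cond_names[key]]])
    if (length(r$on) == 0) next
    parts <- strsplit(key, "_")[[1]]
    pulses[[key]] <- tibble::tibble(
      on = r$on, off = r$off,
      congruency = parts[1], target_side = parts[2]
    )
  }
  if (length(pulses) == 0) {
    return(tibble::tibble(
      fixation_onset_s = numeric(), target_onset_s = numeric(),
      response_onset_s = numeric(), rt_ms = numeric(),
      congruency = character(), target_side = character(),
      responded = logical()
    ))
  }
  ev <- dplyr::arrange(dplyr::bind_rows(pulses), .data$on)

  width_s <- (ifelse(is.na(ev$off), length(time) + 1L, ev$off) - ev$on) * dt
  ev$responded <- !is.na(ev$off) & width_s < timeout_s - dt / 2
  ev$target_onset_s <- time[ev$on]
  ev$response_onset_s <- ifelse(ev$responded, time[ev$off], NA_real_)

  # pair each condition pulse with the closest preceding fixation onset
  fix_idx <- findInterval(ev$on - 1L, fix_on)
  if (any(fix_idx == 0)) {
    stop("trigger structure error: condition pulse with no preceding fixation pulse",
         call. = FALSE)
  }
  if (anyDuplicated(fix_idx) > 0) {
    stop("trigger structure error: two condition pulses share one fixation pulse",
         call. = FALSE)
  }
  ev$fixation_onset_s <- time[fix_on[fix_idx]]
  ev$rt_ms <- (ev$response_onset_s - ev$target_onset_s) * 1000

  tibble::as_tibble(ev)[, c("fixation_onset_s", "target_onset_s",
                            "response_onset_s", "rt_ms", "congruency",
                            "target_side", "responded")]
}
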