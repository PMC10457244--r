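#' Baseline-centre a trial segment
#'
#' Subtracts the mean of the pre-target fixation window (200 ms by design)
#' from the whole segment, per axis and per trial, so that moments are
#' expressed relative to the balance state held during fixation.
#'
#' @param segment Numeric moment series for one trial segment.
#' @param fixation_idx Integer indices of the fixation window within
#'   `segment`.
#' @return The centred segment.
#' @export
baseline_center <- function(segment, fixation_idx) {
  if (length(fixation_idx) == 0 || min(fixation_idx) < 1 ||
      max(fixation_idx) > length(segment)) {
    stop("centering error: fixation window not fully inside segment",
         call. = FALSE)
  }
  segment - mean(segment[fixation_idx])
}

#' Extract a half-open event-aligned bin
#'
#' Bin windows are half-open and inclusive of the anchor sample:
#' `post_target` and `post_response` span `[anchor, anchor + bin)`,
#' `pre_response` spans `[anchor - bin, anchor)`. With this convention the
#' response sample belongs to exactly one bin. The bin length in samples is
#' `round(bin_ms * sample_rate / 1000)`.
#'
#' @param segment Numeric series (typically a centred trial segment or a
#'   whole-block series).
#' @param anchor_idx Sample index of the aligning event within `segment`.
#' @param position One of `"post_target"`, `"pre_response"`,
#'   `"post_response"`.
#' @param sample_rate Sampling frequency in Hz.
#' @param bin_ms Bin duration in milliseconds (default 150).
#'
#' @return Numeric vector of exactly `round(bin_ms * sample_rate / 1000)`
#'   samples. Signals a condition of class `swaybins_bin_range` when the
#'   window exceeds the segment bounds.
#' @export
extract_bin <- function(segment, anchor_idx, position, sample_rate,
                        bin_ms = 150) {
  position <- match.arg(position, .bin_levels)
  n_bin <- as.integer(round(bin_ms * sample_rate / 1000))
  start <- if (position == "pre_response") anchor_idx - n_bin else anchor_idx
  stop_ <- start + n_bin - 1L
  if (start < 1L || stop_ > length(segment)) {
    stop(structure(
      class = c("swaybins_bin_range", "error", "condition"),
      list(message = sprintf(
        "bin out of range: %s window [%d, %d] outside segment of length %d",
        position, start, stop_, length(segment)),
        call = NULL)
    ))
  }
  segment[start:stop_]
}

#' Bin statistics for one window
#'
#' Computes the two balance-control parameters of a bin: the absolute
#' average (AV) of the centred moment (the balance state held in the bin)
#' and the sample standard deviation (SD, the ongoing control effort), plus
#' their natural logs with an epsilon floor. For the ML-controlling moment
#' the signed mean is additionally recoded so that a positive value points
#' towards the side of the manual response; the absolute value (and hence
#' the AV parameter) is unaffected by the recoding.
#'
#' @param window Numeric window of centred moment samples (length >= 2).
#' @param axis_role `"ap_control"` or `"ml_control"`.
#' @param response_side `"left"`, `"right"` or `"none"`; required for ML
#'   recoding.
#' @param positive_ml_direction Physical direction of a positive ML-control
#'   moment (`"rightward"` or `"leftward"`).
#' @param log_epsilon Floor added before the log (N·m).
#'
#' @return A one-row tibble with `mean_raw`, `ml_recoded_mean`, `av_abs`,
#'   `sd`, `log_av`, `log_sd`, `floored_av`, `floored_sd`, `n_samples`.
#' @export
compute_bin_stats <- function(window, axis_role = "ap_control",
                              response_side = "none",
                              positive_ml_direction = "rightward",
                              log_epsilon = 1e-12) {
  axis_role <- match.arg(axis_role, .axis_roles)
  if (length(window) < 2) {
    stop("window too short: standard deviation undefined for length < 2",
         call. = FALSE)
  }
  m <- mean(window)
  s <- stats::sd(window)
  recoded <- m
  if (axis_role == "ml_control" && response_side %in% .side_levels) {
    positive_side <- if (positive_ml_direction == "rightward") "right" else "left"
    recoded <- if (response_side == positive_side) m else -m
  }
  tibble::tibble(
    mean_raw = m,
    ml_recoded_mean = recoded,
    av_abs = abs(m),
    sd = s,
    log_av = log(abs(m) + log_epsilon),
    log_sd = log(s + log_epsilon),
    floored_av = abs(m) == 0,
    floored_sd = s == 0,
    n_samples = length(window)
  )
}

#' Per-trial bin statistics over a whole-block recording
#'
#' For every trial in `trials`, centres the AP- and ML-controlling moment
#' series at the trial's pre-target fixation mean and computes
#' [compute_bin_stats()] in the target-aligned bin (`post_target`) and, when
#' a response exists, the two response-aligned bins (`pre_response`,
#' `post_response`). Trials whose window would leave the recording are
#' dropped from that bin with a log entry in the `dropped` attribute.
#'
#' The recording is expected to be filtered already (see
#' [filter_recording()]).
#'
#' @param rec A (filtered) [fp_recording()].
#' @param trials A trial tibble for this recording (e.g. the sway subset of
#'   [apply_exclusions()]).
#' @param config An [analysis_config()].
#'
#' @return A tidy tibble: one row per trial x axis role x bin, carrying the
#'   trial keys, condition labels and the bin statistics.
#' @export
trial_bin_stats <- function(rec, trials, config = analysis_config()) {
  stopifnot(inherits(rec, "fp_recording"))
  fs <- rec$sample_rate
  t0 <- rec$data$time[1]
  idx <- function(t) as.integer(round((t - t0) * fs)) + 1L
  channels <- c(ap_control = rec$axis_map$ap_control,
                ml_control = rec$axis_map$ml_control)
  series <- lapply(channels, function(ch) rec$data[[ch]])

  n_bin <- as.integer(round(config$bin_ms * fs / 1000))
  positive_side <- if (rec$axis_map$positive_ml_direction == "rightward")
    "right" else "left"
  eps <- config$log_epsilon

  cap <- nrow(trials) * 6L
  row_i <- integer(cap)
  axis_role <- character(cap)
  bin <- character(cap)
  mean_raw <- numeric(cap)
  recoded <- numeric(cap)
  sd_v <- numeric(cap)
  k <- 0L
  dropped <- 0L
  for (i in seq_len(nrow(trials))) {
    fix_i <- idx(trials$fixation_onset_s[i])
    tgt_i <- idx(trials$target_onset_s[i])
    if (fix_i < 1 || tgt_i <= fix_i) next
    anchors <- c(post_target = tgt_i)
    if (isTRUE(trials$responded[i]) && !is.na(trials$response_onset_s[i])) {
      resp_i <- idx(trials$response_onset_s[i])
      anchors <- c(anchors, pre_response = resp_i, post_response = resp_i)
    }
    resp_side <- trials$response_side[i]
    for (role in .axis_roles) {
      x <- series[[role]]
      if (tgt_i - 1L > length(x)) next
      baseline <- mean(x[fix_i:(tgt_i - 1L)])
      for (bn in names(anchors)) {
        a <- anchors[[bn]]
        start <- if (bn == "pre_response") a - n_bin else a
        stop_ <- start + n_bin - 1L
        if (start < 1L || stop_ > length(x)) {
          dropped <- dropped + 1L
          next
        }
        w <- x[start:stop_] - baseline
        m <- mean(w)
        k <- k + 1L
        row_i[k] <- i
        axis_role[k] <- role
        bin[k] <- bn
        mean_raw[k] <- m
        recoded[k] <- if (role == "ml_control" && resp_side %in% .side_levels) {
          if (resp_side == positive_side) m else -m
        } else m
        sd_v[k] <- stats::sd(w)
      }
    }
  }
  if (k == 0) {
    out <- empty_bin_stats()
    attr(out, "dropped") <- dropped
    return(out)
  }
  seqk <- seq_len(k)
  ri <- row_i[seqk]
  out <- tibble::tibble(
    participant = trials$participant[ri],
    block = trials$block[ri],
    trial_index = trials$trial_index[ri],
    congruency = trials$congruency[ri],
    prev_congruency = trials$prev_congruency[ri],
    axis_role = axis_role[seqk],
    bin = bin[seqk],
    mean_raw = mean_raw[seqk],
    ml_recoded_mean = recoded[seqk],
    av_abs = abs(mean_raw[seqk]),
    sd = sd_v[seqk],
    log_av = log(abs(mean_raw[seqk]) + eps),
    log_sd = log(sd_v[seqk] + eps),
    floored_av = abs(mean_raw[seqk]) == 0,
    floored_sd = sd_v[seqk] == 0,
    n_samples = n_bin
  )
  attr(out, "dropped") <- dropped
  out
}

empty_bin_stats <- function() {
  tibble::tibble(
    participant = integer(), block = integer(), trial_index = integer(),
    congruency = character(), prev_congruency = character(),
    axis_role = character(), bin = character(), mean_raw = numeric(),
    ml_recoded_mean = numeric(), av_abs = numeric(), sd = numeric(),
    log_av = numeric(), log_sd = numeric(), floored_av = logical(),
    floored_sd = logical(), n_samples = integer()
  )
}

#' Aggregate bin statistics into participant condition cells
#'
#' Computes the unweighted mean of the per-trial parameters within each
#' participant x axis role x bin x congruency cell (optionally also split by
#' previous-trial congruency). By default the natural log is taken per trial
#' and the logs are averaged (`transform_order = "trial"`); with
#' `transform_order = "cell"` the raw parameters are averaged first and the
#' cell mean is log-transformed. Raw-scale cell means are always reported
#' alongside.
#'
#' @param bin_stats Output of [trial_bin_stats()].
#' @param config An [analysis_config()].
#' @param by_prev Also split cells by `prev_congruency`.
#'
#' @return A tibble with one row per cell: `log_av`, `log_sd` (per
#'   `transform_order`), raw `av_abs` and `sd` means, and `n_trials`.
#' @export
aggregate_by_condition <- function(bin_stats, config = analysis_config(),
                                   by_prev = FALSE) {
  keys <- c("participant", "axis_role", "bin", "congruency")
  if (by_prev) keys <- c(keys, "prev_congruency")
  grouped <- dplyr::group_by(bin_stats, dplyr::across(dplyr::all_of(keys)))
  out <- dplyr::summarise(
    grouped,
    av_abs = mean(.data$av_abs),
    sd = mean(.data$sd),
    log_av_trialwise = mean(.data$log_av),
    log_sd_trialwise = mean(.data$log_sd),
    n_trials = dplyr::n(),
    .groups = "drop"
  )
  if (config$transform_order == "trial") {
    out$log_av <- out$log_av_trialwise
    out$log_sd <- out$log_sd_trialwise
  } else {
    out$log_av <- log(out$av_abs + config$log_epsilon)
    out$log_sd <- log(out$sd + config$log_epsilon)
  }
  out$log_av_trialwise <- NULL
  out$log_sd_trialwise <- NULL
  out
}
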