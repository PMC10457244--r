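#' Session specification for the synthetic Simon-task generator
#'
#' Defaults emulate a standard standing Simon-task session: 48 participants,
#' 10 blocks of 80 trials (800 trials per participant), 200 ms fixation, a
#' 1.5 s response timeout, 350 ms feedback and a 200 ms blank inter-trial
#' interval, so that the response-to-target interval after a response is
#' 750 ms. Recordings default to 1 kHz; 250 Hz is a supported reduced rate
#' for desk-scale simulation.
#'
#' @param n_participants,n_blocks,trials_per_block Session dimensions.
#' @param fixation_ms,target_timeout_ms,feedback_ms,iti_blank_ms Trial phase
#'   durations in ms.
#' @param sample_rate Recording sample rate in Hz.
#' @param lead_in_s,tail_s Recording padding before the first fixation and
#'   after the last trial envelope, in seconds.
#' @return An object of class `session_spec`.
#' @export
session_spec <- function(n_participants = 48, n_blocks = 10,
                         trials_per_block = 80, fixation_ms = 200,
                         target_timeout_ms = 1500, feedback_ms = 350,
                         iti_blank_ms = 200, sample_rate = 1000,
                         lead_in_s = 1, tail_s = 0.5) {
  stopifnot(n_participants >= 1, n_blocks >= 1, trials_per_block >= 1,
            sample_rate > 20, fixation_ms > 0, target_timeout_ms > 0)
  structure(
    list(n_participants = as.integer(n_participants),
         n_blocks = as.integer(n_blocks),
         trials_per_block = as.integer(trials_per_block),
         fixation_ms = fixation_ms, target_timeout_ms = target_timeout_ms,
         feedback_ms = feedback_ms, iti_blank_ms = iti_blank_ms,
         sample_rate = sample_rate, lead_in_s = lead_in_s, tail_s = tail_s),
    class = "session_spec"
  )
}

#' Reaction-time and error model for the synthetic Simon task
#'
#' Cell parameters are keyed by previous-trial congruency x current
#' congruency (`cc`, `ci`, `ic`, `ii`; first letter = previous). The default
#' calibration reproduces the canonical standing Simon-task pattern: a
#' +54 ms post-congruent congruency effect and a -16 ms (reversed)
#' post-incongruent effect around a 459 ms grand mean; error probabilities
#' giving a +7.3 percentage-point post-congruent and a -2.2 point
#' post-incongruent error effect at 5.9% errors overall; and a slow-response
#' tail placing about 3% of correct trials beyond the 1250 ms cutoff.
#' First-in-block trials (undefined previous congruency) use the marginal
#' mean of the two previous-congruency cells.
#'
#' Reaction times are drawn from a lognormal with the cell mean and a common
#' within-cell SD, mixed with a slow exponential tail starting at the RT
#' cutoff; draws reaching the response timeout become unresponsive trials.
#' Between-participant heterogeneity enters as a normal shift of all RT cell
#' means and a normal shift of the error logits.
#'
#' @param rt_mean_ms Named numeric of cell mean RTs (`cc`, `ci`, `ic`, `ii`).
#' @param rt_sd_ms Within-cell RT standard deviation (ms).
#' @param error_prob Named numeric of cell error probabilities.
#' @param slow_prob Probability that a trial's RT comes from the slow tail.
#' @param slow_tail_mean_ms Mean of the exponential slow tail beyond the RT
#'   cutoff (ms).
#' @param rt_cutoff_ms Start of the slow tail (the analysis RT cutoff).
#' @param participant_rt_sd_ms SD of the per-participant RT shift (ms).
#' @param participant_error_logit_sd SD of the per-participant error logit
#'   shift.
#' @return An object of class `rt_model_config`.
#' @export
rt_model_config <- function(rt_mean_ms = c(cc = 432, ci = 486,
                                           ic = 467, ii = 451),
                            rt_sd_ms = 90,
                            error_prob = c(cc = 0.0265, ci = 0.0995,
                                           ic = 0.066, ii = 0.044),
                            slow_prob = 0.035,
                            slow_tail_mean_ms = 80,
                            rt_cutoff_ms = 1250,
                            participant_rt_sd_ms = 40,
                            participant_error_logit_sd = 0.35) {
  cells <- c("cc", "ci", "ic", "ii")
  stopifnot(all(cells %in% names(rt_mean_ms)),
            all(cells %in% names(error_prob)),
            all(rt_mean_ms > 0), rt_sd_ms > 0)
  if (any(error_prob < 0 | error_prob > 1) || slow_prob < 0 || slow_prob > 1) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(rt_mean_ms = rt_mean_ms[cells], rt_sd_ms = rt_sd_ms,
         error_prob = error_prob[cells], slow_prob = slow_prob,
         slow_tail_mean_ms = slow_tail_mean_ms, rt_cutoff_ms = rt_cutoff_ms,
         participant_rt_sd_ms = participant_rt_sd_ms,
         participant_error_logit_sd = participant_error_logit_sd),
    class = "rt_model_config"
  )
}

#' Generate a trial schedule for one participant
#'
#' Target letters and target sides are independent uniform draws; the letter
#' determines the instructed response side (T = left, X = right) and
#' congruency is the match between instructed side and target side.
#'
#' @param spec A [session_spec()].
#' @param participant Participant id.
#' @return A tibble, one row per planned trial, in presentation order.
#' @export
generate_schedule <- function(spec = session_spec(), participant = 1L) {
  n <- spec$n_blocks * spec$trials_per_block
  letter <- sample(c("T", "X"), n, replace = TRUE)
  target_side <- sample(.side_levels, n, replace = TRUE)
  instructed_side <- ifelse(letter == "T", "left", "right")
  tibble::tibble(
    participant = participant,
    block = rep(seq_len(spec$n_blocks), each = spec$trials_per_block),
    trial_index = rep(seq_len(spec$trials_per_block), spec$n_blocks),
    target_letter = letter,
    target_side = target_side,
    instructed_side = instructed_side,
    congruency = ifelse(instructed_side == target_side,
                        "congruent", "incongruent")
  )
}

.cell_key <- function(prev, cur) {
  p <- ifelse(prev == "congruent", "c",
              ifelse(prev == "incongruent", "i", "u"))
  paste0(p, ifelse(cur == "congruent", "c", "i"))
}

# cell parameter lookup with marginal fallback for undefined previous trials
.cell_param <- function(param, key) {
  marg <- c(uc = mean(param[c("cc", "ic")]), ui = mean(param[c("ci", "ii")]))
  out <- numeric(length(key))
  known <- key %in% names(param)
  out[known] <- param[key[known]]
  out[!known] <- marg[key[!known]]
  out
}

#' Sample Simon-task behaviour for a planned schedule
#'
#' Realises correctness, response side and reaction time for every planned
#' trial of one participant, then chains the trial event times: fixation
#' (200 ms), target, response (or timeout), feedback and blank, with the
#' next fixation starting feedback + blank after the response. All event
#' times are quantised to the recording sample grid.
#'
#' @param plan Schedule tibble from [generate_schedule()] (one participant).
#' @param rt_model An [rt_model_config()].
#' @param spec A [session_spec()].
#' @return A trial tibble in the same layout as [segment_and_label()]
#'   output, plus `target_letter` and `instructed_side`.
#' @export
sample_behavior <- function(plan, rt_model = rt_model_config(),
                            spec = session_spec()) {
  n <- nrow(plan)
  prev <- dplyr::lag(plan$congruency, default = "undefined")
  prev[plan$trial_index == 1L] <- "undefined"
  key <- .cell_key(prev, plan$congruency)

  rt_shift <- rnorm(1, 0, rt_model$participant_rt_sd_ms)
  # mean-preserving on the odds scale: a plain normal logit shift would
  # inflate the population-mean error rate above the calibrated cell values
  els <- rt_model$participant_error_logit_sd
  logit_shift <- rnorm(1, -els^2 / 2, els)

  p_err <- .cell_param(rt_model$error_prob, key)
  p_err <- stats::plogis(stats::qlogis(p_err) + logit_shift)
  correct <- runif(n) >= p_err

  m <- pmax(.cell_param(rt_model$rt_mean_ms, key) + rt_shift, 150)
  s <- rt_model$rt_sd_ms
  sdlog <- sqrt(log(1 + (s / m)^2))
  meanlog <- log(m) - sdlog^2 / 2
  rt <- stats::rlnorm(n, meanlog, sdlog)
  slow <- runif(n) < rt_model$slow_prob
  rt[slow] <- rt_model$rt_cutoff_ms +
    stats::rexp(sum(slow), 1 / rt_model$slow_tail_mean_ms)

  fs <- spec$sample_rate
  to_samples <- function(ms) as.integer(round(ms / 1000 * fs))
  rt_smp <- to_samples(rt)
  timeout_smp <- to_samples(spec$target_timeout_ms)
  responded <- rt_smp < timeout_smp
  correct[!responded] <- NA
  fix_smp <- to_samples(spec$fixation_ms)
  post_smp <- to_samples(spec$feedback_ms) + to_samples(spec$iti_blank_ms)

  fix_i <- integer(n)
  tgt_i <- integer(n)
  end_i <- integer(n)
  lead <- as.integer(round(spec$lead_in_s * fs))
  for (i in seq_len(n)) {
    fix_i[i] <- if (i > 1 && plan$block[i] == plan$block[i - 1]) {
      end_i[i - 1]
    } else {
      lead
    }
    tgt_i[i] <- fix_i[i] + fix_smp
    latency <- if (responded[i]) rt_smp[i] else timeout_smp
    end_i[i] <- tgt_i[i] + latency + post_smp
  }
  resp_i <- ifelse(responded, tgt_i + rt_smp, NA_integer_)

  tibble::tibble(
    participant = plan$participant,
    block = plan$block,
    trial_index = plan$trial_index,
    fixation_onset_s = fix_i / fs,
    target_onset_s = tgt_i / fs,
    response_onset_s = resp_i / fs,
    rt_ms = ifelse(responded, rt_smp / fs * 1000, NA_real_),
    congruency = plan$congruency,
    prev_congruency = prev,
    target_side = plan$target_side,
    instructed_side = plan$instructed_side,
    target_letter = plan$target_letter,
    responded = responded,
    duration_s = (end_i - fix_i) / fs,
    first_in_block = plan$trial_index == 1L,
    correct = correct,
    response_side = dplyr::case_when(
      !responded ~ "none",
      correct ~ plan$instructed_side,
      TRUE ~ ifelse(plan$instructed_side == "left", "right", "left")
    )
  )
}

#' Simulate behaviour for a whole study
#'
#' Draws a schedule and behaviour for every participant under a single seed,
#' with per-participant sub-seeds split off the main stream so participant
#' generation order is reproducible.
#'
#' @param spec A [session_spec()].
#' @param rt_model An [rt_model_config()].
#' @param seed Integer seed.
#' @return A trial tibble covering all participants.
#' @export
simulate_behavior_study <- function(spec = session_spec(),
                                    rt_model = rt_model_config(),
                                    seed = 1L) {
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max, spec$n_participants)
  out <- vector("list", spec$n_participants)
  for (p in seq_len(spec$n_participants)) {
    set.seed(sub_seeds[p])
    plan <- generate_schedule(spec, participant = p)
    out[[p]] <- sample_behavior(plan, rt_model, spec)
  }
  dplyr::bind_rows(out)
}
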