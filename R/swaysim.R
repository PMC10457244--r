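#' Sway model for the synthetic force-plate generator
#'
#' Sway moments are generated phenomenologically as the sum of a slow
#' drift process (stationary Ornstein-Uhlenbeck, time constant `tau_slow_s`,
#' emulating the multi-second equilibrium oscillations of quiet stance), a
#' fast fluctuation process (OU, `tau_fast_s`, the balance-corrective
#' activity whose within-bin variability the pipeline measures), white
#' measurement noise, and a per-trial mean-shift ramp from target onset to a
#' plateau at the response (the deliberate postural lean accompanying the
#' manual reaction).
#'
#' The fast fluctuation is scaled by a phase gain profile: 1 during
#' fixation, `gamma_target` from target onset for one bin, `gamma_response`
#' from one bin before to one bin after the response. On incongruent trials
#' only, the ML-controlling fluctuation in the bin before the response is
#' additionally scaled by `1 - delta` (the congruency injection); with
#' `delta = 0` the generator is congruency-blind for sway.
#'
#' Default calibration: `gamma_response = gamma_target * (1 - 0.08)` (an
#' approximately 8% variability drop from target processing to response
#' execution) and `delta = 0.20`. Because the zero-phase low-pass smears the
#' edges of the 150 ms gain windows, the within-bin SD reduction the
#' analysis pipeline measures is attenuated to roughly 0.7 of the configured
#' `delta`; the default is calibrated so the measured ML pre-response
#' reduction lands at approximately 14%.
#'
#' @param tau_slow_s,sigma_slow Drift time constant (s) and SD (N·m).
#' @param tau_fast_s,sigma_fast Fluctuation time constant (s) and SD (N·m).
#' @param noise_sd Measurement noise SD (N·m).
#' @param gamma_target Fast-fluctuation gain in the post-target bin.
#' @param gamma_response Gain around the response (one bin before to one bin
#'   after).
#' @param delta Extra multiplicative reduction `1 - delta` of the
#'   ML-controlling fluctuation in the pre-response bin of incongruent
#'   trials.
#' @param ramp_sd SD of the per-trial mean-shift plateau (N·m); the plateau
#'   sign is random.
#' @param gain_bin_ms Width of the gain windows (ms); matches the analysis
#'   bin.
#' @param body_weight_n Constant vertical load (N) written to `fz`.
#' @return An object of class `sway_model_config`.
#' @export
sway_model_config <- function(tau_slow_s = 20, sigma_slow = 2.0,
                              tau_fast_s = 0.3, sigma_fast = 1.0,
                              noise_sd = 0.3, gamma_target = 1.0,
                              gamma_response = gamma_target * (1 - 0.08),
                              delta = 0.20, ramp_sd = 0.3,
                              gain_bin_ms = 150, body_weight_n = 700) {
  stopifnot(tau_slow_s > 0, tau_fast_s > 0, sigma_slow >= 0, sigma_fast > 0,
            noise_sd >= 0, gamma_target > 0, gamma_response > 0,
            delta >= 0, delta < 1, ramp_sd >= 0, gain_bin_ms > 0)
  structure(
    list(tau_slow_s = tau_slow_s, sigma_slow = sigma_slow,
         tau_fast_s = tau_fast_s, sigma_fast = sigma_fast,
         noise_sd = noise_sd, gamma_target = gamma_target,
         gamma_response = gamma_response, delta = delta, ramp_sd = ramp_sd,
         gain_bin_ms = gain_bin_ms, body_weight_n = body_weight_n),
    class = "sway_model_config"
  )
}

# stationary Ornstein-Uhlenbeck sample path via its exact AR(1) discretisation
.ou_series <- function(n, dt, tau, sigma) {
  if (sigma == 0) return(numeric(n))
  phi <- exp(-dt / tau)
  innov <- rnorm(n, 0, sigma * sqrt(1 - phi^2))
  x0 <- rnorm(1, 0, sigma)
  as.numeric(stats::filter(innov, phi, method = "recursive", init = x0))
}

#' Encode trial events as trigger channels
#'
#' Produces the five binary trigger series for one block: `trig_fixation`
#' high during each fixation period, and exactly one of the four condition
#' channels (congruency x target side) high from target onset to response
#' onset, or for the full response timeout on unresponsive trials.
#'
#' @param trials Trial tibble for one block (needs `fixation_onset_s`,
#'   `target_onset_s`, `response_onset_s`, `responded`, `congruency`,
#'   `target_side`).
#' @param spec A [session_spec()].
#' @param n_samples Length of the block recording.
#' @param high Level of a raised pulse (default 5, TTL-like).
#' @return A tibble of five `trig_*` columns with `n_samples` rows.
#' @export
encode_trigger_channels <- function(trials, spec = session_spec(),
                                    n_samples, high = 5) {
  fs <- spec$sample_rate
  idx <- function(t) as.integer(round(t * fs)) + 1L
  chans <- list(
    trig_fixation = numeric(n_samples),
    trig_congruent_left = numeric(n_samples),
    trig_congruent_right = numeric(n_samples),
    trig_incongruent_left = numeric(n_samples),
    trig_incongruent_right = numeric(n_samples)
  )
  timeout_smp <- as.integer(round(spec$target_timeout_ms / 1000 * fs))
  prev_end <- 0L
  for (i in seq_len(nrow(trials))) {
    tr <- trials[i, ]
    f0 <- idx(tr$fixation_onset_s)
    t0 <- idx(tr$target_onset_s)
    r0 <- if (isTRUE(tr$responded)) idx(tr$response_onset_s)
          else t0 + timeout_smp
    if (f0 <= prev_end) {
      stop("encoding error: overlapping trials", call. = FALSE)
    }
    if (r0 - 1L > n_samples) {
      stop("schedule error: events outside block duration", call. = FALSE)
    }
    chans$trig_fixation[f0:(t0 - 1L)] <- high
    cond <- paste0("trig_", tr$congruency, "_", tr$target_side)
    chans[[cond]][t0:(r0 - 1L)] <- high
    prev_end <- r0 - 1L
  }
  tibble::as_tibble(chans)
}

#' Simulate the force-plate recording of one block
#'
#' Builds the continuous six-channel recording for one block from realised
#' trial events: AP- and ML-controlling moments as drift + gain-scaled fast
#' fluctuation + ramp + noise (see [sway_model_config()]), the vertical
#' force as constant body weight plus noise, the remaining channels as
#' noise, and the encoded trigger channels.
#'
#' @param trials Trial tibble for one block (from [sample_behavior()],
#'   single block).
#' @param sway A [sway_model_config()].
#' @param spec A [session_spec()].
#' @param axis_map An [axis_map()] deciding which moment channels carry the
#'   AP- and ML-controlling signals.
#' @return An [fp_recording()].
#' @export
simulate_sway_block <- function(trials, sway = sway_model_config(),
                                spec = session_spec(),
                                axis_map = swaybins::axis_map()) {
  fs <- spec$sample_rate
  dt <- 1 / fs
  block_end_s <- max(trials$fixation_onset_s + trials$duration_s)
  n <- as.integer(round((block_end_s + spec$tail_s) * fs)) + 1L
  idx <- function(t) as.integer(round(t * fs)) + 1L
  n_bin <- as.integer(round(sway$gain_bin_ms / 1000 * fs))

  gain <- list(ap_control = rep(1, n), ml_control = rep(1, n))
  ramp <- list(ap_control = numeric(n), ml_control = numeric(n))
  for (i in seq_len(nrow(trials))) {
    tr <- trials[i, ]
    t0 <- idx(tr$target_onset_s)
    tgt_win <- t0:min(t0 + n_bin - 1L, n)
    for (role in .axis_roles) gain[[role]][tgt_win] <- sway$gamma_target
    if (!isTRUE(tr$responded)) next
    r0 <- idx(tr$response_onset_s)
    resp_win <- max(r0 - n_bin, 1L):min(r0 + n_bin - 1L, n)
    for (role in .axis_roles) gain[[role]][resp_win] <- sway$gamma_response
    if (tr$congruency == "incongruent" && sway$delta > 0) {
      pre_win <- max(r0 - n_bin, 1L):(r0 - 1L)
      gain$ml_control[pre_win] <- sway$gamma_response * (1 - sway$delta)
    }
    # mean-shift ramp: linear rise target -> response, hold through the
    # feedback period, linear return to rest by the end of the trial
    end_i <- min(idx(tr$fixation_onset_s + tr$duration_s), n)
    hold_i <- min(r0 + as.integer(round(spec$feedback_ms / 1000 * fs)), n)
    for (role in .axis_roles) {
      a <- rnorm(1, 0, sway$ramp_sd)
      if (r0 > t0) {
        ramp[[role]][t0:r0] <- ramp[[role]][t0:r0] +
          a * seq(0, 1, length.out = r0 - t0 + 1L)
      }
      if (hold_i > r0) ramp[[role]][(r0 + 1L):hold_i] <- a
      if (end_i > hold_i) {
        ramp[[role]][hold_i:end_i] <- a * seq(1, 0, length.out = end_i - hold_i + 1L)
      }
    }
  }

  moment <- lapply(.axis_roles, function(role) {
    .ou_series(n, dt, sway$tau_slow_s, sway$sigma_slow) +
      gain[[role]] * .ou_series(n, dt, sway$tau_fast_s, sway$sigma_fast) +
      ramp[[role]] + rnorm(n, 0, sway$noise_sd)
  })
  names(moment) <- .axis_roles

  data <- tibble::tibble(
    time = (seq_len(n) - 1L) / fs,
    fx = rnorm(n, 0, 2),
    fy = rnorm(n, 0, 2),
    fz = -sway$body_weight_n + rnorm(n, 0, 1)
  )
  data[[axis_map$ap_control]] <- moment$ap_control
  data[[axis_map$ml_control]] <- moment$ml_control
  third <- setdiff(c("mx", "my", "mz"),
                   c(axis_map$ap_control, axis_map$ml_control))
  for (ch in third) data[[ch]] <- rnorm(n, 0, 0.2)
  data <- dplyr::bind_cols(
    data[, c("time", "fx", "fy", "fz", "mx", "my", "mz")],
    encode_trigger_channels(trials, spec, n)
  )
  fp_recording(data, axis_map = axis_map,
               block_id = as.character(trials$block[1]))
}

#' Simulate one participant's full session
#'
#' @param spec A [session_spec()].
#' @param rt_model An [rt_model_config()].
#' @param sway A [sway_model_config()].
#' @param participant Participant id.
#' @param axis_map An [axis_map()].
#' @return A list with `trials` (ground-truth behaviour) and `recordings`
#'   (one [fp_recording()] per block).
#' @export
simulate_session <- function(spec = session_spec(),
                             rt_model = rt_model_config(),
                             sway = sway_model_config(),
                             participant = 1L,
                             axis_map = swaybins::axis_map()) {
  plan <- generate_schedule(spec, participant)
  trials <- sample_behavior(plan, rt_model, spec)
  recordings <- lapply(split(trials, trials$block), function(tb) {
    simulate_sway_block(tb, sway, spec, axis_map)
  })
  list(trials = trials, recordings = recordings)
}
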