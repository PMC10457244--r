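# Programmatic fixtures shared across test files.

# Minimal valid recording: flat forces, chosen moment series, optional
# trigger columns.
make_recording <- function(n = 1000, fs = 1000, mx = NULL, my = NULL,
                           triggers = NULL) {
  data <- tibble::tibble(
    time = (seq_len(n) - 1) / fs,
    fx = 0, fy = 0, fz = -700,
    mx = if (is.null(mx)) rep(0, n) else mx,
    my = if (is.null(my)) rep(0, n) else my,
    mz = 0
  )
  if (!is.null(triggers)) data <- dplyr::bind_cols(data, triggers)
  fp_recording(data)
}

# Recording with a full trigger set describing given pulse intervals.
# intervals: list(fix = c(on, off), cond = list(channel, on, off)) in seconds.
make_trigger_recording <- function(n = 3000, fs = 1000, fix_windows = list(),
                                   cond_windows = list()) {
  blank <- function() numeric(n)
  trig <- tibble::tibble(
    trig_fixation = blank(),
    trig_congruent_left = blank(),
    trig_congruent_right = blank(),
    trig_incongruent_left = blank(),
    trig_incongruent_right = blank()
  )
  set_win <- function(col, on, off) {
    i0 <- round(on * fs) + 1
    i1 <- round(off * fs)
    col[i0:i1] <- 5
    col
  }
  for (w in fix_windows) {
    trig$trig_fixation <- set_win(trig$trig_fixation, w[1], w[2])
  }
  for (w in cond_windows) {
    trig[[w$channel]] <- set_win(trig[[w$channel]], w$on, w$off)
  }
  make_recording(n = n, fs = fs, triggers = trig)
}

# Hand-built trial tibble for exclusion-rule tests.
make_trials <- function(correct, rt_ms, responded = !is.na(rt_ms),
                        congruency = rep("congruent", length(correct)),
                        prev = NULL, block = 1L) {
  k <- length(correct)
  tibble::tibble(
    participant = 1L, block = block, trial_index = seq_len(k),
    rt_ms = rt_ms, congruency = congruency,
    prev_congruency = if (is.null(prev)) {
      c("undefined", congruency[-k])
    } else prev,
    responded = responded,
    correct = correct,
    first_in_block = seq_len(k) == 1L
  )
}

# Small session settings used by simulator tests.
tiny_spec <- function(...) {
  session_spec(n_participants = 1, n_blocks = 1, trials_per_block = 6,
               sample_rate = 250, ...)
}
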