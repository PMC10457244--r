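test_that("baseline centering subtracts the fixation-window mean", {
  seg <- c(rep(0.4, 50), rnorm(100, 1))
  out <- baseline_center(seg, 1:50)
  expect_equal(out[1:50], rep(0, 50))
  expect_equal(out, seg - 0.4)
  expect_lt(abs(mean(out[1:50])), 1e-12)
  # constant segment -> all zeros
  expect_equal(baseline_center(rep(2.2, 30), 1:10), rep(0, 30))
  # SD over any window is unchanged by centering
  expect_equal(sd(out[60:120]), sd(seg[60:120]))
  expect_error(baseline_center(seg, 140:160), "centering error")
})

test_that("bin windows are half-open with the documented sample counts", {
  seg <- seq_len(1000)
  w <- extract_bin(seg, 201, "post_target", 1000, 150)
  expect_equal(length(w), 150)
  expect_equal(w, 201:350)
  w2 <- extract_bin(seg, 500, "pre_response", 1000, 150)
  expect_equal(w2, 350:499)
  w3 <- extract_bin(seg, 500, "post_response", 1000, 150)
  expect_equal(w3, 500:649)
  # pre- and post-response windows are adjacent and disjoint
  expect_equal(length(intersect(w2, w3)), 0)
  expect_equal(max(w2) + 1, min(w3))
  # 150 ms at 250 Hz: 37.5 rounds to 38 samples
  expect_equal(length(extract_bin(seq_len(500), 100, "post_target", 250,
                                  150)), 38)
  expect_error(extract_bin(seg, 101, "pre_response", 1000, 150),
               class = "swaybins_bin_range")
})

test_that("bin statistics match hand computations", {
  st <- compute_bin_stats(c(1, 2, 3))
  expect_equal(st$mean_raw, 2)
  expect_equal(st$sd, 1)
  expect_equal(st$av_abs, 2)
  expect_equal(st$log_av, log(2 + 1e-12))

  # constant window: SD floors to log(epsilon) and is flagged
  st2 <- compute_bin_stats(rep(-0.2, 20), log_epsilon = 1e-12)
  expect_equal(st2$sd, 0)
  expect_equal(st2$av_abs, 0.2)
  expect_equal(st2$log_sd, log(1e-12))
  expect_true(st2$floored_sd)
  expect_false(st2$floored_av)

  expect_error(compute_bin_stats(1), "length")
})

test_that("the ML mean is recoded towards the response side", {
  w <- rep(-0.2, 10) + c(-1e-13, 1e-13)
  st <- compute_bin_stats(w, axis_role = "ml_control",
                          response_side = "left",
                          positive_ml_direction = "rightward")
  expect_equal(st$ml_recoded_mean, 0.2, tolerance = 1e-9)
  st2 <- compute_bin_stats(w, axis_role = "ml_control",
                           response_side = "right",
                           positive_ml_direction = "rightward")
  expect_equal(st2$ml_recoded_mean, -0.2, tolerance = 1e-9)
  # AV is recoding-invariant
  expect_equal(st$av_abs, st2$av_abs)
  # AP role never recodes
  st3 <- compute_bin_stats(w, axis_role = "ap_control",
                           response_side = "left")
  expect_equal(st3$ml_recoded_mean, st3$mean_raw)
})

test_that("SD and log SD are invariant under constant segment shifts", {
  set.seed(13)
  spec <- session_spec(n_participants = 1, n_blocks = 1,
                       trials_per_block = 6, sample_rate = 250)
  sess <- simulate_session(spec)
  rec <- sess$recordings[[1]]
  tb <- sess$trials
  analyze <- function(r) {
    ev <- decode_trigger_events(filter_recording(r))
    tr <- segment_and_label(filter_recording(r), ev,
                            behavior = tb[, c("trial_index", "correct",
                                              "response_side")])
    trial_bin_stats(filter_recording(r),
                    apply_exclusions(tr, analysis_config(subset_rule = "all"))$retained)
  }
  base <- analyze(rec)
  shifted <- rec
  shifted$data$mx <- shifted$data$mx + 5.3
  shifted$data$my <- shifted$data$my - 2.1
  out <- analyze(shifted)
  expect_equal(out$sd, base$sd, tolerance = 1e-9)
  expect_equal(out$log_sd, base$log_sd, tolerance = 1e-9)
  # baseline centering also cancels the shift in the means
  expect_equal(out$av_abs, base$av_abs, tolerance = 1e-8)
})

test_that("per-trial bin statistics agree with the per-window operation", {
  set.seed(17)
  spec <- session_spec(n_participants = 1, n_blocks = 1,
                       trials_per_block = 5, sample_rate = 250)
  sess <- simulate_session(spec)
  rec <- filter_recording(sess$recordings[[1]])
  tb <- sess$trials
  ev <- decode_trigger_events(rec)
  tr <- segment_and_label(rec, ev, behavior = tb[, c("trial_index", "correct",
                                                     "response_side")])
  keep <- apply_exclusions(tr, analysis_config(subset_rule = "all"))$retained
  bs <- trial_bin_stats(rec, keep)
  fs <- rec$sample_rate
  idx <- function(t) as.integer(round(t * fs)) + 1L
  for (r in sample(nrow(bs), min(nrow(bs), 8))) {
    row <- bs[r, ]
    tri <- keep[keep$trial_index == row$trial_index, ]
    ch <- if (row$axis_role == "ap_control") rec$axis_map$ap_control
          else rec$axis_map$ml_control
    x <- rec$data[[ch]]
    fixw <- idx(tri$fixation_onset_s):(idx(tri$target_onset_s) - 1L)
    anchor <- if (row$bin == "post_target") idx(tri$target_onset_s)
              else idx(tri$response_onset_s)
    w <- extract_bin(x - mean(x[fixw]), anchor, row$bin, fs, 150)
    ref <- compute_bin_stats(w, axis_role = row$axis_role,
                             response_side = tri$response_side)
    expect_equal(row$sd, ref$sd, tolerance = 1e-12)
    expect_equal(row$av_abs, ref$av_abs, tolerance = 1e-12)
    expect_equal(row$ml_recoded_mean, ref$ml_recoded_mean, tolerance = 1e-12)
  }
})

test_that("condition aggregation averages per-trial values unweighted", {
  bs <- tibble::tibble(
    participant = 1L, block = 1L, trial_index = 1:2,
    congruency = "congruent", prev_congruency = "congruent",
    axis_role = "ml_control", bin = "pre_response",
    mean_raw = c(0.1, 0.2), ml_recoded_mean = c(0.1, 0.2),
    av_abs = c(0.1, 0.2), sd = c(1, exp(0.2)),
    log_av = log(c(0.1, 0.2)), log_sd = c(0, 0.2),
    floored_av = FALSE, floored_sd = FALSE, n_samples = 38L
  )
  agg <- aggregate_by_condition(bs, analysis_config())
  expect_equal(nrow(agg), 1)
  expect_equal(agg$log_sd, 0.1)
  expect_equal(agg$n_trials, 2L)
  # aggregation of a single trial reproduces that trial
  agg1 <- aggregate_by_condition(bs[1, ], analysis_config())
  expect_equal(agg1$log_sd, bs$log_sd[1])
  expect_equal(agg1$av_abs, bs$av_abs[1])
  # cell-first transform order logs the raw cell mean instead
  agg2 <- aggregate_by_condition(bs, analysis_config(transform_order = "cell"))
  expect_equal(agg2$log_sd, log(mean(bs$sd) + 1e-12))
})
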