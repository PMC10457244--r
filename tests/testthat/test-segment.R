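segmented_session <- function(seed = 21, trials_per_block = 8, blocks = 2) {
  set.seed(seed)
  spec <- session_spec(n_participants = 1, n_blocks = blocks,
                       trials_per_block = trials_per_block,
                       sample_rate = 250)
  sess <- simulate_session(spec)
  list(spec = spec, sess = sess)
}

test_that("previous-trial congruency follows the block sequence", {
  x <- segmented_session()
  for (b in seq_len(x$spec$n_blocks)) {
    rec <- x$sess$recordings[[as.character(b)]]
    tb <- x$sess$trials[x$sess$trials$block == b, ]
    ev <- decode_trigger_events(rec)
    tr <- segment_and_label(rec, ev, participant = 1L, block = b)
    expect_equal(tr$prev_congruency[1], "undefined")
    expect_true(tr$first_in_block[1])
    expect_false(any(tr$first_in_block[-1]))
    k <- nrow(tr)
    expect_equal(tr$prev_congruency[2:k], tr$congruency[1:(k - 1)])
  }
})

test_that("trial durations and segments are consistent with events", {
  x <- segmented_session(seed = 31)
  rec <- x$sess$recordings[["1"]]
  tb <- x$sess$trials[x$sess$trials$block == 1, ]
  ev <- decode_trigger_events(rec)
  tr <- segment_and_label(rec, ev,
                          behavior = tb[, c("trial_index", "correct",
                                            "response_side")])
  # responded trials: duration = rt + 750 ms envelope
  ok <- tr$responded
  expect_equal(tr$duration_s[ok], tr$rt_ms[ok] / 1000 + 0.75,
               tolerance = 1 / x$spec$sample_rate)
  expect_true(all(tr$seg_start >= 1 & tr$seg_end <= nrow(rec$data)))
  expect_true(all(tr$seg_end > tr$seg_start))
  # merged behavioural labels survive
  expect_equal(tr$correct, tb$correct)
  expect_equal(tr$response_side, tb$response_side)
})

test_that("trials without a response are flagged unresponsive", {
  trials <- make_trials(correct = c(TRUE, NA, TRUE),
                        rt_ms = c(400, NA, 500),
                        responded = c(TRUE, FALSE, TRUE))
  trials$duration_s <- c(1.15, 2.25, 1.25)
  out <- label_trial_flags(trials)
  expect_equal(out$unresponsive, c(FALSE, TRUE, FALSE))
  excl <- apply_exclusions(trials)
  expect_equal(excl$summary$count[excl$summary$reason == "unresponsive"], 1L)
})

test_that("the toy block excludes by precedence: error, post-error, slow RT", {
  trials <- make_trials(correct = c(TRUE, FALSE, TRUE, TRUE, TRUE),
                        rt_ms = c(420, 510, 430, 1300, 450))
  excl <- apply_exclusions(trials)
  expect_equal(excl$retained$trial_index, c(1L, 5L))
  expect_equal(excl$trials$reason,
               c("retained", "error", "post_error", "slow_rt", "retained"))
})

test_that("an error on the final trial leaves no post-error trial", {
  trials <- make_trials(correct = c(TRUE, TRUE, FALSE),
                        rt_ms = c(400, 420, 410))
  excl <- apply_exclusions(trials)
  expect_equal(excl$retained$trial_index, c(1L, 2L))
  expect_equal(sum(excl$trials$post_error), 0L)
})

test_that("a trial after an unresponsive trial is not post-error", {
  trials <- make_trials(correct = c(TRUE, NA, TRUE),
                        rt_ms = c(400, NA, 410),
                        responded = c(TRUE, FALSE, TRUE))
  out <- label_trial_flags(trials)
  expect_false(out$post_error[3])
})

test_that("ten correct fast trials are all retained", {
  trials <- make_trials(correct = rep(TRUE, 10), rt_ms = rep(450, 10))
  excl <- apply_exclusions(trials)
  expect_equal(nrow(excl$retained), 10L)
  expect_equal(excl$summary$proportion[excl$summary$reason == "retained"], 1)
})

test_that("exclusion counts always partition the total", {
  for (seed in c(2, 5)) {
    trials <- simulate_behavior_study(
      session_spec(n_participants = 3, n_blocks = 2, trials_per_block = 40),
      seed = seed
    )
    excl <- apply_exclusions(trials)
    expect_equal(sum(excl$summary$count), nrow(trials))
    expect_equal(sum(excl$summary$proportion), 1)
    # one reason per trial by construction of the precedence chain
    expect_true(all(table(excl$trials$reason) ==
                      excl$summary$count[match(names(table(excl$trials$reason)),
                                               excl$summary$reason)]))
  }
})

test_that("the post-congruent subset rule filters the sway trials", {
  trials <- make_trials(correct = rep(TRUE, 6), rt_ms = rep(400, 6),
                        congruency = c("congruent", "incongruent", "congruent",
                                       "congruent", "incongruent",
                                       "incongruent"))
  excl <- apply_exclusions(trials, analysis_config())
  expect_true(all(excl$sway_trials$prev_congruency == "congruent"))
  expect_equal(excl$sway_trials$trial_index, c(2L, 4L, 5L))
  all_cfg <- analysis_config(subset_rule = "all")
  expect_equal(nrow(apply_exclusions(trials, all_cfg)$sway_trials), 6L)
  # empty input stays empty with zeroed summary
  empty <- apply_exclusions(trials[0, ], analysis_config())
  expect_equal(nrow(empty$retained), 0L)
  expect_true(all(empty$summary$count == 0L))
})
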