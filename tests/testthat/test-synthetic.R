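test_that("the default schedule has 800 trials and a 750 ms response-target interval", {
  set.seed(1)
  spec <- session_spec(n_participants = 1)
  plan <- generate_schedule(spec)
  expect_equal(nrow(plan), 800)
  trials <- sample_behavior(plan, rt_model_config(), spec)
  # within a block, the next target follows each response by exactly 750 ms
  for (b in c(1, 5, 10)) {
    tb <- trials[trials$block == b, ]
    k <- nrow(tb)
    gap <- tb$target_onset_s[2:k] -
      ifelse(tb$responded[1:(k - 1)], tb$response_onset_s[1:(k - 1)],
             tb$target_onset_s[1:(k - 1)] + 1.5)
    expect_true(all(abs(gap - 0.75) < 1e-9))
  }
})

test_that("congruent trials occur at the uniform rate", {
  set.seed(2)
  plan <- generate_schedule(session_spec(n_participants = 1))
  p_hat <- mean(plan$congruency == "congruent")
  # binomial 99% band around 0.5 at n = 800
  expect_lt(abs(p_hat - 0.5), 2.576 * sqrt(0.25 / 800))
})

test_that("a congruency-blind RT model yields a null Simon effect", {
  flat <- rt_model_config(
    rt_mean_ms = c(cc = 459, ci = 459, ic = 459, ii = 459),
    error_prob = c(cc = 0.059, ci = 0.059, ic = 0.059, ii = 0.059)
  )
  spec <- session_spec(n_participants = 16)
  trials <- simulate_behavior_study(spec, flat, seed = 4)
  eff <- behavior_contrasts(apply_exclusions(trials))$effects
  rt_eff <- eff[eff$measure == "rt_ms", ]
  # |effect| < 3 SEM is |t| < 3
  expect_true(all(abs(rt_eff$t) < 3))
})

test_that("behaviour generation is reproducible under a seed", {
  spec <- session_spec(n_participants = 2, n_blocks = 2, trials_per_block = 10)
  t1 <- simulate_behavior_study(spec, seed = 77)
  t2 <- simulate_behavior_study(spec, seed = 77)
  expect_identical(t1, t2)
  t3 <- simulate_behavior_study(spec, seed = 78)
  expect_false(identical(t1$rt_ms, t3$rt_ms))
})

test_that("unresponsive trials arise from timeout-reaching reaction times", {
  slow <- rt_model_config(slow_prob = 0.5, slow_tail_mean_ms = 400)
  spec <- session_spec(n_participants = 1, n_blocks = 1, trials_per_block = 60)
  set.seed(5)
  trials <- sample_behavior(generate_schedule(spec), slow, spec)
  expect_gt(sum(!trials$responded), 0)
  expect_true(all(is.na(trials$rt_ms[!trials$responded])))
  expect_true(all(trials$response_side[!trials$responded] == "none"))
  expect_true(all(trials$rt_ms[trials$responded] < 1500))
})

test_that("pipeline trial labels match the generator's ground truth exactly", {
  set.seed(12)
  spec <- session_spec(n_participants = 1, n_blocks = 2, trials_per_block = 15,
                       sample_rate = 250)
  sess <- simulate_session(spec)
  for (b in 1:2) {
    truth <- sess$trials[sess$trials$block == b, ]
    rec <- sess$recordings[[as.character(b)]]
    res <- analyze_block(rec, behavior = truth[, c("trial_index", "correct",
                                                   "response_side")],
                         block = b)
    got <- res$trials
    expect_equal(nrow(got), nrow(truth))
    expect_equal(got$congruency, truth$congruency)
    expect_equal(got$prev_congruency, truth$prev_congruency)
    expect_equal(got$correct, truth$correct)
    expect_equal(got$responded, truth$responded)
    ok <- truth$responded
    expect_lte(max(abs(got$rt_ms[ok] - truth$rt_ms[ok])),
               1000 / spec$sample_rate)
  }
})

test_that("recovered SD reduction increases monotonically with the injected delta", {
  spec <- session_spec(n_participants = 20, n_blocks = 3, trials_per_block = 30,
                       sample_rate = 125)
  reduction <- sapply(c(0, 0.07, 0.14, 0.28), function(d) {
    res <- run_study(spec = spec, sway = sway_model_config(delta = d),
                     seed = 61)
    agg <- res$aggregates
    w <- tidyr::pivot_wider(
      agg[agg$axis_role == "ml_control" & agg$bin == "pre_response",
          c("participant", "congruency", "sd")],
      names_from = "congruency", values_from = "sd")
    w <- w[stats::complete.cases(w), ]
    100 * mean(1 - w$incongruent / w$congruent)
  })
  expect_equal(cor(reduction, c(0, 0.07, 0.14, 0.28), method = "spearman"), 1)
  expect_true(all(diff(reduction) > 0))
})

test_that("with no injection and a flat gain profile sway is congruency-blind", {
  spec <- session_spec(n_participants = 16, n_blocks = 2, trials_per_block = 25,
                       sample_rate = 125)
  null_sway <- sway_model_config(delta = 0, gamma_target = 1,
                                 gamma_response = 1)
  res <- run_study(spec = spec, sway = null_sway, seed = 71)
  agg <- res$aggregates
  w <- tidyr::pivot_wider(
    agg[agg$axis_role == "ml_control" & agg$bin == "pre_response",
        c("participant", "congruency", "sd")],
    names_from = "congruency", values_from = "sd")
  w <- w[stats::complete.cases(w), ]
  d <- w$incongruent - w$congruent
  sem <- sd(d) / sqrt(length(d))
  expect_lt(abs(mean(d)), 3 * sem)
})

test_that("a written dataset is byte-identical under the same seed", {
  spec <- session_spec(n_participants = 1, n_blocks = 1, trials_per_block = 5,
                       sample_rate = 125)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_dataset(d1, spec, seed = 9)
  simulate_dataset(d2, spec, seed = 9)
  f1 <- list.files(d1, recursive = TRUE)
  expect_setequal(f1, list.files(d2, recursive = TRUE))
  for (f in setdiff(f1, "manifest.yml")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})

test_that("a minimal session runs end-to-end without error", {
  spec <- session_spec(n_participants = 1, n_blocks = 1, trials_per_block = 4,
                       sample_rate = 125)
  res <- run_study(spec = spec, seed = 3)
  expect_s3_class(res$aggregates, "tbl_df")
  expect_equal(sum(res$exclusions$count), 4L)
})
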