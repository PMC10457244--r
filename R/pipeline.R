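#' Analyse one block recording
#'
#' The per-block analysis chain: filter the controlling moment channels,
#' decode trigger events, segment into labelled trials (merging behavioural
#' correctness when supplied), apply the exclusion rules, and compute bin
#' statistics for the sway-analysis subset.
#'
#' @param rec An [fp_recording()].
#' @param behavior Optional behavioural tibble for this block (columns
#'   `trial_index`, `correct`, `response_side`).
#' @param config An [analysis_config()].
#' @param participant,block Labels stamped onto the rows.
#' @param timeout_s Response timeout used when decoding trigger pulses.
#' @return A list with `trials` (labelled, with exclusion reasons) and
#'   `bin_stats` (sway subset only).
#' @export
analyze_block <- function(rec, behavior = NULL, config = analysis_config(),
                          participant = 1L, block = 1L, timeout_s = 1.5) {
  filtered <- filter_recording(rec, config)
  events <- decode_trigger_events(filtered, timeout_s = timeout_s)
  trials <- segment_and_label(filtered, events, behavior = behavior,
                              config = config, participant = participant,
                              block = block)
  excl <- apply_exclusions(trials, config)
  bins <- trial_bin_stats(filtered, excl$sway_trials, config)
  list(trials = excl$trials, bin_stats = bins)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate and analyse a complete synthetic study in memory
#'
#' Generates every participant's session (schedule, behaviour, sway
#' recordings) and immediately runs the analysis chain block by block, so a
#' full study never has to be held in memory at once. Returns the pipeline's
#' own trial table (recovered from the encoded triggers, not the generator's
#' ground truth), the exclusion summary, per-trial bin statistics,
#' participant condition aggregates, the sway contrasts and the behavioural
#' contrasts.
#'
#' @param spec A [session_spec()].
#' @param rt_model An [rt_model_config()].
#' @param sway A [sway_model_config()].
#' @param config An [analysis_config()].
#' @param seed Integer seed; participant sub-seeds are split off it.
#' @param axis_map An [axis_map()].
#' @return A list of class `study_result`: `trials`, `exclusions`,
#'   `bin_stats`, `aggregates`, `contrasts`, `behavior`.
#' @export
run_study <- function(spec = session_spec(),
                      rt_model = rt_model_config(),
                      sway = sway_model_config(),
                      config = analysis_config(),
                      seed = 1L,
                      axis_map = swaybins::axis_map()) {
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max, spec$n_participants)
  all_trials <- vector("list", spec$n_participants)
  all_bins <- vector("list", spec$n_participants)
  for (p in seq_len(spec$n_participants)) {
    set.seed(sub_seeds[p])
    plan <- generate_schedule(spec, participant = p)
    truth <- sample_behavior(plan, rt_model, spec)
    p_trials <- vector("list", spec$n_blocks)
    p_bins <- vector("list", spec$n_blocks)
    for (b in seq_len(spec$n_blocks)) {
      tb <- truth[truth$block == b, ]
      rec <- simulate_sway_block(tb, sway, spec, axis_map)
      res <- analyze_block(rec, behavior = tb[, c("trial_index", "correct",
                                                  "response_side")],
                           config = config, participant = p, block = b)
      p_trials[[b]] <- res$trials
      p_bins[[b]] <- res$bin_stats
    }
    all_trials[[p]] <- dplyr::bind_rows(p_trials)
    all_bins[[p]] <- dplyr::bind_rows(p_bins)
  }
  trials <- dplyr::bind_rows(all_trials)
  bin_stats <- dplyr::bind_rows(all_bins)
  excl <- apply_exclusions(trials, config)
  aggregates <- aggregate_by_condition(bin_stats, config)
  contrasts <- run_contrasts(aggregates, config)
  behavior <- behavior_contrasts(excl, config)
  structure(
    list(trials = excl$trials, exclusions = excl$summary,
         bin_stats = bin_stats, aggregates = aggregates,
         contrasts = contrasts, behavior = behavior),
    class = "study_result"
  )
}

#' @export
print.study_result <- function(x, ...) {
  cat("<study_result>\n")
  cat(sprintf("  %d trials, %d bin-stat rows, %d aggregate cells\n",
              nrow(x$trials), nrow(x$bin_stats), nrow(x$aggregates)))
  print(x$exclusions)
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' Dataset layout: one TSV recording per participant and block
#' (`recordings/p<participant>_b<block>.tsv`), the ground-truth trial table
#' (`trials.csv`), a YAML snapshot of the generator configuration
#' (`config.yml`) and a run manifest (`manifest.yml`). Outputs are
#' reproducible: the same seed yields identical files.
#'
#' @param dir Output directory (created if missing).
#' @param spec A [session_spec()].
#' @param rt_model An [rt_model_config()].
#' @param sway A [sway_model_config()].
#' @param seed Integer seed.
#' @param axis_map An [axis_map()].
#' @return The manifest (invisibly), also written to `manifest.yml`.
#' @export
simulate_dataset <- function(dir, spec = session_spec(),
                             rt_model = rt_model_config(),
                             sway = sway_model_config(),
                             seed = 1L,
                             axis_map = swaybins::axis_map()) {
  dir.create(file.path(dir, "recordings"), recursive = TRUE,
             showWarnings = FALSE)
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max, spec$n_participants)
  all_trials <- vector("list", spec$n_participants)
  for (p in seq_len(spec$n_participants)) {
    set.seed(sub_seeds[p])
    plan <- generate_schedule(spec, participant = p)
    truth <- sample_behavior(plan, rt_model, spec)
    for (b in seq_len(spec$n_blocks)) {
      tb <- truth[truth$block == b, ]
      rec <- simulate_sway_block(tb, sway, spec, axis_map)
      write_recording(rec, file.path(dir, "recordings",
                                     sprintf("p%03d_b%02d.tsv", p, b)))
    }
    all_trials[[p]] <- truth
  }
  trials <- dplyr::bind_rows(all_trials)
  write_trial_table(trials, file.path(dir, "trials.csv"))
  yaml::write_yaml(
    list(session = unclass(spec), rt_model = lapply(unclass(rt_model), as.list),
         sway = unclass(sway), axis_map = unclass(axis_map), seed = seed),
    file.path(dir, "config.yml")
  )
  manifest <- list(
    stage = "simulate", seed = seed,
    software = paste("swaybins", as.character(utils::packageVersion("swaybins"))),
    n_participants = spec$n_participants,
    n_recordings = spec$n_participants * spec$n_blocks,
    n_trials = nrow(trials)
  )
  yaml::write_yaml(manifest, file.path(dir, "manifest.yml"))
  invisible(manifest)
}

#' Analyse an on-disk dataset
#'
#' Reads every recording in the documented layout, runs the per-block
#' analysis chain, and writes the result tables: `bin_stats.csv`,
#' `aggregates.csv`, `contrasts.csv`, `exclusions.csv`,
#' `behavior_effects.csv`, and an analysis manifest recording the trial
#' accounting (the per-reason counts always partition the total).
#'
#' @param dir Dataset directory (from [simulate_dataset()] or equivalent).
#' @param out Output directory (default `file.path(dir, "results")`).
#' @param config An [analysis_config()].
#' @param axis_map An [axis_map()].
#' @return A `study_result` (invisibly).
#' @export
analyze_dataset <- function(dir, out = file.path(dir, "results"),
                            config = analysis_config(),
                            axis_map = swaybins::axis_map()) {
  rec_dir <- file.path(dir, "recordings")
  truth_path <- file.path(dir, "trials.csv")
  if (!dir.exists(rec_dir) || !file.exists(truth_path)) {
    stop("dataset layout violation: expected `recordings/` and `trials.csv` in ",
         dir, call. = FALSE)
  }
  truth <- read_trial_table(truth_path)
  files <- sort(list.files(rec_dir, pattern = "^p\\d+_b\\d+\\.tsv$"))
  if (length(files) == 0) {
    stop("dataset layout violation: no recordings matching p<i>_b<j>.tsv",
         call. = FALSE)
  }
  all_trials <- list()
  all_bins <- list()
  for (f in files) {
    m <- regmatches(f, regexec("^p(\\d+)_b(\\d+)\\.tsv$", f))[[1]]
    p <- as.integer(m[2])
    b <- as.integer(m[3])
    rec <- tryCatch(
      read_recording(file.path(rec_dir, f), axis_map = axis_map,
                     block_id = as.character(b)),
      error = function(e) {
        stop("invalid recording `", f, "`: ", conditionMessage(e),
             call. = FALSE)
      }
    )
    beh <- truth[truth$participant == p & truth$block == b,
                 c("trial_index", "correct", "response_side")]
    res <- analyze_block(rec, behavior = if (nrow(beh)) beh else NULL,
                         config = config, participant = p, block = b)
    all_trials[[f]] <- res$trials
    all_bins[[f]] <- res$bin_stats
  }
  trials <- dplyr::bind_rows(all_trials)
  bin_stats <- dplyr::bind_rows(all_bins)
  excl <- apply_exclusions(trials, config)
  aggregates <- aggregate_by_condition(bin_stats, config)
  contrasts <- run_contrasts(aggregates, config)
  behavior <- behavior_contrasts(excl, config)

  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(as.data.frame(bin_stats),
                   file.path(out, "bin_stats.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(aggregates),
                   file.path(out, "aggregates.csv"), row.names = FALSE)
  write_contrasts(contrasts, file.path(out, "contrasts.csv"))
  write_exclusion_summary(excl, file.path(out, "exclusions.csv"))
  if (!is.null(behavior$effects)) {
    utils::write.csv(as.data.frame(behavior$effects),
                     file.path(out, "behavior_effects.csv"),
                     row.names = FALSE)
  }
  counts <- stats::setNames(as.list(excl$summary$count), excl$summary$reason)
  manifest <- list(
    stage = "analyze",
    software = paste("swaybins", as.character(utils::packageVersion("swaybins"))),
    config = unclass(config),
    n_recordings = length(files),
    trials_total = nrow(trials),
    trials_by_reason = counts,
    sway_trials = nrow(excl$sway_trials),
    bins_dropped_out_of_range = attr(bin_stats, "dropped") %||% 0L
  )
  yaml::write_yaml(manifest, file.path(out, "manifest.yml"))
  res <- structure(
    list(trials = excl$trials, exclusions = excl$summary,
         bin_stats = bin_stats, aggregates = aggregates,
         contrasts = contrasts, behavior = behavior, manifest = manifest),
    class = "study_result"
  )
  invisible(res)
}
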