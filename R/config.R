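#' Analysis configuration
#'
#' Bundles every tunable parameter of the analysis chain. Defaults follow the
#' standard event-related posturography setup: a 4th-order (per pass)
#' dual-pass Butterworth low-pass at 10 Hz, 150 ms bins, a 1250 ms reaction
#' time cutoff, a 2 s trial-duration ("unresponsive") cutoff, and a 0.01
#' alpha level for the sway contrasts.
#'
#' @param filter_order Butterworth order per pass (the forward-backward
#'   application doubles the effective order).
#' @param cutoff_hz Low-pass cutoff frequency in Hz.
#' @param bin_ms Bin duration in milliseconds.
#' @param rt_max_ms Correct responses at or above this reaction time (ms) are
#'   excluded as slow.
#' @param trial_max_s Trials whose full duration exceeds this (seconds) are
#'   labelled unresponsive.
#' @param alpha Significance level for sway contrasts.
#' @param log_epsilon Floor added before taking natural logs, in N·m.
#' @param subset_rule `"post_congruent_only"` restricts the sway analysis to
#'   trials following a congruent trial; `"all"` keeps every retained trial.
#' @param transform_order `"trial"` log-transforms per trial before averaging
#'   within a participant cell (default); `"cell"` averages raw values per
#'   cell first and logs the cell mean.
#'
#' @return An object of class `analysis_config` (a named list).
#' @export
analysis_config <- function(filter_order = 4,
                            cutoff_hz = 10,
                            bin_ms = 150,
                            rt_max_ms = 1250,
                            trial_max_s = 2.0,
                            alpha = 0.01,
                            log_epsilon = 1e-12,
                            subset_rule = c("post_congruent_only", "all"),
                            transform_order = c("trial", "cell")) {
  subset_rule <- match.arg(subset_rule)
  transform_order <- match.arg(transform_order)
  stopifnot(filter_order >= 1, cutoff_hz > 0, bin_ms > 0,
            trial_max_s > 0, alpha > 0, alpha < 1, log_epsilon > 0)
  if (rt_max_ms >= trial_max_s * 1000) {
    stop("`rt_max_ms` must be smaller than `trial_max_s` * 1000", call. = FALSE)
  }
  structure(
    list(filter_order = as.integer(filter_order), cutoff_hz = cutoff_hz,
         bin_ms = bin_ms, rt_max_ms = rt_max_ms, trial_max_s = trial_max_s,
         alpha = alpha, log_epsilon = log_epsilon, subset_rule = subset_rule,
         transform_order = transform_order),
    class = "analysis_config"
  )
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("<analysis_config>\n")
  for (nm in names(x)) cat(sprintf("  %-16s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Read / write an analysis configuration
#'
#' The on-disk representation is a flat YAML mapping whose keys mirror the
#' arguments of [analysis_config()].
#'
#' @param path File path.
#' @return `read_analysis_config()` returns an `analysis_config`;
#'   `write_analysis_config()` returns `path` invisibly.
#' @export
read_analysis_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(analysis_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(analysis_config, vals)
}

#' @rdname read_analysis_config
#' @param config An `analysis_config`.
#' @export
write_analysis_config <- function(config, path) {
  stopifnot(inherits(config, "analysis_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Map moment channels to the sway direction they control
#'
#' Force plates label moment channels by plate axis, but the analysis
#' addresses them by the sway direction they govern: the moment about the
#' mediolateral plate axis controls anteroposterior (AP) sway, and the moment
#' about the anteroposterior plate axis controls mediolateral (ML) sway. An
#' `axis_map` makes this assignment explicit instead of hard-coding a plate
#' convention.
#'
#' @param ap_control Channel name whose moment governs AP sway (default
#'   `"mx"`).
#' @param ml_control Channel name whose moment governs ML sway (default
#'   `"my"`).
#' @param positive_ml_direction Physical direction of a positive ML-control
#'   moment, `"rightward"` or `"leftward"`. Used for recoding the signed ML
#'   mean towards the response side.
#'
#' @return An object of class `axis_map`.
#' @export
axis_map <- function(ap_control = "mx", ml_control = "my",
                     positive_ml_direction = c("rightward", "leftward")) {
  positive_ml_direction <- match.arg(positive_ml_direction)
  stopifnot(is.character(ap_control), length(ap_control) == 1,
            is.character(ml_control), length(ml_control) == 1)
  if (identical(ap_control, ml_control)) {
    stop("`ap_control` and `ml_control` must name distinct channels",
         call. = FALSE)
  }
  structure(list(ap_control = ap_control, ml_control = ml_control,
                 positive_ml_direction = positive_ml_direction),
            class = "axis_map")
}

#' @export
print.axis_map <- function(x, ...) {
  cat("<axis_map> AP sway <- ", x$ap_control,
      ", ML sway <- ", x$ml_control,
      " (positive = ", x$positive_ml_direction, ")\n", sep = "")
  invisible(x)
}
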