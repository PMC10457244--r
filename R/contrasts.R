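#' Run the standard congruency contrasts on aggregated sway parameters
#'
#' For each axis role (AP-/ML-controlling moment) and parameter (log AV,
#' log SD):
#' * target-aligned: paired t test congruent vs incongruent in the
#'   `post_target` bin;
#' * response-aligned: 2 x 2 within-subject ANOVA with time bin
#'   (`pre_response` / `post_response`) and congruency as factors, plus
#'   follow-up paired t tests per bin. Follow-ups are always computed but
#'   flagged `protected` only when the omnibus interaction passes
#'   `config$alpha`;
#' * bin modulation: one-way ANOVA over the three bins, congruency pooled.
#'
#' Participants missing any required cell are removed listwise per analysis.
#'
#' @param aggregates Output of [aggregate_by_condition()] (post-congruent
#'   subset when the configuration requests it).
#' @param config An [analysis_config()].
#'
#' @return A tibble, one row per effect: `analysis`, `axis_role`,
#'   `parameter`, `effect`, `statistic`, `df_num`, `df_den`, `p`,
#'   `effect_size`, `n`, `significant`, `protected`.
#' @export
run_contrasts <- function(aggregates, config = analysis_config()) {
  if (nrow(aggregates) == 0) return(empty_contrast_table())
  out <- list()
  for (role in unique(aggregates$axis_role)) {
    for (param in c("log_av", "log_sd")) {
      sub <- aggregates[aggregates$axis_role == role,
                        c("participant", "bin", "congruency", param)]
      names(sub)[4] <- "value"

      tw <- .complete_wide(sub[sub$bin == "post_target", ])
      if (!is.null(tw)) {
        tt <- paired_t(tw$congruent, tw$incongruent)
        out[[length(out) + 1]] <- .contrast_row(
          "target_aligned", role, param, "congruency", tt, config)
      }

      resp <- sub[sub$bin %in% c("pre_response", "post_response"), ]
      cells <- .complete_cells(resp)
      if (!is.null(cells)) {
        an <- rm_anova(
          data.frame(participant = cells$participant, a = cells$bin,
                     b = cells$congruency, value = cells$value),
          design = "2x2")
        eff_names <- c(a = "bin", b = "congruency", `a:b` = "bin:congruency")
        inter_p <- an$p[an$effect == "a:b"]
        for (i in seq_len(nrow(an))) {
          out[[length(out) + 1]] <- tibble::tibble(
            analysis = "response_aligned", axis_role = role,
            parameter = param, effect = unname(eff_names[an$effect[i]]),
            statistic = an$F[i], df_num = an$df_num[i], df_den = an$df_den[i],
            p = an$p[i], effect_size = an$partial_eta_sq[i], n = an$n[i],
            significant = an$p[i] < config$alpha, protected = NA
          )
        }
        for (b in c("pre_response", "post_response")) {
          bw <- .complete_wide(cells[cells$bin == b, ])
          if (is.null(bw)) next
          tt <- paired_t(bw$congruent, bw$incongruent)
          row <- .contrast_row("response_aligned_followup", role, param,
                               paste0("congruency@", b), tt, config)
          row$protected <- inter_p < config$alpha
          out[[length(out) + 1]] <- row
        }
      }

      pooled <- dplyr::summarise(
        dplyr::group_by(sub, .data$participant, .data$bin),
        value = mean(.data$value), k = dplyr::n(), .groups = "drop")
      pooled <- pooled[pooled$k == 2, c("participant", "bin", "value")]
      counts <- table(pooled$participant)
      keep <- names(counts)[counts == 3]
      pooled <- pooled[pooled$participant %in% keep, ]
      if (length(keep) >= 2) {
        an <- rm_anova(
          data.frame(participant = pooled$participant, a = pooled$bin,
                     value = pooled$value),
          design = "oneway")
        out[[length(out) + 1]] <- tibble::tibble(
          analysis = "bin_modulation", axis_role = role, parameter = param,
          effect = "bin", statistic = an$F, df_num = an$df_num,
          df_den = an$df_den, p = an$p, effect_size = an$partial_eta_sq,
          n = an$n, significant = an$p < config$alpha, protected = NA
        )
      }
    }
  }
  if (length(out) == 0) return(empty_contrast_table())
  dplyr::bind_rows(out)
}

.contrast_row <- function(analysis, role, param, effect, tt, config) {
  tibble::tibble(
    analysis = analysis, axis_role = role, parameter = param, effect = effect,
    statistic = tt$t, df_num = tt$df, df_den = NA_real_, p = tt$p,
    effect_size = tt$dz, n = tt$n, significant = tt$p < config$alpha,
    protected = NA
  )
}

# wide congruent/incongruent per participant; NULL unless >= 3 complete pairs
.complete_wide <- function(long) {
  if (nrow(long) == 0) return(NULL)
  w <- tidyr::pivot_wider(long[, c("participant", "congruency", "value")],
                          names_from = "congruency", values_from = "value")
  if (!all(.congruency_levels %in% names(w))) return(NULL)
  w <- w[stats::complete.cases(w[, .congruency_levels]), ]
  if (nrow(w) < 3) return(NULL)
  w
}

# participants with all 4 bin x congruency cells
.complete_cells <- function(long) {
  if (nrow(long) == 0) return(NULL)
  counts <- table(long$participant)
  keep <- names(counts)[counts == 4]
  if (length(keep) < 2) return(NULL)
  long[long$participant %in% keep, , drop = FALSE]
}

empty_contrast_table <- function() {
  tibble::tibble(
    analysis = character(), axis_role = character(), parameter = character(),
    effect = character(), statistic = numeric(), df_num = numeric(),
    df_den = numeric(), p = numeric(), effect_size = numeric(),
    n = integer(), significant = logical(), protected = logical()
  )
}

#' Behavioural Simon and congruency-sequence contrasts
#'
#' Computes, per participant, mean reaction times on retained trials and
#' error proportions on responded trials, in congruency x previous-trial
#' congruency cells (first-in-block trials, whose previous congruency is
#' undefined, are omitted). Reports the congruency effect split by
#' previous-trial congruency (the congruency-sequence structure) with paired
#' t tests, and a 2 x 2 within-subject ANOVA for each measure.
#'
#' @param excl An `exclusion_result` from [apply_exclusions()] (or a trial
#'   tibble, in which case exclusions are applied with `config`).
#' @param config An [analysis_config()].
#'
#' @return A list with `cells` (participant x cell means), `effects`
#'   (per-split congruency effects: mean difference, paired t, dz), and
#'   `anova` (2 x 2 results per measure). RT differences are
#'   incongruent - congruent in ms; error differences are
#'   incongruent - congruent in percentage points.
#' @export
behavior_contrasts <- function(excl, config = analysis_config()) {
  if (!inherits(excl, "exclusion_result")) {
    excl <- apply_exclusions(excl, config)
  }
  rt_cells <- excl$retained |>
    dplyr::filter(.data$prev_congruency != "undefined") |>
    dplyr::group_by(.data$participant, .data$prev_congruency,
                    .data$congruency) |>
    dplyr::summarise(value = mean(.data$rt_ms), n_trials = dplyr::n(),
                     .groups = "drop") |>
    dplyr::mutate(measure = "rt_ms")
  err_cells <- excl$trials |>
    dplyr::filter(!.data$unresponsive,
                  .data$prev_congruency != "undefined") |>
    dplyr::group_by(.data$participant, .data$prev_congruency,
                    .data$congruency) |>
    dplyr::summarise(value = 100 * mean(.data$error), n_trials = dplyr::n(),
                     .groups = "drop") |>
    dplyr::mutate(measure = "error_pct")
  cells <- dplyr::bind_rows(rt_cells, err_cells)

  effects <- list()
  anovas <- list()
  for (ms in unique(cells$measure)) {
    sub <- cells[cells$measure == ms, ]
    for (prev in .congruency_levels) {
      w <- .complete_wide(sub[sub$prev_congruency == prev,
                              c("participant", "congruency", "value")])
      if (is.null(w)) next
      # error proportions can tie across a whole small sample; skip the
      # degenerate contrast rather than fail the bundle
      tt <- tryCatch(paired_t(w$incongruent, w$congruent),
                     error = function(e) NULL)
      if (is.null(tt)) next
      effects[[length(effects) + 1]] <- tibble::tibble(
        measure = ms, prev_congruency = prev,
        effect_incongruent_minus_congruent = tt$mean_diff,
        t = tt$t, df = tt$df, p = tt$p, dz = tt$dz, n = tt$n
      )
    }
    cc <- .complete_cells(
      data.frame(participant = sub$participant, bin = sub$prev_congruency,
                 congruency = sub$congruency, value = sub$value))
    if (!is.null(cc)) {
      an <- rm_anova(
        data.frame(participant = cc$participant, a = cc$bin,
                   b = cc$congruency, value = cc$value),
        design = "2x2")
      an$effect <- c("prev_congruency", "congruency",
                     "prev_congruency:congruency")
      an$measure <- ms
      anovas[[length(anovas) + 1]] <- an
    }
  }
  list(
    cells = cells,
    effects = if (length(effects)) dplyr::bind_rows(effects) else NULL,
    anova = if (length(anovas)) dplyr::bind_rows(anovas) else NULL
  )
}

#' Write a contrast table as CSV
#' @param contrasts Tibble from [run_contrasts()].
#' @param path File path.
#' @export
write_contrasts <- function(contrasts, path) {
  utils::write.csv(as.data.frame(contrasts), path, row.names = FALSE)
  invisible(path)
}
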