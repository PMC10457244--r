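#' Paired t test with the dz effect size
#'
#' Standard two-sided paired t test between two per-participant vectors,
#' reporting the paired-samples effect size `dz = mean(diff) / sd(diff)`
#' (which satisfies `dz * sqrt(n) = t`).
#'
#' @param a,b Numeric vectors of per-participant values, paired by position,
#'   no missing values, length >= 3.
#' @return A list of class `ttest_result`: `t`, `df`, `p`, `dz`,
#'   `mean_diff`, `n`.
#' @export
paired_t <- function(a, b) {
  stopifnot(is.numeric(a), is.numeric(b))
  if (length(a) != length(b)) {
    stop("`a` and `b` must have equal length (paired by participant)",
         call. = FALSE)
  }
  if (anyNA(a) || anyNA(b)) stop("missing values not allowed", call. = FALSE)
  n <- length(a)
  if (n < 3) stop("need at least 3 pairs", call. = FALSE)
  d <- a - b
  sdd <- stats::sd(d)
  if (sdd == 0) {
    stop("degenerate variance: all paired differences identical",
         call. = FALSE)
  }
  ht <- stats::t.test(a, b, paired = TRUE)
  structure(
    list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value,
         dz = mean(d) / sdd, mean_diff = mean(d), n = n),
    class = "ttest_result"
  )
}

#' @export
print.ttest_result <- function(x, ...) {
  cat(sprintf("paired t(%d) = %.3f, p = %.4g, dz = %.3f, mean diff = %.4g (n = %d)\n",
              x$df, x$t, x$p, x$dz, x$mean_diff, x$n))
  invisible(x)
}

#' Repeated-measures ANOVA with partial eta squared
#'
#' Univariate within-subject ANOVA for a complete 2 x 2 or one-way
#' (k-level) design: every effect is tested against its own
#' effect-by-subject interaction, degrees of freedom are uncorrected (no
#' sphericity correction; a 2-level factor has none, and multi-level
#' analyses are reported with uncorrected df), and each effect's partial eta
#' squared is `SS_effect / (SS_effect + SS_error)`. Participants with
#' incomplete cells are removed listwise (with a message).
#'
#' The decomposition is delegated to [stats::aov()] with an
#' `Error(subject/...)` stratum per effect.
#'
#' @param cells Long-format data frame with columns `participant`, `value`,
#'   and one (`a`) or two (`a`, `b`) within-subject factor columns.
#' @param design `"2x2"` or `"oneway"`.
#'
#' @return A tibble of class `anova_result`, one row per effect: `effect`,
#'   `F`, `df_num`, `df_den`, `p`, `partial_eta_sq`, `n`.
#' @export
rm_anova <- function(cells, design = c("2x2", "oneway")) {
  design <- match.arg(design)
  cells <- tibble::as_tibble(cells)
  factors <- if (design == "2x2") c("a", "b") else "a"
  stopifnot(all(c("participant", "value", factors) %in% names(cells)))
  for (f in factors) {
    cells[[f]] <- factor(cells[[f]])
    if (nlevels(cells[[f]]) < 2) {
      stop("design error: factor `", f, "` needs at least 2 levels",
           call. = FALSE)
    }
    if (design == "2x2" && nlevels(cells[[f]]) != 2) {
      stop("design error: 2x2 design requires 2-level factors", call. = FALSE)
    }
  }
  cells$participant <- factor(cells$participant)
  n_cells <- prod(vapply(factors, function(f) nlevels(cells[[f]]), integer(1)))
  counts <- table(cells$participant)
  complete <- names(counts)[counts == n_cells]
  if (length(complete) < length(counts)) {
    message(length(counts) - length(complete),
            " participant(s) removed listwise (incomplete cells)")
    cells <- cells[cells$participant %in% complete, , drop = FALSE]
    cells$participant <- droplevels(cells$participant)
  }
  n <- nlevels(cells$participant)
  if (n < 2) stop("sample error: need at least 2 participants", call. = FALSE)

  if (design == "2x2") {
    fit <- stats::aov(value ~ a * b + Error(participant / (a * b)),
                      data = cells)
    strata <- c("Error: participant:a", "Error: participant:b",
                "Error: participant:a:b")
    effects <- c("a", "b", "a:b")
  } else {
    fit <- stats::aov(value ~ a + Error(participant / a), data = cells)
    strata <- "Error: participant:a"
    effects <- "a"
  }
  sm <- summary(fit)
  ss_scale <- sum((cells$value - mean(cells$value))^2)
  rows <- lapply(seq_along(strata), function(i) {
    tab <- sm[[strata[i]]][[1]]
    ss_eff <- tab[1, "Sum Sq"]
    ss_err <- tab[2, "Sum Sq"]
    f_val <- tab[1, "F value"]
    p_val <- tab[1, "Pr(>F)"]
    if (!is.finite(f_val) || ss_eff <= 1e-12 * max(ss_scale, 1)) {
      # no effect variance (e.g. identical cells): report a null effect
      ss_eff <- 0
      f_val <- 0
      p_val <- 1
    }
    tibble::tibble(
      effect = effects[i], F = f_val,
      df_num = tab[1, "Df"], df_den = tab[2, "Df"], p = p_val,
      partial_eta_sq = if (ss_eff + ss_err == 0) 0 else ss_eff / (ss_eff + ss_err),
      n = n
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("anova_result", class(out))
  out
}

#' Power of a two-sided paired t test
#'
#' Computed from the noncentral t distribution with noncentrality
#' `dz * sqrt(n)` and `n - 1` degrees of freedom.
#'
#' @param n Number of participants (>= 2).
#' @param dz Paired-samples effect size (>= 0).
#' @param alpha Two-sided significance level.
#' @return The power probability.
#' @export
#' @examples
#' power_paired_t(48, 0.5, 0.05) # design power of a 48-participant sample
power_paired_t <- function(n, dz, alpha = 0.05) {
  stopifnot(n >= 2, dz >= 0)
  if (!(alpha > 0 && alpha < 1)) {
    stop("`alpha` must lie strictly between 0 and 1", call. = FALSE)
  }
  df <- n - 1
  ncp <- dz * sqrt(n)
  tcrit <- stats::qt(1 - alpha / 2, df)
  stats::pt(tcrit, df, ncp = ncp, lower.tail = FALSE) +
    stats::pt(-tcrit, df, ncp = ncp)
}
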