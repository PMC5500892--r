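#' Round half away from zero
#'
#' Decimal rounding where ties go away from zero (so 96.15 -> 96.2 and
#' 45.5 -> 46), matching how summary percentages are conventionally
#' printed, unlike R's banker's rounding.
#'
#' @param x numeric.
#' @param digits decimal places (may be negative).
#' @return rounded numeric.
#' @export
round_half_away <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

round_to_step <- function(x, step) {
  if (is.null(step) || step <= 0) return(x)
  step * round_half_away(x / step)
}

#' Percentages from a count tally
#'
#' `100 * count / total` per category, rounded half away from zero to
#' `decimals`; exact values are returned alongside. Unrounded proportions
#' always sum to 100%.
#'
#' @param counts named non-negative integer vector.
#' @param decimals decimal places of the rounded percentages.
#' @return data.frame with `category`, `count`, `percent_exact`,
#'   `percent`.
#' @export
proportions_from_counts <- function(counts, decimals = 1) {
  if (any(counts < 0)) stop("counts must be >= 0")
  total <- sum(counts)
  if (total == 0) stop("total count is zero")
  exact <- 100 * counts / total
  data.frame(category = if (is.null(names(counts)))
               as.character(seq_along(counts)) else names(counts),
             count = as.integer(counts),
             percent_exact = unname(exact),
             percent = unname(round_half_away(exact, decimals)),
             stringsAsFactors = FALSE)
}

#' Pooled percent-of-control and percent reduction from group means
#'
#' Treatment group means are pooled by an unweighted mean (conditions
#' are summarized per group first, then averaged), expressed relative to
#' the control mean and optionally rounded to the nearest
#' `rounding_step` (half away from zero). `percent_remaining()` +
#' `percent_reduction()` equals 100% exactly before rounding.
#'
#' @param control_mean control group mean (> 0).
#' @param treatment_means one or more treatment group means (same units).
#' @param rounding_step rounding granularity in percent (`NULL` = no
#'   rounding).
#' @return list with `percent` (rounded) and `percent_exact`.
#' @export
percent_remaining <- function(control_mean, treatment_means,
                              rounding_step = NULL) {
  if (control_mean <= 0) stop("control mean must be > 0")
  if (length(treatment_means) < 1) stop("at least one treatment mean required")
  exact <- 100 * mean(treatment_means) / control_mean
  list(percent = round_to_step(exact, rounding_step), percent_exact = exact)
}

#' @rdname percent_remaining
#' @export
percent_reduction <- function(control_mean, treatment_means,
                              rounding_step = NULL) {
  rem <- percent_remaining(control_mean, treatment_means, rounding_step = NULL)
  exact <- 100 - rem$percent_exact
  list(percent = round_to_step(exact, rounding_step), percent_exact = exact)
}

#' Mann-Whitney U test
#'
#' Nonparametric two-sample test used for all group differences in the
#' electrophysiology summaries. The exact null distribution is used for
#' combined sample sizes up to `exact_max_n` without ties; otherwise the
#' normal approximation with tie correction and continuity correction.
#' When every observation is identical the statistic is its null mean
#' and p = 1.
#'
#' @param group_a,group_b numeric vectors (each non-empty).
#' @param exact_max_n largest combined n for the exact distribution.
#' @return list with `U` (statistic of `group_a`), `p_value`, `method`.
#' @export
mann_whitney_u <- function(group_a, group_b, exact_max_n = 20) {
  if (length(group_a) < 1 || length(group_b) < 1) {
    stop("both groups must be non-empty")
  }
  n_a <- length(group_a)
  n_b <- length(group_b)
  if (length(unique(c(group_a, group_b))) == 1) {
    return(list(U = n_a * n_b / 2, p_value = 1, method = "degenerate_ties"))
  }
  ties <- anyDuplicated(c(group_a, group_b)) > 0
  exact <- (n_a + n_b) <= exact_max_n && !ties
  res <- suppressWarnings(
    wilcox.test(group_a, group_b, alternative = "two.sided",
                exact = exact, correct = TRUE))
  list(U = unname(res$statistic), p_value = res$p.value,
       method = if (exact) "exact" else "normal_approximation")
}

#' Assemble the aggregate report bundle
#'
#' Collects the outputs of the individual analysis stages into a single
#' bundle: the normalized-abundance heat-map matrix, specificity calls,
#' two-step partition fractions, group comparisons and EPSC summaries.
#' Missing stages are listed as absent; the report is still produced.
#'
#' @param normalized_abundance matrix (proteins x datasets) or `NULL`.
#' @param specificity_calls data.frame from [call_specific()] or `NULL`.
#' @param twostep_fractions data.frame from [twostep_partition()] or
#'   `NULL`.
#' @param comparisons data.frame from [compare_groups()] or `NULL`.
#' @param ephys_summary list or data.frame of EPSC summaries or `NULL`.
#' @param out_dir optional directory; when given, writes `report.json`
#'   and `heatmap.tsv` there.
#' @return list with `sections` (the non-`NULL` stages), `absent`
#'   (names of missing stages), and `out_dir`.
#' @export
build_report <- function(normalized_abundance = NULL,
                         specificity_calls = NULL,
                         twostep_fractions = NULL,
                         comparisons = NULL,
                         ephys_summary = NULL,
                         out_dir = NULL) {
  stages <- list(normalized_abundance = normalized_abundance,
                 specificity_calls = specificity_calls,
                 twostep_fractions = twostep_fractions,
                 comparisons = comparisons,
                 ephys_summary = ephys_summary)
  present <- !vapply(stages, is.null, logical(1))
  report <- list(sections = stages[present],
                 absent = names(stages)[!present],
                 out_dir = out_dir)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    meta <- lapply(stages[present], function(s) {
      if (is.matrix(s)) list(type = "matrix", dim = dim(s))
      else if (is.data.frame(s)) s
      else s
    })
    jsonlite::write_json(list(sections = meta,
                              absent = names(stages)[!present]),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (!is.null(normalized_abundance)) {
      write_matrix_tsv(normalized_abundance, file.path(out_dir, "heatmap.tsv"))
    }
  }
  report
}
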