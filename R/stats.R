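#' Per-group summary of bead counts
#'
#' Mean and standard error of the mean (SEM, sd/sqrt(n) with the n-1
#' denominator) of per-animal bead counts by group. A single-animal group
#' gets SEM 0 with `sem_defined = FALSE`.
#'
#' @param counts data frame with columns `group` and `count` (extra columns
#'   ignored).
#' @return data frame with `group`, `n`, `mean`, `sem`, `sem_defined`.
#' @export
group_summary <- function(counts) {
  if (!nrow(counts)) stop("`counts` must be non-empty", call. = FALSE)
  if (any(counts$count < 0)) stop("bead counts must be >= 0", call. = FALSE)
  groups <- unique(counts$group)
  out <- do.call(rbind, lapply(groups, function(g) {
    x <- counts$count[counts$group == g]
    n <- length(x)
    data.frame(group = g, n = n, mean = mean(x),
               sem = if (n > 1) stats::sd(x) / sqrt(n) else 0,
               sem_defined = n > 1)
  }))
  rownames(out) <- NULL
  out
}

#' Fold change between two groups of counts
#'
#' Ratio of group means, `mean(a) / mean(b)`.
#'
#' @param group_a_counts,group_b_counts numeric count vectors.
#' @return scalar fold change.
#' @export
fold_change <- function(group_a_counts, group_b_counts) {
  mb <- mean(group_b_counts)
  if (mb == 0) stop("denominator group mean is zero; fold change undefined", call. = FALSE)
  mean(group_a_counts) / mb
}

#' Percent reduction of a treated group relative to control
#'
#' `100 * (1 - mean(treated) / mean(control))`, with a first-order
#' delta-method standard error propagated from the two group SEMs.
#'
#' @param control_counts,treated_counts numeric count vectors.
#' @return list with `reduction_percent` and `se_percent`.
#' @export
percent_reduction <- function(control_counts, treated_counts) {
  mc <- mean(control_counts)
  if (mc == 0) stop("control group mean is zero; reduction undefined", call. = FALSE)
  mt <- mean(treated_counts)
  sem_c <- if (length(control_counts) > 1) stats::sd(control_counts) / sqrt(length(control_counts)) else 0
  sem_t <- if (length(treated_counts) > 1) stats::sd(treated_counts) / sqrt(length(treated_counts)) else 0
  se_ratio <- sqrt((sem_t / mc)^2 + (mt * sem_c / mc^2)^2)
  list(reduction_percent = 100 * (1 - mt / mc), se_percent = 100 * se_ratio)
}

#' One-tailed pooled-variance Student's t-test
#'
#' Equal-variance (pooled) Student's t-test with an a-priori one-sided
#' alternative: the direction is fixed by the experimental hypothesis (e.g.
#' day-5 accumulation exceeds day 1; statin reduces recruitment) and must be
#' stated explicitly.
#'
#' @param group_a,group_b numeric vectors, each with at least 2 values.
#' @param direction `"greater"` tests `mean(a) > mean(b)`, `"less"` tests
#'   `mean(a) < mean(b)`.
#' @return one-sided p-value.
#' @export
one_tailed_t <- function(group_a, group_b, direction = c("greater", "less")) {
  direction <- match.arg(direction)
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop("both groups need at least 2 samples", call. = FALSE)
  }
  stats::t.test(group_a, group_b, var.equal = TRUE,
                alternative = direction)$p.value
}

#' Compare two groups of an experiment
#'
#' Bundles the summary statistics reported for a two-group bead-count
#' comparison: group means with SEM, fold change, percent reduction with
#' propagated error, and the one-tailed pooled t-test p-value.
#'
#' @param counts data frame with `group` and `count`.
#' @param group_a,group_b group labels; `group_a` is the numerator of the
#'   fold change and the *control* of the reduction.
#' @param direction one-sided alternative for `group_a` vs `group_b` passed
#'   to [one_tailed_t()].
#' @return list of class `group_comparison`.
#' @export
compare_groups <- function(counts, group_a, group_b,
                           direction = c("greater", "less")) {
  direction <- match.arg(direction)
  a <- counts$count[counts$group == group_a]
  b <- counts$count[counts$group == group_b]
  if (!length(a) || !length(b)) stop("unknown group label", call. = FALSE)
  red <- percent_reduction(a, b)
  structure(list(
    group_a = group_a, group_b = group_b,
    summary = group_summary(counts[counts$group %in% c(group_a, group_b), ]),
    fold_change = fold_change(a, b),
    reduction_percent = red$reduction_percent,
    reduction_se_percent = red$se_percent,
    p_value = if (length(a) > 1 && length(b) > 1) one_tailed_t(a, b, direction) else NA_real_,
    direction = direction), class = "group_comparison")
}
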