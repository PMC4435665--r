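#' Student's two-sample t test
#'
#' Classic two-sample t test as used throughout the study: pooled-variance
#' (Student) by default for unpaired comparisons, with Welch available via
#' `welch = TRUE`; paired where stated. Two-sided p values from the t
#' distribution. When both groups have zero variance the statistic is
#' undefined and is flagged rather than raised.
#'
#' @param a,b Numeric vectors (n >= 2 each; equal lengths when paired).
#' @param paired Paired test (within-cell drug comparisons).
#' @param welch Use the Welch (unequal-variance) form instead of the pooled
#'   form.
#' @return A one-row tibble: `t_stat`, `df`, `p_value`, `paired`,
#'   `undefined` (TRUE when variance is degenerate).
#' @examples
#' two_sample_t(c(1, 2, 3, 4), c(2, 3, 4, 5))
#' @export
two_sample_t <- function(a, b, paired = FALSE, welch = FALSE) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2)
    abort("each group needs at least 2 finite values.")
  if (paired && length(a) != length(b))
    abort("paired test requires equal-length groups.")
  res <- tryCatch(
    stats::t.test(a, b, paired = paired, var.equal = !welch && !paired),
    error = function(e) NULL)
  if (is.null(res)) {
    return(tibble(t_stat = NA_real_, df = NA_real_, p_value = NA_real_,
                  paired = paired, undefined = TRUE))
  }
  tibble(t_stat = unname(res$statistic), df = unname(res$parameter),
         p_value = res$p.value, paired = paired, undefined = FALSE)
}

group_summary <- function(x, label) {
  x <- x[is.finite(x)]
  tibble(label = label, n = length(x), mean = mean(x),
         sem = sd(x) / sqrt(length(x)))
}

#' Metric-by-metric comparison of two cohorts
#'
#' Builds the comparison table of a two-strain study: one row per metric
#' with group means, standard errors and a Student t test. No
#' multiple-testing correction is applied, matching the study's practice;
#' interpret families of rows accordingly.
#'
#' @param cohort_a,cohort_b Data frames with one row per cell and the
#'   metric columns; non-finite values (e.g. cells with no measurable
#'   burst) are dropped per metric.
#' @param metrics Character vector of metric columns to compare; default:
#'   all shared numeric columns.
#' @param labels Length-2 group labels.
#' @param paired Paired t tests.
#' @return A `cohort_comparison` tibble: `metric`, `n_a`, `mean_a`,
#'   `sem_a`, `n_b`, `mean_b`, `sem_b`, `t_stat`, `p_value`,
#'   `significant`.
#' @export
cohort_comparison <- function(cohort_a, cohort_b, metrics = NULL,
                              labels = c("A", "B"), paired = FALSE) {
  if (is.null(metrics)) {
    num_a <- names(cohort_a)[vapply(cohort_a, is.numeric, TRUE)]
    num_b <- names(cohort_b)[vapply(cohort_b, is.numeric, TRUE)]
    metrics <- intersect(num_a, num_b)
  }
  miss <- setdiff(metrics, intersect(names(cohort_a), names(cohort_b)))
  if (length(miss))
    abort(sprintf("metric(s) missing from a cohort: %s.",
                  paste(miss, collapse = ", ")))
  rows <- purrr::map(metrics, function(m) {
    a <- cohort_a[[m]]; b <- cohort_b[[m]]
    sa <- group_summary(a, labels[1]); sb <- group_summary(b, labels[2])
    tt <- if (sa$n >= 2 && sb$n >= 2)
      two_sample_t(a, b, paired = paired)
    else tibble(t_stat = NA_real_, df = NA_real_, p_value = NA_real_,
                paired = paired, undefined = TRUE)
    tibble(metric = m, n_a = sa$n, mean_a = sa$mean, sem_a = sa$sem,
           n_b = sb$n, mean_b = sb$mean, sem_b = sb$sem,
           t_stat = tt$t_stat, p_value = tt$p_value,
           significant = !is.na(tt$p_value) & tt$p_value < 0.05)
  }) %>% list_rbind()
  attr(rows, "labels") <- labels
  class(rows) <- c("cohort_comparison", class(rows))
  rows
}
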