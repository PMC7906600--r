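# Group-comparison statistics: chi-squared homogeneity of regional
# distributions, the knockout-vs-control two-sample t-test with
# percent-reduction summary, iterative Grubbs outlier flagging, and
# ROI-pooled co-expression fraction summaries.

#' Chi-squared test of homogeneity
#'
#' Pearson chi-squared on a groups x regions contingency table: expected
#' counts from the row/column marginals, `df = (rows - 1)(cols - 1)`,
#' p-value from the upper tail of the chi-squared distribution. No
#' continuity correction. A thalamus-wide test of whole distributions is
#' robust to cells mis-assigned between neighbouring nuclei, which only move
#' counts between columns.
#'
#' @param table numeric matrix of non-negative counts, >= 2 rows and >= 2
#'   columns, no all-zero row or column.
#' @param proportions if `TRUE`, each row is first rescaled to sum to the
#'   mean row total ("average relative cell numbers"); default uses raw
#'   counts, which preserves the test's sampling theory.
#' @return a `thalamap_test` with `statistic`, `df`, `p_value`, `expected`.
#' @export
chi2_homogeneity <- function(table, proportions = FALSE) {
  x <- as.matrix(table)
  if (nrow(x) < 2L || ncol(x) < 2L) {
    stop("table must have >= 2 rows and >= 2 columns", call. = FALSE)
  }
  if (any(x < 0) || any(!is.finite(x))) {
    stop("counts must be finite and non-negative", call. = FALSE)
  }
  if (any(rowSums(x) == 0) || any(colSums(x) == 0)) {
    stop("table has an all-zero row or column", call. = FALSE)
  }
  if (proportions) {
    x <- x / rowSums(x) * mean(rowSums(x))
  }
  expected <- outer(rowSums(x), colSums(x)) / sum(x)
  stat <- sum((x - expected)^2 / expected)
  df <- (nrow(x) - 1L) * (ncol(x) - 1L)
  test_result(statistic = stat, df = df,
              p_value = stats::pchisq(stat, df, lower.tail = FALSE),
              method = "Chi-squared test of homogeneity",
              expected = expected)
}

#' Unpaired two-sample two-tailed t-test
#'
#' Pooled-variance by default (`var_equal = TRUE`); Welch's unequal-variance
#' form available as an option.
#'
#' @param sample_a,sample_b numeric vectors, each with >= 2 values.
#' @param var_equal pool the variances?
#' @return a `thalamap_test` with `statistic` (t, sign of a - b), `df`,
#'   `p_value`.
#' @export
ttest_two_sample <- function(sample_a, sample_b, var_equal = TRUE) {
  a <- as.numeric(sample_a); b <- as.numeric(sample_b)
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L) {
    stop("each sample needs >= 2 values", call. = FALSE)
  }
  va <- stats::var(a); vb <- stats::var(b)
  if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  t <- if (se == 0) 0 else (mean(a) - mean(b)) / se
  test_result(statistic = t, df = df,
              p_value = 2 * stats::pt(abs(t), df, lower.tail = FALSE),
              method = if (var_equal) {
                "Two-sample t-test (pooled variance)"
              } else {
                "Welch two-sample t-test"
              })
}

#' Percent reduction of a test group relative to a reference group
#'
#' Default (`method = "per_brain"`): each test brain's reduction is
#' `1 - test_i / mean(reference)`, summarised as mean and SEM across test
#' brains, reported in percent. The alternative (`method = "of_means"`)
#' reports `1 - mean(test)/mean(reference)` with a delta-method SEM.
#'
#' @param reference numeric totals for the reference group (mean must be
#'   > 0).
#' @param test numeric totals for the test group (>= 1 value).
#' @param method `"per_brain"` or `"of_means"`.
#' @return list with `mean_percent`, `sem_percent`, `reductions_percent`
#'   (per test brain; `NA` for `"of_means"`), `method`.
#' @export
percent_change <- function(reference, test, method = c("per_brain",
                                                       "of_means")) {
  method <- match.arg(method)
  reference <- as.numeric(reference); test <- as.numeric(test)
  if (!length(reference) || !length(test)) {
    stop("both groups need >= 1 value", call. = FALSE)
  }
  mref <- mean(reference)
  if (mref <= 0) stop("reference mean must be > 0", call. = FALSE)
  if (method == "per_brain") {
    red <- (1 - test / mref) * 100
    list(mean_percent = mean(red), sem_percent = sem(red),
         reductions_percent = red, method = method)
  } else {
    red <- (1 - mean(test) / mref) * 100
    # delta method on the ratio of independent means
    se_ratio <- (mean(test) / mref) *
      sqrt(sem(test)^2 / mean(test)^2 + sem(reference)^2 / mref^2)
    list(mean_percent = red, sem_percent = 100 * se_ratio,
         reductions_percent = NA_real_, method = method)
  }
}

# Two-sided Grubbs critical value: G_crit(n, alpha) =
# (n-1)/sqrt(n) * sqrt(t^2 / (n - 2 + t^2)), t = qt(1 - alpha/(2n), n - 2).
grubbs_critical <- function(n, alpha) {
  t <- stats::qt(1 - alpha / (2 * n), df = n - 2)
  (n - 1) / sqrt(n) * sqrt(t^2 / (n - 2 + t^2))
}

#' Iterative two-sided Grubbs outlier flagging
#'
#' Repeatedly computes `G = max |x_i - mean| / SD` on the remaining values,
#' compares it to the critical value `G_crit(n, alpha)`, removes and flags
#' the extreme value if `G > G_crit`, and stops otherwise. Flagged indices
#' refer to the original input ordering. All-equal values yield no outliers.
#'
#' @param values numeric vector, n >= 3.
#' @param alpha per-dataset significance level in (0, 0.2].
#' @return integer vector of flagged indices (possibly empty), in flagging
#'   order.
#' @export
grubbs_outliers <- function(values, alpha = 0.05) {
  x <- as.numeric(values)
  if (length(x) < 3L) stop("need at least 3 values", call. = FALSE)
  if (any(!is.finite(x))) stop("values must be finite", call. = FALSE)
  check_number(alpha, "alpha", 0, 0.2, strict_lower = TRUE)
  idx <- seq_along(x)
  flagged <- integer(0)
  while (length(x) >= 3L) {
    s <- stats::sd(x)
    if (s == 0) break
    dev <- abs(x - mean(x))
    g <- max(dev) / s
    if (g <= grubbs_critical(length(x), alpha)) break
    worst <- which.max(dev)
    flagged <- c(flagged, idx[worst])
    x <- x[-worst]
    idx <- idx[-worst]
  }
  flagged
}

#' ROI-pooled double-positive fraction summary
#'
#' Counts from fixed-size sampled fields (ROIs) are pooled across ROIs
#' within each (brain, nucleus) *before* dividing — pooling then dividing,
#' not averaging per-ROI fractions — giving one representative
#' double-positive fraction per brain per nucleus, then mean and SEM across
#' brains per nucleus. Invariant to ROI order and to splitting one ROI's
#' counts over two rows.
#'
#' @param roi_counts `data.frame` with columns `brain_id`, `nucleus`, `roi`,
#'   `n_double` (double-positive cells) and `n_single` (single-positive
#'   cells).
#' @return list with `per_brain` (`data.frame`: brain, nucleus, pooled
#'   counts, fraction) and `summary` (`data.frame`: nucleus, mean_fraction,
#'   sem_fraction, n_brains).
#' @export
roi_fraction_summary <- function(roi_counts) {
  need <- c("brain_id", "nucleus", "n_double", "n_single")
  miss <- setdiff(need, names(roi_counts))
  if (length(miss)) {
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  agg <- stats::aggregate(cbind(n_double, n_single) ~ brain_id + nucleus,
                          data = roi_counts, FUN = sum)
  agg$total <- agg$n_double + agg$n_single
  zero <- agg$total == 0
  if (any(zero)) {
    stop(sprintf("pooled total is zero for brain '%s', nucleus '%s'",
                 agg$brain_id[zero][1], agg$nucleus[zero][1]), call. = FALSE)
  }
  agg$fraction <- agg$n_double / agg$total
  summ <- do.call(rbind, lapply(split(agg, agg$nucleus), function(s) {
    data.frame(nucleus = s$nucleus[1], mean_fraction = mean(s$fraction),
               sem_fraction = sem(s$fraction), n_brains = nrow(s),
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  list(per_brain = agg, summary = summ)
}
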