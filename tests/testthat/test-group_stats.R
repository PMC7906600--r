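# Group-comparison statistics: chi-squared homogeneity, t-test, percent
# reduction, Grubbs outliers, ROI pooling.

test_that("chi2_homogeneity matches hand values and stats::chisq.test", {
  # proportional rows: statistic 0, p = 1
  prop <- rbind(c(10, 20, 30), c(20, 40, 60))
  res <- chi2_homogeneity(prop)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  # closed form: expected counts all 15, statistic 20/3
  res <- chi2_homogeneity(rbind(c(20, 10), c(10, 20)))
  expect_equal(res$statistic, 20 / 3)
  expect_equal(res$df, 1L)
  expect_true(all(res$expected == 15))

  # oracle agreement and row-order invariance on random tables
  for (s in 1:25) {
    set.seed(s)
    nr <- sample(2:4, 1); nc <- sample(2:6, 1)
    tab <- matrix(rpois(nr * nc, 20) + 1, nrow = nr)
    got <- chi2_homogeneity(tab)
    ref <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
    expect_gte(got$statistic, 0)
    expect_equal(chi2_homogeneity(tab[rev(seq_len(nrow(tab))), ])$statistic,
                 got$statistic, tolerance = 1e-12)
  }

  expect_error(chi2_homogeneity(rbind(c(0, 0), c(1, 2))), "all-zero")
  expect_error(chi2_homogeneity(matrix(1:3, 1)), ">= 2 rows")
})

test_that("proportion-scaled chi-squared variant preserves the zero case", {
  tab <- rbind(c(10, 20, 30), c(2, 4, 6))
  # proportional rows stay null under rescaling
  expect_equal(chi2_homogeneity(tab, proportions = TRUE)$statistic, 0)
  # rescaling equalises row totals, generally changing the statistic
  tab2 <- rbind(c(30, 10), c(10, 30))
  expect_false(isTRUE(all.equal(
    chi2_homogeneity(tab2, proportions = TRUE)$statistic,
    chi2_homogeneity(rbind(c(60, 20), c(10, 30)))$statistic)))
})

test_that("ttest_two_sample matches hand values and stats::t.test", {
  same <- c(1, 2, 3)
  res <- ttest_two_sample(same, same)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  # pooled s^2 = 1, SE = sqrt(2/3), |t| = 3 / sqrt(2/3)
  res <- ttest_two_sample(c(1, 2, 3), c(4, 5, 6))
  expect_equal(abs(res$statistic), 3 / sqrt(2 / 3))
  expect_equal(res$df, 4)

  # swapping flips the sign, p unchanged
  swap <- ttest_two_sample(c(4, 5, 6), c(1, 2, 3))
  expect_equal(swap$statistic, -res$statistic)
  expect_equal(swap$p_value, res$p_value)
  expect_error(ttest_two_sample(1, c(1, 2)), ">= 2 values")

  for (s in 1:20) {
    set.seed(s)
    a <- rnorm(sample(3:12, 1)); b <- rnorm(sample(3:12, 1), 0.5)
    got <- ttest_two_sample(a, b)
    ref <- stats::t.test(a, b, var.equal = TRUE)
    expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
    gw <- ttest_two_sample(a, b, var_equal = FALSE)
    rw <- stats::t.test(a, b)
    expect_equal(gw$statistic, unname(rw$statistic), tolerance = 1e-12)
    expect_equal(gw$df, unname(rw$parameter), tolerance = 1e-9)
  }
})

test_that("percent_change summarises per-brain reductions", {
  # test equals reference: 0% reduction
  res <- percent_change(c(100, 110, 90), c(100, 110, 90))
  expect_equal(res$mean_percent, 0)
  # hand case: mean(ref) = 100, reductions 90/89/91%
  res <- percent_change(c(100, 110, 90), c(10, 11, 9))
  expect_equal(res$mean_percent, 90)
  expect_equal(res$sem_percent, stats::sd(c(90, 89, 91)) / sqrt(3))
  expect_equal(sort(res$reductions_percent), c(89, 90, 91))
  # total loss
  res <- percent_change(c(50, 60), c(0, 0, 0))
  expect_equal(res$mean_percent, 100)
  expect_equal(res$sem_percent, 0)
  expect_error(percent_change(c(0, 0), c(1, 2)), "reference mean")
  # ratio-of-means variant agrees on the point estimate here
  alt <- percent_change(c(100, 110, 90), c(10, 11, 9), method = "of_means")
  expect_equal(alt$mean_percent, 90)
})

test_that("grubbs_outliers flags iteratively with the t-based critical value", {
  # G ~ 1.789 exceeds G_crit(5, 0.05) ~ 1.715
  expect_equal(grubbs_outliers(c(1, 1, 1, 1, 100), 0.05), 5L)
  # flagged indices refer to the original ordering
  expect_equal(grubbs_outliers(c(100, 1, 1, 1, 1), 0.05), 1L)
  # all equal: no outliers
  expect_equal(grubbs_outliers(rep(3, 6)), integer(0))
  # two planted outliers fall in successive iterations
  set.seed(20)
  expect_setequal(grubbs_outliers(c(rnorm(10), 50, -60)), c(11L, 12L))
  expect_error(grubbs_outliers(c(1, 2)), "at least 3")
  expect_error(grubbs_outliers(1:5, alpha = 0.5), "alpha")
})

test_that("roi_fraction_summary pools counts before dividing", {
  # three ROIs 3/4, 2/3, 4/5 double/total: pooled 9/12
  df <- data.frame(brain_id = "b1", nucleus = "MD", roi = 1:3,
                   n_double = c(3, 2, 4), n_single = c(1, 1, 1))
  res <- roi_fraction_summary(df)
  expect_equal(res$per_brain$fraction, 9 / 12)

  # all double-positive: fraction 1
  alld <- data.frame(brain_id = "b1", nucleus = "LD", roi = 1:2,
                     n_double = c(5, 7), n_single = 0)
  expect_equal(roi_fraction_summary(alld)$per_brain$fraction, 1)

  # across-brain summary: fractions 0.9, 0.8, 0.7 -> mean 0.8, SEM 0.0577
  three <- data.frame(brain_id = rep(c("b1", "b2", "b3"), each = 1),
                      nucleus = "MD", roi = 1,
                      n_double = c(9, 8, 7), n_single = c(1, 2, 3))
  res <- roi_fraction_summary(three)
  expect_equal(res$summary$mean_fraction, 0.8)
  expect_equal(res$summary$sem_fraction, 0.1 / sqrt(3), tolerance = 1e-9)

  # invariance to ROI order and to splitting a ROI's counts in two
  base <- roi_fraction_summary(df)
  shuffled <- roi_fraction_summary(df[c(3, 1, 2), ])
  expect_equal(shuffled$per_brain$fraction, base$per_brain$fraction)
  split_roi <- data.frame(brain_id = "b1", nucleus = "MD", roi = 1:4,
                          n_double = c(1, 2, 2, 4), n_single = c(1, 0, 1, 1))
  expect_equal(roi_fraction_summary(split_roi)$per_brain$fraction,
               base$per_brain$fraction)

  # zero pooled total names brain and nucleus
  zero <- data.frame(brain_id = "b9", nucleus = "LP", roi = 1,
                     n_double = 0, n_single = 0)
  expect_error(roi_fraction_summary(zero), "b9.*LP")
})
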