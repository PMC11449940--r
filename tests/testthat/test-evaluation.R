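test_that("sensitivity and specificity follow their defining ratios", {
  expect_equal(sensitivity(confusion_table(77, 2, 91, 1)), 77 / 79)
  expect_equal(round_half_up(100 * sensitivity(confusion_table(77, 2, 91, 1))),
               97.5)
  expect_equal(round_half_up(100 * sensitivity(confusion_table(74, 5, 92, 0))),
               93.7)
  expect_equal(specificity(confusion_table(77, 2, 91, 1)), 91 / 92)
  expect_equal(specificity(confusion_table(74, 5, 92, 0)), 1)
  expect_equal(sensitivity(confusion_table(10, 0, 5, 5)), 1)
  expect_equal(specificity(confusion_table(1, 1, 0, 1)), 0)
  expect_error(sensitivity(confusion_table(0, 0, 5, 5)),
               class = "afib_invalid_parameter")
})

test_that("Wilson intervals reproduce the published accuracy bounds", {
  ci <- wilson_ci(77, 79)
  expect_equal(round(c(ci$ci_low, ci$ci_high), 3), c(0.912, 0.993))
  ci <- wilson_ci(92, 92)
  expect_equal(round(c(ci$ci_low, ci$ci_high), 3), c(0.960, 1.000))
  expect_equal(wilson_ci(0, 10)$ci_low, 0)    # clipped at the boundary
  expect_error(wilson_ci(11, 10), class = "afib_invalid_parameter")
})

test_that("Wilson intervals are ordered and cover on exhaustive small n", {
  for (n in 1:30) {
    for (x in 0:n) {
      ci <- wilson_ci(x, n)
      expect_true(ci$ci_low >= 0 && ci$ci_low <= ci$point &&
                    ci$point <= ci$ci_high && ci$ci_high <= 1)
    }
  }
  ## simulated coverage at n = 79, p = 0.97
  cover <- withr::with_seed(10, {
    mean(vapply(1:2000, function(i) {
      x <- rbinom(1, 79, 0.97)
      ci <- wilson_ci(x, 79)
      ci$ci_low <= 0.97 && 0.97 <= ci$ci_high
    }, TRUE))
  })
  expect_gte(cover, 0.90)
  expect_lte(cover, 0.99)
})

test_that("McNemar p-values are symmetric and match closed forms", {
  expect_equal(mcnemar_test(4, 4), 1)
  expect_equal(mcnemar_test(3, 0), 0.25)            # 2 * (1/2)^3
  expect_equal(mcnemar_test(0, 0), 1)
  for (b in 0:6) {
    for (cc in 0:6) {
      expect_equal(mcnemar_test(b, cc), mcnemar_test(cc, b))
    }
  }
  ## continuity-corrected variant against the closed form and stats::
  expect_equal(mcnemar_test(5, 1, method = "chi2_cc"),
               pchisq((abs(5 - 1) - 1)^2 / 6, 1, lower.tail = FALSE))
  ref <- stats::mcnemar.test(matrix(c(10, 5, 1, 10), 2), correct = TRUE)
  expect_equal(mcnemar_test(5, 1, method = "chi2_cc"), ref$p.value)
})

test_that("Pearson chi-square matches stats::chisq.test and the subgroup p-values", {
  tables <- list(
    age_sens = list(m = matrix(c(15, 0, 62, 2), 2, byrow = TRUE), p = 0.49),
    age_spec = list(m = matrix(c(34, 0, 57, 1), 2, byrow = TRUE), p = 0.44),
    arm_sens = list(m = matrix(c(30, 1, 47, 1), 2, byrow = TRUE), p = 0.75),
    arm_spec = list(m = matrix(c(42, 0, 49, 1), 2, byrow = TRUE), p = 0.36)
  )
  for (tb in tables) {
    got <- pearson_chi2_2x2(tb$m)
    expect_equal(round_half_up(got$p_value, 2), tb$p)
    ref <- suppressWarnings(stats::chisq.test(tb$m, correct = FALSE))
    expect_equal(got$statistic, unname(ref$statistic))
    expect_equal(got$p_value, ref$p.value)
  }
  ## independence (ad = bc) gives statistic 0, p = 1
  ind <- pearson_chi2_2x2(matrix(c(10, 5, 20, 10), 2, byrow = TRUE))
  expect_equal(ind$statistic, 0)
  expect_equal(ind$p_value, 1)
  expect_error(pearson_chi2_2x2(matrix(c(0, 0, 5, 5), 2, byrow = TRUE)),
               class = "afib_degenerate_table")
  ## random tables against a brute-force expected-counts computation
  for (i in 1:50) {
    m <- withr::with_seed(i, matrix(rpois(4, 20) + 1, 2))
    got <- pearson_chi2_2x2(m)
    expected <- outer(rowSums(m), colSums(m)) / sum(m)
    expect_equal(got$statistic, sum((m - expected)^2 / expected))
  }
})

test_that("irregularity index is the population CV of the intervals", {
  expect_equal(irregularity_index(ppi_series(rep(0.75, 22))), 0)
  for (i in 1:50) {
    x <- withr::with_seed(i, runif(sample(2:30, 1), 0.3, 2))
    s <- ppi_series(x)
    expect_equal(irregularity_index(s),
                 sqrt(mean((x - mean(x))^2)) / mean(x))
  }
  ## index 0.13 at a 0.75 s mean implies a 97.5 ms interval SD
  expect_equal(0.13 * 0.75 * 1000, 97.5)
  expect_equal(measurement_period(21.6, 80), 16.2)
})

test_that("study evaluation renders published-style rows from count replays", {
  truth <- c(rep("AFIB", 79), rep("SINUS", 92))
  pred <- c(rep("AFIB", 77), rep("NON_AFIB", 2),
            rep("AFIB", 1), rep("NON_AFIB", 91))
  rep1 <- evaluate_study(pred, truth)
  expect_equal(rep1$strata[["all"]]$rendered[["sensitivity"]],
               "97.5 (91.2-99.3)")
  expect_equal(rep1$strata[["all"]]$rendered[["specificity"]],
               "98.9 (94.1-99.8)")
  ## perfect predictions give 100% everywhere
  perfect <- evaluate_study(truth, truth, strata = rep(c("a", "b"), 86)[1:171])
  for (p in perfect$strata) {
    expect_equal(p$sensitivity$point, 1)
    expect_equal(p$specificity$point, 1)
  }
  ## identical strata compare as independent (p = 1)
  truth2 <- rep(c("AFIB", "SINUS"), 40)
  pred2 <- truth2
  pred2[c(1, 41)] <- c("NON_AFIB", "NON_AFIB")
  same <- evaluate_study(pred2, truth2, strata = rep(c("g1", "g2"), each = 40))
  expect_equal(same$comparisons$sensitivity$p_value, 1)
  expect_equal(same$comparisons$specificity$p_value, 1)
  expect_error(evaluate_study("AFIB", c("AFIB", "SINUS")),
               class = "afib_invalid_parameter")
})

test_that("two-strata evaluation recomputes the subgroup chi-squares", {
  ## rebuild the age subgroup from its counts as prediction/truth vectors
  mk <- function(tp, fn, tn, fp, g) {
    list(truth = c(rep("AFIB", tp + fn), rep("SINUS", tn + fp)),
         pred = c(rep("AFIB", tp), rep("NON_AFIB", fn),
                  rep("NON_AFIB", tn), rep("AFIB", fp)),
         strata = rep(g, tp + fn + tn + fp))
  }
  young <- mk(15, 0, 34, 0, "age<65")
  old <- mk(62, 2, 57, 1, "age>=65")
  rep2 <- evaluate_study(c(young$pred, old$pred),
                         c(young$truth, old$truth),
                         c(young$strata, old$strata))
  expect_equal(round_half_up(rep2$comparisons$sensitivity$p_value, 2), 0.49)
  expect_equal(round_half_up(rep2$comparisons$specificity$p_value, 2), 0.44)
})
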