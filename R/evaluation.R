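## Diagnostic-accuracy statistics: sensitivity/specificity from confusion
## counts, Wilson score confidence intervals, McNemar's paired test,
## Pearson chi-square subgroup comparison, the irregularity index, and a
## study-report assembler that renders counts the way screening studies
## print them (percentage with 95% CI, one decimal, half-up).

#' Confusion table
#'
#' @param tp,fn,tn,fp Nonnegative counts: true positives, false negatives,
#'   true negatives, false positives. The positive class is AFib.
#' @return An object of class `confusion_table`.
#' @export
confusion_table <- function(tp, fn, tn, fp) {
  for (nm in c("tp", "fn", "tn", "fp")) {
    check_count(get(nm), nm, min = 0L)
  }
  structure(list(tp = as.integer(tp), fn = as.integer(fn),
                 tn = as.integer(tn), fp = as.integer(fp)),
            class = "confusion_table")
}

#' @export
print.confusion_table <- function(x, ...) {
  cat(sprintf("<confusion_table: TP %d  FN %d  TN %d  FP %d>\n",
              x$tp, x$fn, x$tn, x$fp))
  invisible(x)
}

#' Sensitivity and specificity
#'
#' Sensitivity is the number of AFib measurements output as AFib over the
#' total number of AFib measurements, `tp / (tp + fn)`; specificity is the
#' number of non-AFib measurements output as not AFib over the total
#' non-AFib measurements, `tn / (tn + fp)`.
#'
#' @param ct A [confusion_table].
#' @return A proportion in \[0, 1\].
#' @export
sensitivity <- function(ct) {
  stopifnot(inherits(ct, "confusion_table"))
  if (ct$tp + ct$fn < 1L) {
    afib_error("sensitivity needs tp + fn >= 1", "afib_invalid_parameter")
  }
  ct$tp / (ct$tp + ct$fn)
}

#' @rdname sensitivity
#' @export
specificity <- function(ct) {
  stopifnot(inherits(ct, "confusion_table"))
  if (ct$tn + ct$fp < 1L) {
    afib_error("specificity needs tn + fp >= 1", "afib_invalid_parameter")
  }
  ct$tn / (ct$tn + ct$fp)
}

#' Wilson score confidence interval for a proportion
#'
#' The Wilson interval has good small-sample and boundary behaviour
#' (bounds never leave \[0, 1\] after clipping) and reproduces the printed
#' intervals of cuff-screening accuracy tables.
#'
#' @param successes,n Counts with `0 <= successes <= n`, `n >= 1`.
#' @param confidence Confidence level (default 0.95, two-sided).
#' @return An object of class `proportion_estimate` with fields
#'   `successes`, `n`, `point`, `ci_low`, `ci_high`, `confidence`.
#' @examples
#' wilson_ci(77, 79)   # 0.975 (0.912-0.993)
#' @export
wilson_ci <- function(successes, n, confidence = 0.95) {
  n <- check_count(n, "n")
  successes <- check_count(successes, "successes", min = 0L)
  if (successes > n) {
    afib_error("`successes` cannot exceed `n`", "afib_invalid_parameter")
  }
  check_scalar_number(confidence, "confidence", lower = 0, upper = 1,
                      allow_equal_lower = FALSE)
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  p <- successes / n
  center <- p + z^2 / (2 * n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
  denom <- 1 + z^2 / n
  lo <- max(0, min(p, (center - half) / denom))
  hi <- min(1, max(p, (center + half) / denom))
  structure(list(successes = successes, n = n, point = p,
                 ci_low = lo, ci_high = hi,
                 confidence = confidence),
            class = "proportion_estimate")
}

#' @export
print.proportion_estimate <- function(x, ...) {
  cat(sprintf("%s\n", format_estimate(x)))
  invisible(x)
}

#' Render a proportion estimate the way accuracy tables print it
#'
#' `"97.5 (91.2-99.3)"`: percentage and CI bounds at one decimal, half-up.
#'
#' @param est A `proportion_estimate` from [wilson_ci()].
#' @return A character scalar.
#' @export
format_estimate <- function(est) {
  stopifnot(inherits(est, "proportion_estimate"))
  fmt <- function(p) {
    v <- round_half_up(100 * p, 1)
    ifelse(v == 100, "100", sprintf("%.1f", v))
  }
  sprintf("%s (%s-%s)", fmt(est$point), fmt(est$ci_low), fmt(est$ci_high))
}

#' McNemar's test on discordant pairs
#'
#' Compares paired classifications from two devices on the same subjects
#' using only the discordant counts `b` (device 1 correct, device 2 wrong)
#' and `c` (the reverse). `exact_binomial` doubles the smaller binomial
#' tail under p = 1/2 (capped at 1); `chi2_cc` is the continuity-corrected
#' statistic `(|b - c| - 1)^2 / (b + c)` referred to chi-square with 1
#' degree of freedom. With no discordant pairs the p-value is 1.
#'
#' @param discordant_b,discordant_c Nonnegative discordant counts.
#' @param method `"exact_binomial"` (default) or `"chi2_cc"`.
#' @return The p-value.
#' @export
mcnemar_test <- function(discordant_b, discordant_c,
                         method = c("exact_binomial", "chi2_cc")) {
  b <- check_count(discordant_b, "discordant_b", min = 0L)
  cc <- check_count(discordant_c, "discordant_c", min = 0L)
  method <- match.arg(method)
  m <- b + cc
  if (m == 0L) return(1)
  if (method == "exact_binomial") {
    min(1, 2 * stats::pbinom(min(b, cc), m, 0.5))
  } else {
    stat <- (abs(b - cc) - 1)^2 / m
    stats::pchisq(stat, df = 1, lower.tail = FALSE)
  }
}

#' Pearson chi-square test on a 2x2 table
#'
#' Without continuity correction:
#' `N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))` referred to chi-square with 1
#' degree of freedom — the variant that reproduces printed subgroup
#' p-values. Use with the usual caution at small expected counts.
#'
#' @param table A 2x2 numeric matrix of nonnegative counts (rows = groups,
#'   columns = correct/incorrect).
#' @return List with `statistic` and `p_value`.
#' @export
pearson_chi2_2x2 <- function(table) {
  tb <- as.matrix(table)
  if (!all(dim(tb) == c(2L, 2L)) || any(tb < 0) || any(!is.finite(tb))) {
    afib_error("`table` must be a 2x2 matrix of nonnegative counts",
               "afib_invalid_parameter")
  }
  if (any(rowSums(tb) < 1) || any(colSums(tb) < 1)) {
    afib_error("each margin of the 2x2 table must be at least 1",
               "afib_degenerate_table")
  }
  a <- tb[[1, 1]]; b <- tb[[1, 2]]; cc <- tb[[2, 1]]; d <- tb[[2, 2]]
  n <- sum(tb)
  stat <- unname(n * (a * d - b * cc)^2 /
    ((a + b) * (cc + d) * (a + cc) * (b + d)))
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Irregularity index of an interval series
#'
#' SD of the pulse intervals divided by their mean (population SD
#' convention) — a coefficient of variation. Roughly 0.13 in AFib: at a
#' 0.75 s mean interval (80 bpm) that implies an interval SD of 97.5 ms.
#'
#' @param series A [ppi_series] with at least 2 intervals.
#' @return Dimensionless index >= 0.
#' @export
irregularity_index <- function(series) {
  stopifnot(inherits(series, "ppi_series"))
  if (length(series$intervals) < 2L) {
    afib_error("irregularity index needs at least 2 intervals",
               "afib_insufficient_data")
  }
  pop_sd(series$intervals) / mean(series$intervals)
}

#' Measurement period implied by a pulse count
#'
#' A measurement capturing `n_pulses` pulse intervals at `pulse_rate_bpm`
#' beats per minute lasts `n_pulses * 60 / pulse_rate_bpm` seconds (21.6
#' pulses at 80 bpm is 16.2 s).
#'
#' @param n_pulses Mean number of pulses per measurement.
#' @param pulse_rate_bpm Pulse rate in beats per minute (default 80).
#' @return Period in seconds.
#' @export
measurement_period <- function(n_pulses, pulse_rate_bpm = 80) {
  check_scalar_number(n_pulses, "n_pulses", lower = 0,
                      allow_equal_lower = FALSE)
  check_scalar_number(pulse_rate_bpm, "pulse_rate_bpm", lower = 0,
                      allow_equal_lower = FALSE)
  n_pulses * 60 / pulse_rate_bpm
}

confusion_from_vectors <- function(predictions, truth) {
  pos_t <- truth == POSITIVE_CLASS
  pos_p <- predictions == POSITIVE_CLASS
  confusion_table(tp = sum(pos_t & pos_p), fn = sum(pos_t & !pos_p),
                  tn = sum(!pos_t & !pos_p), fp = sum(!pos_t & pos_p))
}

#' Evaluate a study: confusion tables, CIs, subgroup comparisons
#'
#' Aligns predictions with ground truth, optionally per stratum, and
#' derives every study statistic: per-stratum confusion tables,
#' sensitivity/specificity with Wilson CIs, and — when exactly two strata
#' are supplied — Pearson chi-square comparisons of sensitivity and of
#' specificity between them, with rendered one-decimal percentage rows.
#'
#' @param predictions Character vector of predicted labels (`"AFIB"` /
#'   anything else = non-AFib).
#' @param truth Character vector of true labels, same length.
#' @param strata Optional grouping vector (same length); `NULL` evaluates
#'   one overall stratum.
#' @param confidence CI level (default 0.95).
#' @return List of class `afib_study_report`: `strata` (per-stratum list
#'   with `confusion`, `sensitivity`, `specificity`, rendered strings) and
#'   `comparisons` (chi-square results, two-strata case only).
#' @export
evaluate_study <- function(predictions, truth, strata = NULL,
                           confidence = 0.95) {
  if (length(predictions) != length(truth)) {
    afib_error("`predictions` and `truth` must have the same length",
               "afib_invalid_parameter")
  }
  predictions <- binarize_labels(as.character(predictions))
  truth <- binarize_labels(as.character(truth))
  if (is.null(strata)) strata <- rep("all", length(truth))
  if (length(strata) != length(truth)) {
    afib_error("`strata` must align with `truth`", "afib_invalid_parameter")
  }
  levels <- unique(strata)
  per <- lapply(levels, function(g) {
    sel <- strata == g
    ct <- confusion_from_vectors(predictions[sel], truth[sel])
    sens <- wilson_ci(ct$tp, ct$tp + ct$fn, confidence)
    spec <- wilson_ci(ct$tn, ct$tn + ct$fp, confidence)
    list(stratum = g, confusion = ct, sensitivity = sens,
         specificity = spec,
         rendered = c(sensitivity = format_estimate(sens),
                      specificity = format_estimate(spec)))
  })
  names(per) <- levels
  comparisons <- NULL
  if (length(levels) == 2L) {
    mk <- function(field_ok, field_all) {
      tb <- t(vapply(per, function(p) {
        ct <- p$confusion
        if (field_ok == "tp") c(ct$tp, ct$fn) else c(ct$tn, ct$fp)
      }, numeric(2)))
      ## all-correct (or all-wrong) strata: the table is independent by
      ## construction, so the comparison is uninformative and p = 1
      tryCatch(pearson_chi2_2x2(tb),
               afib_degenerate_table = function(e)
                 list(statistic = 0, p_value = 1))
    }
    comparisons <- list(sensitivity = mk("tp", "pos"),
                        specificity = mk("tn", "neg"))
  }
  structure(list(strata = per, comparisons = comparisons,
                 confidence = confidence),
            class = "afib_study_report")
}

#' @export
print.afib_study_report <- function(x, ...) {
  for (p in x$strata) {
    cat(sprintf("%-12s sensitivity %-18s specificity %-18s (TP %d FN %d TN %d FP %d)\n",
                p$stratum, p$rendered[["sensitivity"]],
                p$rendered[["specificity"]],
                p$confusion$tp, p$confusion$fn,
                p$confusion$tn, p$confusion$fp))
  }
  if (!is.null(x$comparisons)) {
    cat(sprintf("chi-square: sensitivity p = %.2f, specificity p = %.2f\n",
                x$comparisons$sensitivity$p_value,
                x$comparisons$specificity$p_value))
  }
  invisible(x)
}
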