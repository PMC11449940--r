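## Distributional features of one interval series, including the clustered
## standard deviation (C_STD): the pooled within-cluster SD of the interval
## multiset. AFib intervals spread into a single broad cluster, so C_STD
## stays close to the plain SD; patterned ectopy (bigeminy, trigeminy)
## splits into a few tight clusters, so C_STD collapses toward zero even
## though the plain SD is large. That contrast is what the classifier
## exploits, and it also confers noise tolerance: a merged (missed-beat)
## interval decomposes into its own cluster instead of inflating the SD.

#' Feature schema
#'
#' Names and order of the features computed by [compute_features()].
#' Percentiles are of the mean-normalized intervals (dimensionless);
#' kurtosis and other low-importance moments are deliberately absent.
#'
#' @format Character vector of feature names.
#' @export
FEATURE_SCHEMA <- c("mean_s", "max_s", "min_s", "sd_s", "cstd_s",
                    "p05", "p25", "p50", "p75", "p95",
                    "cv", "cstd_ratio", "n_intervals")

#' @rdname FEATURE_SCHEMA
#' @export
FEATURE_SCHEMA_VERSION <- "ppi-features/1"

default_gap <- function(intervals) 0.12 * stats::median(intervals)

#' Cluster intervals by sorted-gap splitting
#'
#' Sorts the intervals ascending and starts a new cluster wherever the gap
#' between adjacent sorted values exceeds the threshold. The clusters
#' partition the multiset; order within a cluster is irrelevant.
#'
#' With the default relative threshold (0.12 x median interval, about
#' 90 ms at 0.75 s), a typical AFib spread stays one broad cluster while
#' premature-coupling clusters several hundred ms apart split.
#'
#' @param intervals Numeric vector of intervals in seconds (>= 1).
#' @param gap_threshold Absolute gap in seconds, or `NULL` (default) for
#'   0.12 times the median interval.
#' @return List of numeric vectors, one per cluster, in ascending order of
#'   cluster location.
#' @export
cluster_intervals <- function(intervals, gap_threshold = NULL) {
  if (!is.numeric(intervals) || length(intervals) < 1L) {
    afib_error("`intervals` must be a non-empty numeric vector",
               "afib_invalid_parameter")
  }
  if (is.null(gap_threshold)) gap_threshold <- default_gap(intervals)
  check_scalar_number(gap_threshold, "gap_threshold", lower = 0,
                      allow_equal_lower = FALSE)
  s <- sort(intervals)
  if (length(s) == 1L) return(list(s))
  breaks <- which(diff(s) > gap_threshold)
  starts <- c(1L, breaks + 1L)
  ends <- c(breaks, length(s))
  mapply(function(a, b) s[a:b], starts, ends, SIMPLIFY = FALSE)
}

#' Clustered standard deviation (C_STD)
#'
#' Pools squared deviations from each cluster's own mean instead of the
#' grand mean:
#' \deqn{C_{STD} = \sqrt{\frac{1}{N} \sum_c \sum_{x \in c} (x - \bar x_c)^2}}
#' with `N` the total interval count (population convention). When exactly
#' one cluster forms, this equals the plain population SD; it is never
#' larger than the plain SD.
#'
#' @param intervals Numeric vector of intervals (>= 2).
#' @inheritParams cluster_intervals
#' @return C_STD in seconds.
#' @export
compute_cstd <- function(intervals, gap_threshold = NULL) {
  if (!is.numeric(intervals) || length(intervals) < 2L) {
    afib_error("C_STD needs at least 2 intervals",
               "afib_insufficient_data")
  }
  clusters <- cluster_intervals(intervals, gap_threshold)
  ss <- sum(vapply(clusters, function(cl) sum((cl - mean(cl))^2), 0.0))
  sqrt(ss / length(intervals))
}

#' Compute the feature vector of an interval series
#'
#' All distributional statistics of the schema: mean/max/min/SD/C_STD in
#' seconds, percentiles (5, 25, 50, 75, 95) of the mean-normalized
#' intervals (linear-interpolation definition), the coefficient of
#' variation `cv = sd/mean` (the irregularity index), the ratio
#' `cstd_ratio = cstd/sd` (defined as 1 when `sd = 0`), and the interval
#' count. Features are order-free: permuting the series leaves the vector
#' unchanged.
#'
#' @param series A [ppi_series] (assumed to have passed QC).
#' @param gap_threshold Clustering gap passed to [compute_cstd()]; `NULL`
#'   for the relative default.
#' @param min_intervals Minimum interval count (default 10); fewer is an
#'   insufficient-data error carrying the observed count.
#' @return Named numeric vector over [FEATURE_SCHEMA] with attribute
#'   `schema_version`.
#' @examples
#' compute_features(simulate_afib(22, seed = 7))
#' @export
compute_features <- function(series, gap_threshold = NULL,
                             min_intervals = 10) {
  stopifnot(inherits(series, "ppi_series"))
  x <- series$intervals
  n <- length(x)
  if (n < min_intervals) {
    afib_error(sprintf(
      "series has %d intervals; at least %d are required", n, min_intervals),
      "afib_insufficient_data")
  }
  m <- mean(x)
  sd_s <- pop_sd(x)
  cstd_s <- compute_cstd(x, gap_threshold)
  q <- stats::quantile(x / m, probs = c(.05, .25, .50, .75, .95),
                       names = FALSE, type = 7)
  fv <- c(mean_s = m, max_s = max(x), min_s = min(x),
          sd_s = sd_s, cstd_s = cstd_s,
          p05 = q[1], p25 = q[2], p50 = q[3], p75 = q[4], p95 = q[5],
          cv = sd_s / m,
          cstd_ratio = if (sd_s == 0) 1 else cstd_s / sd_s,
          n_intervals = n)
  attr(fv, "schema_version") <- FEATURE_SCHEMA_VERSION
  fv
}

#' Build a feature table from a dataset
#'
#' One row per measurement: `measurement_id`, `label`, then the feature
#' columns of [FEATURE_SCHEMA]. Measurements with too few intervals are
#' dropped with a warning naming them (they cannot be classified).
#'
#' @param dataset List of [ppi_series] (e.g. from [generate_dataset()]).
#' @inheritParams compute_features
#' @return A data.frame; the classifier module's input format.
#' @export
feature_table <- function(dataset, gap_threshold = NULL,
                          min_intervals = 10) {
  stopifnot(is.list(dataset), length(dataset) > 0L)
  rows <- vector("list", length(dataset))
  skipped <- character(0)
  for (i in seq_along(dataset)) {
    s <- dataset[[i]]
    fv <- tryCatch(compute_features(s, gap_threshold, min_intervals),
                   afib_insufficient_data = function(e) NULL)
    if (is.null(fv)) {
      skipped <- c(skipped, s$measurement_id)
      next
    }
    rows[[i]] <- data.frame(measurement_id = s$measurement_id,
                            label = s$label, t(fv),
                            stringsAsFactors = FALSE)
  }
  if (length(skipped) > 0L) {
    warning(sprintf("dropped %d measurement(s) with too few intervals: %s",
                    length(skipped), paste(skipped, collapse = ", ")))
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out) || nrow(out) == 0L) {
    afib_error("no measurement had enough intervals",
               "afib_insufficient_data")
  }
  rownames(out) <- NULL
  out
}
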