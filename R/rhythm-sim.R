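## Rhythm simulator: seeded generation of labelled pulse-to-pulse interval
## (PPI) series emulating normal sinus rhythm, atrial fibrillation, premature
## contractions, and missed-pulse artifacts. Stands in for clinical data so
## the whole screening pipeline can be trained and tested from code alone.

#' Rhythm labels
#'
#' The three rhythm classes the simulator produces. `AFIB` is the positive
#' class for classification; sinus rhythm and premature contractions (PC)
#' are both "non-AFib".
#'
#' @format Character constants `"AFIB"`, `"SINUS"`, `"PC"`.
#' @export
RHYTHM_LABELS <- c(AFIB = "AFIB", SINUS = "SINUS", PC = "PC")

check_label <- function(label) {
  if (length(label) != 1L) {
    afib_error("`label` must be a single value", "afib_invalid_parameter")
  }
  if (is.na(label)) return(NA_character_)
  if (!is.character(label) || !(label %in% RHYTHM_LABELS)) {
    afib_error("`label` must be one of AFIB, SINUS, PC or NA",
               "afib_invalid_parameter")
  }
  label
}

#' Construct a pulse-interval series
#'
#' A `ppi_series` holds the ordered pulse-to-pulse intervals (seconds) of a
#' single blood-pressure measurement, an optional ground-truth rhythm label,
#' a measurement id, and free-form provenance metadata.
#'
#' @param intervals Numeric vector of strictly positive intervals in seconds.
#' @param label One of `"AFIB"`, `"SINUS"`, `"PC"`, or `NA` when unknown.
#' @param measurement_id Identifier string.
#' @param meta Named list of provenance (generator, seed, parameters).
#' @return An object of class `ppi_series`.
#' @export
ppi_series <- function(intervals, label = NA_character_,
                       measurement_id = "m1", meta = list()) {
  if (!is.numeric(intervals) || length(intervals) < 1L ||
      any(!is.finite(intervals)) || any(intervals <= 0)) {
    afib_error("`intervals` must be a non-empty vector of positive seconds",
               "afib_invalid_parameter")
  }
  label <- check_label(label)
  structure(
    list(intervals = as.numeric(intervals), label = label,
         measurement_id = as.character(measurement_id), meta = meta),
    class = "ppi_series"
  )
}

#' @export
print.ppi_series <- function(x, ...) {
  cat(sprintf("<ppi_series %s: %d intervals, label %s, mean %.3f s>\n",
              x$measurement_id, length(x$intervals),
              ifelse(is.na(x$label), "unknown", x$label),
              mean(x$intervals)))
  invisible(x)
}

#' @export
length.ppi_series <- function(x) length(x$intervals)

## Positive-truncated Gaussian draw by rejection (jitter is small relative
## to the mean, so rejection is essentially never exercised in practice).
rnorm_pos <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x <= 0)
  while (length(bad) > 0L) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] <= 0]
  }
  x
}

#' Simulate a sinus-rhythm interval series
#'
#' Normal sinus rhythm shows near-constant pulse intervals: each interval is
#' the mean plus small zero-mean Gaussian jitter (truncated positive).
#'
#' @param n Number of intervals (>= 1).
#' @param mean_interval Mean interval in seconds (> 0). Default 0.75 s
#'   (80 bpm).
#' @param jitter_sd Standard deviation of the jitter in seconds (>= 0).
#'   Default 0.02 s, typical resting heart-rate variability.
#' @param seed Integer seed; the draw is reproducible given the seed.
#' @return A [ppi_series] labelled `"SINUS"`.
#' @examples
#' simulate_sinus(22, 0.75, 0.02, seed = 1)
#' @export
simulate_sinus <- function(n, mean_interval = 0.75, jitter_sd = 0.02, seed) {
  n <- check_count(n, "n")
  check_scalar_number(mean_interval, "mean_interval", lower = 0,
                      allow_equal_lower = FALSE)
  check_scalar_number(jitter_sd, "jitter_sd", lower = 0)
  x <- if (jitter_sd == 0) {
    check_seed(seed)
    rep(mean_interval, n)
  } else {
    with_rng(seed, rnorm_pos(n, mean_interval, jitter_sd))
  }
  ppi_series(x, "SINUS", meta = list(
    generator = "simulate_sinus", seed = seed,
    params = list(n = n, mean_interval = mean_interval, jitter_sd = jitter_sd)
  ))
}

#' Simulate an atrial-fibrillation interval series
#'
#' AFib produces an "irregularly irregular" pulse: intervals are drawn
#' i.i.d. (lag-1 autocorrelation ~ 0) from a positive distribution with the
#' requested mean and coefficient of variation. The default `cv = 0.13` is
#' the irregularity index reported for AFib in the cuff-based screening
#' literature; at a mean of 0.75 s it implies an interval SD of 97.5 ms.
#'
#' @param n Number of intervals (>= 1).
#' @param mean_interval Mean interval in seconds (> 0).
#' @param cv Coefficient of variation (SD/mean), in (0, 1). Default 0.13.
#' @param seed Integer seed.
#' @param dist Interval distribution: `"gamma"` (default; positive support,
#'   right skew typical of RR data) or `"truncnorm"` (Gaussian truncated
#'   positive).
#' @return A [ppi_series] labelled `"AFIB"`.
#' @export
simulate_afib <- function(n, mean_interval = 0.75, cv = 0.13, seed,
                          dist = c("gamma", "truncnorm")) {
  n <- check_count(n, "n")
  check_scalar_number(mean_interval, "mean_interval", lower = 0,
                      allow_equal_lower = FALSE)
  if (!is.numeric(cv) || length(cv) != 1L || !is.finite(cv) ||
      cv <= 0 || cv >= 1) {
    afib_error("`cv` must lie strictly between 0 and 1",
               "afib_invalid_parameter")
  }
  dist <- match.arg(dist)
  x <- with_rng(seed, {
    if (dist == "gamma") {
      shape <- 1 / cv^2
      stats::rgamma(n, shape = shape, scale = mean_interval / shape)
    } else {
      rnorm_pos(n, mean_interval, cv * mean_interval)
    }
  })
  ppi_series(x, "AFIB", meta = list(
    generator = "simulate_afib", seed = seed,
    params = list(n = n, mean_interval = mean_interval, cv = cv, dist = dist)
  ))
}

#' Simulate premature contractions
#'
#' A premature contraction (PC) is an early beat: a short coupling interval
#' `coupling_fraction * mean_interval` followed by a compensatory pause
#' `(2 - coupling_fraction) * mean_interval`, so each couplet conserves two
#' mean intervals. `bigeminy` makes every beat alternate normal/premature
#' (intervals alternate short/long), `trigeminy` makes every third beat
#' premature, and `random` makes each interval premature independently with
#' probability `pc_probability` (the following interval, when not itself
#' premature, is the compensatory pause).
#'
#' @param n Number of intervals.
#' @param mean_interval Mean normal interval in seconds.
#' @param pattern `"bigeminy"`, `"trigeminy"`, or `"random"`.
#' @param coupling_fraction Premature coupling as a fraction of the normal
#'   interval, in (0, 1). Default 0.7.
#' @param pc_probability Per-interval premature probability for the
#'   `"random"` pattern, in \[0, 1\]. Ignored otherwise.
#' @param jitter_sd Gaussian jitter SD in seconds added to every interval
#'   (default 0.02 s; set to 0 for the idealised patterned series).
#' @param seed Integer seed.
#' @return A [ppi_series] labelled `"PC"`.
#' @export
simulate_pc <- function(n, mean_interval = 0.75,
                        pattern = c("bigeminy", "trigeminy", "random"),
                        coupling_fraction = 0.7, pc_probability = 0.2,
                        jitter_sd = 0.02, seed) {
  n <- check_count(n, "n")
  check_scalar_number(mean_interval, "mean_interval", lower = 0,
                      allow_equal_lower = FALSE)
  pattern <- match.arg(pattern)
  if (!is.numeric(coupling_fraction) || length(coupling_fraction) != 1L ||
      coupling_fraction <= 0 || coupling_fraction >= 1) {
    afib_error("`coupling_fraction` must lie strictly between 0 and 1",
               "afib_invalid_parameter")
  }
  check_scalar_number(pc_probability, "pc_probability", lower = 0, upper = 1)
  check_scalar_number(jitter_sd, "jitter_sd", lower = 0)
  short <- coupling_fraction * mean_interval
  long <- (2 - coupling_fraction) * mean_interval
  x <- with_rng(seed, {
    base <- switch(pattern,
      bigeminy = rep_len(c(short, long), n),
      trigeminy = rep_len(c(mean_interval, short, long), n),
      random = {
        premature <- stats::runif(n) < pc_probability
        out <- rep(mean_interval, n)
        out[premature] <- short
        compensatory <- c(FALSE, premature[-n]) & !premature
        out[compensatory] <- long
        out
      }
    )
    if (jitter_sd > 0) base <- rnorm_pos(n, base, jitter_sd)
    base
  })
  ppi_series(x, "PC", meta = list(
    generator = "simulate_pc", seed = seed,
    params = list(n = n, mean_interval = mean_interval, pattern = pattern,
                  coupling_fraction = coupling_fraction,
                  pc_probability = pc_probability, jitter_sd = jitter_sd)
  ))
}

#' Inject missed-pulse artifacts
#'
#' Emulates the pulse detector skipping a beat (for example when the pulse
#' amplitude temporarily drops): each missed beat merges two adjacent
#' intervals into their exact sum, so the total measurement duration is
#' conserved while the series shortens by one interval per merge.
#'
#' @param series A [ppi_series].
#' @param k Number of merges; must satisfy `k < length(series) - 1`.
#' @param seed Integer seed choosing which adjacent pairs merge.
#' @return A [ppi_series] with `length(series) - k` intervals and the same
#'   label.
#' @export
inject_missed_beats <- function(series, k, seed) {
  stopifnot(inherits(series, "ppi_series"))
  k <- check_count(k, "k", min = 0L)
  if (k >= length(series$intervals) - 1L) {
    afib_error("`k` must be smaller than length(series) - 1",
               "afib_invalid_parameter")
  }
  if (k == 0L) return(series)
  x <- with_rng(seed, {
    out <- series$intervals
    for (i in seq_len(k)) {
      j <- sample.int(length(out) - 1L, 1L)
      out[j] <- out[j] + out[j + 1L]
      out <- out[-(j + 1L)]
    }
    out
  })
  meta <- series$meta
  meta$missed_beats <- list(k = k, seed = seed)
  ppi_series(x, series$label, series$measurement_id, meta)
}

#' Generate a labelled dataset of interval series
#'
#' Produces a collection of measurements across rhythm classes, with the
#' per-measurement interval count drawn as Normal(`n_intervals_mean`,
#' `n_intervals_sd`) rounded and truncated at `n_intervals_min`, emulating
#' the ~22 pulses captured by one oscillometric blood-pressure measurement.
#'
#' @param class_specs List of class specifications; each element is a list
#'   with `label` (`"AFIB"`, `"SINUS"` or `"PC"`), `count` (number of
#'   measurements), and optional `params` (arguments forwarded to the class
#'   generator, e.g. `cv`, `jitter_sd`, `pattern`).
#' @param n_intervals_mean Mean interval count per measurement (default 22).
#' @param n_intervals_sd SD of the interval count (default 3).
#' @param n_intervals_min Lower truncation of the count (default 10).
#' @param seed Master seed; all per-measurement seeds derive from it.
#' @return List of [ppi_series]; class counts are exactly as requested.
#' @examples
#' ds <- generate_dataset(list(
#'   list(label = "AFIB", count = 5),
#'   list(label = "SINUS", count = 5)
#' ), seed = 42)
#' table(vapply(ds, function(s) s$label, ""))
#' @export
generate_dataset <- function(class_specs, n_intervals_mean = 22,
                             n_intervals_sd = 3, n_intervals_min = 10,
                             seed) {
  if (!is.list(class_specs) || length(class_specs) == 0L) {
    afib_error("`class_specs` must be a non-empty list",
               "afib_invalid_parameter")
  }
  counts <- vapply(class_specs, function(s) check_count(s$count, "count"), 1L)
  total <- sum(counts)
  seeds <- derive_seeds(seed, total + 1L)
  lengths <- with_rng(seeds[total + 1L], {
    pmax(n_intervals_min, round(stats::rnorm(total, n_intervals_mean,
                                             n_intervals_sd)))
  })
  out <- vector("list", total)
  idx <- 0L
  for (spec in class_specs) {
    label <- check_label(spec$label)
    params <- spec$params %||% list()
    for (i in seq_len(spec$count)) {
      idx <- idx + 1L
      args <- c(list(n = lengths[idx]), params, list(seed = seeds[idx]))
      s <- switch(label,
        AFIB = do.call(simulate_afib, args),
        SINUS = do.call(simulate_sinus, args),
        PC = do.call(simulate_pc, args)
      )
      s$measurement_id <- sprintf("%s_%04d", tolower(label), idx)
      out[[idx]] <- s
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
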