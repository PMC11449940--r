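## Oscillometric front end: synthesize pressure pulse waveforms (PPWs) from
## interval series, recover pulse peaks, and difference them back into
## pulse-to-pulse intervals — a functional stand-in for the blood-pressure
## monitor's (proprietary) pulse detector, sufficient to reproduce the
## missed-beat phenomenology and the constant-interval simulator experiment.

#' Construct a pressure pulse wave
#'
#' @param samples Numeric amplitude vector (arbitrary pressure units).
#' @param sampling_rate Sampling rate in Hz (> 0).
#' @param true_peak_times Optional strictly increasing ground-truth peak
#'   times in seconds (recorded when the wave is synthesized).
#' @return An object of class `ppw`.
#' @export
ppw <- function(samples, sampling_rate, true_peak_times = NULL) {
  check_scalar_number(sampling_rate, "sampling_rate", lower = 0,
                      allow_equal_lower = FALSE)
  if (!is.numeric(samples) || any(!is.finite(samples))) {
    afib_error("`samples` must be finite numeric", "afib_invalid_parameter")
  }
  if (!is.null(true_peak_times)) {
    if (is.unsorted(true_peak_times, strictly = TRUE)) {
      afib_error("`true_peak_times` must be strictly increasing",
                 "afib_invalid_parameter")
    }
  }
  structure(list(samples = as.numeric(samples),
                 sampling_rate = sampling_rate,
                 true_peak_times = true_peak_times),
            class = "ppw")
}

#' @export
print.ppw <- function(x, ...) {
  cat(sprintf("<ppw: %d samples @ %g Hz (%.1f s)%s>\n",
              length(x$samples), x$sampling_rate,
              length(x$samples) / x$sampling_rate,
              if (is.null(x$true_peak_times)) "" else
                sprintf(", %d true peaks", length(x$true_peak_times))))
  invisible(x)
}

#' Synthesize an oscillometric pressure pulse wave
#'
#' Places one Gaussian-shaped pulse per beat at the cumulative interval
#' times of `series` (plus a lead-in pad). The `oscillometric_bell`
#' envelope modulates pulse amplitudes with a raised cosine over the
#' measurement, mimicking the amplitude envelope seen during cuff
#' deflation; `amplitude_dips` attenuates selected pulses so the missed-
#' beat scenario can be reproduced by construction.
#'
#' @param series A [ppi_series]; `n` intervals yield `n + 1` pulses.
#' @param sampling_rate Sampling rate in Hz (>= 50). Default 100.
#' @param pulse_width Gaussian standard deviation of one pulse in seconds;
#'   must be smaller than the shortest interval. Default 0.08 s.
#' @param envelope `"flat"` (all pulses unit amplitude) or
#'   `"oscillometric_bell"` (raised-cosine modulation, floor 0.2).
#' @param amplitude_dips Optional list of `c(pulse_index, factor)` pairs;
#'   pulse `pulse_index` (1-based) is scaled by `factor`. Attenuating an
#'   interior pulse `k` below the detector threshold merges intervals
#'   `k - 1` and `k` downstream.
#' @param noise_sd Additive white Gaussian noise SD (amplitude units).
#' @param seed Integer seed (used only when `noise_sd > 0`).
#' @return A [ppw] carrying the true peak times.
#' @export
synthesize_ppw <- function(series, sampling_rate = 100, pulse_width = 0.08,
                           envelope = c("flat", "oscillometric_bell"),
                           amplitude_dips = list(), noise_sd = 0,
                           seed = 0L) {
  stopifnot(inherits(series, "ppi_series"))
  check_scalar_number(sampling_rate, "sampling_rate", lower = 50)
  check_scalar_number(pulse_width, "pulse_width", lower = 0,
                      allow_equal_lower = FALSE)
  check_scalar_number(noise_sd, "noise_sd", lower = 0)
  envelope <- match.arg(envelope)
  if (pulse_width >= min(series$intervals)) {
    afib_error("`pulse_width` must be smaller than the shortest interval",
               "afib_pulse_overlap")
  }
  pad <- 4 * pulse_width
  peak_times <- pad + c(0, cumsum(series$intervals))
  n_pulse <- length(peak_times)
  duration <- peak_times[n_pulse] + pad
  t <- seq(0, duration, by = 1 / sampling_rate)

  amps <- rep(1, n_pulse)
  if (envelope == "oscillometric_bell") {
    span <- peak_times[n_pulse] - peak_times[1]
    phase <- (peak_times - peak_times[1]) / span
    amps <- 0.2 + 0.8 * (1 - cos(2 * pi * phase)) / 2
  }
  for (dip in amplitude_dips) {
    k <- check_count(dip[[1]], "amplitude_dips index")
    if (k > n_pulse) {
      afib_error("amplitude dip index exceeds the pulse count",
                 "afib_invalid_parameter")
    }
    amps[k] <- amps[k] * dip[[2]]
  }

  x <- numeric(length(t))
  for (j in seq_len(n_pulse)) {
    x <- x + amps[j] * exp(-((t - peak_times[j])^2) / (2 * pulse_width^2))
  }
  if (noise_sd > 0) {
    x <- x + with_rng(seed, stats::rnorm(length(t), 0, noise_sd))
  }
  ppw(x, sampling_rate, true_peak_times = peak_times)
}

## Centered rolling maximum, window in samples (odd), edges padded by the
## edge value so early/late pulses compare against their local envelope.
rolling_max <- function(x, window) {
  window <- max(1L, as.integer(window))
  if (window %% 2L == 0L) window <- window + 1L
  half <- (window - 1L) %/% 2L
  padded <- c(rep(x[1], half), x, rep(x[length(x)], half))
  as.numeric(zoo::rollmax(padded, k = window, align = "center"))
}

#' Detect pulse peaks in a pressure pulse wave
#'
#' Local maxima exceeding `threshold_fraction` times the rolling maximum
#' amplitude (window `window_s`), thinned so accepted peaks are separated
#' by at least the refractory period; candidates are accepted in order of
#' decreasing amplitude, which is deterministic.
#'
#' @param wave A [ppw].
#' @param threshold_fraction Fraction of the rolling maximum a local
#'   maximum must exceed, in (0, 1). Default 0.3 — a 10-fold amplitude dip
#'   falls below it and is missed, as intended.
#' @param refractory Minimum separation between accepted peaks in seconds
#'   (> 0). Default 0.3 s.
#' @param window_s Rolling-maximum window in seconds. Default 3 s.
#' @return Strictly increasing peak times in seconds; an empty numeric
#'   vector for a flat or empty signal (not an error).
#' @export
detect_pulse_peaks <- function(wave, threshold_fraction = 0.3,
                               refractory = 0.3, window_s = 3) {
  stopifnot(inherits(wave, "ppw"))
  if (threshold_fraction <= 0 || threshold_fraction >= 1) {
    afib_error("`threshold_fraction` must lie strictly between 0 and 1",
               "afib_invalid_parameter")
  }
  check_scalar_number(refractory, "refractory", lower = 0,
                      allow_equal_lower = FALSE)
  x <- wave$samples
  n <- length(x)
  if (n < 3L || max(x) == min(x)) return(numeric(0))
  i <- 2:(n - 1L)
  is_max <- x[i] > x[i - 1L] & x[i] >= x[i + 1L]
  cand <- i[is_max]
  roll <- rolling_max(x, round(window_s * wave$sampling_rate))
  cand <- cand[x[cand] > threshold_fraction * roll[cand]]
  if (length(cand) == 0L) return(numeric(0))
  ## greedy acceptance by amplitude, enforcing the refractory period
  cand <- cand[order(x[cand], decreasing = TRUE)]
  gap <- refractory * wave$sampling_rate
  kept <- integer(0)
  for (c_ix in cand) {
    if (all(abs(kept - c_ix) >= gap)) kept <- c(kept, c_ix)
  }
  sort((kept - 1L) / wave$sampling_rate)
}

#' Difference peak times into pulse-to-pulse intervals
#'
#' @param peak_times Strictly increasing peak times in seconds (>= 2).
#' @param measurement_id Identifier for the resulting series.
#' @return A [ppi_series] of successive differences (label unknown); its
#'   intervals sum exactly to `last peak - first peak`.
#' @export
extract_ppi <- function(peak_times, measurement_id = "extracted") {
  if (!is.numeric(peak_times) || length(peak_times) < 2L) {
    afib_error("need at least 2 peak times to form an interval",
               "afib_insufficient_data")
  }
  if (is.unsorted(peak_times, strictly = TRUE)) {
    afib_error("`peak_times` must be strictly increasing",
               "afib_invalid_parameter")
  }
  ppi_series(diff(peak_times), NA_character_, measurement_id,
             meta = list(generator = "extract_ppi"))
}

#' Quality-control an interval series
#'
#' Removes intervals outside the physiological plausibility window
#' (defaults 0.3–2.0 s, i.e. 30–200 bpm) and records how many were removed
#' in the series metadata.
#'
#' @param series A [ppi_series].
#' @param min_s,max_s Plausibility bounds in seconds, `min_s < max_s`.
#' @return The filtered [ppi_series]; `meta$qc_removed` holds the count.
#' @export
qc_intervals <- function(series, min_s = 0.3, max_s = 2.0) {
  stopifnot(inherits(series, "ppi_series"))
  if (min_s >= max_s) {
    afib_error("`min_s` must be smaller than `max_s`",
               "afib_invalid_parameter")
  }
  keep <- series$intervals >= min_s & series$intervals <= max_s
  if (!any(keep)) {
    afib_error("QC removed every interval", "afib_insufficient_data")
  }
  meta <- series$meta
  meta$qc_removed <- sum(!keep)
  ppi_series(series$intervals[keep], series$label, series$measurement_id,
             meta)
}

#' Constant-interval pulse-extraction experiment
#'
#' Emulates the bench evaluation of pulse-to-pulse interval accuracy
#' against a simulator producing an artificial pressure wave with a
#' precisely constant interval (0.75 s, 80 bpm): for each repeat a
#' constant-interval wave with per-interval Gaussian timing jitter is
#' synthesized, peaks are detected, intervals extracted, and their mean and
#' SD recorded.
#'
#' Device timing jitter is applied per interval (each pulse perturbed
#' relative to the previous one), so the per-measurement interval SD
#' estimates `device_jitter_sd` directly.
#'
#' @param device_jitter_sd Timing jitter SD in seconds (default 0.011,
#'   calibrated to the ~11 ms interval SD such devices show on a constant
#'   input).
#' @param repeats Number of repeated measurements (default 30).
#' @param n_intervals Intervals per measurement (default 22).
#' @param true_interval The constant interval in seconds (default 0.75).
#' @param sampling_rate Waveform sampling rate in Hz (default 500, so
#'   sample quantization contributes ~1 ms, negligible next to the jitter).
#' @param seed Integer seed.
#' @return A list with per-measurement `mean_s` and `sd_s` vectors and the
#'   aggregates `mean_ppi_s`, `sd_of_means_s`, `mean_sd_ms`, `sd_of_sd_ms`.
#' @export
cufflink_experiment <- function(device_jitter_sd = 0.011, repeats = 30,
                                n_intervals = 22, true_interval = 0.75,
                                sampling_rate = 500, seed) {
  repeats <- check_count(repeats, "repeats")
  check_scalar_number(device_jitter_sd, "device_jitter_sd", lower = 0)
  seeds <- derive_seeds(seed, 2L * repeats)
  means <- sds <- numeric(repeats)
  for (r in seq_len(repeats)) {
    base <- ppi_series(rep(true_interval, n_intervals), "SINUS",
                       sprintf("cufflink_%02d", r))
    if (device_jitter_sd > 0) {
      jittered <- with_rng(seeds[r], {
        rnorm_pos(n_intervals, base$intervals, device_jitter_sd)
      })
      base <- ppi_series(jittered, "SINUS", base$measurement_id)
    }
    wave <- synthesize_ppw(base, sampling_rate = sampling_rate,
                           seed = seeds[repeats + r])
    got <- extract_ppi(detect_pulse_peaks(wave))
    means[r] <- mean(got$intervals)
    sds[r] <- pop_sd(got$intervals)
  }
  list(mean_s = means, sd_s = sds,
       mean_ppi_s = mean(means), sd_of_means_s = stats::sd(means),
       mean_sd_ms = mean(sds) * 1000, sd_of_sd_ms = stats::sd(sds) * 1000)
}
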