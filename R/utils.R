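#' @keywords internal
"_PACKAGE"

## Input checking helpers shared across modules. All user-facing errors are
## classed so callers (and the CLI) can branch on condition class.

afib_error <- function(msg, class) {
  stop(structure(
    class = c(class, "afibscreen_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                allow_equal_lower = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    afib_error(sprintf("`%s` must be a single finite number", name),
               "afib_invalid_parameter")
  }
  bad_low <- if (allow_equal_lower) x < lower else x <= lower
  if (bad_low || x > upper) {
    afib_error(sprintf("`%s` = %g is outside its valid range", name, x),
               "afib_invalid_parameter")
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x != as.integer(x) || x < min) {
    afib_error(sprintf("`%s` must be an integer >= %d", name, min),
               "afib_invalid_parameter")
  }
  invisible(as.integer(x))
}

check_seed <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed) ||
      seed != as.integer(seed)) {
    afib_error("`seed` must be a single integer", "afib_invalid_parameter")
  }
  invisible(as.integer(seed))
}

## Evaluate `code` under a fixed RNG state without touching the caller's
## stream (no hidden global state: every stochastic operation is seeded).
with_rng <- function(seed, code) {
  withr::with_seed(check_seed(seed), code)
}

## Derive per-item sub-seeds from a master seed, each < 2^31.
derive_seeds <- function(seed, n) {
  with_rng(seed, sample.int(.Machine$integer.max, n, replace = FALSE))
}

## Population (1/N) standard deviation: the convention used throughout so
## that the clustered SD equals the plain SD exactly in the one-cluster case.
pop_sd <- function(x) {
  sqrt(mean((x - mean(x))^2))
}

## Half-up decimal rounding for table rendering (R's round() is half-even).
round_half_up <- function(x, digits = 1) {
  floor(x * 10^digits + 0.5) / 10^digits
}
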