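# Shared helpers: condition classes, SEM, seed derivation.

stop_parameter <- function(message, ...) {
  rlang::abort(message, class = "motorunit_parameter_error", ...)
}

stop_data <- function(message, ...) {
  rlang::abort(message, class = "motorunit_data_error", ...)
}

stop_schema <- function(message, ...) {
  rlang::abort(message, class = "motorunit_schema_error", ...)
}

check_scalar_number <- function(x, name, min = -Inf, max = Inf,
                                strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_parameter(sprintf("`%s` must be a single finite number", name))
  }
  if (strict_min && x <= min) {
    stop_parameter(sprintf("`%s` must be > %s (got %s)", name, min, x))
  }
  if (!strict_min && x < min) {
    stop_parameter(sprintf("`%s` must be >= %s (got %s)", name, min, x))
  }
  if (x > max) {
    stop_parameter(sprintf("`%s` must be <= %s (got %s)", name, max, x))
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x != round(x) || x < min) {
    stop_parameter(sprintf("`%s` must be an integer >= %s", name, min))
  }
  invisible(as.integer(x))
}

check_probability <- function(x, name) {
  check_scalar_number(x, name, min = 0, max = 1)
}

#' Mean and standard error of the mean
#'
#' SEM uses the n - 1 sample standard deviation; a single observation has
#' SEM 0 so that singleton groups are reportable.
#'
#' @param x Numeric vector.
#' @return A one-row tibble with `mean`, `sem` and `n`.
#' @export
mean_sem <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  s <- if (n > 1L) stats::sd(x) / sqrt(n) else 0
  tibble::tibble(mean = if (n > 0L) mean(x) else NA_real_, sem = s, n = n)
}

#' Derive reproducible sub-seeds from one master seed
#'
#' All randomness in a multi-unit simulation (chambers, tracks, explants)
#' flows from a single user-supplied seed via sub-seeds drawn here, so
#' whole cohorts are reproducible from one integer. The caller's RNG
#' state is left untouched and every derived seed stays below 2^31.
#'
#' @param seed Master seed (non-negative integer).
#' @param n Number of sub-seeds.
#' @return An integer vector of `n` seeds.
#' @export
derive_seeds <- function(seed, n) {
  check_count(seed, "seed", min = 0L)
  check_count(n, "n", min = 1L)
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Maximal runs of TRUE in a logical vector, kept only if >= min_len.
# Returns a data.frame with 1-based `start` and `length`.
runs_of <- function(flag, min_len) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  data.frame(start = starts[keep], length = r$lengths[keep])
}
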