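#' Dense regularly sampled timeseries
#'
#' Container for a regularly sampled series: a start time, a fixed spacing,
#' and a vector of values. Values are rates (events per hour by convention);
#' time is always in days. `NA` values mark missing stretches that
#' [interpolate_gaps()] can fill.
#'
#' @param values Numeric vector of length `N` (may contain `NA`).
#' @param t0 Start time of the first sample, in days.
#' @param dt Sample spacing in days (`> 0`).
#' @return An object of class `dense_series` with fields `t0`, `dt`, `values`.
#' @seealso [sampled_series()], [series_times()]
#' @export
dense_series <- function(values, t0 = 0, dt) {
  stopifnot(is.numeric(values), length(values) >= 1)
  if (!is.numeric(dt) || length(dt) != 1 || !is.finite(dt) || dt <= 0)
    stop("'dt' must be a single positive number (days)")
  if (!is.numeric(t0) || length(t0) != 1 || !is.finite(t0))
    stop("'t0' must be a single finite number (days)")
  if (any(!is.finite(values) & !is.na(values)))
    stop("values must be finite or NA")
  structure(list(t0 = as.numeric(t0), dt = as.numeric(dt),
                 values = as.numeric(values)),
            class = "dense_series")
}

#' @export
print.dense_series <- function(x, ...) {
  n <- length(x$values)
  cat(sprintf("<dense_series> N = %d, dt = %.6g days, span = [%.4g, %.4g] days",
              n, x$dt, x$t0, x$t0 + (n - 1) * x$dt), "\n")
  if (anyNA(x$values))
    cat(sprintf("  %d missing values\n", sum(is.na(x$values))))
  invisible(x)
}

#' @export
length.dense_series <- function(x) length(x$values)

#' Sample times of a series
#'
#' @param x A `dense_series` or `sampled_series`.
#' @return Numeric vector of times in days.
#' @export
series_times <- function(x) {
  if (inherits(x, "dense_series"))
    return(x$t0 + (seq_along(x$values) - 1) * x$dt)
  if (inherits(x, "sampled_series")) return(x$times)
  stop("no times for object of class ", paste(class(x), collapse = "/"))
}

#' Sparse irregularly sampled timeseries
#'
#' The observed vector `y` together with its irregular sample times. When the
#' samples were drawn from a dense grid (see [random_sample()]) the object
#' also records the grid geometry (`N`, `t0`, `dt`) and the row-selection
#' `mask`, which the fitting routines use to subsample the dictionaries.
#'
#' @param times Strictly increasing numeric vector of sample times (days).
#' @param values Numeric vector of the same length (events/hour).
#' @param mask Optional integer vector of source-grid indices (strictly
#'   increasing, unique), one per sample.
#' @param N,t0,dt Optional source dense-grid geometry.
#' @return An object of class `sampled_series`.
#' @export
sampled_series <- function(times, values, mask = NULL,
                           N = NULL, t0 = NULL, dt = NULL) {
  stopifnot(is.numeric(times), is.numeric(values))
  if (length(times) != length(values))
    stop("'times' and 'values' must have equal length")
  if (length(times) >= 2 && any(diff(times) <= 0))
    stop("'times' must be strictly increasing")
  if (!all(is.finite(values))) stop("values must be finite")
  if (!is.null(mask)) {
    mask <- as.integer(mask)
    if (length(mask) != length(times)) stop("mask length mismatch")
    if (anyDuplicated(mask) || any(diff(mask) <= 0))
      stop("mask indices must be strictly increasing and unique")
    if (!is.null(N) && (any(mask < 1) || any(mask > N)))
      stop("mask indices out of range [1, N]")
  }
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 mask = mask, N = N, t0 = t0, dt = dt),
            class = "sampled_series")
}

#' @export
print.sampled_series <- function(x, ...) {
  cat(sprintf("<sampled_series> m = %d samples over [%.4g, %.4g] days",
              length(x$times), min(x$times), max(x$times)), "\n")
  if (!is.null(x$N))
    cat(sprintf("  source grid: N = %d, dt = %.6g days\n", x$N, x$dt))
  invisible(x)
}

#' @export
length.sampled_series <- function(x) length(x$times)

#' Align a sampled series to a dense analysis grid
#'
#' Maps each sample time to the nearest index of a regular grid so that the
#' oscillation and trend dictionaries can be subsampled at the observation
#' rows. Used when samples come from a file rather than [random_sample()].
#'
#' @param x A `sampled_series`.
#' @param N Grid length.
#' @param dt Grid spacing (days).
#' @param t0 Grid start time (days); default the first sample time.
#' @return The series with `mask`, `N`, `t0`, `dt` filled in.
#' @export
attach_grid <- function(x, N, dt, t0 = x$times[1]) {
  stopifnot(inherits(x, "sampled_series"))
  idx <- round((x$times - t0) / dt) + 1L
  if (any(idx < 1L) || any(idx > N))
    stop("sample times fall outside the dense grid")
  if (anyDuplicated(idx))
    stop("two samples map to the same grid point; use a finer grid")
  sampled_series(x$times, x$values, mask = as.integer(idx),
                 N = as.integer(N), t0 = t0, dt = dt)
}

#' Event-time series (e.g. seizure onsets)
#'
#' @param event_times Sorted, nonnegative numeric vector of event times (days).
#' @return An object of class `event_series`.
#' @export
event_series <- function(event_times) {
  stopifnot(is.numeric(event_times))
  event_times <- as.numeric(event_times)
  if (length(event_times) && any(event_times < 0))
    stop("event times must be nonnegative")
  if (is.unsorted(event_times)) event_times <- sort(event_times)
  structure(list(event_times = event_times), class = "event_series")
}

#' @export
print.event_series <- function(x, ...) {
  cat(sprintf("<event_series> %d events\n", length(x$event_times)))
  invisible(x)
}
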