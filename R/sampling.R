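#' Draw sparse random samples from a dense series
#'
#' Selects `floor(rate_per_day * window length)` grid indices uniformly at
#' random without replacement from the requested window (optionally excluding
#' dropped intervals), emulating sparse irregular acquisition at a nominal
#' average rate. The draw is a single global draw over the window, so the
#' total count is exact rather than binomial.
#'
#' @param dense A `dense_series`.
#' @param rate_per_day Average number of samples per day (> 0). Ignored when
#'   `n_total` is given.
#' @param window_days Length-2 numeric: start and end of the sampling window
#'   in days (default the full record).
#' @param seed Integer seed.
#' @param exclude Optional `drop_mask` (see [make_drop_mask()]) or a 2-column
#'   matrix of excluded intervals in days; no samples are drawn inside them.
#' @param n_total Optional fixed total sample count, overriding the
#'   rate-derived count (used for the data-drop experiments where the sample
#'   budget is held constant across drop conditions).
#' @param per_day Logical; if `TRUE`, stratify the draw day by day
#'   (`floor(rate)` samples from each whole day) instead of the default global
#'   draw.
#' @return A `sampled_series` carrying the selection `mask` and source grid
#'   geometry.
#' @examples
#' d <- dense_series(sin(2 * pi * (0:999) / 100), dt = 0.1)
#' s <- random_sample(d, rate_per_day = 2, seed = 7)
#' length(s)  # floor(2 * 100) = 200 samples over the 100-day record
#' @export
random_sample <- function(dense, rate_per_day = NULL, window_days = NULL,
                          seed = 1L, exclude = NULL, n_total = NULL,
                          per_day = FALSE) {
  stopifnot(inherits(dense, "dense_series"))
  N <- length(dense$values)
  tt <- series_times(dense)
  if (is.null(window_days)) window_days <- c(tt[1], tt[N])
  stopifnot(length(window_days) == 2, window_days[2] > window_days[1])
  in_window <- tt >= window_days[1] & tt <= window_days[2]
  eligible <- which(in_window & !is.na(dense$values))
  if (!is.null(exclude)) {
    iv <- if (inherits(exclude, "drop_mask")) exclude$intervals else exclude
    stopifnot(is.matrix(iv) || is.null(iv))
    if (!is.null(iv) && nrow(iv)) {
      drop <- rep(FALSE, length(eligible))
      for (r in seq_len(nrow(iv)))
        drop <- drop | (tt[eligible] >= iv[r, 1] & tt[eligible] < iv[r, 2])
      eligible <- eligible[!drop]
    }
  }
  span <- window_days[2] - window_days[1]
  if (per_day) {
    if (is.null(rate_per_day)) stop("per-day sampling needs 'rate_per_day'")
    k <- floor(rate_per_day)
    if (k < 1) stop("per-day sampling needs rate_per_day >= 1")
    edges <- seq(window_days[1], window_days[2], by = 1)
    idx <- with_seed(seed, {
      unlist(lapply(seq_len(length(edges) - 1), function(i) {
        pool <- eligible[tt[eligible] >= edges[i] & tt[eligible] < edges[i + 1]]
        if (length(pool) < k) stop("not enough grid points in day ", i)
        pool[sample.int(length(pool), k)]
      }))
    })
  } else {
    m <- if (!is.null(n_total)) as.integer(n_total)
         else floor(rate_per_day * span)
    if (m < 1) stop("requested sample count is zero")
    if (m > length(eligible))
      stop(sprintf("requested %d samples but only %d grid points available",
                   m, length(eligible)))
    idx <- with_seed(seed, eligible[sample.int(length(eligible), m)])
  }
  idx <- sort(idx)
  sampled_series(tt[idx], dense$values[idx], mask = idx,
                 N = N, t0 = dense$t0, dt = dense$dt)
}

#' Random placement of contiguous data-drop blocks
#'
#' Places `total_drop_days / block_length_days` non-overlapping contiguous
#' intervals uniformly at random inside the window. The intervals are meant
#' to be passed to [random_sample()] via `exclude` while holding the total
#' sample count fixed, emulating multiday telemetry drops.
#'
#' @param window_days Length-2 numeric window (days).
#' @param block_length_days Length of each dropped block (days).
#' @param total_drop_days Total dropped duration; must be a multiple of the
#'   block length.
#' @param seed Integer seed.
#' @return An object of class `drop_mask` with an `intervals` matrix
#'   (columns: start, end in days).
#' @export
make_drop_mask <- function(window_days, block_length_days, total_drop_days,
                           seed = 1L) {
  stopifnot(length(window_days) == 2, window_days[2] > window_days[1])
  if (total_drop_days == 0)
    return(structure(list(intervals = matrix(numeric(0), ncol = 2),
                          block_length = block_length_days, seed = seed),
                     class = "drop_mask"))
  if (total_drop_days %% block_length_days != 0)
    stop("'total_drop_days' must be a multiple of 'block_length_days'")
  n_blocks <- total_drop_days / block_length_days
  span <- window_days[2] - window_days[1]
  free <- span - total_drop_days
  if (free < 0) stop("drop blocks do not fit in the window")
  # classic uniform placement of non-overlapping segments: draw the gaps
  starts <- with_seed(seed, {
    g <- sort(runif(n_blocks, 0, free))
    window_days[1] + g + (seq_len(n_blocks) - 1) * block_length_days
  })
  intervals <- cbind(start = starts, end = starts + block_length_days)
  structure(list(intervals = intervals, block_length = block_length_days,
                 seed = seed),
            class = "drop_mask")
}

#' @export
print.drop_mask <- function(x, ...) {
  cat(sprintf("<drop_mask> %d blocks of %g days\n",
              nrow(x$intervals), x$block_length))
  invisible(x)
}

#' Shuffle observed values over fixed sample times
#'
#' Permutes the values of a sampled series uniformly at random while leaving
#' the sample times (and hence all inter-sample intervals) untouched. This is
#' the null-generating operation behind the shuffle noise floor: temporal
#' structure is destroyed, the sampling pattern and value distribution are
#' preserved.
#'
#' @param sampled A `sampled_series` with at least 2 samples.
#' @param seed Integer seed.
#' @return A `sampled_series` with permuted values.
#' @export
shuffle_values <- function(sampled, seed = 1L) {
  stopifnot(inherits(sampled, "sampled_series"))
  m <- length(sampled$values)
  if (m < 2) stop("need at least 2 samples to shuffle")
  perm <- with_seed(seed, sample.int(m))
  out <- sampled
  out$values <- sampled$values[perm]
  out
}

#' Interpolate missing stretches and peri-ictal windows
#'
#' Marks samples inside each event's peri-ictal window (`periictal_hours`
#' before the event through `periictal_hours` after) as invalid, then fills
#' every invalid or missing stretch by linear interpolation between the
#' flanking valid points. Leading and trailing gaps take the nearest valid
#' value.
#'
#' @param dense A `dense_series`, possibly with `NA` values.
#' @param events Optional `event_series` of event onsets (days). Events may
#'   carry a duration via `event_end`; by default events are instantaneous.
#' @param periictal_hours Half-width of the exclusion window in hours
#'   (default 2).
#' @param event_end Optional numeric vector of event end times (days),
#'   parallel to the events.
#' @return A `dense_series` with no missing values.
#' @export
interpolate_gaps <- function(dense, events = NULL, periictal_hours = 2,
                             event_end = NULL) {
  stopifnot(inherits(dense, "dense_series"))
  v <- dense$values
  tt <- series_times(dense)
  valid <- !is.na(v)
  if (!is.null(events)) {
    stopifnot(inherits(events, "event_series"))
    et <- events$event_times
    ee <- if (is.null(event_end)) et else event_end
    stopifnot(length(ee) == length(et))
    half <- periictal_hours / 24
    for (i in seq_along(et))
      valid[tt >= et[i] - half & tt <= ee[i] + half] <- FALSE
  }
  if (!any(valid)) stop("no valid points left to interpolate from")
  if (all(valid)) return(dense)
  filled <- stats::approx(tt[valid], v[valid], xout = tt, method = "linear",
                          rule = 2)$y
  out <- dense
  out$values <- ifelse(valid, v, filled)
  out
}
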