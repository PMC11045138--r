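#' Time-averaged wavelet reference spectrum
#'
#' Continuous wavelet transform of a dense regular series with a generalized
#' Morse wavelet (symmetry gamma = 3, time-bandwidth product P^2 = 60 by
#' default), power averaged over time at each scale. This is the dense-data
#' broadband reference against which the narrowband BPWP spectrum is judged.
#'
#' @param dense A gap-free `dense_series`.
#' @param periods_days Center periods (days) at which to evaluate; default
#'   log-spaced, 12 voices per octave, from `max(0.5, 4 dt)` to
#'   `min(150, span / 2)` days.
#' @param gamma Morse symmetry parameter (default 3).
#' @param time_bandwidth Morse time-bandwidth product `beta * gamma`
#'   (default 60).
#' @return A data frame of class `reference_spectrum` with columns
#'   `period_days`, `power`.
#' @export
reference_spectrum <- function(dense, periods_days = NULL, gamma = 3,
                               time_bandwidth = 60) {
  stopifnot(inherits(dense, "dense_series"))
  v <- dense$values
  if (anyNA(v)) stop("reference_spectrum needs a gap-free series")
  N <- length(v)
  dt <- dense$dt
  span <- N * dt
  if (is.null(periods_days)) {
    pmin_ <- max(0.5, 4 * dt)
    pmax_ <- min(150, span / 2)
    n_scales <- ceiling(log2(pmax_ / pmin_) * 12) + 1
    periods_days <- exp(seq(log(pmin_), log(pmax_), length.out = n_scales))
  } else if (any(periods_days > span / 2)) {
    warning("record shorter than 2x the longest analyzed period; period range truncated")
    periods_days <- periods_days[periods_days <= span / 2]
    if (!length(periods_days)) stop("no analyzable periods left")
  }
  beta <- time_bandwidth / gamma
  omega_peak <- (beta / gamma)^(1 / gamma)
  xf <- stats::fft(v - mean(v))
  # angular frequencies of the FFT bins, cycles: omega_j = 2 pi j / (N dt)
  j <- 0:(N - 1)
  om <- 2 * pi * ifelse(j <= N / 2, j, j - N) / (N * dt)
  power <- vapply(periods_days, function(P) {
    s <- omega_peak / (2 * pi / P)       # scale mapping peak to 1/P cycles/day
    w <- s * om
    psi <- numeric(N)
    pos <- which(w > 0)
    psi[pos] <- 2 * exp(beta * log(w[pos]) - w[pos]^gamma -
                          (beta * log(omega_peak) - omega_peak^gamma))
    W <- stats::fft(xf * psi, inverse = TRUE) / N
    mean(Mod(W)^2)
  }, numeric(1))
  out <- data.frame(period_days = periods_days, power = power)
  class(out) <- c("reference_spectrum", "data.frame")
  out
}

#' Local maxima of a spectrum
#'
#' Finds local maxima above a prominence floor given as a fraction of the
#' global maximum (default 5%).
#'
#' @param spectrum A `reference_spectrum`, or any data frame with a period
#'   column and a height column (the second numeric column).
#' @param prominence_frac Minimum height as a fraction of the global maximum.
#' @return A data frame of class `peak_set` with columns `period_days`,
#'   `height`; possibly zero rows.
#' @export
find_peaks <- function(spectrum, prominence_frac = 0.05) {
  stopifnot(is.data.frame(spectrum), nrow(spectrum) >= 1)
  p <- spectrum$period_days
  h <- spectrum[[setdiff(names(spectrum), "period_days")[1]]]
  stopifnot(all(is.finite(h)))
  n <- length(h)
  is_peak <- logical(n)
  if (n >= 3) {
    for (i in 2:(n - 1)) is_peak[i] <- h[i] > h[i - 1] && h[i] >= h[i + 1]
  }
  floor_ <- prominence_frac * max(h)
  is_peak <- is_peak & h >= floor_ & h > 0
  out <- data.frame(period_days = p[is_peak], height = h[is_peak])
  out <- out[order(out$period_days), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("peak_set", "data.frame")
  out
}

#' Scaled offsets between reference peaks and significant BPWP peaks
#'
#' For each reference (CWT) peak of period `P_ref`, the offset to the nearest
#' significant BPWP coefficient period, in days, divided by `P_ref`. When the
#' BPWP spectrum has no significant peaks the offsets are `NA`.
#'
#' @param reference_peaks A `peak_set` (from [find_peaks()]).
#' @param bpwp_spectrum A `bpwp_spectrum` with `significant` flags filled.
#' @return A data frame with columns `ref_period_days`,
#'   `nearest_bpwp_period`, `scaled_offset`.
#' @export
peak_offset_metric <- function(reference_peaks, bpwp_spectrum) {
  stopifnot(is.data.frame(reference_peaks))
  sig <- bpwp_spectrum$period_days[which(bpwp_spectrum$significant)]
  sig <- sig[is.finite(sig)]
  ref <- reference_peaks$period_days
  if (!length(sig)) {
    return(data.frame(ref_period_days = ref,
                      nearest_bpwp_period = NA_real_,
                      scaled_offset = NA_real_))
  }
  nearest <- vapply(ref, function(P) sig[which.min(abs(sig - P))], numeric(1))
  data.frame(ref_period_days = ref, nearest_bpwp_period = nearest,
             scaled_offset = abs(ref - nearest) / ref)
}

#' Sampling-density sweep
#'
#' Runs the full pipeline (sample, cross-validate delta, fit, shuffle null,
#' flag) at several average sampling rates, several times each, and measures
#' the scaled offsets between the dense-data wavelet reference peaks and the
#' significant BPWP peaks.
#'
#' @param dense The dense `dense_series` ground-truth record.
#' @param grid A `frequency_grid` on the dense geometry.
#' @param rates_per_day Sampling rates to test (default 1:5).
#' @param n_repeats Resampling repeats per rate (default 10).
#' @param window_days Sampling window (default full record).
#' @param seed Base seed.
#' @param cv A [cv_config()] for delta selection.
#' @param n_shuffle Null iterations per fit (default 25).
#' @param max_degree Trend degree (default 1).
#' @param reference Optional precomputed `reference_spectrum`.
#' @param pipeline_tol Solver tolerance inside the pipeline (default 1e-6).
#' @return A list of class `offset_result`: `per_fit` (long data frame with
#'   rate, repeat, ref peak, offset), `summary` (mean and 95% CI of the
#'   scaled offset per rate and reference peak), `n_repeats`.
#' @export
sampling_density_sweep <- function(dense, grid, rates_per_day = 1:5,
                                   n_repeats = 10L, window_days = NULL,
                                   seed = 1L, cv = cv_config(),
                                   n_shuffle = 25L, max_degree = 1,
                                   reference = NULL, pipeline_tol = 1e-6) {
  stopifnot(inherits(dense, "dense_series"), inherits(grid, "frequency_grid"))
  if (is.null(reference)) reference <- reference_spectrum(dense)
  ref_peaks <- find_peaks(reference)
  if (!nrow(ref_peaks)) stop("no peaks found in the reference spectrum")
  rows <- list()
  for (r in seq_along(rates_per_day)) {
    for (it in seq_len(n_repeats)) {
      sd_ <- child_seed(seed, r * 1000L + it)
      s <- random_sample(dense, rate_per_day = rates_per_day[r],
                         window_days = window_days, seed = sd_)
      an <- bpwp(s, grid, max_degree = max_degree, cv = cv,
                 n_shuffle = n_shuffle, seed = sd_,
                 tol = pipeline_tol, pipeline_tol = pipeline_tol)
      off <- peak_offset_metric(ref_peaks, an$spectrum)
      off$rate_per_day <- rates_per_day[r]
      off$rep <- it
      rows[[length(rows) + 1]] <- off
    }
  }
  per_fit <- do.call(rbind, rows)
  agg <- stats::aggregate(scaled_offset ~ rate_per_day + ref_period_days,
                          data = per_fit, FUN = mean, na.action = stats::na.omit)
  sds <- stats::aggregate(scaled_offset ~ rate_per_day + ref_period_days,
                          data = per_fit, FUN = stats::sd,
                          na.action = stats::na.omit)
  agg$ci95 <- 1.96 * sds$scaled_offset / sqrt(n_repeats)
  names(agg)[names(agg) == "scaled_offset"] <- "mean_scaled_offset"
  structure(list(per_fit = per_fit, summary = agg,
                 n_repeats = as.integer(n_repeats)),
            class = "offset_result")
}

#' @export
print.offset_result <- function(x, ...) {
  cat(sprintf("<offset_result> %d repeats\n", x$n_repeats))
  print(x$summary)
  invisible(x)
}

#' Frequency-specific correlation between a dense record and a reconstruction
#'
#' Both series are zero-phase bandpass filtered in bands of 90% to 110% of
#' each central period; the filtered original is sampled in time at the
#' reconstruction's time grid, and the two band-limited series are compared
#' with the Pearson correlation.
#'
#' @param dense_original The dense, gap-free original `dense_series`.
#' @param reconstruction A `dense_series` (e.g. from [reconstruct()]).
#' @param center_periods Central periods in days (default 1 to 120: 1, then
#'   5-day steps).
#' @return A data frame with columns `center_period_days`, `r`, `p`; bands
#'   longer than a third of the record are skipped with a warning.
#' @export
bandpass_correlation <- function(dense_original, reconstruction,
                                 center_periods = c(1, seq(5, 120, by = 5))) {
  stopifnot(inherits(dense_original, "dense_series"),
            inherits(reconstruction, "dense_series"))
  n_orig <- length(dense_original$values)
  n_rec <- length(reconstruction$values)
  rec_t <- series_times(reconstruction)
  res <- lapply(center_periods, function(P) {
    band <- c(0.9 * P, 1.1 * P)
    if (band[2] > n_orig * dense_original$dt / 3 ||
        band[2] > n_rec * reconstruction$dt / 3) {
      warning(sprintf("band around %g days longer than a third of the record; skipped", P))
      return(NULL)
    }
    f1 <- design_zero_phase_bandpass(band, dense_original$dt, n_orig)
    f2 <- design_zero_phase_bandpass(band, reconstruction$dt, n_rec)
    a <- filter_series(dense_original, f1)
    b <- filter_series(reconstruction, f2)
    # sample the filtered original at the reconstruction's time vector
    idx <- round((rec_t - a$t0) / a$dt) + 1
    keep <- idx >= 1 & idx <= n_orig
    ct <- stats::cor.test(a$values[idx[keep]], b$values[keep],
                          method = "pearson")
    data.frame(center_period_days = P, r = unname(ct$estimate),
               p = ct$p.value)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) out <- data.frame(center_period_days = numeric(0),
                                      r = numeric(0), p = numeric(0))
  rownames(out) <- NULL
  out
}

#' Detection-rate experiment over cycle length, variance and SNR
#'
#' For each cell (period x variance x SNR x sampling rate): simulate a
#' single-oscillation series, sample it sparsely, fit BPWP with a shuffle
#' null, and score a detection when some significant coefficient lies within
#' 10% of the true period. The percent of repeats detected is reported per
#' cell. The budget `delta` is selected by cross-validation on the first
#' repeat of each cell and reused within the cell.
#'
#' @param periods_days Oscillation periods to test.
#' @param variance_levels,snr_levels Condition subsets (default both).
#' @param rates_per_week Sparse sampling rates in samples/week (default 1
#'   and 4).
#' @param n_repeats Repeats per cell (default 10).
#' @param base_spec Template [simulation_spec()] (duration, grid, baseline).
#' @param grid Optional `frequency_grid`; default built from the base spec
#'   geometry.
#' @param cv A [cv_config()].
#' @param n_shuffle Null iterations (default 25).
#' @param detection_tol Relative period tolerance for a detection
#'   (default 0.10).
#' @param seed Base seed.
#' @param pipeline_tol Solver tolerance (default 1e-6).
#' @return Data frame with columns `period_days`, `variance`, `snr`,
#'   `rate_per_week`, `percent_detected`.
#' @export
detection_rate_experiment <- function(periods_days,
                                      variance_levels = c("low", "high"),
                                      snr_levels = c("low", "high"),
                                      rates_per_week = c(1, 4),
                                      n_repeats = 10L,
                                      base_spec = simulation_spec(),
                                      grid = NULL, cv = cv_config(),
                                      n_shuffle = 25L, detection_tol = 0.10,
                                      seed = 1L, pipeline_tol = 1e-6) {
  dt <- base_spec$update_minutes / 1440
  N <- round(base_spec$duration_days / dt)
  if (is.null(grid)) grid <- build_frequency_mapping(N, dt)
  cells <- expand.grid(period_days = periods_days, variance = variance_levels,
                       snr = snr_levels, rate_per_week = rates_per_week,
                       stringsAsFactors = FALSE)
  cells$percent_detected <- NA_real_
  per_grid <- grid_periods(grid)
  for (ci in seq_len(nrow(cells))) {
    cell <- cells[ci, ]
    delta <- NULL
    hits <- 0L
    for (it in seq_len(n_repeats)) {
      sd_ <- child_seed(seed, ci * 101L + it)
      spec <- base_spec
      spec$seed <- sd_
      d <- simulate_single_cycle(cell$period_days, cell$variance, cell$snr,
                                 base_spec = spec)
      s <- random_sample(d, rate_per_day = cell$rate_per_week / 7, seed = sd_)
      an <- bpwp(s, grid, delta = delta, cv = cv, n_shuffle = n_shuffle,
                 seed = sd_, tol = pipeline_tol, pipeline_tol = pipeline_tol)
      if (is.null(delta)) delta <- an$delta
      sig <- significant_periods(an)
      if (length(sig) &&
          any(abs(sig - cell$period_days) / cell$period_days <= detection_tol))
        hits <- hits + 1L
    }
    cells$percent_detected[ci] <- 100 * hits / n_repeats
  }
  cells
}
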