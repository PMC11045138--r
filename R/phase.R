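#' Conserved cycle bands for event-phase analysis
#'
#' The period bands (days) in which seizure-phase preference is commonly
#' examined: circadian, weekly, two-to-three weeks, and monthly. The daily
#' band is taken as 0.9 to 1.1 days.
#'
#' @return Named list of length-2 numeric period intervals (days).
#' @export
default_cycle_bands <- function() {
  list(daily = c(0.9, 1.1), weekly = c(5, 10),
       fortnightly = c(15, 25), monthly = c(25, 35))
}

#' Least-squares FIR bandpass for zero-phase filtering
#'
#' Designs a linear-phase (type I) FIR bandpass by unweighted least squares
#' on the continuous frequency axis: the desired response is 1 inside the
#' passband, 0 in the stopbands, with linear transitions of 15% of each edge
#' frequency, and the optimal taps follow in closed form from the integrals
#' of the desired response against the cosine basis. The band is given as a
#' period interval in days; the filter is meant to be applied forward and
#' backward ([filter_series()]) for zero net phase. The order is three times
#' the upper band period in samples, capped at a third of the record.
#'
#' @param band_days Length-2 numeric: period interval (days), shorter first
#'   or longer first (sorted internally).
#' @param dt_days Sample spacing of the series to be filtered (days).
#' @param n_record Record length in samples (used to cap the order).
#' @param order Optional explicit filter order (number of taps minus one;
#'   rounded up to even).
#' @param transition Transition width as a fraction of each band-edge
#'   frequency (default 0.15).
#' @return An object of class `fir_bandpass` with fields `taps`, `band_days`,
#'   `dt_days`, `order`.
#' @export
design_zero_phase_bandpass <- function(band_days, dt_days, n_record,
                                       order = NULL, transition = 0.15) {
  stopifnot(length(band_days) == 2, all(band_days > 0), dt_days > 0)
  band_days <- sort(band_days)
  if (band_days[1] <= 2 * dt_days)
    stop("lower band period must exceed twice the sample spacing")
  if (band_days[2] > n_record * dt_days / 3)
    stop("upper band period exceeds a third of the record")
  # band edges in cycles/sample
  f_hi <- dt_days / band_days[1]   # upper passband edge (higher frequency)
  f_lo <- dt_days / band_days[2]   # lower passband edge
  if (is.null(order)) {
    order <- 3 * ceiling(band_days[2] / dt_days)
    order <- min(order, floor(n_record / 3))
  }
  order <- as.integer(order)
  if (order %% 2 == 1) order <- order + 1L   # type I: even order, odd taps
  M <- order %/% 2
  # transition edges, kept inside (0, 0.5)
  fs1 <- max(f_lo * (1 - transition), 0)
  fp1 <- f_lo
  fp2 <- f_hi
  fs2 <- min(f_hi * (1 + transition), 0.5)
  # Desired amplitude D(f): 0 on [0, fs1], ramp to 1 on [fs1, fp1],
  # 1 on [fp1, fp2], ramp to 0 on [fp2, fs2], 0 on [fs2, 0.5].
  # Unweighted LS taps: h[k] = 2 * int_0^{1/2} D(f) cos(2 pi f k) df.
  k <- 0:M
  h_half <- ramp_integral(fs1, fp1, 0, 1, k) +
    ramp_integral(fp1, fp2, 1, 1, k) +
    ramp_integral(fp2, fs2, 1, 0, k)
  taps <- c(rev(h_half[-1]), h_half)   # symmetric, length order + 1
  structure(list(taps = taps, band_days = band_days, dt_days = dt_days,
                 order = order),
            class = "fir_bandpass")
}

# int_fa^fb (da + s (f - fa)) * 2 cos(2 pi f k) df for each k (vectorized),
# with s = (db - da) / (fb - fa); exact antiderivatives.
ramp_integral <- function(fa, fb, da, db, k) {
  if (fb <= fa) return(numeric(length(k)))
  s <- (db - da) / (fb - fa)
  out <- numeric(length(k))
  z <- k == 0
  if (any(z)) out[z] <- 2 * ((da - s * fa) * (fb - fa) + s * (fb^2 - fa^2) / 2)
  kk <- k[!z]
  if (length(kk)) {
    w <- 2 * pi * kk
    c0 <- da - s * fa
    # int 2 cos(w f) df = 2 sin(w f)/w ; int 2 f cos(w f) df =
    #   2 (f sin(w f)/w + cos(w f)/w^2)
    term <- function(f) {
      2 * c0 * sin(w * f) / w + 2 * s * (f * sin(w * f) / w + cos(w * f) / w^2)
    }
    out[!z] <- term(fb) - term(fa)
  }
  out
}

#' Frequency response of an FIR filter
#'
#' @param filt A `fir_bandpass`.
#' @param periods_days Periods (days) at which to evaluate the amplitude.
#' @return Numeric vector of amplitude responses (single pass).
#' @export
fir_response <- function(filt, periods_days) {
  stopifnot(inherits(filt, "fir_bandpass"))
  f <- filt$dt_days / periods_days     # cycles/sample
  M <- (length(filt$taps) - 1) / 2
  k <- -M:M
  vapply(f, function(fi) abs(sum(filt$taps * cos(2 * pi * fi * k))),
         numeric(1))
}

#' Zero-phase filtering of a dense series
#'
#' Applies the FIR filter forward and backward (via [signal::filtfilt()]),
#' giving zero net phase shift and the squared amplitude response.
#'
#' @param series A `dense_series` (spacing must match the filter design).
#' @param filt A `fir_bandpass`.
#' @return A `dense_series` of the band-limited signal.
#' @export
filter_series <- function(series, filt) {
  stopifnot(inherits(series, "dense_series"), inherits(filt, "fir_bandpass"))
  if (abs(series$dt - filt$dt_days) > 1e-9 * filt$dt_days)
    stop("series spacing does not match the filter design")
  v <- series$values
  if (anyNA(v)) stop("filter_series needs a gap-free series; interpolate first")
  out <- series
  out$values <- as.numeric(signal::filtfilt(filt$taps, 1, v - mean(v)))
  out
}

# Analytic signal by the frequency-domain construction: zero out negative
# frequencies, double positive ones.
analytic_signal <- function(v) {
  n <- length(v)
  H <- numeric(n)
  if (n %% 2 == 0) {
    H[1] <- 1; H[n / 2 + 1] <- 1; H[2:(n / 2)] <- 2
  } else {
    H[1] <- 1; H[2:((n + 1) / 2)] <- 2
  }
  stats::fft(stats::fft(v) * H, inverse = TRUE) / n
}

#' Instantaneous phase of a band-limited series
#'
#' Phase of the analytic signal (Hilbert transform construction). The
#' convention is phase 0 at the oscillation peak, increasing through the
#' cycle (so +pi/2 a quarter period after the peak and ±pi at the trough).
#'
#' @param series A band-limited `dense_series`.
#' @param min_amplitude_frac Stretches where the analytic amplitude falls
#'   below this fraction of its median are flagged in the `low_amplitude`
#'   attribute (default 0.05).
#' @return A `dense_series` whose values are phases in (-pi, pi].
#' @export
instantaneous_phase <- function(series, min_amplitude_frac = 0.05) {
  stopifnot(inherits(series, "dense_series"))
  a <- analytic_signal(series$values)
  ph <- Arg(a)
  out <- series
  out$values <- ph
  amp <- Mod(a)
  attr(out, "low_amplitude") <- amp < min_amplitude_frac * stats::median(amp)
  out
}

#' Phases at event times
#'
#' Looks up the instantaneous phase at the grid point nearest each event.
#' Events outside the record are skipped (their count is reported in the
#' `n_skipped` attribute).
#'
#' @param phase A phase `dense_series` (from [instantaneous_phase()]).
#' @param events An `event_series`.
#' @return Numeric vector of angles in (-pi, pi]; attribute `n_skipped`.
#' @export
event_phases <- function(phase, events) {
  stopifnot(inherits(phase, "dense_series"), inherits(events, "event_series"))
  tt <- series_times(phase)
  et <- events$event_times
  inside <- et >= tt[1] - phase$dt / 2 & et <= tt[length(tt)] + phase$dt / 2
  idx <- pmin(pmax(round((et[inside] - phase$t0) / phase$dt) + 1, 1),
              length(tt))
  out <- phase$values[idx]
  attr(out, "n_skipped") <- sum(!inside)
  out
}

#' Hodges-Ajne (Omnibus) test of circular uniformity
#'
#' Nonparametric test for non-uniformity of angles on the circle, based on
#' `m`, the minimum number of angles falling in any closed half-circle. The
#' exact tail `p = 2^(1-n) (n - 2m) choose(n, m)` is used for n <= 50; the
#' standard large-sample approximation
#' `p = sqrt(2 pi) / A * exp(-pi^2 / (8 A^2))` with
#' `A = pi sqrt(n) / (2 (n - 2m))` beyond. The p-value is capped at 1.
#'
#' @param angles Numeric vector of angles in radians (any wrapping).
#' @return List of class `hodges_ajne` with `m`, `n`, `p`, `method`.
#' @examples
#' hodges_ajne_test(runif(10, 0, pi))$p   # all in a half circle: ~0.0195
#' @export
hodges_ajne_test <- function(angles) {
  n <- length(angles)
  if (n < 2) stop("need at least 2 angles")
  a <- sort(angles %% (2 * pi))
  # max count over closed half circles with boundary at a data point
  a2 <- c(a, a + 2 * pi)
  cmax <- 0L
  for (i in seq_len(n)) {
    # points j >= i with a2[j] in the closed arc [a_i, a_i + pi]
    cnt <- findInterval(a[i] + pi + 1e-12, a2) - (i - 1L)
    cmax <- max(cmax, cnt)
  }
  m <- n - cmax
  if (n <= 50) {
    p <- if (n - 2 * m <= 0) 1
         else exp((1 - n) * log(2) + log(n - 2 * m) + lchoose(n, m))
    method <- "exact"
  } else {
    if (n - 2 * m <= 0) { p <- 1 }
    else {
      A <- pi * sqrt(n) / (2 * (n - 2 * m))
      p <- sqrt(2 * pi) / A * exp(-pi^2 / (8 * A^2))
    }
    method <- "large-sample"
  }
  structure(list(m = as.integer(m), n = as.integer(n), p = min(p, 1),
                 method = method),
            class = "hodges_ajne")
}

#' @export
print.hodges_ajne <- function(x, ...) {
  cat(sprintf("Hodges-Ajne omnibus test: n = %d, m = %d, p = %.4g (%s)\n",
              x$n, x$m, x$p, x$method))
  invisible(x)
}

#' Band-limited event-phase analysis of a reconstruction
#'
#' For each period band: zero-phase bandpass the series, take the analytic
#' phase, look up the phase at each event, and test circular uniformity.
#'
#' @param series A gap-free `dense_series` (typically a BPWP reconstruction).
#' @param events An `event_series`.
#' @param bands List of period intervals in days (default
#'   [default_cycle_bands()]).
#' @return A list of per-band results (`band`, `phases`, `n_events`,
#'   `omnibus_p`, `m`), of class `phase_result`.
#' @export
phase_analysis <- function(series, events, bands = default_cycle_bands()) {
  stopifnot(inherits(series, "dense_series"))
  n_rec <- length(series$values)
  out <- lapply(seq_along(bands), function(i) {
    band <- bands[[i]]
    filt <- design_zero_phase_bandpass(band, series$dt, n_rec)
    bl <- filter_series(series, filt)
    ph <- instantaneous_phase(bl)
    ang <- event_phases(ph, events)
    test <- if (length(ang) >= 4) hodges_ajne_test(ang) else NULL
    list(band = band,
         name = if (!is.null(names(bands))) names(bands)[i] else NULL,
         phases = as.numeric(ang), n_events = length(ang),
         omnibus_p = if (!is.null(test)) test$p else NA_real_,
         m = if (!is.null(test)) test$m else NA_integer_)
  })
  class(out) <- "phase_result"
  out
}

#' @export
print.phase_result <- function(x, ...) {
  for (b in x) {
    cat(sprintf("band %5.1f-%5.1f days: n = %d events, omnibus p = %.4g%s\n",
                b$band[1], b$band[2], b$n_events, b$omnibus_p,
                if (!is.na(b$omnibus_p) && b$omnibus_p < 0.001) " ***" else ""))
  }
  invisible(x)
}
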