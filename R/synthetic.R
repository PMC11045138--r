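#' Specification of a simulated IED-rate series
#'
#' Defines a year-long synthetic hourly event-rate record: a set of
#' stationary cosine oscillations, a slow polynomial trend, a baseline, and
#' additive noise, on a dense grid of one-hour rate windows updated every
#' `update_minutes`. The defaults emulate long-term inter-ictal discharge
#' rates: component cycles at 1, 7, 15, 21, 30, 50 and 100 days, a first
#' order (linear) trend, and a baseline high enough that clipping at zero is
#' rare.
#'
#' @param duration_days Record length in days (default 365).
#' @param update_minutes Grid update interval in minutes (default 20).
#' @param periods_days Oscillation periods in days (default
#'   `c(1, 7, 15, 21, 30, 50, 100)`).
#' @param amplitudes Oscillation amplitudes, events/hour (default 10 each).
#' @param phases Phases in radians (default 0).
#' @param trend Polynomial trend coefficients over normalized time
#'   `u = t / duration` in `[0, 1]`: value `sum(trend[j] * u^(j-1))`.
#'   Default `c(0, 20)` — a first order trend rising 20 events/hour across
#'   the record.
#' @param baseline Constant baseline, events/hour (default 60).
#' @param noise_sd Gaussian noise standard deviation, events/hour
#'   (default 8). Ignored in Poisson mode.
#' @param poisson If `TRUE`, draw each sample as a Poisson count with the
#'   noiseless rate as mean instead of adding Gaussian noise.
#' @param seed Integer seed (default 1).
#' @return An object of class `simulation_spec`.
#' @export
simulation_spec <- function(duration_days = 365, update_minutes = 20,
                            periods_days = c(1, 7, 15, 21, 30, 50, 100),
                            amplitudes = rep(10, length(periods_days)),
                            phases = rep(0, length(periods_days)),
                            trend = c(0, 20), baseline = 60, noise_sd = 8,
                            poisson = FALSE, seed = 1L) {
  stopifnot(duration_days > 0, update_minutes > 0,
            all(periods_days > 0),
            length(amplitudes) == length(periods_days),
            length(phases) == length(periods_days),
            noise_sd >= 0)
  structure(list(duration_days = duration_days,
                 update_minutes = update_minutes,
                 periods_days = as.numeric(periods_days),
                 amplitudes = as.numeric(amplitudes),
                 phases = as.numeric(phases),
                 trend = as.numeric(trend), baseline = baseline,
                 noise_sd = noise_sd, poisson = isTRUE(poisson),
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Simulate a dense IED-rate series
#'
#' Generates the dense grid of `duration_days * 1440 / update_minutes`
#' hourly-rate samples:
#' `value(t) = clip0(baseline + sum_i a_i cos(2 pi t / P_i + phi_i)
#'             + trend(t) + noise)`.
#' Oscillations are stationary over the whole record. In Gaussian mode the
#' noiseless rate is clipped at zero after adding noise; in Poisson mode each
#' sample is a Poisson draw with the (clipped) noiseless rate as its mean.
#'
#' @param spec A [simulation_spec()].
#' @return A `dense_series` starting at day 0.
#' @examples
#' d <- simulate_ied_series(simulation_spec(duration_days = 30,
#'                                          update_minutes = 60))
#' length(d)  # 30 * 24
#' @export
simulate_ied_series <- function(spec = simulation_spec()) {
  stopifnot(inherits(spec, "simulation_spec"))
  dt <- spec$update_minutes / 1440
  N <- round(spec$duration_days / dt)
  tt <- (seq_len(N) - 1) * dt
  clean <- rep(spec$baseline, N)
  for (i in seq_along(spec$periods_days))
    clean <- clean + spec$amplitudes[i] *
      cos(2 * pi * tt / spec$periods_days[i] + spec$phases[i])
  u <- tt / spec$duration_days
  for (j in seq_along(spec$trend))
    clean <- clean + spec$trend[j] * u^(j - 1)
  if (mean(clean) < 0)
    stop("simulation has negative mean rate; raise the baseline")
  vals <- if (spec$poisson) {
    with_seed(spec$seed, stats::rpois(N, pmax(clean, 0)))
  } else {
    noisy <- clean + with_seed(spec$seed, stats::rnorm(N, 0, spec$noise_sd))
    pmax(noisy, 0)
  }
  dense_series(as.numeric(vals), t0 = 0, dt = dt)
}

#' Noiseless component of a simulation
#'
#' The baseline + oscillations + trend of a [simulation_spec()] without noise
#' or clipping; ground truth for recovery tests.
#'
#' @param spec A [simulation_spec()].
#' @return A `dense_series`.
#' @export
simulate_clean_series <- function(spec = simulation_spec()) {
  spec$noise_sd <- 0
  spec$poisson <- FALSE
  simulate_ied_series(spec)
}

#' Simulate a single-oscillation series at named variance/SNR conditions
#'
#' One cosine of the requested period plus Gaussian noise, for the detection
#' rate experiment grid: `variance_level` scales the oscillation amplitude
#' (high = 10, low = 3 events/hour) and `snr_level` sets the noise so the
#' realized amplitude-to-noise power ratio `a^2 / (2 sigma^2)` equals the
#' named condition (high = 10, low = 1).
#'
#' @param period_days Oscillation period, 1 to 120 days.
#' @param variance_level `"low"` or `"high"`.
#' @param snr_level `"low"` or `"high"`.
#' @param base_spec Template [simulation_spec()] supplying duration, grid,
#'   baseline, trend and seed.
#' @return A `dense_series`; the realized spec is attached as attribute
#'   `"spec"`.
#' @export
simulate_single_cycle <- function(period_days,
                                  variance_level = c("high", "low"),
                                  snr_level = c("high", "low"),
                                  base_spec = simulation_spec()) {
  variance_level <- match.arg(variance_level)
  snr_level <- match.arg(snr_level)
  stopifnot(period_days >= 2 * base_spec$update_minutes / 1440,
            period_days <= base_spec$duration_days)
  a <- if (variance_level == "high") 10 else 3
  snr <- if (snr_level == "high") 10 else 1
  sigma <- sqrt(a^2 / (2 * snr))
  spec <- base_spec
  spec$periods_days <- period_days
  spec$amplitudes <- a
  spec$phases <- 0
  spec$noise_sd <- sigma
  out <- simulate_ied_series(spec)
  attr(out, "spec") <- spec
  out
}
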