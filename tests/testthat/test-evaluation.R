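tone_series <- function(periods, amps, N = 360 * 24, dt = 1 / 24) {
  tt <- (seq_len(N) - 1) * dt
  v <- rep(0, N)
  for (i in seq_along(periods)) v <- v + amps[i] * cos(2 * pi * tt / periods[i])
  dense_series(v, t0 = 0, dt = dt)
}

test_that("wavelet reference spectrum locates tones", {
  rs <- reference_spectrum(tone_series(30, 5))
  expect_lt(abs(rs$period_days[which.max(rs$power)] - 30) / 30, 0.05)

  # constant series carries (numerically) no power
  rs0 <- reference_spectrum(dense_series(rep(3, 360 * 24), 0, 1 / 24))
  expect_lt(max(rs0$power), 1e-6 * max(rs$power))

  # two well-separated tones give two local maxima
  rs2 <- reference_spectrum(tone_series(c(7, 60), c(5, 5)))
  pk <- find_peaks(rs2)
  expect_equal(nrow(pk), 2)
  expect_lt(abs(pk$period_days[1] - 7) / 7, 0.1)
  expect_lt(abs(pk$period_days[2] - 60) / 60, 0.1)

  # doubling a tone's amplitude raises its averaged peak power
  lo <- max(reference_spectrum(tone_series(30, 2))$power)
  hi <- max(reference_spectrum(tone_series(30, 4))$power)
  expect_gt(hi, lo)
})

test_that("peak finding respects monotonicity and the prominence floor", {
  mono <- data.frame(period_days = 1:20, power = seq(1, 2, length.out = 20))
  expect_equal(nrow(find_peaks(mono)), 0)
  one <- find_peaks(reference_spectrum(tone_series(20, 3)))
  expect_equal(nrow(one), 1)
  # a tiny bump below the 5% floor is suppressed
  spec <- data.frame(period_days = 1:9,
                     power = c(0, 0.01, 0, 0, 1, 0, 0, 0.2, 0))
  pk <- find_peaks(spec)
  expect_equal(pk$period_days, c(5, 8))
})

test_that("peak offsets are scaled by the reference period", {
  ref <- data.frame(period_days = c(7, 30), height = c(1, 1))
  sp <- data.frame(period_days = c(7, 27), amplitude = c(1, 1),
                   significant = c(TRUE, TRUE))
  off <- peak_offset_metric(ref, sp)
  expect_equal(off$scaled_offset, c(0, 0.1), tolerance = 1e-12)

  # identical peak sets: all zero
  sp2 <- data.frame(period_days = c(7, 30), significant = c(TRUE, TRUE))
  expect_equal(peak_offset_metric(ref, sp2)$scaled_offset, c(0, 0))

  # scale invariance: rescaling all periods leaves offsets unchanged
  ref_s <- ref; ref_s$period_days <- ref$period_days * 3.7
  sp_s <- sp; sp_s$period_days <- sp$period_days * 3.7
  expect_equal(peak_offset_metric(ref_s, sp_s)$scaled_offset,
               off$scaled_offset, tolerance = 1e-12)

  # no significant peaks: offsets reported missing
  sp3 <- data.frame(period_days = c(7, 30), significant = c(FALSE, FALSE))
  expect_true(all(is.na(peak_offset_metric(ref, sp3)$scaled_offset)))
})

test_that("band-limited correlation separates identity from noise", {
  N <- 2160; dt <- 1 / 6
  tt <- (seq_len(N) - 1) * dt
  d <- dense_series(10 * cos(2 * pi * tt / 30) + 4 * cos(2 * pi * tt / 7),
                    0, dt)
  self <- bandpass_correlation(d, d, center_periods = c(7, 30))
  expect_equal(self$r, c(1, 1), tolerance = 1e-6)
  expect_true(all(self$p < 1e-10))

  # independent noise: needs many cycles per band for the correlation to
  # concentrate near zero, hence a long record and short-period bands
  set.seed(2)
  Nn <- 3 * 2880
  a <- dense_series(rnorm(Nn), 0, 1 / 3)
  b <- dense_series(rnorm(Nn), 0, 1 / 3)
  ind <- bandpass_correlation(a, b, center_periods = c(5, 7, 10, 15))
  expect_lt(mean(abs(ind$r)), 0.1)

  # symmetry in the two inputs
  ab <- bandpass_correlation(a, b, center_periods = c(10, 20))
  ba <- bandpass_correlation(b, a, center_periods = c(10, 20))
  expect_equal(ab$r, ba$r, tolerance = 1e-10)

  # bands longer than a third of the record are skipped
  expect_warning(
    short <- bandpass_correlation(d, d, center_periods = c(10, 150)),
    "skipped")
  expect_equal(short$center_period_days, 10)
})

test_that("density sweep aggregates offsets for every rate and peak", {
  spec <- small_sim_spec(seed = 21)
  d <- simulate_ied_series(spec)
  g <- small_grid(length(d$values), d$dt)
  sw <- sampling_density_sweep(d, g, rates_per_day = c(1, 5), n_repeats = 2,
                               seed = 5, cv = quick_cv(), n_shuffle = 10)
  ref_n <- length(unique(sw$per_fit$ref_period_days))
  expect_gt(ref_n, 0)
  # every (rate, repeat) produced one record per reference peak
  expect_equal(nrow(sw$per_fit), 2 * 2 * ref_n)
  expect_true(all(c("rate_per_day", "ref_period_days", "mean_scaled_offset",
                    "ci95") %in% names(sw$summary)))
  expect_true(all(sw$per_fit$scaled_offset >= 0 |
                    is.na(sw$per_fit$scaled_offset)))
})

test_that("detection table reports percent detected per condition cell", {
  base <- simulation_spec(duration_days = 84, update_minutes = 360,
                          trend = c(0, 5), baseline = 60)
  g <- small_grid(84 * 4, 1 / 4)
  tab <- detection_rate_experiment(periods_days = 7,
                                   variance_levels = "high",
                                   snr_levels = c("low", "high"),
                                   rates_per_week = c(4, 28),
                                   n_repeats = 2, base_spec = base, grid = g,
                                   cv = quick_cv(), n_shuffle = 10, seed = 3)
  expect_equal(nrow(tab), 4)
  expect_true(all(tab$percent_detected >= 0 & tab$percent_detected <= 100))
  # dense, high-SNR observation of a strong tone is always detected
  expect_equal(tab$percent_detected[tab$rate_per_week == 28 &
                                      tab$snr == "high"], 100)
})
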