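test_that("bandpass design passes the band and rejects the stopband", {
  dt <- 1 / 6
  filt <- design_zero_phase_bandpass(c(25, 35), dt, n_record = 2190)
  # single-pass amplitude near 1 in band, small out of band
  expect_equal(fir_response(filt, 30), 1, tolerance = 0.15)
  expect_lt(fir_response(filt, 70), 0.05)

  # stopband tone at twice the upper band period: steady-state RMS < 5%
  # (the first/last filter length carries the startup transient)
  tt <- (seq_len(2190) - 1) * dt
  tone <- dense_series(cos(2 * pi * tt / 70), t0 = 0, dt = dt)
  out <- filter_series(tone, filt)
  interior <- (filt$order + 1):(2190 - filt$order)
  expect_lt(sqrt(mean(out$values[interior]^2)) /
              sqrt(mean(tone$values[interior]^2)), 0.05)

  # passband tone comes through with zero phase: cross-correlation peaks at 0
  tone30 <- dense_series(cos(2 * pi * tt / 30), t0 = 0, dt = dt)
  out30 <- filter_series(tone30, filt)
  cc <- ccf(out30$values, tone30$values, lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)

  expect_error(design_zero_phase_bandpass(c(0.1, 0.2), dt, 2190), "spacing")
  expect_error(design_zero_phase_bandpass(c(25, 2000), dt, 2190), "third")
})

test_that("default analysis bands cover circadian through monthly cycles", {
  bands <- default_cycle_bands()
  expect_equal(bands$daily, c(0.9, 1.1))
  expect_equal(bands$weekly, c(5, 10))
  expect_equal(bands$fortnightly, c(15, 25))
  expect_equal(bands$monthly, c(25, 35))
})

test_that("instantaneous phase follows the peak-zero convention", {
  dt <- 1 / 24
  tt <- (0:8759) * dt
  tone <- dense_series(cos(2 * pi * tt / 30), t0 = 0, dt = dt)
  ph <- instantaneous_phase(tone)
  # phase 0 at a peak well inside the record (t = 90 days)
  i_peak <- which.min(abs(tt - 90))
  expect_lt(abs(ph$values[i_peak]), 0.02)
  # +pi/2 a quarter period after the peak
  i_q <- which.min(abs(tt - 97.5))
  expect_lt(abs(ph$values[i_q] - pi / 2), 0.02)
  # unwrapped phase advances 2 pi / P per day
  mid <- 2000:2500
  slope <- mean(diff(ph$values[mid]) %% (2 * pi)) / dt
  expect_equal(slope, 2 * pi / 30, tolerance = 0.01)
})

test_that("event phases look up the nearest grid sample", {
  dt <- 1 / 24
  tt <- (0:2399) * dt
  ph <- instantaneous_phase(dense_series(cos(2 * pi * tt / 20), 0, dt))
  # event exactly at an interior tone peak
  ev <- event_series(c(40, 60))
  ang <- event_phases(ph, ev)
  expect_length(ang, 2L)
  expect_lt(max(abs(ang)), 0.05)
  # off-grid events use the nearest sample
  ev2 <- event_series(40 + dt * 0.4)
  expect_equal(as.numeric(event_phases(ph, ev2)),
               ph$values[round((40 + dt * 0.4) / dt) + 1], tolerance = 1e-12)
  # empty and out-of-range events
  expect_length(event_phases(ph, event_series(numeric(0))), 0L)
  out <- event_phases(ph, event_series(5000))
  expect_length(out, 0L)
  expect_equal(attr(out, "n_skipped"), 1L)
})

test_that("hodges-ajne matches the closed form and is rotation invariant", {
  a <- seq(0.2, 2.9, length.out = 10)      # all within one half circle
  res <- hodges_ajne_test(a)
  expect_equal(res$m, 0L)
  expect_equal(res$p, 2^(-9) * 10, tolerance = 1e-12)

  # rotation invariance
  for (shift in c(0.5, 2, 4.7)) {
    expect_equal(hodges_ajne_test(a + shift)$p, res$p, tolerance = 1e-12)
  }

  # a concentrated sample clears the reporting threshold p < 0.001
  set.seed(1)
  conc <- rnorm(30, mean = 1, sd = 0.3)
  expect_lt(hodges_ajne_test(conc)$p, 0.001)

  # near-uniform angles are not flagged
  expect_gt(hodges_ajne_test(seq(0, 2 * pi, length.out = 21)[-21])$p, 0.5)
  expect_error(hodges_ajne_test(1))
})

test_that("filtering perturbs in-band event phases by less than 0.05 rad", {
  dt <- 1 / 6
  tt <- (seq_len(2190) - 1) * dt
  tone <- dense_series(cos(2 * pi * tt / 30 + 0.7), t0 = 0, dt = dt)
  filt <- design_zero_phase_bandpass(c(25, 35), dt, length(tt))
  ph_raw <- instantaneous_phase(tone)
  ph_fil <- instantaneous_phase(filter_series(tone, filt))
  ev <- event_series(seq(80, 280, by = 7))
  d_ang <- abs(event_phases(ph_fil, ev) - event_phases(ph_raw, ev))
  d_ang <- pmin(d_ang, 2 * pi - d_ang)
  expect_lt(max(d_ang), 0.05)
})

test_that("events thinned toward cycle peaks yield a non-uniform histogram", {
  # 20-day oscillation; events drawn preferentially near phase 0
  dt <- 1 / 6
  tt <- (seq_len(2160) - 1) * dt
  sig <- dense_series(10 * cos(2 * pi * tt / 20) + rnorm(2160), 0, dt)
  filt <- design_zero_phase_bandpass(c(17, 23), dt, length(tt))
  ph <- instantaneous_phase(filter_series(sig, filt))
  set.seed(42)
  cand <- sort(runif(400, 10, 350))
  idx <- round(cand / dt) + 1
  keep <- runif(400) < (1 + cos(ph$values[idx]))^2 / 4
  ev <- event_series(cand[keep])
  expect_gt(length(ev$event_times), 20)
  pr <- phase_analysis(sig, ev, bands = list(c(17, 23)))
  expect_lt(pr[[1]]$omnibus_p, 0.01)
  expect_equal(pr[[1]]$n_events, length(ev$event_times))
  expect_true(all(abs(pr[[1]]$phases) <= pi + 1e-9))
})
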