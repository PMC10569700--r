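test_that("noise-free stimuli are the exact DC + sinusoid waveform", {
  spec <- stimulus_spec(rheobase = 100, freq = 10, dc_frac = 0.8,
                        noise_sd_frac = 0, duration_s = 2, seed = 1)
  stim <- generate_stimulus(spec, dt = 0.1)
  tt <- (seq_along(stim$values) - 1) * 0.1
  pred <- 100 * (0.8 + 0.15 * sin(2 * pi * 10 * tt / 1000))
  expect_equal(stim$values, pred, tolerance = 1e-12)
})

test_that("filtered noise hits the commanded SD and is seed-frozen", {
  spec <- stimulus_spec(rheobase = 200, freq = 5, dc_frac = 0.8,
                        duration_s = 60, seed = 12)
  stim <- generate_stimulus(spec)
  tt <- (seq_along(stim$values) - 1) * 0.025
  det <- 200 * (0.8 + 0.15 * sin(2 * pi * 5 * tt / 1000))
  noise <- stim$values - det
  expect_rel(sd(noise), 0.30 * 200, 0.02)
  # same seed -> bit-identical
  again <- generate_stimulus(spec)
  expect_identical(stim$values, again$values)
  # autocorrelation time reflects the 5-ms exponential filter
  ac <- acf(noise, lag.max = 400, plot = FALSE)$acf
  lag_1e <- which(ac < exp(-1))[1] * 0.025
  expect_rel(lag_1e, 5, 0.1)
})

test_that("M/R oracle values: uniform, delta and modulated-Poisson spikes", {
  # uniform spikes over the cycle -> no modulation
  st <- seq(0.0005, 100, by = 0.01)
  res <- phase_locking_mr(st, freq = 10, duration_s = 100)
  expect_lt(res$mr, 0.05)
  # all spikes in one bin: least-squares sinusoid on a delta histogram
  # has amplitude/mean = 2 (closed-form Fourier coefficient of a delta)
  set.seed(19)
  delta <- rep(0.013, 500) + floor(runif(500, 0, 999)) * 0.1
  res2 <- phase_locking_mr(delta, freq = 10, duration_s = 100)
  expect_equal(res2$mr, 2, tolerance = 1e-9)
  # inhomogeneous Poisson with rate R(1 + 0.5 cos) -> M/R ~ 0.5
  set.seed(31)
  dur <- 2000; f <- 7; R <- 20
  tt <- seq(0, dur, by = 1e-3)
  lam <- R * (1 + 0.5 * cos(2 * pi * f * tt))
  spikes <- tt[runif(length(tt)) < lam * 1e-3]
  res3 <- phase_locking_mr(spikes, freq = f, duration_s = dur)
  expect_equal(res3$mr, 0.5, tolerance = 0.03)
  expect_rel(res3$R, R, 0.05)
  # zero spikes are flagged
  expect_true(is.na(phase_locking_mr(numeric(0), 10, 10)$mr))
})

test_that("M/R is invariant to shifting all spikes by whole cycles", {
  set.seed(2)
  st <- sort(runif(500, 0, 50))
  a <- phase_locking_mr(st, freq = 8, duration_s = 50)
  b <- phase_locking_mr(st + 5 / 8, freq = 8, duration_s = 50) # 5 cycles
  expect_equal(a$mr, b$mr, tolerance = 1e-9)
})

test_that("cutoff interpolation follows the 0.4 crossing", {
  expect_equal(interpolate_cutoff(c(10, 20), c(1.0, 0.4))$cutoff, 20)
  expect_equal(interpolate_cutoff(c(40, 80), c(0.6, 0.2))$cutoff, 60)
  nc <- interpolate_cutoff(c(10, 20, 40), c(0.9, 0.8, 0.7))
  expect_true(nc$no_cutoff)
  # already below at the lowest frequency
  expect_equal(interpolate_cutoff(c(10, 20), c(0.3, 0.2))$cutoff, 10)
})

test_that("pre-AP availability averages the 0.8-2.8 ms window before the peak", {
  h <- ephys_trace(rep(0.7, 4000), dt = 0.2, units = "mV")
  res <- pre_ap_availability(h, c(100, 300, 600))
  expect_equal(res$per_ap$h, rep(0.7, 3))
  expect_equal(res$median_h, 0.7)
  # brute-force window oracle on a varying trace
  set.seed(8)
  hv <- pmin(pmax(0.5 + cumsum(rnorm(4000, sd = 0.01)), 0), 1)
  h2 <- ephys_trace(hv, dt = 0.2, units = "mV")
  tt <- trace_times(h2)
  peaks <- c(50, 222.2, 700)
  res2 <- pre_ap_availability(h2, peaks)
  for (j in seq_along(peaks)) {
    idx <- which(tt >= peaks[j] - 2.8 & tt <= peaks[j] - 0.8)
    expect_equal(res2$per_ap$h[j], mean(hv[idx]))
  }
  # an AP earlier than the window is excluded
  res3 <- pre_ap_availability(h2, c(1, 500))
  expect_equal(nrow(res3$per_ap), 1)
  expect_error(pre_ap_availability(h2, 1), "window")
})

test_that("spike detection from voltage traces uses peaks above 0 mV", {
  dt <- 0.025
  v <- rep(-70, 80000)
  # three spikes at 500, 1000, 1500 ms
  for (tms in c(500, 1000, 1500)) {
    i <- round(tms / dt)
    v[i + (-3:3)] <- c(-20, 10, 35, 40, 35, 10, -20)
  }
  st <- spike_times_s(ephys_trace(v, dt, units = "mV"), discard_s = 0.2)
  expect_equal(st, c(0.5, 1.0, 1.5), tolerance = 1e-4)
  # subthreshold bumps are ignored
  v2 <- -70 + 30 * sin(seq(0, 20, length.out = 4000))
  expect_length(spike_times_s(ephys_trace(v2, dt, units = "mV"), discard_s = 0), 0)
})
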