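piecewise_spike <- function(dt = 0.025) {
  # dv/dt ramps slowly (10 mV/ms), then jumps to 400 mV/ms at a known sample
  v <- c(seq(-70, -45, by = 10 * dt),    # subthreshold ramp
         seq(-45, 30, by = 400 * dt),    # upstroke: crossing at its first sample
         seq(30, -70, by = -100 * dt))   # downstroke
  ephys_trace(v, dt, units = "mV")
}

test_that("threshold detection finds the constructed 23 mV/ms crossing", {
  tr <- piecewise_spike()
  thr <- detect_threshold(tr)
  expect_equal(nrow(thr), 1)
  # crossing happens where the 400 mV/ms segment starts (central differences
  # see the rate rise one sample earlier)
  expect_lt(abs(thr$v_thr - (-45)), 6)
  expect_equal(thr$v_peak, 30, tolerance = 0.5)
})

test_that("subthreshold traces yield no APs", {
  tr <- ephys_trace(-70 + 5 * sin(seq(0, 10, by = 0.01)), 0.025, units = "mV")
  expect_equal(nrow(detect_threshold(tr)), 0)
})

test_that("threshold rule matches an exhaustive scan on simulated APs", {
  m <- spiking_patch()
  tr <- simulate_ap_train(m, freq = 20, n_aps = 3)$trace
  thr <- detect_threshold(tr)
  expect_equal(nrow(thr), 3)
  v <- tr$values
  dv <- c(diff(v)[1], (v[-(1:2)] - v[1:(length(v) - 2)]) / (2 * tr$dt),
          diff(v)[length(v) - 1])
  for (j in seq_len(nrow(thr))) {
    imax <- which.max(dv[max(1, thr$i_peak[j] - 200):thr$i_peak[j]]) +
      max(1, thr$i_peak[j] - 200) - 1
    cand <- which(dv[1:imax] < 23)
    brute <- max(cand[cand < imax]) + 1
    expect_equal(thr$i_thr[j], brute)
  }
})

test_that("AP features on an ideal linear upstroke are exact", {
  dt <- 0.005
  v <- c(seq(-70, -46, by = 2 * dt),     # slow approach below 23 mV/ms
         seq(-46, 30, by = 400 * dt),    # linear 400 mV/ms upstroke
         seq(30, -70, by = -200 * dt))   # linear 200 mV/ms downstroke
  tr <- ephys_trace(v, dt, units = "mV")
  ft <- ap_features(tr)
  expect_equal(nrow(ft), 1)
  expect_equal(ft$rise_max, 400, tolerance = 2)
  expect_equal(ft$rise_fit, 400, tolerance = 2)
  expect_equal(ft$fall_max, 200, tolerance = 2)
  expect_equal(ft$fall_fit, 200, tolerance = 2)
  # amplitude is threshold -> peak
  expect_equal(ft$amplitude, ft$v_peak - ft$v_thr)
})

test_that("features are invariant to DC offset and robust to 2x resampling", {
  m <- spiking_patch()
  tr <- simulate_ap_train(m, freq = 20, n_aps = 2, dt = 0.0125)$trace
  ft <- ap_features(tr)
  shifted <- ephys_trace(tr$values + 7, tr$dt, units = "mV")
  ft_s <- ap_features(shifted)
  expect_equal(ft_s$rise_max, ft$rise_max, tolerance = 1e-9)
  expect_equal(ft_s$amplitude, ft$amplitude, tolerance = 1e-9)
  coarse <- ephys_trace(tr$values[seq(1, length(tr$values), by = 2)],
                        tr$dt * 2, units = "mV")
  ft_c <- ap_features(coarse)
  expect_rel(ft_c$rise_max[1], ft$rise_max[1], 0.05)
})

test_that("train stability ratios are anchored at the first AP", {
  # constructed train of identical APs
  dt <- 0.025
  one <- c(seq(-70, -46, by = 2 * dt), seq(-46, 30, by = 400 * dt),
           seq(30, -70, by = -150 * dt), rep(-70, 400))
  tr <- ephys_trace(rep(one, 5), dt, units = "mV")
  st <- train_stability(tr, 5)
  expect_equal(st$rel_rise, rep(1, 5), tolerance = 1e-9)
  expect_equal(st$rise_ap5, 1)
  expect_error(train_stability(tr, 8), "missed")
})

test_that("an injected monotone amplitude decay is recovered as monotone ratios", {
  dt <- 0.025
  mk_ap <- function(scale) c(seq(-70, -46, by = 2 * dt),
                             seq(-46, -46 + 86 * scale, by = 400 * scale * dt),
                             seq(-46 + 86 * scale, -70, by = -150 * dt),
                             rep(-70, 400))
  tr <- ephys_trace(unlist(lapply(c(1, 0.9, 0.8, 0.7, 0.6), mk_ap)), dt,
                    units = "mV")
  st <- train_stability(tr, 5)
  expect_true(all(diff(st$rel_rise) < 0))
  expect_equal(st$rel_rise, c(1, 0.9, 0.8, 0.7, 0.6), tolerance = 0.02)
})

test_that("bootstrap confidence intervals behave", {
  expect_equal(unname(bootstrap_ci(rep(3, 10))), c(3, 3))
  set.seed(5)
  x <- rnorm(40, mean = 2)
  ci <- bootstrap_ci(x, seed = 9)
  expect_lt(ci["lower"], mean(x))
  expect_gt(ci["upper"], mean(x))
  # reproducible from its seed
  expect_identical(bootstrap_ci(x, seed = 9), ci)
})

test_that("bootstrap CI coverage is close to nominal", {
  set.seed(123)
  hits <- 0
  n_cohorts <- 400
  for (i in seq_len(n_cohorts)) {
    x <- rnorm(20, mean = 1, sd = 2)
    ci <- bootstrap_ci(x, n_boot = 400, seed = i)
    if (ci["lower"] <= 1 && ci["upper"] >= 1) hits <- hits + 1
  }
  expect_gt(hits / n_cohorts, 0.90)
  expect_lt(hits / n_cohorts, 0.99)
})
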