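test_that("activation curve equals renormalized m_inf^p when inactivation is off", {
  m <- patch_model(na = list(na_no_inact(50)))
  steps <- seq(-80, 40, by = 10)
  pr <- activation_protocol(m, steps = steps, dt = 0.01)
  minf <- steady_state(pr$curve$v, m$na[[1]]$m)^3
  expect_equal(pr$curve$gnorm, minf / max(minf), tolerance = 0.02)
  # contracts: near-zero at the most hyperpolarized step, monotone rise
  expect_lt(pr$curve$gnorm[1], 0.01)
  expect_true(all(diff(pr$curve$gnorm) > -1e-6))
})

test_that("steps at the reversal potential are excluded with a warning", {
  m <- patch_model(na = list(na_no_inact(50)), ena = 0)
  expect_warning(pr <- activation_protocol(m, steps = seq(-20, 20, by = 10),
                                           dt = 0.01), "Erev")
  expect_false(0 %in% pr$curve$v)
})

test_that("availability curve reproduces h_inf for an equilibrating prepulse", {
  m <- na_patch("human", gmax = 50)
  pre <- seq(-120, -30, by = 10)
  pr <- inactivation_protocol(m, prepulses = pre, prepulse_ms = 400, dt = 0.01)
  hinf <- steady_state(pre, m$na[[1]]$h)
  expect_equal(pr$curve$avail, hinf / max(hinf), tolerance = 0.03)
  expect_gt(pr$curve$avail[1], 0.97) # full availability at -120 mV
  # Boltzmann midpoint of the curve sits at the gate midpoint
  bf <- fit_boltzmann(pr$curve$v, pr$curve$avail, "inactivation")
  expect_lt(abs(bf$vhalf - m$na[[1]]$h$vhalf), 1)
})

test_that("fitted recovery time constant equals tau_h at the recovery potential", {
  na <- species_preset("human_na", gmax = 50)
  m <- patch_model(na = list(na))
  rec <- recovery_protocol(m, vrec = -80)
  expect_rel(rec$tau_rec, time_constant(-80, na$h), 0.01)
  expect_true(rec$monotone)
  # long delays approach the steady-state availability at vrec
  long_frac <- tail(rec$curve$fraction, 1)
  expect_rel(long_frac, steady_state(-80, na$h), 0.05)
  # zero-ish delay leaves only the residual availability after conditioning
  expect_lt(rec$curve$fraction[1], 0.2)
})

test_that("AP-clamp normalizes to the first AP and validates ap_times", {
  cmd <- synth_ap_command("human", freq = 40, n_aps = 6)
  m <- na_patch("human", gmax = 50)
  res <- ap_clamp(m, cmd$trace, cmd$ap_times, current = "na")
  expect_equal(res$norm[1], 1)
  expect_equal(nrow(res), 6)
  expect_error(ap_clamp(m, cmd$trace, c(cmd$ap_times, 1e6)), "outside")
})

test_that("instantaneous gate kinetics erase history dependence in AP-clamp", {
  fast <- c(a = 500, ka = 1e6, b = 500, kb = 1e6) # tau ~ 1e-3 ms everywhere
  na <- na_channel(50, gate_spec(-35, 6, "activation", fast),
                   gate_spec(-60, 7, "inactivation", fast), p = 3L)
  m <- patch_model(na = list(na), eleak = -80)
  cmd <- synth_ap_command("human", freq = 40, n_aps = 5)
  res <- ap_clamp(m, cmd$trace, cmd$ap_times, current = "na", dt = 0.01)
  expect_equal(res$norm, rep(1, 5), tolerance = 0.01)
})

test_that("rheobase bisection agrees with an exhaustive grid scan", {
  m <- spiking_patch()
  prec <- 10
  rb <- find_rheobase(m, precision = prec)
  # brute force over the same grid
  spike_at <- function(amp) {
    stim <- c(rep(amp, round(3 / 0.025)), rep(0, round(20 / 0.025)))
    max(simulate_patch(m, stim, mode = "current")$trace$values) > 0
  }
  grid <- seq(prec, rb + 3 * prec, by = prec)
  brute <- grid[which(vapply(grid, spike_at, TRUE))[1]]
  expect_equal(rb, brute)
  expect_equal(rb %% prec, 0)
})

test_that("raising the Na+ density lowers the rheobase", {
  r1 <- find_rheobase(spiking_patch(gmax_na = 150), precision = 1)
  r2 <- find_rheobase(spiking_patch(gmax_na = 300), precision = 1)
  expect_lt(r2, r1)
  expect_error(find_rheobase(patch_model(), max_amp = 100), "no AP")
})

test_that("AP trains hold the commanded frequency with 100% firing", {
  m <- spiking_patch()
  tr <- simulate_ap_train(m, freq = 40, n_aps = 10)
  expect_equal(nrow(tr$ap_peaks), 10)
  expect_equal(diff(tr$pulse_times), rep(25, 9))
  # peak-to-peak intervals track the pulse interval
  expect_equal(diff(tr$ap_peaks$t), rep(25, 9), tolerance = 0.1)
  # a single AP is trivially stable
  one <- simulate_ap_train(m, freq = 40, n_aps = 1)
  st <- train_stability(one$trace, 1)
  expect_equal(st$rel_rise, 1)
})

test_that("pulse failures are reported with their indices", {
  m <- spiking_patch()
  expect_error(simulate_ap_train(m, freq = 40, n_aps = 5, amp = 1),
               "failure.*1, 2, 3, 4, 5")
  expect_error(simulate_ap_train(m, freq = 400, n_aps = 5), "interval")
})
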