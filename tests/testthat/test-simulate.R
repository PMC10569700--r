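test_that("a passive patch settles to the leak reversal", {
  m <- patch_model(eleak = -70)
  sim <- simulate_patch(m, rep(0, 2000), mode = "current")
  expect_equal(tail(sim$trace$values, 1), -70, tolerance = 1e-9)
  m2 <- patch_model(eleak = -55)
  sim2 <- simulate_patch(m2, rep(0, 2000), mode = "current")
  expect_equal(tail(sim2$trace$values, 1), -55, tolerance = 1e-9)
})

test_that("passive step response matches the RC closed form", {
  m <- patch_model(eleak = -70, gleak = 2, diameter = 10)
  g_ns <- 2 * membrane_area(m) / 1000
  c_pf <- m$cm * membrane_area(m) * 0.01
  tau <- c_pf / g_ns
  dt <- 0.001
  i0 <- 20
  sim <- simulate_patch(m, rep(i0, round(60 / dt)), mode = "current", dt = dt)
  tt <- trace_times(sim$trace) + dt
  pred <- -70 + (i0 / g_ns) * (1 - exp(-tt / tau))
  expect_lt(max(abs(sim$trace$values - pred)), 0.02)
})

test_that("simulation is deterministic: identical inputs, identical traces", {
  m <- spiking_patch()
  stim <- c(rep(60, 120), rep(0, 2000))
  a <- simulate_patch(m, stim, mode = "current")
  b <- simulate_patch(m, stim, mode = "current")
  expect_identical(a$trace$values, b$trace$values)
})

test_that("voltage-clamp output splits into consistent components", {
  m <- na_patch("human", gmax = 50)
  dt <- 0.005
  cmd <- c(rep(-90, round(5 / dt)), rep(0, round(20 / dt)))
  sim <- simulate_patch(m, cmd, mode = "voltage", dt = dt)
  expect_equal(sim$trace$values, sim$ina$values + sim$ik$values)
  # leak current is ohmic against the command
  expect_equal(sim$ileak$values,
               (m$gleak * membrane_area(m) / 1000) * (cmd - m$eleak),
               tolerance = 1e-9)
  # capacitive transient only at the step edge
  expect_equal(sum(abs(sim$icap$values) > 0), 1L)
})

test_that("halving dt changes the peak Na+ current by less than 0.5%", {
  m <- na_patch("human", gmax = 50)
  peak_at <- function(dt) {
    cmd_ms <- c(rep(-90, 5 / 0.001), rep(-10, 20 / 0.001)) # build at 1 us, resample
    cmd <- cmd_ms[seq(1, length(cmd_ms), by = round(dt / 0.001))]
    sim <- simulate_patch(m, cmd, mode = "voltage", dt = dt)
    min(sim$ina$values)
  }
  p1 <- peak_at(0.005)
  p2 <- peak_at(0.0025)
  expect_lt(abs(p1 / p2 - 1), 0.005)
})

test_that("halving dt moves the AP peak by less than one default sample", {
  m <- spiking_patch()
  peak_time <- function(dt) {
    stim <- rep(c(60, 0), c(round(3 / dt), round(25 / dt)))
    sim <- simulate_patch(m, stim, mode = "current", dt = dt)
    trace_times(sim$trace)[which.max(sim$trace$values)]
  }
  expect_lt(abs(peak_time(0.025) - peak_time(0.0125)), 0.025)
})

test_that("stimulus validation rejects bad input", {
  m <- patch_model()
  expect_error(simulate_patch(m, c(0, NaN, 0), mode = "current"), "NaN")
  expect_error(simulate_patch(m, rep(0, 10), mode = "current", dt = -1), "dt")
})

test_that("recorded gates stay within [0, 1] during hard drive", {
  m <- spiking_patch()
  stim <- rep(c(500, 0), c(120, 800))
  sim <- simulate_patch(m, stim, mode = "current", record_gates = TRUE,
                        gate_stride = 1L)
  expect_true(all(sim$gates >= 0 & sim$gates <= 1))
})

test_that("na_availability is the density-weighted mean of the h gates", {
  mix <- channel_mix(100, 0, humanfrac_na = 0.25)
  m <- hybrid_patch(mix)
  sim <- simulate_patch(m, rep(0, 800), mode = "current", record_gates = TRUE)
  h <- na_availability(sim, m)
  manual <- 0.25 * sim$gates[, "human_na.h"] + 0.75 * sim$gates[, "mouse_na.h"]
  expect_equal(h$values, as.numeric(manual))
})
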