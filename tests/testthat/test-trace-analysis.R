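test_that("monoexponential decay is recovered exactly on clean data", {
  tt <- seq(0, 30, by = 0.01)
  tr <- ephys_trace(2 * exp(-tt / 5) + 1, dt = 0.01, units = "pA")
  fit <- fit_inactivation_monoexp(tr, window = c(0, 30))
  expect_equal(fit$a, 2, tolerance = 1e-6)
  expect_equal(fit$tau_h, 5, tolerance = 1e-6)
  expect_equal(fit$b, 1, tolerance = 1e-6)
  expect_equal(fit$r2, 1, tolerance = 1e-9)
  expect_true(fit$included)
})

test_that("noisy decays are recovered within 5% and noise is excluded", {
  set.seed(42)
  tt <- seq(0, 40, by = 0.02)
  clean <- -100 * exp(-tt / 6)
  noisy <- clean + rnorm(length(tt), sd = 5) # SNR 20
  fit <- fit_inactivation_monoexp(ephys_trace(noisy, 0.02, units = "pA"),
                                  window = c(0, 40))
  expect_rel(fit$tau_h, 6, 0.05)
  pure_noise <- ephys_trace(rnorm(2000), 0.02, units = "pA")
  nf <- fit_inactivation_monoexp(pure_noise, window = c(0, 39))
  expect_false(isTRUE(nf$included))
})

test_that("compound activation fit recovers its generating parameters", {
  dt <- 0.002
  tt <- seq(0, 8, by = dt)
  d0 <- 0.1; tau_m <- 0.2; tau_h <- 1.5; a <- -100; b <- 0
  i <- ifelse(tt < d0, 0,
              (1 - exp(-(tt - d0) / tau_m)) * (a * exp(-(tt - d0) / tau_h) + b))
  fit <- fit_activation_compound(ephys_trace(i, dt, units = "pA"))
  expect_rel(fit$tau_m, tau_m, 0.01)
  expect_rel(fit$tau_h, tau_h, 0.01)
  expect_rel(fit$a, a, 0.01)
  expect_false(fit$ill_conditioned)
})

test_that("clean simulated Na+ currents fit with r2 above 0.98", {
  m <- na_patch("human", gmax = 50)
  dt <- 0.005
  cmd <- c(rep(-90, round(5 / dt)), rep(-10, round(15 / dt)))
  sim <- simulate_patch(m, cmd, mode = "voltage", dt = dt)
  onset <- trace_window(sim$ina, 5 + dt, 18)
  fit <- fit_activation_compound(onset)
  expect_gt(fit$r2, 0.98)
})

test_that("time-to-half-peak ranks activation speed like the compound fit", {
  dt <- 0.002
  tt <- seq(0, 8, by = dt)
  taus <- c(0.1, 0.25, 0.5, 1)
  mk <- function(tm) ephys_trace(
    (1 - exp(-tt / tm)) * (-80 * exp(-tt / 3)), dt, units = "pA")
  fits <- vapply(taus, function(tm) fit_activation_compound(mk(tm))$tau_m, 0)
  halves <- vapply(taus, function(tm) time_to_half_peak(mk(tm)), 0)
  expect_equal(order(fits), order(halves))
})

test_that("double-exponential decays separate fast and slow components", {
  set.seed(7)
  tt <- seq(0, 400, by = 0.5)
  i <- 60 * exp(-tt / 15) + 40 * exp(-tt / 120) + 5 + rnorm(length(tt), sd = 0.5)
  fit <- fit_double_exp(ephys_trace(i, 0.5, units = "pA"))
  expect_rel(fit$tau_f, 15, 0.05)
  expect_rel(fit$tau_s, 120, 0.05)
  expect_lt(fit$tau_f, fit$tau_s)
  expect_false(fit$collapsed)
  # single-exponential input collapses with a flag
  mono <- 80 * exp(-tt / 30) + 2
  mf <- fit_double_exp(ephys_trace(mono, 0.5, units = "pA"))
  expect_true(mf$collapsed || abs(mf$a_s) < 1)
})

test_that("Boltzmann fits recover exact curves and evaluate availability", {
  v <- seq(-110, -20, by = 10)
  g <- 1 / (1 + exp((v + 66) / 7))
  fit <- fit_boltzmann(v, g, "inactivation")
  expect_equal(fit$vhalf, -66, tolerance = 1e-6)
  expect_equal(fit$q, 7, tolerance = 1e-6)
  expect_equal(fit$availability_at(fit$vhalf), fit$gmax_norm / 2, tolerance = 1e-9)
  expect_error(fit_boltzmann(v, rep(0.5, length(v)), "activation"), "transition")
})

test_that("fits are projections: refitting a fit's prediction is idempotent", {
  set.seed(11)
  tt <- seq(0, 30, by = 0.02)
  noisy <- 50 * exp(-tt / 4) + 3 + rnorm(length(tt), sd = 2)
  f1 <- fit_inactivation_monoexp(ephys_trace(noisy, 0.02, units = "pA"),
                                 window = c(0, 30))
  pred <- f1$a * exp(-tt / f1$tau_h) + f1$b
  f2 <- fit_inactivation_monoexp(ephys_trace(pred, 0.02, units = "pA"),
                                 window = c(0, 30))
  expect_rel(f2$tau_h, f1$tau_h, 1e-5)
  expect_equal(f2$r2, 1, tolerance = 1e-9)
})

test_that("conductance density uses the sphere-surface convention", {
  expect_equal(conductance_density(pi * 100 / 1000, 10), 1)
  expect_equal(conductance_density(1, 20), conductance_density(1, 10) / 4)
  m <- patch_model(diameter = 10)
  expect_equal(conductance_density(membrane_area(m) * 5 / 1000, 10), 5)
  expect_error(conductance_density(1, 0), "diameter")
})

test_that("Na+ charge fractions split at the AP peak", {
  dt <- 0.01
  tt <- seq(0, 2, by = dt)
  tri <- ephys_trace(-pmax(0, 1 - abs(tt - 1)), dt, units = "pA")
  expect_equal(na_charge_fractions(tri, 1), 0.5, tolerance = 0.02)
  before <- ephys_trace(c(rep(-1, 100), rep(0, 101)), dt, units = "pA")
  expect_equal(na_charge_fractions(before, 1), 0, tolerance = 1e-9)
  expect_error(na_charge_fractions(ephys_trace(rep(0, 10), dt, units = "pA"), 0.05),
               "zero")
})

test_that("protocol round trip recovers the generating gates", {
  # simulate -> analyze: vhalf within 1 mV, tau within 5% on noise-free data
  na <- species_preset("mouse_na", gmax = 50)
  m <- patch_model(na = list(na))
  pr <- inactivation_protocol(m, prepulses = seq(-120, -40, by = 10),
                              prepulse_ms = 400, dt = 0.01)
  bf <- fit_boltzmann(pr$curve$v, pr$curve$avail, "inactivation")
  expect_lt(abs(bf$vhalf - na$h$vhalf), 1)
  rec <- recovery_protocol(m, vrec = -90)
  expect_rel(rec$tau_rec, time_constant(-90, na$h), 0.05)
})
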