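test_that("CMA-ES minimizes standard test functions reproducibly", {
  sphere <- function(x) sum((x - c(1, -2, 3))^2)
  r1 <- cma_es(sphere, c(0, 0, 0), sigma0 = 1, generations = 120, seed = 4)
  expect_lt(r1$value, 1e-8)
  expect_equal(r1$par, c(1, -2, 3), tolerance = 1e-3)
  # best-so-far trajectory is non-increasing
  expect_true(all(diff(r1$trajectory) <= 0))
  # same seed, same result
  r2 <- cma_es(sphere, c(0, 0, 0), sigma0 = 1, generations = 120, seed = 4)
  expect_identical(r1$par, r2$par)
  # different seeds land within 2x of each other on a rough benchmark
  rosen <- function(x) 100 * (x[2] - x[1]^2)^2 + (1 - x[1])^2
  v1 <- cma_es(rosen, c(-1, 1), sigma0 = 0.5, generations = 200, seed = 1)$value
  v2 <- cma_es(rosen, c(-1, 1), sigma0 = 0.5, generations = 200, seed = 2)$value
  expect_lt(max(v1, v2) / max(min(v1, v2), 1e-12), 2 + 1e-9)
})

test_that("CMA-ES respects box constraints", {
  f <- function(x) sum(x^2)
  r <- cma_es(f, c(2, 2), sigma0 = 0.5, lower = 1, upper = 3, generations = 80,
              seed = 3)
  expect_true(all(r$par >= 1 - 1e-12))
  expect_equal(r$par, c(1, 1), tolerance = 1e-6)
})

test_that("Powell's method finds minima of smooth functions", {
  quad <- function(x) (x[1] - 2)^2 + 10 * (x[2] + 1)^2 + 2
  r <- powell_minimize(quad, c(0, 0), step = 1)
  expect_true(r$converged)
  expect_equal(r$par, c(2, -1), tolerance = 1e-3)
  expect_equal(r$value, 2, tolerance = 1e-6)
})

test_that("CMA-ES channel fitting recovers a known generating model", {
  truth <- species_preset("human_na", gmax = 50)
  template <- species_preset("mouse_na", gmax = 50)
  targets <- channel_targets(truth, v = seq(-100, 20, by = 10))
  fit <- fit_channel_cmaes(targets, template, generations = 150, seed = 2)
  expect_true(fit$converged)
  expect_lt(fit$error, 1e-3)
  expect_lt(abs(fit$channel$m$vhalf - truth$m$vhalf), 0.5)
  expect_lt(abs(fit$channel$h$vhalf - truth$h$vhalf), 0.5)
  vv <- seq(-100, 20, by = 10)
  expect_lt(max(abs(time_constant(vv, fit$channel$h) /
                      time_constant(vv, truth$h) - 1)), 0.05)
  expect_lt(max(abs(time_constant(vv, fit$channel$m) /
                      time_constant(vv, truth$m) - 1)), 0.05)
})

test_that("protocol-emulated steady-state fitting stays close to the truth", {
  truth <- species_preset("mouse_na", gmax = 50)
  template <- species_preset("human_na", gmax = 50)
  v <- seq(-110, -40, by = 10)
  targets <- fit_targets(hinf = data.frame(v = v,
                                           value = steady_state(v, truth$h)))
  fit <- fit_channel_cmaes(targets, template, protocol_emulation = TRUE,
                           generations = 25, popsize = 6, seed = 5)
  expect_lt(abs(fit$channel$h$vhalf - truth$h$vhalf), 1.5)
})

test_that("density fit targets are validated", {
  expect_error(fit_targets(minf = data.frame(v = c(0, -10),
                                             value = c(0.5, 0.4))),
               "increasing")
  expect_error(fit_targets(minf = data.frame(v = c(-10, 0),
                                             value = c(0.5, NA))),
               "finite")
})

test_that("Powell density fitting converges to a genuine local minimum", {
  fit <- fit_gmax_powell(humanfrac_na = 1, humanfrac_k = 1)
  expect_true(fit$converged)
  expect_gt(fit$gmax_na, 0)
  expect_gt(fit$gmax_k, 0)
  # perturbing either density by +-5% must not improve the objective
  obj <- function(gna, gk) {
    mix <- channel_mix(gna, gk, 1, 1)
    model <- hybrid_patch(mix)
    rheo <- find_rheobase(model)
    stim <- c(rep(1.5 * rheo, 120), rep(0, 800))
    ft <- ap_features(simulate_patch(model, stim, mode = "current")$trace)
    sum((c(ft$amplitude[1], ft$rise_max[1], ft$fall_max[1]) - fit$targets)^2)
  }
  base <- obj(fit$gmax_na, fit$gmax_k)
  expect_gt(obj(fit$gmax_na * 1.05, fit$gmax_k), base - 1e-6)
  expect_gt(obj(fit$gmax_na * 0.95, fit$gmax_k), base - 1e-6)
  expect_gt(obj(fit$gmax_na, fit$gmax_k * 1.05), base - 1e-6)
  expect_gt(obj(fit$gmax_na, fit$gmax_k * 0.95), base - 1e-6)
  # the stored features are what the fitted model actually produces
  expect_equal(unname(fit$value), sum((fit$features - fit$targets)^2),
               tolerance = 1e-6)
})
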