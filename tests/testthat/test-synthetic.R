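small_spec <- function(...) {
  cohort_spec(n_cells = 2, species = "human", channel = "na", seed = 5, ...)
}
small_grids <- list(act_steps = seq(-80, 0, by = 20),
                    inact_prepulses = seq(-110, -40, by = 35),
                    prepulse_ms = 100, dt = 0.02)

test_that("cohort generation is bit-reproducible from (spec, seed)", {
  a <- do.call(synth_vclamp_cohort, c(list(small_spec()), small_grids))
  b <- do.call(synth_vclamp_cohort, c(list(small_spec()), small_grids))
  expect_identical(a$cells[[1]]$truth, b$cells[[1]]$truth)
  expect_identical(a$cells[[1]]$raw_sweeps[[1]]$raw,
                   b$cells[[1]]$raw_sweeps[[1]]$raw)
})

test_that("without noise and artifacts the raw sweeps equal clean output", {
  spec <- small_spec(noise_sd = 0, gleak_ns = 0, cap_amp_pa_mv = 0)
  coh <- do.call(synth_vclamp_cohort, c(list(spec), small_grids))
  sw <- coh$cells[[1]]$raw_sweeps[[1]]
  expect_equal(sw$raw, sw$clean, tolerance = 1e-12)
})

test_that("P/-5 subtraction removes the injected linear artifact exactly", {
  spec <- small_spec(noise_sd = 0) # artifacts on, noise off
  coh <- do.call(synth_vclamp_cohort, c(list(spec), small_grids))
  sw <- coh$cells[[1]]$raw_sweeps[[2]]
  corrected <- pn_subtract(sw$raw, sw$pn)
  clean_b <- sw$clean - mean(sw$clean[1:50])
  expect_lt(max(abs(corrected - clean_b)), 1e-8 * max(abs(clean_b)) + 1e-8)
  # and with noise on, subtraction still recovers the decay to fit quality
  spec2 <- small_spec(noise_sd = 10)
  coh2 <- do.call(synth_vclamp_cohort, c(list(spec2), small_grids))
  sw2 <- coh2$cells[[1]]$raw_sweeps[[2]]
  corrected2 <- pn_subtract(sw2$raw, sw2$pn)
  resid <- corrected2 - (sw2$clean - mean(sw2$clean[1:50]))
  expect_lt(sd(resid), 10 * sqrt(6) * 1.2) # main + 5 pn sweeps of noise
})

test_that("per-cell analysis recovers the generating inactivation midpoints", {
  spec <- cohort_spec(n_cells = 3, species = "mouse", channel = "na",
                      noise_sd = 0, gleak_ns = 0, cap_amp_pa_mv = 0, seed = 9)
  coh <- synth_vclamp_cohort(spec, act_steps = seq(-80, 0, by = 20),
                             inact_prepulses = seq(-120, -40, by = 10),
                             prepulse_ms = 300, dt = 0.02)
  for (cell in coh$cells) {
    bf <- fit_boltzmann(cell$inactivation$curve$v, cell$inactivation$curve$avail,
                        "inactivation")
    expect_lt(abs(bf$vhalf - cell$truth$h_vhalf), 1.5)
  }
})

test_that("AP-train commands are annotated at the commanded frequency", {
  cmd <- synth_ap_command("human", freq = 40, n_aps = 8)
  expect_length(cmd$ap_times, 8)
  expect_equal(diff(cmd$ap_times), rep(25, 7), tolerance = 0.2)
})

test_that("replaying a command onto its generating model matches the free run", {
  dt <- 0.025
  mix <- channel_mix(200, 70, 1, 1)
  model <- hybrid_patch(mix)
  train <- simulate_ap_train(model, freq = 40, n_aps = 3, dt = dt,
                             record_gates = TRUE)
  sim <- simulate_patch(model, train$trace, mode = "voltage", dt = dt,
                        record_gates = TRUE, gate_stride = 8L)
  # gating trajectories under clamp match the free-running ones
  free_h <- train$gates[, "human_na.h"]
  clamp_h <- sim$gates[, "human_na.h"]
  n <- min(length(free_h), length(clamp_h))
  expect_lt(max(abs(free_h[seq_len(n)] - clamp_h[seq_len(n)])), 0.02)
})

test_that("species ordering of AP-clamp adaptation is command-independent", {
  for (origin in c("human", "mouse")) {
    cmd <- synth_ap_command(origin, freq = 40, n_aps = 6)
    a5 <- vapply(c("human", "mouse"), function(sp) {
      m <- na_patch(sp, gmax = 50)
      ap_clamp(m, cmd$trace, cmd$ap_times, current = "na")$norm[5]
    }, 0)
    expect_gt(a5[["human"]], a5[["mouse"]])
  }
})
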