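# shared fixtures, all built in code

# activation gate with an (almost) voltage-independent rate: alpha = beta = 1
flat_gate <- function(kind = "activation") {
  gate_spec(-40, 6, kind, c(a = 1, ka = 1e6, b = 1, kb = 1e6))
}

# Na channel whose inactivation never engages (h_inf ~ 1 below +60 mV)
na_no_inact <- function(gmax = 50) {
  m <- species_preset("human_na")$m
  h <- gate_spec(300, 7, "inactivation", c(a = 1e-4, ka = 1e6, b = 1e-4, kb = 1e6))
  na_channel(gmax, m, h, p = 3L)
}

# single-population patches around the shipped presets
na_patch <- function(species = "human", gmax = 50, ...) {
  patch_model(na = list(species_preset(paste0(species, "_na"), gmax = gmax)),
              eleak = -80, ...)
}
k_patch <- function(species = "human", gmax = 50, ...) {
  patch_model(k = list(species_preset(paste0(species, "_k"), gmax = gmax)),
              eleak = -80, ...)
}

# small spiking model used across tests (densities near the joint fit optimum)
spiking_patch <- function(humanfrac = 1, gmax_na = 200, gmax_k = 70) {
  hybrid_patch(channel_mix(gmax_na, gmax_k, humanfrac, humanfrac))
}

expect_rel <- function(actual, expected, tol) {
  expect_lt(abs(actual / expected - 1), tol)
}
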