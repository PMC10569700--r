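#' Species channel presets
#'
#' Fully specified human/mouse Na+ and K+ channel models. The
#' `"printed_means"` source builds each model from the published cohort-mean
#' half-(in)activation voltages (Na+ activation -32.1/-37.9 mV,
#' inactivation -66.0/-74.8 mV; K+ activation -3.0/-7.9 mV, inactivation
#' -52.7/-65.0 mV for human/mouse) combined with assumed Boltzmann slopes
#' (Na+ 5 mV activation / 7 mV inactivation; K+ 9 / 6 mV) and synthetic
#' time-constant curves. The kinetic parameters are this package's own
#' choices, fixed once to reproduce the qualitative species differences
#' seen experimentally: human Na+ activates and inactivates more slowly at
#' suprathreshold potentials but sheds its inactivation much faster at
#' subthreshold potentials (fast recovery, ~5 ms at -80 mV vs ~35 ms for
#' mouse); human K+ activates faster at subthreshold voltages; K+
#' inactivation kinetics are identical across species (only the
#' steady-state inactivation curve differs).
#'
#' `align` controls where the printed activation midpoints are placed.
#' The published V1/2 values are Boltzmann fits to measured G/Gmax curves,
#' i.e. to the m^p-composite conductance. With `align = "conductance"`
#' (default, used by the assembled patch models) the activation-gate
#' midpoint is shifted by `q * log(2^(1/p) - 1)` so that the simulated
#' conductance curve reproduces the printed midpoint. With
#' `align = "gate"` the printed value is placed directly on the gate.
#' Inactivation midpoints are availability measurements and are always
#' placed directly on the h gate.
#'
#' The `"table_s2"` source would use the original supplementary parameter
#' table, which is not distributed with this package.
#'
#' @param name One of `"human_na"`, `"mouse_na"`, `"human_k"`, `"mouse_k"`.
#' @param source `"printed_means"` (default) or `"table_s2"`.
#' @param gmax Maximal conductance density assigned to the model
#'   (pS um^-2); densities are normally set later through [channel_mix()].
#' @param align `"conductance"` or `"gate"` (see above).
#' @return An [na_channel()] or [k_channel()].
#' @export
species_preset <- function(name = c("human_na", "mouse_na", "human_k", "mouse_k"),
                           source = c("printed_means", "table_s2"), gmax = 1,
                           align = c("conductance", "gate")) {
  name <- match.arg(name)
  source <- match.arg(source)
  align <- match.arg(align)
  if (source == "table_s2")
    stop("the supplementary channel parameter table (table S2) is not ",
         "available to this package; use source = \"printed_means\", which ",
         "falls back to the published cohort-mean midpoints with documented ",
         "assumed slopes and kinetics")
  p <- preset_params()[[name]]
  is_na <- grepl("_na$", name)
  pexp <- if (is_na) 3 else 2
  m_vhalf <- if (align == "conductance")
    p$m_vhalf + p$m_q * log(2^(1 / pexp) - 1) else p$m_vhalf
  if (is_na) {
    na_channel(gmax,
               m = gate_spec(m_vhalf, p$m_q, "activation", p$m_kin),
               h = gate_spec(p$h_vhalf, p$h_q, "inactivation", p$h_kin),
               p = 3L, label = name)
  } else {
    k_channel(gmax,
              m = gate_spec(m_vhalf, p$m_q, "activation", p$m_kin),
              h1 = gate_spec(p$h_vhalf, p$h_q, "inactivation", p$h_kin),
              h2_tau_inact = p$h2_tau_inact, h2_tau_rec = p$h2_tau_rec,
              label = name)
  }
}

# Shared K+ inactivation kinetics (species differ only in the steady state):
# fast inactivation during the AP (~11 ms at +40 mV), recovery ~16 ms at
# -80 mV, bell peak ~65 ms near -55 mV.
k_shared_h_kin <- function()
  c(a = 0.0673, ka = 25, b = 4.19e-5, kb = 10, taumin = 8, tauscale = 1)

preset_params <- function() {
  # activation tau bells peak at the conductance-aligned midpoints
  vm_na_h <- -32.1 + 5 * log(2^(1 / 3) - 1)
  vm_na_m <- -37.9 + 5 * log(2^(1 / 3) - 1)
  list(
    human_na = list(
      m_vhalf = -32.1, m_q = 5,
      m_kin = bell_rates(vm_na_h, 1 / 0.14, 15), # tau_m peak ~0.14 ms
      h_vhalf = -66.0, h_q = 7,
      # slow inactivation at suprathreshold V (~1.9 ms at 0 mV) with a
      # shallow subthreshold limb: the inactivation tail dies quickly below
      # threshold and recovery is fast (~4 ms at -80 mV)
      h_kin = c(a = 0.714, ka = 70, b = 1.5e-5, kb = 10,
                taumin = 0.5, tauscale = 1)
    ),
    mouse_na = list(
      m_vhalf = -37.9, m_q = 5,
      m_kin = bell_rates(vm_na_m, 1 / 0.13, 15), # tau_m peak ~0.13 ms
      h_vhalf = -74.8, h_q = 7,
      # faster inactivation (~1.1 ms at 0 mV), much slower recovery
      # (~35 ms at -80 mV, ~30 ms at -70 mV)
      h_kin = c(a = 1.43, ka = 18, b = 4.06e-6, kb = 10,
                taumin = 0.4, tauscale = 1)
    ),
    human_k = list(
      m_vhalf = -3.0, m_q = 9,
      # activation ~1.4 ms at 0 mV; deactivation ~3 ms near -60 mV so the
      # channels opened during an AP keep conducting through repolarization
      m_kin = c(a = 0.91, ka = 20, b = 0.0759, kb = 40,
                taumin = 0.4, tauscale = 1),
      h_vhalf = -52.7, h_q = 6,
      h_kin = k_shared_h_kin(),
      h2_tau_inact = 200, h2_tau_rec = 20
    ),
    mouse_k = list(
      m_vhalf = -7.9, m_q = 9,
      # slower activation at subthreshold voltages than the human model
      m_kin = c(a = 0.55, ka = 20, b = 0.048, kb = 40,
                taumin = 0.4, tauscale = 1),
      h_vhalf = -65.0, h_q = 6,
      h_kin = k_shared_h_kin(),
      h2_tau_inact = 200, h2_tau_rec = 20
    )
  )
}
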