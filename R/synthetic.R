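#' Synthetic voltage-clamp cohort specification
#'
#' Describes a cohort of simulated nucleated-patch recordings from one
#' species/channel combination: per-cell channel parameters are drawn
#' around the species preset with the printed between-cell SDs of the
#' half-(in)activation voltages, and the "raw" sweeps carry linear leak,
#' biexponential capacitive transients at step edges (amplitude linear in
#' step size, so P/-5 subtraction cancels them by construction) and
#' Gaussian recording noise.
#'
#' @param n_cells Number of cells.
#' @param species `"human"` or `"mouse"`.
#' @param channel `"na"` or `"k"`.
#' @param vhalf_sd_act,vhalf_sd_inact Between-cell SDs of the activation/
#'   inactivation midpoints, mV (defaults ~ the printed cohort SDs).
#' @param q_sd Between-cell SD of the Boltzmann slopes, mV.
#' @param tau_lsd Log-SD of a per-cell scaling of all time constants.
#' @param gmax Channel density used in the generator, pS um^-2.
#' @param noise_sd Recording noise SD, pA.
#' @param gleak_ns Linear leak conductance of the artifact model, nS.
#' @param cap_amp_pa_mv Capacitive transient amplitude per mV of step, pA/mV.
#' @param cap_taus Fast/slow capacitive decay constants, ms.
#' @param seed Cohort seed; the dataset is bit-reproducible from
#'   (spec, seed).
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_cells = 15, species = c("human", "mouse"),
                        channel = c("na", "k"),
                        vhalf_sd_act = 5, vhalf_sd_inact = 7, q_sd = 1,
                        tau_lsd = 0.15, gmax = 50, noise_sd = 20,
                        gleak_ns = 2, cap_amp_pa_mv = 5, cap_taus = c(0.1, 1),
                        seed = 1) {
  species <- match.arg(species)
  channel <- match.arg(channel)
  stopifnot(n_cells >= 1, vhalf_sd_act >= 0, vhalf_sd_inact >= 0, q_sd >= 0,
            tau_lsd >= 0, noise_sd >= 0, gleak_ns >= 0)
  structure(as.list(environment()), class = "cohort_spec")
}

perturb_gate <- function(gate, dvhalf, dq, tau_scale) {
  kin <- gate$kin
  if (length(kin) == 4) kin[c("a", "b")] <- kin[c("a", "b")] / tau_scale
  else {
    kin[c("a", "b")] <- kin[c("a", "b")] / tau_scale
    kin["taumin"] <- kin["taumin"] * tau_scale
  }
  gate_spec(gate$vhalf + dvhalf, max(gate$q + dq, 1), gate$kind, kin)
}

# linear leak + capacitive artifact for a command waveform (pA)
linear_artifact <- function(cmd, dt, gleak_ns, eleak, cap_amp_pa_mv, cap_taus) {
  out <- gleak_ns * (cmd - eleak)
  jumps <- which(abs(diff(cmd)) > 1e-9)
  tt <- seq_along(cmd)
  for (j in jumps) {
    dv <- cmd[j + 1] - cmd[j]
    idx <- (j + 1):length(cmd)
    trel <- (idx - (j + 1)) * dt
    out[idx] <- out[idx] + cap_amp_pa_mv * dv *
      (0.7 * exp(-trel / cap_taus[1]) + 0.3 * exp(-trel / cap_taus[2]))
  }
  out
}

#' Generate a synthetic voltage-clamp cohort
#'
#' For each cell, draws channel parameters around the species preset,
#' simulates the steady-state activation and inactivation protocol
#' batteries, and produces raw sweeps (ionic + leak + capacitive + noise)
#' together with P/-5 scaling sweeps so leak subtraction can be exercised.
#' The generating ("ground truth") parameters are returned alongside; all
#' recovery tests compare against them.
#'
#' @param spec A [cohort_spec()].
#' @param act_steps,inact_prepulses Protocol voltage grids, mV.
#' @param prepulse_ms Inactivation prepulse duration, ms.
#' @param dt Integration/sampling step, ms.
#' @param n_pn Number of P/-N scaling sweeps (default 5).
#' @return List of class `synth_cohort`: `cells` (per cell: `truth`
#'   gate parameters, `activation`/`inactivation` protocol outputs with
#'   `raw` sweeps, `pn` sweeps and `clean` currents) and `spec`.
#' @export
synth_vclamp_cohort <- function(spec, act_steps = seq(-80, 40, by = 10),
                                inact_prepulses = seq(-120, -30, by = 10),
                                prepulse_ms = 300, dt = 0.01, n_pn = 5) {
  stopifnot(inherits(spec, "cohort_spec"))
  old <- .Random.seed_exists()
  on.exit(restore_seed(old), add = TRUE)
  set.seed(spec$seed)
  preset_name <- paste0(spec$species, "_", spec$channel)
  base <- species_preset(preset_name, gmax = spec$gmax)
  eleak_art <- -70

  make_raw <- function(cmd, clean) {
    art <- linear_artifact(cmd, dt, spec$gleak_ns, eleak_art,
                           spec$cap_amp_pa_mv, spec$cap_taus)
    raw <- clean + art + stats::rnorm(length(clean), sd = spec$noise_sd)
    pn <- lapply(seq_len(n_pn), function(i) {
      cmd_pn <- cmd[1] - (cmd - cmd[1]) / n_pn
      linear_artifact(cmd_pn, dt, spec$gleak_ns, eleak_art,
                      spec$cap_amp_pa_mv, spec$cap_taus) +
        stats::rnorm(length(clean), sd = spec$noise_sd)
    })
    list(raw = raw, pn = pn)
  }

  cells <- lapply(seq_len(spec$n_cells), function(ci) {
    dva <- stats::rnorm(1, 0, spec$vhalf_sd_act)
    dvi <- stats::rnorm(1, 0, spec$vhalf_sd_inact)
    dqa <- stats::rnorm(1, 0, spec$q_sd)
    dqi <- stats::rnorm(1, 0, spec$q_sd)
    tsc <- exp(stats::rnorm(1, 0, spec$tau_lsd))
    if (spec$channel == "na") {
      ch <- na_channel(spec$gmax,
                       perturb_gate(base$m, dva, dqa, tsc),
                       perturb_gate(base$h, dvi, dqi, tsc),
                       p = base$p, label = preset_name)
      model <- patch_model(na = list(ch))
    } else {
      ch <- k_channel(spec$gmax,
                      perturb_gate(base$m, dva, dqa, tsc),
                      perturb_gate(base$h1, dvi, dqi, tsc),
                      base$h2_tau_inact, base$h2_tau_rec,
                      base$frac_inact, base$frac_h2, label = preset_name)
      model <- patch_model(k = list(ch))
    }
    act <- activation_protocol(model, steps = act_steps, dt = dt,
                               measure = if (spec$channel == "na") "peak" else "steady")
    inact <- inactivation_protocol(model, prepulses = inact_prepulses,
                                   prepulse_ms = prepulse_ms, dt = dt)
    # raw sweeps for the inactivation battery (used by the P/-5 tests)
    raw_sweeps <- lapply(seq_along(inact_prepulses), function(k) {
      vp <- inact_prepulses[k]
      cmd <- c(rep(vp, round(prepulse_ms / dt)), rep(0, round(20 / dt)))
      clean <- inact$traces[[as.character(vp)]]
      # rebuild full-length clean current for the command
      sim <- simulate_patch(model, cmd, mode = "voltage", dt = dt, v0 = vp)
      cl <- protocol_current(sim, model, spec$channel)$values
      c(list(command = cmd, clean = cl), make_raw(cmd, cl))
    })
    truth <- list(
      m_vhalf = ch$m$vhalf, m_q = ch$m$q,
      h_vhalf = if (spec$channel == "na") ch$h$vhalf else ch$h1$vhalf,
      h_q = if (spec$channel == "na") ch$h$q else ch$h1$q,
      tau_scale = tsc)
    list(truth = truth, channel = ch,
         activation = act, inactivation = inact, raw_sweeps = raw_sweeps)
  })
  structure(list(cells = cells, spec = spec, dt = dt), class = "synth_cohort")
}

#' P/-N leak subtraction
#'
#' Baseline-subtracts the main sweep and each scaling sweep (mean over the
#' first `baseline_n` samples), then adds the N scaling-sweep responses to
#' the main sweep. For artifacts linear in the command, this cancels leak
#' and capacitive currents exactly (up to noise).
#'
#' @param main Raw main-sweep current (numeric).
#' @param pn_sweeps List of N raw scaling-sweep currents.
#' @param baseline_n Samples used for the baseline estimate.
#' @return Leak-subtracted current vector.
#' @export
pn_subtract <- function(main, pn_sweeps, baseline_n = 50) {
  bsub <- function(x) x - mean(x[seq_len(min(baseline_n, length(x)))])
  out <- bsub(main)
  for (p in pn_sweeps) out <- out + bsub(p)
  out
}

#' Synthetic AP-train command waveform
#'
#' Simulates the spiking model of the requested species (its own preset
#' channels at nominal densities) firing an evoked AP train, and returns
#' the voltage trace for use as an AP-clamp command, with annotated AP
#' peak times.
#'
#' @param species_like `"human"` or `"mouse"`.
#' @param freq Train frequency, Hz.
#' @param n_aps Number of APs.
#' @param gmax_na,gmax_k Densities of the command-generating model,
#'   pS um^-2.
#' @param dt Integration step, ms.
#' @return List with `trace` (voltage [ephys_trace()]) and `ap_times`
#'   (peak times, ms).
#' @export
synth_ap_command <- function(species_like = c("human", "mouse"), freq = 40,
                             n_aps = 200, gmax_na = 150, gmax_k = 40,
                             dt = 0.025) {
  species_like <- match.arg(species_like)
  hf <- if (species_like == "human") 1 else 0
  model <- hybrid_patch(channel_mix(gmax_na, gmax_k, hf, hf))
  train <- simulate_ap_train(model, freq = freq, n_aps = n_aps, dt = dt)
  list(trace = train$trace, ap_times = train$ap_peaks$t)
}
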