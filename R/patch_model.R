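#' Single-compartment nucleated-patch model
#'
#' A spherical single compartment standing in for a somatic nucleated patch:
#' diameter 10 um, specific capacitance 1 uF cm^-2, reversal potentials
#' ENa = 53 mV and EK = -101 mV, and a passive leak of 1 pS um^-2. The
#' phase-locking configuration ([phaselock_patch()]) raises ENa to 100 mV
#' and the leak to 2.5 pS um^-2 to prevent depolarization block during long
#' simulations. Membrane area uses the sphere-surface convention
#' \eqn{A = \pi d^2}.
#'
#' @param na List of [na_channel()] objects (possibly empty); each `gmax`
#'   is a density in pS um^-2.
#' @param k List of [k_channel()] objects (possibly empty).
#' @param diameter Compartment diameter, um.
#' @param cm Specific membrane capacitance, uF cm^-2.
#' @param ena,ek Reversal potentials, mV.
#' @param gleak Leak conductance density, pS um^-2.
#' @param eleak Leak reversal potential, mV (resting potential proxy).
#' @return Object of class `patch_model`.
#' @export
patch_model <- function(na = list(), k = list(), diameter = 10, cm = 1,
                        ena = 53, ek = -101, gleak = 1, eleak = -70) {
  if (inherits(na, "na_channel")) na <- list(na)
  if (inherits(k, "k_channel")) k <- list(k)
  stopifnot(all(vapply(na, inherits, TRUE, "na_channel")),
            all(vapply(k, inherits, TRUE, "k_channel")))
  if (diameter <= 0 || cm <= 0 || gleak < 0) stop("invalid passive parameters")
  structure(list(na = na, k = k, diameter = diameter, cm = cm,
                 ena = ena, ek = ek, gleak = gleak, eleak = eleak),
            class = "patch_model")
}

#' Membrane area of a patch model
#' @param model A [patch_model()] (or a diameter in um).
#' @return Area in um^2 (\eqn{\pi d^2}).
#' @export
membrane_area <- function(model) {
  d <- if (inherits(model, "patch_model")) model$diameter else model
  pi * d^2
}

#' Convert a fitted total conductance to a density
#' @param gmax_ns Total conductance in nS.
#' @param diameter Patch diameter in um.
#' @return Density in pS um^-2 (sphere-surface convention, area = pi d^2).
#' @export
conductance_density <- function(gmax_ns, diameter) {
  if (any(diameter <= 0)) stop("diameter must be > 0")
  gmax_ns * 1000 / membrane_area(diameter)
}

#' Assemble a hybrid human/mouse patch from the species presets
#'
#' Builds a [patch_model()] holding the four preset channel populations
#' with densities assigned by a [channel_mix()]:
#' `gmax_na * humanfrac_na` of human Na+, `gmax_na * (1 - humanfrac_na)` of
#' mouse Na+, and likewise for K+.
#'
#' @param mix A [channel_mix()].
#' @param phaselock Logical; use the long-simulation configuration
#'   (ENa = 100 mV, gleak = 2.5 pS um^-2).
#' @param eleak Leak reversal, mV. Default -80: the resting potential in
#'   the voltage frame of the channel midpoints (the junction-corrected
#'   resting potential of the recordings the models derive from).
#' @param source Preset source passed to [species_preset()].
#' @param ... Further arguments to [patch_model()].
#' @return A [patch_model()].
#' @export
hybrid_patch <- function(mix, phaselock = FALSE, eleak = -80,
                         source = "printed_means", ...) {
  stopifnot(inherits(mix, "channel_mix"))
  dens <- mixed_densities(mix)
  na <- list()
  if (dens[["na_human"]] > 0)
    na <- c(na, list(species_preset("human_na", source, gmax = dens[["na_human"]])))
  if (dens[["na_mouse"]] > 0)
    na <- c(na, list(species_preset("mouse_na", source, gmax = dens[["na_mouse"]])))
  k <- list()
  if (dens[["k_human"]] > 0)
    k <- c(k, list(species_preset("human_k", source, gmax = dens[["k_human"]])))
  if (dens[["k_mouse"]] > 0)
    k <- c(k, list(species_preset("mouse_k", source, gmax = dens[["k_mouse"]])))
  patch_model(na = na, k = k, eleak = eleak,
              ena = if (phaselock) 100 else 53,
              gleak = if (phaselock) 2.5 else 1, ...)
}

#' @rdname hybrid_patch
#' @export
phaselock_patch <- function(mix, ...) hybrid_patch(mix, phaselock = TRUE, ...)

# total capacitance in pF: cm [uF/cm^2] * area [um^2] * 0.01
patch_capacitance_pf <- function(model) model$cm * membrane_area(model) * 0.01

# encode for the C++ core (total conductances in nS)
encode_patch <- function(model) {
  area <- membrane_area(model)
  dens_to_ns <- function(g) g * area / 1000
  list(
    c_pf = patch_capacitance_pf(model),
    gleak_ns = dens_to_ns(model$gleak),
    eleak = model$eleak, ena = model$ena, ek = model$ek,
    na = lapply(model$na, function(ch)
      list(g_ns = dens_to_ns(ch$gmax), p = ch$p,
           m = encode_gate(ch$m), h = encode_gate(ch$h))),
    k = lapply(model$k, function(ch)
      list(g_ns = dens_to_ns(ch$gmax),
           m = encode_gate(ch$m), h1 = encode_gate(ch$h1),
           frac_inact = ch$frac_inact, frac_h2 = ch$frac_h2,
           tau_inact = ch$h2_tau_inact, tau_rec = ch$h2_tau_rec))
  )
}

patch_gate_names <- function(model) {
  nm <- character(0)
  for (i in seq_along(model$na)) {
    lab <- if (!is.null(model$na[[i]]$label)) model$na[[i]]$label else paste0("na", i)
    nm <- c(nm, paste0(lab, ".m"), paste0(lab, ".h"))
  }
  for (i in seq_along(model$k)) {
    lab <- if (!is.null(model$k[[i]]$label)) model$k[[i]]$label else paste0("k", i)
    nm <- c(nm, paste0(lab, ".m"), paste0(lab, ".h1"), paste0(lab, ".h2"))
  }
  nm
}
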