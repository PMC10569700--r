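#' Na+ channel model (m^p h)
#'
#' Transient sodium conductance \eqn{g = g_{max} m^p h} with independent
#' Boltzmann steady states for activation (m) and inactivation (h). The
#' activation exponent defaults to 3 (m^3 h).
#'
#' @param gmax Maximal conductance density, pS um^-2 (>= 0).
#' @param m Activation [gate_spec()].
#' @param h Inactivation [gate_spec()].
#' @param p Integer activation exponent (>= 1).
#' @param label Optional name.
#' @return Object of class `na_channel`.
#' @export
na_channel <- function(gmax, m, h, p = 3L, label = NULL) {
  stopifnot(inherits(m, "gate_spec"), inherits(h, "gate_spec"))
  if (m$kind != "activation" || h$kind != "inactivation")
    stop("m must be an activation gate and h an inactivation gate")
  if (gmax < 0) stop("gmax must be >= 0")
  p <- as.integer(p)
  if (p < 1) stop("activation exponent p must be >= 1")
  structure(list(gmax = gmax, m = m, h = h, p = p, label = label),
            class = "na_channel")
}

#' K+ channel model (three inactivation fractions)
#'
#' Delayed-rectifier-like potassium conductance with m^2 activation and the
#' total conductance split over three fractions with distinct inactivation
#' behavior: a fast-inactivating fraction (gate h1), a slow-inactivating
#' fraction (gate h2, fixed two-regime time constant), and a
#' non-inactivating remainder:
#' \deqn{g = g_{max} m^2 [f_{inact}((1-f_{h2})h_1 + f_{h2}h_2) + (1-f_{inact})]}
#' with `frac_inact` = 0.85 and `frac_h2` = 0.4 by default. h2 relaxes to
#' the same species-specific steady-state inactivation curve as h1, with
#' \eqn{\tau = }`h2_tau_inact` while inactivating (h2 above its steady
#' state) and `h2_tau_rec` while recovering.
#'
#' @param gmax Maximal conductance density, pS um^-2.
#' @param m Activation [gate_spec()] (exponent fixed at 2).
#' @param h1 Fast-inactivation [gate_spec()].
#' @param h2_tau_inact,h2_tau_rec Slow-inactivation/recovery time constants, ms.
#' @param frac_inact Inactivating fraction of the conductance (default 0.85).
#' @param frac_h2 Share of the inactivating fraction that inactivates slowly
#'   (default 0.4).
#' @param label Optional name.
#' @return Object of class `k_channel`.
#' @export
k_channel <- function(gmax, m, h1, h2_tau_inact, h2_tau_rec,
                      frac_inact = 0.85, frac_h2 = 0.4, label = NULL) {
  stopifnot(inherits(m, "gate_spec"), inherits(h1, "gate_spec"))
  if (m$kind != "activation" || h1$kind != "inactivation")
    stop("m must be an activation gate and h1 an inactivation gate")
  if (gmax < 0) stop("gmax must be >= 0")
  if (frac_inact < 0 || frac_inact > 1 || frac_h2 < 0 || frac_h2 > 1)
    stop("fractions must lie in [0, 1]")
  if (h2_tau_inact <= 0 || h2_tau_rec <= 0) stop("h2 time constants must be > 0")
  structure(list(gmax = gmax, m = m, h1 = h1,
                 h2_tau_inact = h2_tau_inact, h2_tau_rec = h2_tau_rec,
                 frac_inact = frac_inact, frac_h2 = frac_h2, label = label),
            class = "k_channel")
}

#' Sodium conductance at given gate values
#' @param m,h Gate values in \[0, 1\].
#' @param model An [na_channel()].
#' @return Conductance density, same units as `model$gmax`.
#' @export
na_conductance <- function(m, h, model) {
  stopifnot(inherits(model, "na_channel"))
  if (any(m < 0 | m > 1 | h < 0 | h > 1)) stop("gate value outside [0, 1]")
  model$gmax * m^model$p * h
}

#' Potassium conductance at given gate values
#' @param m,h1,h2 Gate values in \[0, 1\].
#' @param model A [k_channel()].
#' @return Conductance density, same units as `model$gmax`.
#' @export
k_conductance <- function(m, h1, h2, model) {
  stopifnot(inherits(model, "k_channel"))
  if (any(m < 0 | m > 1 | h1 < 0 | h1 > 1 | h2 < 0 | h2 > 1))
    stop("gate value outside [0, 1]")
  fi <- model$frac_inact
  f2 <- model$frac_h2
  model$gmax * m^2 * (fi * ((1 - f2) * h1 + f2 * h2) + (1 - fi))
}

#' Human/mouse channel mixing fractions
#'
#' The hybrid models distribute a total Na+ and K+ density over human- and
#' mouse-property channel populations:
#' `gmax_na_human = gmax_na * humanfrac_na`, etc. Densities of the four
#' populations always sum to `gmax_na + gmax_k`.
#'
#' @param gmax_na,gmax_k Total conductance densities, pS um^-2.
#' @param humanfrac_na,humanfrac_k Fractions in \[0, 1\] of each density
#'   assigned to the human-property channel.
#' @return Object of class `channel_mix`.
#' @export
channel_mix <- function(gmax_na, gmax_k, humanfrac_na = 1, humanfrac_k = 1) {
  if (gmax_na < 0 || gmax_k < 0) stop("densities must be >= 0")
  if (any(c(humanfrac_na, humanfrac_k) < 0 | c(humanfrac_na, humanfrac_k) > 1))
    stop("human fractions must lie in [0, 1]")
  structure(list(gmax_na = gmax_na, gmax_k = gmax_k,
                 humanfrac_na = humanfrac_na, humanfrac_k = humanfrac_k),
            class = "channel_mix")
}

#' Resolve a channel mix into the four population densities
#' @param mix A [channel_mix()].
#' @return Named numeric vector
#'   `c(na_human, na_mouse, k_human, k_mouse)` in pS um^-2.
#' @export
mixed_densities <- function(mix) {
  stopifnot(inherits(mix, "channel_mix"))
  c(na_human = mix$gmax_na * mix$humanfrac_na,
    na_mouse = mix$gmax_na * (1 - mix$humanfrac_na),
    k_human  = mix$gmax_k * mix$humanfrac_k,
    k_mouse  = mix$gmax_k * (1 - mix$humanfrac_k))
}

#' Pair of K+ channels sharing inactivation kinetics
#'
#' The human and mouse K+ models share identical inactivation dynamics (h1
#' kinetic parameters and the two-regime h2 time constants) while keeping
#' species-specific steady-state inactivation curves. This constructor
#' enforces the sharing: it rebuilds both channels from one set of kinetics.
#'
#' @param human,mouse [k_channel()] objects.
#' @param kin Shared h1 kinetic parameter vector (defaults to the human one).
#' @param h2_tau_inact,h2_tau_rec Shared slow time constants (default human).
#' @return List with elements `human` and `mouse`.
#' @export
share_k_inactivation <- function(human, mouse, kin = human$h1$kin,
                                 h2_tau_inact = human$h2_tau_inact,
                                 h2_tau_rec = human$h2_tau_rec) {
  rebuild <- function(ch) {
    h1 <- gate_spec(ch$h1$vhalf, ch$h1$q, "inactivation", kin)
    k_channel(ch$gmax, ch$m, h1, h2_tau_inact, h2_tau_rec,
              ch$frac_inact, ch$frac_h2, ch$label)
  }
  list(human = rebuild(human), mouse = rebuild(mouse))
}
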