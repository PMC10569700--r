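#' Gating-variable specification
#'
#' A gating variable is described by a Boltzmann steady state and a
#' voltage-dependent time constant built from forward/backward rates,
#' \eqn{\tau(V) = 1/(\alpha(V)+\beta(V))} with
#' \eqn{\alpha = a e^{V/k_a}}, \eqn{\beta = b e^{-V/k_b}} (bell-shaped and
#' strictly positive). Two kinetic forms are supported:
#'
#' * `bell4` — 4 parameters `(a, ka, b, kb)`, \eqn{\tau = 1/(\alpha+\beta)}
#'   (used for Na+ activation);
#' * `bell6` — 6 parameters `(a, ka, b, kb, taumin, tauscale)`,
#'   \eqn{\tau = \tau_{min} + s/(\alpha+\beta)} (used for inactivation
#'   gates and K+ activation).
#'
#' @param vhalf Boltzmann midpoint (mV).
#' @param q Boltzmann slope factor (mV, > 0).
#' @param kind `"activation"` (steady state increasing in V) or
#'   `"inactivation"` (decreasing).
#' @param kin Named numeric vector of kinetic parameters; either
#'   `c(a, ka, b, kb)` or `c(a, ka, b, kb, taumin, tauscale)`. Rates in
#'   ms^-1, slopes in mV, taumin in ms.
#'
#' @return Object of class `gate_spec`.
#' @export
gate_spec <- function(vhalf, q, kind = c("activation", "inactivation"), kin) {
  kind <- match.arg(kind)
  if (!is.finite(vhalf)) stop("vhalf must be finite")
  if (!is.finite(q) || q <= 0) stop("Boltzmann slope q must be > 0")
  kin <- as.numeric(kin)
  if (!length(kin) %in% c(4L, 6L))
    stop("kin must have 4 (bell4) or 6 (bell6) parameters, got ", length(kin))
  if (any(!is.finite(kin))) stop("kinetic parameters must be finite")
  if (any(kin[c(1, 3)] <= 0)) stop("rate amplitudes a, b must be > 0")
  if (any(kin[c(2, 4)] <= 0)) stop("rate slopes ka, kb must be > 0")
  if (length(kin) == 6 && (kin[5] < 0 || kin[6] <= 0))
    stop("taumin must be >= 0 and tauscale > 0")
  names(kin) <- if (length(kin) == 4) c("a", "ka", "b", "kb")
                else c("a", "ka", "b", "kb", "taumin", "tauscale")
  structure(list(vhalf = vhalf, q = q, kind = kind, kin = kin),
            class = "gate_spec")
}

#' Boltzmann steady state of a gate
#'
#' Activation gates follow \eqn{1/(1+e^{(v_{1/2}-V)/q})}, inactivation gates
#' \eqn{1/(1+e^{(V-v_{1/2})/q})}; both equal 0.5 at the midpoint.
#'
#' @param V Membrane potential(s), mV.
#' @param gate A [gate_spec()].
#' @return Steady-state open/available fraction in \[0, 1\].
#' @export
steady_state <- function(V, gate) {
  stopifnot(inherits(gate, "gate_spec"))
  if (any(!is.finite(V))) stop("V must be finite")
  z <- if (gate$kind == "activation") (gate$vhalf - V) / gate$q
       else (V - gate$vhalf) / gate$q
  1 / (1 + exp(z))
}

#' Voltage-dependent time constant of a gate
#'
#' @inheritParams steady_state
#' @return Time constant(s) in ms, strictly positive.
#' @export
time_constant <- function(V, gate) {
  stopifnot(inherits(gate, "gate_spec"))
  if (any(!is.finite(V))) stop("V must be finite")
  k <- gate$kin
  rate <- k[["a"]] * exp(V / k[["ka"]]) + k[["b"]] * exp(-V / k[["kb"]])
  tau <- if (length(k) == 4) 1 / rate else k[["taumin"]] + k[["tauscale"]] / rate
  pmax(tau, 1e-4)
}

#' First-order relaxation rate of a gating variable
#'
#' \eqn{dx/dt = (x_\infty(V) - x)/\tau(V)}, the HH relaxation law.
#'
#' @param x Current gate value in \[0, 1\].
#' @param V Membrane potential, mV.
#' @param gate A [gate_spec()].
#' @return Rate of change per ms.
#' @export
gate_derivative <- function(x, V, gate) {
  if (any(x < 0 | x > 1)) stop("gate value outside [0, 1]")
  (steady_state(V, gate) - x) / time_constant(V, gate)
}

#' Build bell-shaped rate parameters from a peak location and rate
#'
#' Convenience inverse parameterization: given the voltage `vpeak` at which
#' \eqn{\tau} peaks, the total rate `rate_peak` \eqn{= \alpha+\beta} there,
#' and the two limb slopes, returns `c(a, ka, b, kb)` such that
#' \eqn{\alpha(v_{peak}) = \beta(v_{peak}) = rate_{peak}/2} (exact peak for
#' `ka == kb`, near-peak otherwise).
#'
#' @param vpeak Peak voltage (mV).
#' @param rate_peak Total transition rate at the peak (ms^-1).
#' @param ka,kb Voltage slopes of the depolarized/hyperpolarized limbs (mV).
#' @return Named numeric vector `c(a, ka, b, kb)`.
#' @export
bell_rates <- function(vpeak, rate_peak, ka, kb = ka) {
  c(a = rate_peak / 2 * exp(-vpeak / ka), ka = ka,
    b = rate_peak / 2 * exp(vpeak / kb), kb = kb)
}

# encode a gate for the C++ core: c(kind, vhalf, q, form, a, ka, b, kb[, taumin, tauscale])
encode_gate <- function(gate) {
  stopifnot(inherits(gate, "gate_spec"))
  form <- if (length(gate$kin) == 4) 0 else 1
  c(ifelse(gate$kind == "activation", 0, 1), gate$vhalf, gate$q, form,
    unname(gate$kin))
}
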