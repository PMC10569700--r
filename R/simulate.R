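#' Integrate a patch model against a stimulus
#'
#' Core simulation entry point. In `"current"` (current-clamp) mode the
#' stimulus is an injected current waveform (pA) and the result is the
#' membrane potential; in `"voltage"` (voltage-clamp) mode the stimulus is
#' the command voltage (mV) and the result is the recorded membrane
#' current, returned both as the total ionic current and split into
#' components (`ina`, `ik`, `ileak`, `icap`).
#'
#' Numerics: gating variables are advanced by an exact exponential update
#' at the voltage frozen over one step; the membrane potential by an
#' implicit backward-Euler update (unconditionally stable). Before the
#' stimulus proper, the model is settled for `settle_ms` at the initial
#' voltage (leak reversal in current clamp, first command sample in voltage
#' clamp) with gates initialized at their steady states, so results do not
#' depend on arbitrary initial conditions. The run is fully deterministic.
#'
#' @param model A [patch_model()].
#' @param stimulus An [ephys_trace()] or plain numeric vector (then `dt`
#'   must be given).
#' @param mode `"current"` or `"voltage"` clamp.
#' @param dt Integration/sampling step, ms (default 0.025; use 0.005 for
#'   fast Na+ kinetics protocols).
#' @param record_gates Logical; also record gating-variable trajectories.
#' @param gate_stride Record every `gate_stride`-th sample of the gates.
#' @param settle_ms Settling period before the stimulus, ms.
#' @param v0 Override for the settling/initial voltage.
#' @return A list of class `patch_sim` with elements `trace` (voltage or
#'   total ionic current as [ephys_trace()]), in voltage-clamp mode also
#'   `ina`, `ik`, `ileak`, `icap`, and when `record_gates = TRUE` a matrix
#'   `gates` (attribute `"dt"` = `dt * gate_stride`) with one column per
#'   gating variable.
#' @export
simulate_patch <- function(model, stimulus, mode = c("current", "voltage"),
                           dt = 0.025, record_gates = FALSE, gate_stride = 8L,
                           settle_ms = 200, v0 = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(model, "patch_model"))
  if (inherits(stimulus, "ephys_trace")) {
    if (abs(stimulus$dt - dt) > 1e-9)
      stimulus <- resample_values(stimulus$values, stimulus$dt, dt)
    else stimulus <- stimulus$values
  }
  stimulus <- as.numeric(stimulus)
  if (anyNA(stimulus) || any(!is.finite(stimulus))) stop("NaN/Inf in stimulus")
  if (dt <= 0) stop("dt must be > 0")
  gate_stride <- max(1L, as.integer(gate_stride))
  stride <- if (record_gates) gate_stride else 0L

  # settle length padded to a multiple of the recording stride so recorded
  # gate rows stay aligned with the stimulus after trimming
  n0 <- ceiling(settle_ms / dt)
  if (stride > 0) n0 <- as.integer(ceiling(n0 / stride) * stride) else n0 <- as.integer(n0)

  enc <- encode_patch(model)
  if (mode == "current") {
    vinit <- if (is.null(v0)) model$eleak else v0
    full <- c(rep(0, n0), stimulus)
    res <- .cc_core(enc, full, dt, vinit, stride)
    keep <- (n0 + 1):length(full)
    out <- list(trace = ephys_trace(res$v[keep], dt, units = "mV",
                                    kind = "voltage"))
  } else {
    vinit <- if (is.null(v0)) stimulus[1] else v0
    full <- c(rep(vinit, n0), stimulus)
    res <- .vc_core(enc, full, dt, stride)
    keep <- (n0 + 1):length(full)
    comp <- lapply(res[c("ina", "ik", "ileak", "icap")], function(x)
      ephys_trace(x[keep], dt, units = "pA", kind = "current"))
    out <- c(list(trace = ephys_trace(res$ina[keep] + res$ik[keep], dt,
                                      units = "pA", kind = "current")),
             comp)
  }
  if (stride > 0) {
    g <- res$gates
    row_keep <- seq(n0 / stride + 1, nrow(g))
    g <- g[row_keep, , drop = FALSE]
    colnames(g) <- patch_gate_names(model)
    attr(g, "dt") <- dt * stride
    out$gates <- g
  }
  out$dt <- dt
  out$mode <- mode
  class(out) <- "patch_sim"
  out
}

# nearest-neighbour resampling onto a new uniform grid covering the same span
resample_values <- function(values, dt_from, dt_to) {
  n_to <- max(2L, floor((length(values) - 1) * dt_from / dt_to) + 1L)
  idx <- round((seq_len(n_to) - 1) * dt_to / dt_from) + 1
  values[pmin(idx, length(values))]
}

#' Weighted Na+ availability (h) trajectory from a recorded simulation
#'
#' Density-weighted mean of the Na+ inactivation gates across channel
#' populations, as a trace sampled at the gate-recording rate.
#'
#' @param sim A `patch_sim` result with recorded gates.
#' @param model The [patch_model()] that produced it.
#' @return An [ephys_trace()] of h in \[0, 1\] (units field reads "mV" is
#'   not applicable; values are dimensionless fractions).
#' @export
na_availability <- function(sim, model) {
  if (is.null(sim$gates)) stop("simulation was run without record_gates = TRUE")
  cols <- grep("\\.h$", colnames(sim$gates))
  if (length(cols) == 0) stop("model has no Na+ channels")
  w <- vapply(model$na, function(ch) ch$gmax, 0)
  w <- w / sum(w)
  h <- as.numeric(sim$gates[, cols, drop = FALSE] %*% w)
  ephys_trace(h, attr(sim$gates, "dt"), units = "mV", kind = "na_availability")
}
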