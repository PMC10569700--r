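#' @keywords internal
# pick the recorded current for a protocol: the isolated channel type
protocol_current <- function(sim, model, current = c("auto", "na", "k")) {
  current <- match.arg(current)
  if (current == "auto") {
    has_na <- length(model$na) > 0
    has_k <- length(model$k) > 0
    if (has_na && has_k)
      stop("model carries both Na+ and K+ channels; set current = \"na\" or \"k\"")
    current <- if (has_na) "na" else "k"
  }
  if (current == "na") sim$ina else sim$ik
}

step_command <- function(hold, levels_ms) {
  # levels_ms: list of c(V, duration_ms); returns values at dt resolution later
  do.call(c, lapply(levels_ms, function(x) rep(x[1], x[2])))
}

#' Steady-state activation protocol
#'
#' Depolarizing voltage steps from a hyperpolarized holding potential; the
#' peak (Na+) or steady-state (K+) current at each step is converted to a
#' conductance \eqn{G = I/(V - E_{rev})} and normalized to its maximum.
#'
#' @param model A [patch_model()] carrying one channel type.
#' @param steps Step-potential grid, mV.
#' @param holding Holding potential, mV.
#' @param step_ms Step duration, ms.
#' @param measure `"peak"` (transient currents) or `"steady"` (mean over
#'   the last 10% of the step).
#' @param current Which recorded current to analyze (`"auto"` for a
#'   single-channel-type model).
#' @param dt Integration step, ms.
#' @return List with `curve` (data.frame `v`, `i`, `g`, `gnorm`) and
#'   `traces` (per-step current [ephys_trace()]s).
#' @export
activation_protocol <- function(model, steps = seq(-80, 60, by = 10),
                                holding = -90, step_ms = 30,
                                measure = c("peak", "steady"),
                                current = "auto", dt = 0.005) {
  measure <- match.arg(measure)
  stopifnot(all(diff(steps) > 0))
  erev <- if (identical(current, "k") ||
              (identical(current, "auto") && length(model$na) == 0)) model$ek else model$ena
  traces <- list()
  rows <- lapply(steps, function(v) {
    if (abs(v - erev) < 5) {
      warning("step ", v, " mV within 5 mV of Erev (", erev, " mV); excluded")
      return(NULL)
    }
    cmd <- c(rep(holding, round(5 / dt)), rep(v, round(step_ms / dt)))
    sim <- simulate_patch(model, cmd, mode = "voltage", dt = dt, v0 = holding)
    i <- protocol_current(sim, model, current)
    win <- trace_window(i, 5, 5 + step_ms)
    amp <- if (measure == "peak") win$values[which.max(abs(win$values))]
           else mean(win$values[seq(ceiling(0.9 * length(win$values)), length(win$values))])
    traces[[as.character(v)]] <<- win
    data.frame(v = v, i = amp, g = amp / (v - erev))
  })
  curve <- do.call(rbind, rows)
  curve$gnorm <- curve$g / max(curve$g)
  list(curve = curve, traces = traces)
}

#' Steady-state inactivation (availability) protocol
#'
#' Long conditioning prepulses over a grid of potentials followed by a
#' fixed test pulse; peak test-pulse current, normalized to its maximum,
#' gives the availability curve.
#'
#' @param model A [patch_model()].
#' @param prepulses Prepulse potential grid, mV.
#' @param vtest Test-pulse potential, mV.
#' @param prepulse_ms Prepulse duration, ms (long enough to equilibrate h).
#' @param test_ms Test-pulse duration, ms.
#' @inheritParams activation_protocol
#' @return List with `curve` (data.frame `v`, `i`, `avail`) and `traces`.
#' @export
inactivation_protocol <- function(model, prepulses = seq(-120, -30, by = 10),
                                  vtest = 0, prepulse_ms = 500, test_ms = 20,
                                  current = "auto", dt = 0.005) {
  stopifnot(all(diff(prepulses) > 0))
  traces <- list()
  amps <- vapply(prepulses, function(vp) {
    cmd <- c(rep(vp, round(prepulse_ms / dt)), rep(vtest, round(test_ms / dt)))
    sim <- simulate_patch(model, cmd, mode = "voltage", dt = dt, v0 = vp)
    i <- protocol_current(sim, model, current)
    win <- trace_window(i, prepulse_ms, prepulse_ms + test_ms)
    traces[[as.character(vp)]] <<- win
    win$values[which.max(abs(win$values))]
  }, 0)
  curve <- data.frame(v = prepulses, i = amps, avail = abs(amps) / max(abs(amps)))
  list(curve = curve, traces = traces)
}

#' Recovery from inactivation protocol
#'
#' Channels are fully inactivated by a long depolarizing conditioning
#' pulse; after increasing delays at the recovery potential a test pulse
#' measures the recovered fraction of the pre-conditioning peak current. A
#' monoexponential fit to fraction-vs-delay yields the recovery time
#' constant.
#'
#' @param model A [patch_model()].
#' @param vrec Recovery potential, mV.
#' @param delays Delay grid, ms (default log-spaced 1-300 ms).
#' @param vcond Conditioning/test potential, mV.
#' @param cond_ms Conditioning duration, ms.
#' @param holding Pre-protocol holding potential, mV (hyperpolarized so the
#'   reference pulse sees full availability).
#' @inheritParams activation_protocol
#' @return List with `curve` (data.frame `delay`, `fraction`), `tau_rec`
#'   (fitted ms), `fit` (the [minpack.lm::nlsLM] object) and `monotone`
#'   (FALSE flags non-monotone recovery beyond small numerical jitter).
#' @export
recovery_protocol <- function(model, vrec = -80,
                              delays = round(exp(seq(log(1), log(300), length.out = 12)), 2),
                              vcond = 0, cond_ms = 100, holding = -120,
                              current = "auto", dt = 0.005) {
  fracs <- vapply(delays, function(d) {
    cmd <- c(rep(holding, round(5 / dt)),
             rep(vcond, round(cond_ms / dt)),
             rep(vrec, round(d / dt)),
             rep(vcond, round(15 / dt)))
    sim <- simulate_patch(model, cmd, mode = "voltage", dt = dt, v0 = holding)
    i <- protocol_current(sim, model, current)
    t_cond_on <- 5
    t_test_on <- 5 + cond_ms + d
    p1 <- max(abs(trace_window(i, t_cond_on, t_cond_on + 10)$values))
    p2 <- max(abs(trace_window(i, t_test_on, t_test_on + 10)$values))
    p2 / p1
  }, 0)
  curve <- data.frame(delay = delays, fraction = fracs)
  fit <- minpack.lm::nlsLM(
    fraction ~ a * (1 - exp(-delay / tau)) + c0, data = curve,
    start = list(a = max(fracs), tau = stats::median(delays), c0 = min(fracs)),
    lower = c(0, 1e-3, -0.5), upper = c(2, 5e3, 1),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  monotone <- all(diff(fracs) > -0.02 * max(fracs))
  if (!monotone) warning("non-monotone recovery beyond numerical jitter")
  list(curve = curve, tau_rec = stats::coef(fit)[["tau"]], fit = fit,
       monotone = monotone)
}

#' AP-clamp replay
#'
#' Replays an AP-train voltage waveform as the voltage-clamp command and
#' measures the peak channel current evoked by each AP, normalized to the
#' first AP.
#'
#' @param model A [patch_model()].
#' @param command Voltage-command [ephys_trace()] (the AP train).
#' @param ap_times AP peak times, ms (within the command trace).
#' @inheritParams activation_protocol
#' @param window_ms Half-width of the search window around each AP, ms.
#' @return data.frame with `ap`, `t`, `amp` (|peak current|, pA) and `norm`
#'   (`amp/amp[1]`).
#' @export
ap_clamp <- function(model, command, ap_times, current = "auto", dt = 0.025,
                     window_ms = NULL) {
  stopifnot(inherits(command, "ephys_trace"))
  tt_end <- command$t0 + (length(command) - 1) * command$dt
  if (any(ap_times < command$t0 | ap_times > tt_end))
    stop("ap_times outside the command trace")
  sim <- simulate_patch(model, command, mode = "voltage", dt = dt)
  i <- protocol_current(sim, model, current)
  if (is.null(window_ms))
    window_ms <- if (length(ap_times) > 1) min(diff(sort(ap_times))) / 2 else 10
  res <- lapply(seq_along(ap_times), function(j) {
    w <- trace_window(i, max(0, ap_times[j] - window_ms),
                      min(tt_end, ap_times[j] + window_ms))
    k <- which.max(abs(w$values))
    data.frame(ap = j, t = trace_times(w)[k], amp = abs(w$values[k]))
  })
  out <- do.call(rbind, res)
  out$norm <- out$amp / out$amp[1]
  out
}

has_ap <- function(values, peak_v = 0) any(values > peak_v)

#' Rheobase of a patch model for a square pulse
#'
#' Smallest pulse amplitude on the precision grid that elicits an AP
#' (membrane potential exceeding `peak_v`), found by bracketing and
#' bisection over grid indices; equivalent to an exhaustive grid scan for
#' monotone spike generation.
#'
#' @param model A [patch_model()].
#' @param pulse_ms Pulse width, ms.
#' @param precision Amplitude resolution, pA (10 pA for AP-train work,
#'   0.1 pA for phase-locking calibration).
#' @param max_amp Largest amplitude tried, pA.
#' @param tail_ms Observation window after the pulse, ms.
#' @param peak_v AP detection level, mV.
#' @inheritParams simulate_patch
#' @return Rheobase in pA (a multiple of `precision`).
#' @export
find_rheobase <- function(model, pulse_ms = 3, precision = 10, max_amp = 1e4,
                          tail_ms = 20, peak_v = 0, dt = 0.025) {
  spike_at <- function(amp) {
    stim <- c(rep(amp, round(pulse_ms / dt)), rep(0, round(tail_ms / dt)))
    sim <- simulate_patch(model, stim, mode = "current", dt = dt)
    has_ap(sim$trace$values, peak_v)
  }
  hi <- precision
  while (!spike_at(hi)) {
    hi <- hi * 2
    if (hi > max_amp) stop("no AP up to ", max_amp, " pA")
  }
  lo_idx <- 0L; hi_idx <- as.integer(ceiling(hi / precision))
  while (hi_idx - lo_idx > 1L) {
    mid <- (lo_idx + hi_idx) %/% 2L
    if (spike_at(mid * precision)) hi_idx <- mid else lo_idx <- mid
  }
  hi_idx * precision
}

#' Evoke an AP train with short current pulses
#'
#' Square pulses (default 3 ms, 150% of rheobase) at a fixed frequency;
#' firing must be 100% reliable, otherwise an error lists the failed pulse
#' indices.
#'
#' @param model A [patch_model()].
#' @param freq Pulse frequency, Hz.
#' @param n_aps Number of pulses/APs.
#' @param pulse_ms Pulse width, ms.
#' @param amp Pulse amplitude, pA; default 1.5x the 10-pA-precision rheobase.
#' @param record_gates Passed to [simulate_patch()].
#' @inheritParams simulate_patch
#' @return List with `trace` ([ephys_trace()]), `pulse_times` (onsets, ms),
#'   `ap_peaks` (data.frame `t`, `v` per AP), `amp`, and `gates` when
#'   recorded.
#' @export
simulate_ap_train <- function(model, freq, n_aps, pulse_ms = 3, amp = NULL,
                              dt = 0.025, record_gates = FALSE) {
  interval <- 1000 / freq
  if (interval <= pulse_ms) stop("inter-pulse interval shorter than the pulse")
  if (is.null(amp)) amp <- 1.5 * find_rheobase(model, pulse_ms = pulse_ms, dt = dt)
  n_int <- round(interval / dt)
  n_pulse <- round(pulse_ms / dt)
  one <- c(rep(amp, n_pulse), rep(0, n_int - n_pulse))
  stim <- c(rep(one, n_aps), rep(0, round(10 / dt)))
  sim <- simulate_patch(model, stim, mode = "current", dt = dt,
                        record_gates = record_gates)
  pulse_times <- (seq_len(n_aps) - 1) * interval
  v <- sim$trace$values
  peaks <- lapply(seq_len(n_aps), function(j) {
    i0 <- (j - 1) * n_int + 1
    i1 <- min(j * n_int, length(v))
    seg <- v[i0:i1]
    k <- which.max(seg)
    if (seg[k] <= 0) return(NULL)
    data.frame(t = (i0 + k - 2) * dt, v = seg[k])
  })
  failed <- which(vapply(peaks, is.null, TRUE))
  if (length(failed) > 0)
    stop("AP failure at pulse indices: ", paste(failed, collapse = ", "))
  out <- list(trace = sim$trace, pulse_times = pulse_times,
              ap_peaks = do.call(rbind, peaks), amp = amp, freq = freq)
  if (record_gates) out$gates <- sim$gates
  out
}
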