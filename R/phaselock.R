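#' Stimulus specification for phase-locking simulations
#'
#' The input current is DC + sinusoid + exponentially filtered Gaussian
#' noise, all scaled to fractions of the model's rheobase: sinusoid
#' amplitude 15%, noise SD 30% (after filtering), DC 84% (human), 94%
#' (mouse at matched ~12.5 Hz firing) or 83% (mouse at the human input
#' level).
#'
#' @param rheobase Rheobase, pA (0.1-pA precision in this configuration).
#' @param freq Sinusoid frequency, Hz.
#' @param dc_frac DC level as a fraction of rheobase.
#' @param sine_amp_frac Sinusoid amplitude fraction (default 0.15).
#' @param noise_sd_frac Noise SD fraction after filtering (default 0.30).
#' @param noise_filter_tau Exponential filter time constant, ms (default 5).
#' @param duration_s Stimulus duration, s (600 in the full-length setting).
#' @param seed Noise seed; keep identical across models so phase-locking
#'   differences cannot come from different noise realizations.
#' @return Object of class `stimulus_spec`.
#' @export
stimulus_spec <- function(rheobase, freq, dc_frac, sine_amp_frac = 0.15,
                          noise_sd_frac = 0.30, noise_filter_tau = 5,
                          duration_s = 600, seed = 1) {
  stopifnot(rheobase > 0, freq > 0,
            dc_frac >= 0, sine_amp_frac >= 0, noise_sd_frac >= 0)
  if (duration_s <= 10 / freq) stop("duration must exceed 10 cycles")
  structure(list(rheobase = rheobase, freq = freq, dc_frac = dc_frac,
                 sine_amp_frac = sine_amp_frac, noise_sd_frac = noise_sd_frac,
                 noise_filter_tau = noise_filter_tau, duration_s = duration_s,
                 seed = seed),
            class = "stimulus_spec")
}

#' Generate the frozen-noise sinusoidal stimulus
#'
#' White Gaussian samples are filtered with a first-order (single-pole)
#' exponential filter of time constant `noise_filter_tau`, rescaled to the
#' target SD after filtering, and added to the DC + sinusoid waveform.
#' Identical seeds give bit-identical traces.
#'
#' @param spec A [stimulus_spec()].
#' @param dt Sampling step, ms.
#' @return Current [ephys_trace()] in pA.
#' @export
generate_stimulus <- function(spec, dt = 0.025) {
  stopifnot(inherits(spec, "stimulus_spec"))
  n <- round(spec$duration_s * 1000 / dt)
  tt <- (seq_len(n) - 1) * dt
  det <- spec$rheobase *
    (spec$dc_frac + spec$sine_amp_frac * sin(2 * pi * spec$freq * tt / 1000))
  if (spec$noise_sd_frac > 0) {
    old <- .Random.seed_exists()
    on.exit(restore_seed(old), add = TRUE)
    set.seed(spec$seed)
    w <- stats::rnorm(n)
    a <- exp(-dt / spec$noise_filter_tau)
    x <- stats::filter(w * (1 - a), a, method = "recursive")
    x <- as.numeric(x)
    x <- x / stats::sd(x) * spec$noise_sd_frac * spec$rheobase
    det <- det + x
  }
  ephys_trace(det, dt, units = "pA", kind = "current")
}

#' Phase-locking index M/R from spike times
#'
#' Spike times are folded into the stimulus cycle (`t %% (1/f)`), binned
#' into a 30-bin cycle histogram of instantaneous rate, and a
#' single-cycle sinusoid (offset + amplitude + phase, linear in the
#' cos/sin basis) is fitted by least squares. M is the fitted amplitude, R
#' the fitted offset (mean rate); M/R is the phase-locking strength.
#'
#' @param spike_times Spike times in s.
#' @param freq Stimulus frequency, Hz.
#' @param duration_s Total analyzed duration, s (to express R in Hz).
#' @param n_bins Histogram bins per cycle (default 30).
#' @return List of class `phaselock_result` with `freq`, `R` (Hz), `M`
#'   (Hz), `mr`, `n_spikes`, `phase` (radians), `hist` (the cycle
#'   histogram). `mr` is `NA` (flagged) for zero spikes.
#' @export
phase_locking_mr <- function(spike_times, freq, duration_s, n_bins = 30) {
  if (length(spike_times) == 0)
    return(structure(list(freq = freq, R = 0, M = NA_real_, mr = NA_real_,
                          n_spikes = 0L, phase = NA_real_, hist = NULL),
                     class = "phaselock_result"))
  cycle <- 1 / freq
  ct <- spike_times %% cycle
  breaks <- seq(0, cycle, length.out = n_bins + 1)
  counts <- graphics::hist(ct, breaks = breaks, plot = FALSE)$counts
  # rate per bin in Hz: counts / (n_cycles * bin_width)
  n_cycles <- duration_s / cycle
  rate <- counts / (n_cycles * cycle / n_bins)
  centers <- (breaks[-1] + breaks[-(n_bins + 1)]) / 2
  ang <- 2 * pi * centers / cycle
  X <- cbind(1, cos(ang), sin(ang))
  cf <- stats::lm.fit(X, rate)$coefficients
  R <- cf[1]
  M <- sqrt(cf[2]^2 + cf[3]^2)
  structure(list(freq = freq, R = unname(R), M = unname(M),
                 mr = unname(M / R), n_spikes = length(spike_times),
                 phase = atan2(cf[3], cf[2]),
                 hist = data.frame(center_s = centers, rate_hz = rate)),
            class = "phaselock_result")
}

#' Spike times from a simulated voltage trace
#' @param trace Voltage [ephys_trace()].
#' @param peak_v Spike acceptance level, mV (AP peak above 0 mV).
#' @param discard_s Initial transient to discard, s.
#' @return Spike peak times in s.
#' @export
spike_times_s <- function(trace, peak_v = 0, discard_s = 1) {
  v <- trace$values
  n <- length(v)
  idx <- which(c(FALSE, v[2:(n - 1)] >= v[1:(n - 2)] & v[2:(n - 1)] > v[3:n],
                 FALSE) & v > peak_v)
  if (length(idx) > 1) idx <- idx[c(TRUE, diff(idx) * trace$dt > 1)]
  st <- (trace$t0 + (idx - 1) * trace$dt) / 1000
  st[st >= discard_s]
}

#' Calibrate the DC fraction to a target firing rate
#'
#' Bisection on the DC fraction (sinusoid and noise held at their spec
#' fractions) until the mean firing rate over a probe simulation is within
#' `rate_tol` of `target_hz`.
#'
#' @param model A [patch_model()] in the phase-locking configuration.
#' @param rheobase Rheobase, pA.
#' @param target_hz Target mean rate (default 12.5 Hz).
#' @param freq Probe sinusoid frequency, Hz.
#' @param probe_s Probe duration, s.
#' @param seed Noise seed.
#' @param bounds DC fraction search interval.
#' @param rate_tol Acceptable rate error, Hz.
#' @param dt Integration step, ms.
#' @return The calibrated DC fraction.
#' @export
calibrate_dc <- function(model, rheobase, target_hz = 12.5, freq = 5,
                         probe_s = 20, seed = 1, bounds = c(0.3, 1.5),
                         rate_tol = 0.5, dt = 0.025) {
  rate_at <- function(dc) {
    spec <- stimulus_spec(rheobase, freq, dc, duration_s = probe_s, seed = seed)
    stim <- generate_stimulus(spec, dt)
    sim <- simulate_patch(model, stim, mode = "current", dt = dt)
    length(spike_times_s(sim$trace)) / (probe_s - 1)
  }
  lo <- bounds[1]; hi <- bounds[2]
  for (i in 1:20) {
    mid <- (lo + hi) / 2
    r <- rate_at(mid)
    if (abs(r - target_hz) < rate_tol) return(mid)
    if (r > target_hz) hi <- mid else lo <- mid
  }
  mid
}

#' M/R vs input frequency and the bandwidth cutoff
#'
#' Runs the phase-locking simulation at each input frequency (frozen noise
#' seed shared across frequencies and models) and locates the cutoff
#' frequency where M/R drops below `threshold` (0.4), by linear
#' interpolation between the bracketing frequencies.
#'
#' @param model A [patch_model()] (phase-locking configuration).
#' @param rheobase Rheobase, pA (0.1-pA precision).
#' @param dc_frac DC fraction of rheobase.
#' @param freqs Input frequency grid, Hz.
#' @param duration_s Simulated duration per frequency, s.
#' @param threshold M/R cutoff level (default 0.4).
#' @param seed Noise seed.
#' @param dt Integration step, ms.
#' @param record_h Record the Na+ availability gate (for
#'   [pre_ap_availability()]).
#' @return List of class `mr_curve` with `table` (data.frame `freq`, `R`,
#'   `M`, `mr`, `n_spikes`), `cutoff_hz` (`NA` with `no_cutoff = TRUE` when
#'   the curve never crosses), and per-frequency `details` (spike times and,
#'   optionally, h traces).
#' @export
mr_curve_and_cutoff <- function(model, rheobase, dc_frac,
                                freqs = c(1, 3, 5, 10, 20, 30, 40, 50, 60, 70, 80, 100),
                                duration_s = 60, threshold = 0.4, seed = 1,
                                dt = 0.025, record_h = FALSE) {
  details <- list()
  rows <- lapply(freqs, function(f) {
    spec <- stimulus_spec(rheobase, f, dc_frac, duration_s = duration_s,
                          seed = seed)
    stim <- generate_stimulus(spec, dt)
    sim <- simulate_patch(model, stim, mode = "current", dt = dt,
                          record_gates = record_h)
    st <- spike_times_s(sim$trace)
    res <- phase_locking_mr(st, f, duration_s - 1)
    det <- list(spike_times = st)
    if (record_h) det$h <- na_availability(sim, model)
    details[[as.character(f)]] <<- det
    data.frame(freq = f, R = res$R, M = res$M, mr = res$mr,
               n_spikes = res$n_spikes)
  })
  tab <- do.call(rbind, rows)
  cutoff <- interpolate_cutoff(tab$freq, tab$mr, threshold)
  structure(list(table = tab, cutoff_hz = cutoff$cutoff,
                 no_cutoff = cutoff$no_cutoff, threshold = threshold,
                 details = details),
            class = "mr_curve")
}

interpolate_cutoff <- function(freq, mr, threshold = 0.4) {
  ok <- is.finite(mr)
  freq <- freq[ok]; mr <- mr[ok]
  below <- which(mr <= threshold)
  if (length(below) == 0)
    return(list(cutoff = NA_real_, no_cutoff = TRUE))
  i <- below[1]
  if (i == 1) return(list(cutoff = freq[1], no_cutoff = FALSE))
  f0 <- freq[i - 1]; f1 <- freq[i]
  m0 <- mr[i - 1]; m1 <- mr[i]
  cutoff <- if (m1 == threshold) f1
            else f0 + (m0 - threshold) / (m0 - m1) * (f1 - f0)
  list(cutoff = cutoff, no_cutoff = FALSE)
}

#' Pre-AP Na+ channel availability
#'
#' Mean of the Na+ inactivation gate h over the window 0.8-2.8 ms before
#' each AP peak (a 2-ms window ending 0.8 ms before the peak), the median
#' across APs, and the spike-phase spread of above- vs below-median APs.
#'
#' @param h_trace Na+ availability [ephys_trace()] (see
#'   [na_availability()]).
#' @param peak_times_ms AP peak times, ms (APs earlier than the window are
#'   excluded).
#' @param freq Optional stimulus frequency (Hz) for the phase analysis.
#' @param window_ms `c(late, early)` window bounds before the peak, ms.
#' @return List with `per_ap` (data.frame `t_peak_ms`, `h`), `median_h`,
#'   and, when `freq` is given, `phase_sd_above`/`phase_sd_below`: the
#'   circular standard deviation of spike phases for APs with above- and
#'   below-median pre-AP h.
#' @export
pre_ap_availability <- function(h_trace, peak_times_ms, freq = NULL,
                                window_ms = c(0.8, 2.8)) {
  tt <- trace_times(h_trace)
  rows <- lapply(peak_times_ms, function(tp) {
    if (tp - window_ms[2] < tt[1]) return(NULL)
    idx <- which(tt >= tp - window_ms[2] & tt <= tp - window_ms[1])
    if (length(idx) == 0) return(NULL)
    data.frame(t_peak_ms = tp, h = mean(h_trace$values[idx]))
  })
  per_ap <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(per_ap) || nrow(per_ap) == 0) stop("no APs with a full pre-AP window")
  out <- list(per_ap = per_ap, median_h = stats::median(per_ap$h))
  if (!is.null(freq)) {
    phases <- 2 * pi * ((per_ap$t_peak_ms / 1000) %% (1 / freq)) * freq
    circ_sd <- function(th) {
      if (length(th) < 2) return(NA_real_)
      Rbar <- sqrt(mean(cos(th))^2 + mean(sin(th))^2)
      sqrt(-2 * log(max(Rbar, 1e-12)))
    }
    hi <- per_ap$h > out$median_h
    out$phase_sd_above <- circ_sd(phases[hi])
    out$phase_sd_below <- circ_sd(phases[!hi])
  }
  out
}
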