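r_squared <- function(obs, pred) {
  ss_res <- sum((obs - pred)^2)
  ss_tot <- sum((obs - mean(obs))^2)
  if (ss_tot == 0) return(ifelse(ss_res == 0, 1, -Inf))
  1 - ss_res / ss_tot
}

# bounded Levenberg-Marquardt with a few perturbed restarts; keeps the best
multistart_nls <- function(formula, data, start, lower, upper, n_starts = 3,
                           seed_jitter = 0.3) {
  best <- NULL; best_rss <- Inf
  starts <- c(list(start), lapply(seq_len(max(0, n_starts - 1)), function(i) {
    lapply(seq_along(start), function(j) {
      s <- start[[j]] * (1 + seed_jitter * (2 * ((i + j) %% 2) - 1))
      min(max(s, lower[j]), upper[j])
    }) |> stats::setNames(names(start))
  }))
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(formula, data = data, start = s, lower = lower,
                        upper = upper,
                        control = minpack.lm::nls.lm.control(
                          maxiter = 300, ftol = 1e-8, ptol = 1e-8)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::residuals(fit)^2)
      if (rss < best_rss) { best <- fit; best_rss <- rss }
    }
  }
  best
}

exp_fit_result <- function(pars, r2, window = NULL, converged = TRUE) {
  structure(c(as.list(pars),
              list(r2 = r2, included = isTRUE(converged) && is.finite(r2) && r2 > 0.9,
                   converged = converged, window = window)),
            class = "exp_fit_result")
}

#' Monoexponential fit to an inactivating current
#'
#' Fits \eqn{I(t) = a e^{-t/\tau_h} + b} to the decay phase of a current
#' trace by bounded least squares (time measured from the window start).
#' Raw traces are low-pass filtered first (6 kHz default). Fits with
#' \eqn{R^2 \le 0.9} are flagged as excluded.
#'
#' @param trace Current [ephys_trace()].
#' @param window `c(from, to)` in ms; default: from the absolute peak to
#'   the end of the trace.
#' @param filter_khz Low-pass cutoff applied when `trace$raw` is TRUE.
#' @return An `exp_fit_result` with fields `a`, `b`, `tau_h`, `r2`,
#'   `included`.
#' @export
fit_inactivation_monoexp <- function(trace, window = NULL, filter_khz = 6) {
  if (trace$raw) trace <- lowpass_trace(trace, filter_khz)
  tt <- trace_times(trace)
  if (is.null(window)) {
    k <- which.max(abs(trace$values))
    window <- c(tt[k], tt[length(tt)])
  }
  w <- trace_window(trace, window[1], window[2])
  d <- data.frame(t = trace_times(w) - window[1], i = w$values)
  amp0 <- d$i[1] - d$i[nrow(d)]
  span <- max(d$t)
  fit <- multistart_nls(i ~ a * exp(-t / tau) + b, d,
                        start = list(a = amp0, tau = span / 5, b = d$i[nrow(d)]),
                        lower = c(-Inf, 1e-4, -Inf), upper = c(Inf, 100 * span, Inf))
  if (is.null(fit))
    return(exp_fit_result(c(a = NA, b = NA, tau_h = NA), r2 = NA,
                          window = window, converged = FALSE))
  cf <- stats::coef(fit)
  exp_fit_result(c(a = cf[["a"]], b = cf[["b"]], tau_h = cf[["tau"]]),
                 r2 = r_squared(d$i, stats::fitted(fit)), window = window)
}

#' Compound activation fit for Na+ currents
#'
#' Na+ currents inactivate appreciably while still activating, so the
#' activation fit multiplies the rising exponential by a decaying one:
#' \deqn{I(t) = [1 - e^{-(t-d)/\tau_m}][a e^{-(t-d)/\tau_h} + b]}
#' with onset delay `d`. Fitted by bounded least squares with multiple
#' starts. A fit reaching \eqn{\tau_m \ge \tau_h} is flagged
#' ill-conditioned.
#'
#' @param trace Current [ephys_trace()] containing the rising and early
#'   decaying phase (time from trace start).
#' @param filter_khz Low-pass cutoff applied when `trace$raw` is TRUE
#'   (14 kHz, the Na+ activation setting).
#' @return An `exp_fit_result` with fields `a`, `b`, `d`, `tau_m`, `tau_h`,
#'   `r2`, `included`, `ill_conditioned`.
#' @export
fit_activation_compound <- function(trace, filter_khz = 14) {
  if (trace$raw) trace <- lowpass_trace(trace, filter_khz)
  tt <- trace_times(trace) - trace$t0
  d <- data.frame(t = tt, i = trace$values)
  k <- which.max(abs(d$i))
  ipk <- d$i[k]
  span <- max(d$t)
  # data-driven starts: onset where the current first reaches 2% of peak,
  # activation tau from the remaining rise time, inactivation tau from a
  # rough monoexponential on the decay
  onset_idx <- which(abs(d$i) >= 0.02 * abs(ipk))[1]
  d0_start <- max(d$t[onset_idx] - trace$dt, 0)
  taum_start <- max((d$t[k] - d0_start) / 3, trace$dt)
  tauh_start <- if (k < nrow(d) - 4) {
    tail_i <- d$i[k:nrow(d)]
    drop <- which(abs(tail_i) <= abs(ipk) / exp(1))[1]
    if (is.na(drop)) span / 3 else max(drop * trace$dt, 5 * trace$dt)
  } else span / 3
  # the onset delay couples strongly with tau_m; profile it over a small
  # grid and refit the remaining parameters at each candidate
  d0_grid <- unique(pmax(0, d0_start + c(-2, -1, 0, 1, 2) * trace$dt))
  fit <- NULL; best_rss <- Inf
  for (d0c in d0_grid) {
    f <- multistart_nls(
      i ~ pmax(1 - exp(-(t - d0) / tau_m), 0) *
        (a * exp(-(t - d0) / tau_h) + b),
      d,
      start = list(d0 = d0c, tau_m = taum_start,
                   a = ipk, tau_h = tauh_start, b = 0),
      lower = c(0, 1e-4, -Inf, 1e-3, -Inf),
      upper = c(max(d$t[k], 0.2), span, Inf, 100 * span, Inf), n_starts = 3)
    if (!is.null(f)) {
      rss <- sum(stats::residuals(f)^2)
      if (rss < best_rss) { fit <- f; best_rss <- rss }
    }
  }
  if (is.null(fit))
    return(exp_fit_result(c(a = NA, b = NA, d = NA, tau_m = NA, tau_h = NA),
                          r2 = NA, converged = FALSE))
  cf <- stats::coef(fit)
  out <- exp_fit_result(c(a = cf[["a"]], b = cf[["b"]], d = cf[["d0"]],
                          tau_m = cf[["tau_m"]], tau_h = cf[["tau_h"]]),
                        r2 = r_squared(d$i, stats::fitted(fit)))
  out$ill_conditioned <- cf[["tau_m"]] >= cf[["tau_h"]]
  out
}

#' Time to half-peak: direct activation-speed estimator
#'
#' Alternative to the compound exponential fit: the time from trace start
#' at which the current first reaches 50% of its peak magnitude.
#'
#' @param trace Current [ephys_trace()].
#' @return Time in ms.
#' @export
time_to_half_peak <- function(trace) {
  v <- abs(trace$values)
  k <- which.max(v)
  j <- which(v[seq_len(k)] >= v[k] / 2)[1]
  (j - 1) * trace$dt
}

#' Double-exponential fit to an inactivating K+ current
#'
#' \eqn{I(t) = a_f e^{-t/\tau_f} + a_s e^{-t/\tau_s} + b} with
#' \eqn{\tau_f < \tau_s} enforced by ordering after the fit. Near-degenerate
#' components (\eqn{\tau_s/\tau_f < 1.5}) are collapsed to a
#' monoexponential and flagged.
#'
#' @param trace Current [ephys_trace()] over the decay window.
#' @param filter_khz Low-pass cutoff applied when `trace$raw` is TRUE
#'   (2 kHz, the K+ setting).
#' @return List with `a_f`, `tau_f`, `a_s`, `tau_s`, `b`, `r2`,
#'   `collapsed` (TRUE when degenerate).
#' @export
fit_double_exp <- function(trace, filter_khz = 2) {
  if (trace$raw) trace <- lowpass_trace(trace, filter_khz)
  tt <- trace_times(trace) - trace$t0
  d <- data.frame(t = tt, i = trace$values)
  amp0 <- d$i[1] - d$i[nrow(d)]
  span <- max(d$t)
  fit <- multistart_nls(
    i ~ af * exp(-t / tf) + as_ * exp(-t / ts) + b, d,
    start = list(af = amp0 * 0.6, tf = span / 20, as_ = amp0 * 0.4,
                 ts = span / 2, b = d$i[nrow(d)]),
    lower = c(-Inf, 1e-4, -Inf, 1e-4, -Inf),
    upper = c(Inf, 100 * span, Inf, 1000 * span, Inf), n_starts = 4)
  if (is.null(fit)) stop("double-exponential fit did not converge")
  cf <- stats::coef(fit)
  taus <- c(cf[["tf"]], cf[["ts"]]); amps <- c(cf[["af"]], cf[["as_"]])
  o <- order(taus)
  out <- list(a_f = amps[o[1]], tau_f = taus[o[1]],
              a_s = amps[o[2]], tau_s = taus[o[2]], b = cf[["b"]],
              r2 = r_squared(d$i, stats::fitted(fit)), collapsed = FALSE)
  if (out$tau_s / out$tau_f < 1.5) {
    mono <- fit_inactivation_monoexp(trace)
    out <- list(a_f = mono$a, tau_f = mono$tau_h, a_s = 0, tau_s = NA,
                b = mono$b, r2 = mono$r2, collapsed = TRUE)
  }
  out
}

#' Boltzmann fit to a normalized conductance/availability curve
#'
#' @param v Voltages, mV.
#' @param g Normalized conductance or availability values.
#' @param kind `"activation"` (rising in V) or `"inactivation"` (falling).
#' @return List of class `boltzmann_fit` with `vhalf`, `q`, `gmax_norm`,
#'   `r2`, and `availability_at(V)` evaluating the fitted curve.
#' @export
fit_boltzmann <- function(v, g, kind = c("activation", "inactivation")) {
  kind <- match.arg(kind)
  stopifnot(length(v) == length(g), length(v) >= 4)
  if (max(g) - min(g) < 0.2)
    stop("no transition within the voltage range (curve spans < 0.2)")
  sgn <- if (kind == "activation") 1 else -1
  d <- data.frame(v = v, g = g)
  v0 <- stats::approx(g, v, xout = (max(g) + min(g)) / 2, ties = mean)$y
  if (is.na(v0)) v0 <- mean(range(v))
  fit <- multistart_nls(g ~ gmax / (1 + exp(sgn * (vh - v) / q)), d,
                        start = list(gmax = max(g), vh = v0, q = 7),
                        lower = c(1e-3, min(v) - 50, 0.5),
                        upper = c(10, max(v) + 50, 50))
  if (is.null(fit)) stop("Boltzmann fit did not converge")
  cf <- stats::coef(fit)
  out <- list(vhalf = cf[["vh"]], q = cf[["q"]], gmax_norm = cf[["gmax"]],
              r2 = r_squared(d$g, stats::fitted(fit)), kind = kind)
  out$availability_at <- function(V)
    out$gmax_norm / (1 + exp(sgn * (out$vhalf - V) / out$q))
  class(out) <- "boltzmann_fit"
  out
}

#' Fraction of Na+ charge entering after the AP peak
#'
#' \eqn{\int |I|\,dt} after the AP peak divided by the total
#' \eqn{\int |I|\,dt}, for an isolated Na+ current during one AP.
#'
#' @param current Na+ current [ephys_trace()] spanning one AP.
#' @param ap_peak_t AP peak time, ms.
#' @return Fraction in \[0, 1\].
#' @export
na_charge_fractions <- function(current, ap_peak_t) {
  tt <- trace_times(current)
  absI <- abs(current$values)
  total <- sum(absI) * current$dt
  if (total == 0) stop("zero total charge")
  after <- sum(absI[tt > ap_peak_t]) * current$dt
  after / total
}
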