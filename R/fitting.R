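#' Target curves for channel-model fitting
#'
#' Bundles the four voltage-dependent target functions used to constrain a
#' channel model: steady-state activation (m_inf) and inactivation (h_inf)
#' and the activation/inactivation time constants tau_m(V), tau_h(V). Each
#' is a data.frame with columns `v` (mV) and `value` (fraction or ms).
#'
#' @param minf,hinf,taum,tauh data.frames `v`, `value` (any may be NULL to
#'   skip that function).
#' @return Object of class `fit_targets`.
#' @export
fit_targets <- function(minf = NULL, hinf = NULL, taum = NULL, tauh = NULL) {
  chk <- function(d, nm) {
    if (is.null(d)) return(NULL)
    stopifnot(is.data.frame(d), all(c("v", "value") %in% names(d)))
    if (is.unsorted(d$v, strictly = TRUE)) stop(nm, ": voltage grid must be increasing")
    if (any(!is.finite(d$value))) stop(nm, ": non-finite target values")
    d
  }
  structure(list(minf = chk(minf, "minf"), hinf = chk(hinf, "hinf"),
                 taum = chk(taum, "taum"), tauh = chk(tauh, "tauh")),
            class = "fit_targets")
}

#' Extract the target curves implied by a channel model
#'
#' Convenience for ground-truth recovery studies: evaluates a model's gate
#' steady states and time constants on a voltage grid.
#'
#' @param channel An [na_channel()] or [k_channel()].
#' @param v Voltage grid, mV.
#' @return A [fit_targets()].
#' @export
channel_targets <- function(channel, v = seq(-100, 40, by = 10)) {
  m <- channel$m
  h <- if (inherits(channel, "na_channel")) channel$h else channel$h1
  fit_targets(
    minf = data.frame(v = v, value = steady_state(v, m)),
    hinf = data.frame(v = v, value = steady_state(v, h)),
    taum = data.frame(v = v, value = time_constant(v, m)),
    tauh = data.frame(v = v, value = time_constant(v, h))
  )
}

# sum of squared differences normalized by the curve's maximum magnitude
curve_error <- function(target, value_fn) {
  pred <- value_fn(target$v)
  scale <- max(abs(target$value))
  sum(((pred - target$value) / scale)^2)
}

#' Fit a channel model to target curves with CMA-ES
#'
#' The four target functions are fitted separately (to keep each search
#' low-dimensional): Boltzmann midpoint/slope for each steady state (2
#' parameters), then the kinetic parameter vector for each time-constant
#' curve (4 for a bell4 activation gate, 6 for bell6). The error is the sum
#' of squared differences normalized by each curve's maximum magnitude.
#' Initial values come from direct least-squares fits (steady states) and
#' from the template's parameters (kinetics); CMA-ES then refines them.
#'
#' With `protocol_emulation = TRUE` the steady-state errors are computed by
#' running the voltage-clamp protocol battery on a patch carrying the
#' candidate channel and comparing the derived activation/availability
#' curves to the targets (slower, but includes the protocol's own biases);
#' time-constant curves are always compared as direct evaluations.
#'
#' @param targets A [fit_targets()].
#' @param template An [na_channel()] or [k_channel()] providing structure
#'   (gate kinds, kinetic form, exponent) and initial kinetics.
#' @param protocol_emulation Logical (see above).
#' @param generations CMA-ES generations per function (50-500).
#' @param seed RNG seed.
#' @param popsize Optional CMA-ES population size.
#' @return List of class `channel_fit` with `channel` (fitted model),
#'   `error` (total normalized error), `runs` (per-function CMA-ES
#'   results) and `converged` (FALSE when a run failed to improve over its
#'   first 50 generations).
#' @export
fit_channel_cmaes <- function(targets, template, protocol_emulation = FALSE,
                              generations = 150, seed = 1, popsize = NULL) {
  stopifnot(inherits(targets, "fit_targets"))
  is_na_model <- inherits(template, "na_channel")
  m0 <- template$m
  h0 <- if (is_na_model) template$h else template$h1
  runs <- list()
  fitted <- list(m = m0, h = h0)

  fit_ss <- function(curve, gate0, which) {
    # direct Boltzmann fit for the start, CMA-ES refinement
    init <- tryCatch(fit_boltzmann(curve$v, curve$value / max(curve$value),
                                   kind = gate0$kind),
                     error = function(e) list(vhalf = gate0$vhalf, q = gate0$q))
    obj <- function(p) {
      g <- tryCatch(gate_spec(p[1], p[2], gate0$kind, gate0$kin),
                    error = function(e) NULL)
      if (is.null(g)) return(1e6)
      if (protocol_emulation) ss_protocol_error(g, gate0, curve, which)
      else curve_error(curve, function(v) steady_state(v, g))
    }
    res <- cma_es(obj, c(init$vhalf, init$q), sigma0 = 2,
                  lower = c(-120, 0.5), upper = c(60, 50),
                  generations = generations, popsize = popsize, seed = seed)
    res
  }
  fit_tau <- function(curve, gate0) {
    k0 <- unname(gate0$kin)
    # log-parameterization keeps rates/slopes positive
    obj <- function(lp) {
      kin <- exp(lp)
      if (length(kin) == 6) kin[5] <- exp(lp[5]) - 1e-3 # taumin may reach ~0
      g <- tryCatch(gate_spec(gate0$vhalf, gate0$q, gate0$kind, kin),
                    error = function(e) NULL)
      if (is.null(g)) return(1e6)
      curve_error(curve, function(v) time_constant(v, g))
    }
    lp0 <- log(ifelse(k0 <= 0, 1e-3, k0))
    if (length(k0) == 6) lp0[5] <- log(k0[5] + 1e-3)
    res <- cma_es(obj, lp0, sigma0 = 0.3, lower = lp0 - 6, upper = lp0 + 6,
                  generations = generations, popsize = popsize, seed = seed)
    res$kin <- exp(res$par)
    if (length(res$kin) == 6) res$kin[5] <- exp(res$par[5]) - 1e-3
    res
  }
  ss_protocol_error <- function(g, gate0, curve, which) {
    ch <- if (which == "m") replace_gate(template, m = g) else replace_gate(template, h = g)
    mdl <- single_channel_patch(ch)
    sim_curve <- tryCatch({
      if (which == "m") {
        pr <- activation_protocol(mdl, steps = curve$v, dt = 0.01,
                                  measure = if (is_na_model) "peak" else "steady")
        stats::approx(pr$curve$v, pr$curve$gnorm, xout = curve$v, rule = 2)$y
      } else {
        pr <- inactivation_protocol(mdl, prepulses = curve$v, prepulse_ms = 300,
                                    dt = 0.01)
        pr$curve$avail
      }
    }, error = function(e) NULL)
    if (is.null(sim_curve)) return(1e6)
    scale <- max(abs(curve$value))
    sum(((sim_curve - curve$value / scale))^2)
  }

  if (!is.null(targets$minf)) {
    runs$minf <- fit_ss(targets$minf, m0, "m")
    fitted$m <- gate_spec(runs$minf$par[1], runs$minf$par[2], m0$kind, m0$kin)
  }
  if (!is.null(targets$hinf)) {
    runs$hinf <- fit_ss(targets$hinf, h0, "h")
    fitted$h <- gate_spec(runs$hinf$par[1], runs$hinf$par[2], h0$kind, h0$kin)
  }
  if (!is.null(targets$taum)) {
    runs$taum <- fit_tau(targets$taum, fitted$m)
    fitted$m <- gate_spec(fitted$m$vhalf, fitted$m$q, fitted$m$kind, runs$taum$kin)
  }
  if (!is.null(targets$tauh)) {
    runs$tauh <- fit_tau(targets$tauh, fitted$h)
    fitted$h <- gate_spec(fitted$h$vhalf, fitted$h$q, fitted$h$kind, runs$tauh$kin)
  }

  channel <- if (is_na_model)
    na_channel(template$gmax, fitted$m, fitted$h, template$p, template$label)
  else
    k_channel(template$gmax, fitted$m, fitted$h, template$h2_tau_inact,
              template$h2_tau_rec, template$frac_inact, template$frac_h2,
              template$label)
  converged <- all(vapply(runs, function(r) {
    n50 <- min(50, length(r$trajectory))
    r$trajectory[length(r$trajectory)] < r$trajectory[n50] ||
      r$trajectory[length(r$trajectory)] < 1e-6
  }, TRUE))
  structure(list(channel = channel, runs = runs,
                 error = sum(vapply(runs, function(r) r$value, 0)),
                 converged = converged),
            class = "channel_fit")
}

replace_gate <- function(channel, m = NULL, h = NULL) {
  if (inherits(channel, "na_channel")) {
    na_channel(channel$gmax, if (is.null(m)) channel$m else m,
               if (is.null(h)) channel$h else h, channel$p, channel$label)
  } else {
    k_channel(channel$gmax, if (is.null(m)) channel$m else m,
              if (is.null(h)) channel$h1 else h, channel$h2_tau_inact,
              channel$h2_tau_rec, channel$frac_inact, channel$frac_h2,
              channel$label)
  }
}

single_channel_patch <- function(channel, ...) {
  ch <- channel; ch$gmax <- if (ch$gmax > 0) ch$gmax else 50
  if (inherits(ch, "na_channel")) patch_model(na = list(ch), ...)
  else patch_model(k = list(ch), ...)
}

#' Fit total conductance densities to AP waveform targets (Powell)
#'
#' For a given human/mouse mixing fraction pair, finds the total Na+ and
#' K+ conductance densities whose evoked AP best matches a target feature
#' triple (amplitude mV, rise speed mV/ms, fall speed mV/ms; defaults
#' 48.4 / 420 / 73.1, the cross-species experimental means). The AP is
#' evoked by the standard short-pulse protocol (3-ms pulse at 150% of the
#' 10-pA-precision rheobase) and the objective is the plain sum of squared
#' feature differences, minimized by Powell's method over log densities.
#'
#' @param humanfrac_na,humanfrac_k Mixing fractions in \[0, 1\].
#' @param targets Named vector `c(amplitude, rise, fall)`.
#' @param init Initial densities `c(gmax_na, gmax_k)` in pS um^-2.
#' @param eleak Leak reversal, mV.
#' @param dt Integration step, ms.
#' @param tol Powell convergence tolerance on the objective.
#' @return List of class `gmax_fit` with `gmax_na`, `gmax_k`, `value`
#'   (objective at the optimum), `features` (achieved triple), `rheobase`,
#'   `converged`.
#' @export
fit_gmax_powell <- function(humanfrac_na = 1, humanfrac_k = humanfrac_na,
                            targets = c(amplitude = 48.4, rise = 420, fall = 73.1),
                            init = c(100, 50), eleak = -80, dt = 0.025,
                            tol = 1e-5) {
  feat <- function(gna, gk) {
    mix <- channel_mix(gna, gk, humanfrac_na, humanfrac_k)
    model <- hybrid_patch(mix, eleak = eleak)
    rheo <- tryCatch(find_rheobase(model, dt = dt), error = function(e) NA)
    if (is.na(rheo)) return(NULL)
    stim <- c(rep(1.5 * rheo, round(3 / dt)), rep(0, round(20 / dt)))
    sim <- simulate_patch(model, stim, mode = "current", dt = dt)
    ft <- ap_features(sim$trace)
    if (nrow(ft) == 0) return(NULL)
    list(features = c(amplitude = ft$amplitude[1], rise = ft$rise_max[1],
                      fall = ft$fall_max[1]),
         rheobase = rheo)
  }
  obj <- function(lg) {
    f <- feat(exp(lg[1]), exp(lg[2]))
    if (is.null(f)) return(1e8)
    sum((f$features - targets)^2)
  }
  res <- powell_minimize(obj, log(init), step = 0.5, tol = tol, maxit = 60)
  gna <- exp(res$par[1]); gk <- exp(res$par[2])
  f <- feat(gna, gk)
  if (is.null(f)) stop("no AP at the fitted densities")
  structure(list(gmax_na = gna, gmax_k = gk, value = res$value,
                 features = f$features, rheobase = f$rheobase,
                 humanfrac_na = humanfrac_na, humanfrac_k = humanfrac_k,
                 targets = targets, converged = res$converged),
            class = "gmax_fit")
}
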