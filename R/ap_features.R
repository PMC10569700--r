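# central-difference dv/dt in mV/ms
dvdt_central <- function(v, dt) {
  n <- length(v)
  d <- numeric(n)
  d[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / (2 * dt)
  d[1] <- (v[2] - v[1]) / dt
  d[n] <- (v[n] - v[n - 1]) / dt
  d
}

#' Detect AP thresholds in a voltage trace
#'
#' APs are segmented at local maxima of dv/dt exceeding the detection rate;
#' the threshold of each AP is the voltage at the last time dv/dt crossed
#' `rate_mvms` (23 mV/ms) from below before that dv/dt maximum. Raw traces
#' are low-pass filtered at 20 kHz first; model output is used as is.
#'
#' @param trace Voltage [ephys_trace()].
#' @param rate_mvms Threshold crossing rate, mV/ms.
#' @param peak_v Minimum AP peak voltage, mV (spike acceptance).
#' @param filter_khz Filter cutoff for raw traces.
#' @return data.frame with one row per AP: `t_thr`, `v_thr`, `i_thr`
#'   (sample index), `t_peak`, `v_peak`, `i_peak`. Zero rows when no AP.
#' @export
detect_threshold <- function(trace, rate_mvms = 23, peak_v = 0,
                             filter_khz = 20) {
  if (trace$raw) trace <- lowpass_trace(trace, filter_khz)
  v <- trace$values
  dt <- trace$dt
  dv <- dvdt_central(v, dt)
  n <- length(v)
  # spike peaks: local maxima above peak_v
  is_peak <- c(FALSE, v[2:(n - 1)] >= v[1:(n - 2)] & v[2:(n - 1)] > v[3:n] &
                 v[2:(n - 1)] > peak_v, FALSE)
  peaks <- which(is_peak)
  # merge peaks closer than 1 ms (same AP)
  if (length(peaks) > 1) {
    keep <- c(TRUE, diff(peaks) * dt > 1)
    peaks <- peaks[keep]
  }
  if (length(peaks) == 0)
    return(data.frame(t_thr = numeric(0), v_thr = numeric(0),
                      i_thr = integer(0), t_peak = numeric(0),
                      v_peak = numeric(0), i_peak = integer(0)))
  bounds <- c(1, floor((peaks[-length(peaks)] + peaks[-1]) / 2), n)
  rows <- lapply(seq_along(peaks), function(j) {
    lo <- bounds[j]; pk <- peaks[j]
    seg <- lo:pk
    imax <- seg[which.max(dv[seg])]
    # last upward crossing of the detection rate before the dv/dt maximum
    pre <- lo:imax
    below <- dv[pre] < rate_mvms
    cross <- which(below[-length(below)] & !below[-1])
    if (length(cross) == 0) {
      if (all(!below)) cross <- 0 else return(NULL)
    }
    i_thr <- pre[max(cross) + 1]
    data.frame(t_thr = trace$t0 + (i_thr - 1) * dt, v_thr = v[i_thr],
               i_thr = i_thr, t_peak = trace$t0 + (pk - 1) * dt,
               v_peak = v[pk], i_peak = pk)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0)
    return(data.frame(t_thr = numeric(0), v_thr = numeric(0),
                      i_thr = integer(0), t_peak = numeric(0),
                      v_peak = numeric(0), i_peak = integer(0)))
  do.call(rbind, rows)
}

#' AP waveform features
#'
#' Computes, per detected AP: amplitude (threshold to peak), rise speed
#' (maximum dv/dt of the upstroke, and the slope of a linear fit within the
#' 30-70% amplitude window) and fall speed (magnitude of the minimum dv/dt
#' of the downstroke, and the 70-30% linear-fit slope magnitude).
#'
#' @param trace Voltage [ephys_trace()].
#' @param thresholds Result of [detect_threshold()]; computed when NULL.
#' @return data.frame with one row per AP: `amplitude`, `rise_max`,
#'   `rise_fit`, `fall_max`, `fall_fit`, `v_thr`, `v_peak`, `t_peak`,
#'   `fit_ok` (FALSE when a 30-70% window held < 3 samples and only the
#'   derivative estimator is reliable).
#' @export
ap_features <- function(trace, thresholds = NULL) {
  if (is.null(thresholds)) thresholds <- detect_threshold(trace)
  v <- trace$values
  dt <- trace$dt
  dv <- dvdt_central(v, dt)
  n <- length(v)
  ends <- c(thresholds$i_thr[-1], n)
  rows <- lapply(seq_len(nrow(thresholds)), function(j) {
    i0 <- thresholds$i_thr[j]; ip <- thresholds$i_peak[j]; i1 <- ends[j]
    amp <- v[ip] - v[i0]
    lo_v <- v[i0] + 0.3 * amp
    hi_v <- v[i0] + 0.7 * amp
    up <- i0:ip
    rise_max <- max(dv[up])
    # downstroke: from peak until v falls back to threshold (or next AP)
    down <- ip:i1
    below_thr <- which(v[down] <= v[i0])
    if (length(below_thr) > 0) down <- down[seq_len(below_thr[1])]
    fall_max <- -min(dv[down])
    linfit <- function(idx) {
      if (length(idx) < 3) return(NA_real_)
      unname(stats::coef(stats::lm.fit(cbind(1, idx * dt), v[idx]))[2])
    }
    up_win <- up[v[up] >= lo_v & v[up] <= hi_v]
    down_win <- down[v[down] >= lo_v & v[down] <= hi_v]
    rise_fit <- linfit(up_win)
    fall_fit <- -linfit(down_win)
    data.frame(amplitude = amp, rise_max = rise_max, rise_fit = rise_fit,
               fall_max = fall_max, fall_fit = fall_fit,
               v_thr = v[i0], v_peak = v[ip], t_peak = thresholds$t_peak[j],
               fit_ok = !is.na(rise_fit) && !is.na(fall_fit))
  })
  do.call(rbind, rows)
}

#' Train stability: per-AP speeds relative to the first AP
#'
#' @param train Voltage [ephys_trace()] holding an evoked AP train.
#' @param n_aps Expected number of APs; an error names missing indices if
#'   fewer are detected.
#' @param features Optional precomputed [ap_features()] table.
#' @return List of class `train_stability` with `rel_rise`, `rel_fall`,
#'   `rel_amplitude` (first entry 1 by construction), the feature table,
#'   and the summary ratios `rise_ap5`, `fall_ap5`, `rise_ap_last`,
#'   `fall_ap_last`.
#' @export
train_stability <- function(train, n_aps, features = NULL) {
  if (is.null(features)) features <- ap_features(train)
  if (nrow(features) < n_aps)
    stop("missed AP(s): expected ", n_aps, ", detected ", nrow(features),
         " (missing indices ", paste(seq_len(n_aps)[-seq_len(nrow(features))],
                                     collapse = ", "), ")")
  features <- features[seq_len(n_aps), ]
  rel <- function(x) x / x[1]
  out <- list(rel_rise = rel(features$rise_max),
              rel_fall = rel(features$fall_max),
              rel_amplitude = rel(features$amplitude),
              features = features, n_aps = n_aps)
  out$rise_ap5 <- if (n_aps >= 5) out$rel_rise[5] else NA_real_
  out$fall_ap5 <- if (n_aps >= 5) out$rel_fall[5] else NA_real_
  out$rise_ap_last <- out$rel_rise[n_aps]
  out$fall_ap_last <- out$rel_fall[n_aps]
  class(out) <- "train_stability"
  out
}

#' Percentile bootstrap confidence interval
#'
#' @param samples Numeric vector (n >= 2).
#' @param stat Statistic function (default mean).
#' @param level Confidence level.
#' @param n_boot Number of bootstrap resamples.
#' @param seed RNG seed (local to this call).
#' @return Named vector `c(lower, upper)`.
#' @export
bootstrap_ci <- function(samples, stat = mean, level = 0.95, n_boot = 2000,
                         seed = 1) {
  stopifnot(length(samples) >= 2)
  old <- .Random.seed_exists()
  on.exit(restore_seed(old), add = TRUE)
  set.seed(seed)
  stats_b <- vapply(seq_len(n_boot), function(i)
    stat(sample(samples, replace = TRUE)), 0)
  alpha <- (1 - level) / 2
  out <- stats::quantile(stats_b, c(alpha, 1 - alpha), names = FALSE)
  c(lower = out[1], upper = out[2])
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
restore_seed <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
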