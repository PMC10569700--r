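#' Uniformly sampled electrophysiology trace
#'
#' Lightweight container for a uniformly sampled time series (membrane
#' potential or membrane current). Units are mandatory so downstream
#' analyses never have to guess scales.
#'
#' @param values Numeric vector of samples.
#' @param dt Sampling interval in ms (> 0).
#' @param t0 Time of the first sample in ms.
#' @param units Unit string, `"mV"` or `"pA"`.
#' @param kind Free-text label (`"voltage"`, `"current"`, ...).
#' @param raw Logical; `TRUE` marks traces carrying recording noise, which
#'   makes the analysis functions apply their offline low-pass filters.
#' @param meta Optional named list of extra metadata.
#'
#' @return An object of class `ephys_trace`.
#' @export
ephys_trace <- function(values, dt, t0 = 0, units = c("mV", "pA"),
                        kind = "voltage", raw = FALSE, meta = list()) {
  units <- match.arg(units)
  stopifnot(is.numeric(values), length(values) >= 1)
  if (!is.finite(dt) || dt <= 0) stop("dt must be a positive number (ms)")
  if (anyNA(values)) stop("trace contains NA samples")
  structure(
    list(values = as.numeric(values), dt = dt, t0 = t0, units = units,
         kind = kind, raw = isTRUE(raw), meta = meta),
    class = "ephys_trace"
  )
}

#' @export
print.ephys_trace <- function(x, ...) {
  cat(sprintf("<ephys_trace> %s [%s], %d samples, dt = %g ms (%.6g kHz), %g..%g ms\n",
              x$kind, x$units, length(x$values), x$dt, 1 / x$dt,
              x$t0, x$t0 + (length(x$values) - 1) * x$dt))
  invisible(x)
}

#' @export
length.ephys_trace <- function(x) length(x$values)

#' Sample times of a trace
#' @param trace An [ephys_trace()].
#' @return Numeric vector of times in ms.
#' @export
trace_times <- function(trace) {
  trace$t0 + (seq_along(trace$values) - 1) * trace$dt
}

#' Extract a time window from a trace
#' @param trace An [ephys_trace()].
#' @param from,to Window bounds in ms (inclusive).
#' @return An [ephys_trace()] covering the window.
#' @export
trace_window <- function(trace, from, to) {
  tt <- trace_times(trace)
  idx <- which(tt >= from & tt <= to)
  if (length(idx) == 0) stop("window [", from, ", ", to, "] ms contains no samples")
  ephys_trace(trace$values[idx], trace$dt, t0 = tt[idx[1]], units = trace$units,
              kind = trace$kind, raw = trace$raw, meta = trace$meta)
}

#' Read a trace from a CSV file
#'
#' Expects a two-column `time,value` layout (time in ms) plus a mandatory
#' header comment line of the form `# units: mV` (or `pA`). Sampling must be
#' uniform. NWB/HDF5 containers are not supported by this build; export to
#' CSV first.
#'
#' @param path File path.
#' @param format Only `"csv"` is supported.
#' @return An [ephys_trace()].
#' @export
read_trace <- function(path, format = c("csv", "nwb", "hdf5")) {
  format <- match.arg(format)
  if (format != "csv")
    stop("format '", format, "' is not supported by this build; export the ",
         "series to CSV (time_ms,value with a '# units:' header line)")
  if (!file.exists(path)) stop("no such file: ", path)
  head_lines <- readLines(path, n = 10)
  unit_line <- grep("^#\\s*units\\s*:", head_lines, value = TRUE)
  if (length(unit_line) == 0)
    stop("trace file must declare units in a '# units: mV|pA' header line")
  units <- trimws(sub("^#\\s*units\\s*:", "", unit_line[1]))
  if (!units %in% c("mV", "pA")) stop("unsupported units '", units, "'")
  kind_line <- grep("^#\\s*kind\\s*:", head_lines, value = TRUE)
  kind <- if (length(kind_line)) trimws(sub("^#\\s*kind\\s*:", "", kind_line[1]))
          else if (units == "mV") "voltage" else "current"
  d <- utils::read.csv(path, comment.char = "#")
  if (ncol(d) < 2 || nrow(d) < 2) stop("malformed trace file: ", path)
  dts <- diff(d[[1]])
  if (diff(range(dts)) > 1e-6 * mean(dts)) stop("non-uniform sampling in ", path)
  ephys_trace(d[[2]], dt = mean(dts), t0 = d[[1]][1], units = units, kind = kind)
}

#' Write a trace to CSV
#' @param trace An [ephys_trace()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("# units:", trace$units), paste("# kind:", trace$kind)), con)
  utils::write.csv(data.frame(time_ms = trace_times(trace), value = trace$values),
                   con, row.names = FALSE)
  invisible(path)
}

#' Zero-phase Butterworth low-pass filter
#'
#' 4th-order Butterworth applied forward and backward
#' (via [signal::filtfilt()]), matching the offline filters used on raw
#' recordings (20 kHz for current-clamp, 14/6/2 kHz for Na+ activation,
#' Na+ inactivation and K+ voltage-clamp traces).
#'
#' @param trace An [ephys_trace()].
#' @param cutoff_khz Cutoff frequency in kHz.
#' @return Filtered [ephys_trace()] with `raw = FALSE`.
#' @export
lowpass_trace <- function(trace, cutoff_khz) {
  fs_khz <- 1 / trace$dt
  wn <- cutoff_khz / (fs_khz / 2)
  if (wn >= 1) return(trace) # already band-limited below the cutoff
  bf <- signal::butter(4, wn, type = "low")
  out <- signal::filtfilt(bf, trace$values)
  ephys_trace(out, trace$dt, trace$t0, trace$units, trace$kind,
              raw = FALSE, meta = trace$meta)
}
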