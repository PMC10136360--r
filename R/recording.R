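#' @keywords internal
new_recording <- function(time, pressure, flow, diameter, ppg = NULL,
                          sampling_rate, protocol,
                          beat_onsets = integer(0),
                          pause_segments = NULL,
                          vessel = NULL,
                          truth = NULL) {
  n <- length(time)
  stopifnot(length(pressure) == n, length(flow) == n, length(diameter) == n,
            is.null(ppg) || length(ppg) == n)
  structure(
    list(time = time, pressure = pressure, flow = flow, diameter = diameter,
         ppg = ppg, sampling_rate = sampling_rate, protocol = protocol,
         beat_onsets = beat_onsets, pause_segments = pause_segments,
         vessel = vessel, truth = truth),
    class = "hemodynamic_recording"
  )
}

#' Uniformly sampled hemodynamic recording
#'
#' Container for simultaneously recorded (or generated) time series: pressure
#' (mmHg), flow (mL/min), diameter (mm) and, optionally, PPG (a.u.), on one
#' uniform time grid. Pulsatile and intermittent recordings carry beat-onset
#' sample indices; intermittent recordings additionally carry the zero-flow
#' pause segments used by the biexponential decay fit.
#'
#' Construct recordings with the `generate_*()` protocol generators or load
#' them from CSV with [read_recording_csv()].
#'
#' @param x A `hemodynamic_recording`.
#' @param ... Unused.
#' @name hemodynamic_recording
NULL

#' @rdname hemodynamic_recording
#' @export
print.hemodynamic_recording <- function(x, ...) {
  cat(sprintf("<hemodynamic_recording> %s: %d samples @ %g Hz (%.1f s)%s\n",
              x$protocol, length(x$time), x$sampling_rate,
              length(x$time) / x$sampling_rate,
              if (!is.null(x$ppg)) ", with PPG" else ""))
  cat(sprintf("  pressure %.1f-%.1f mmHg, flow %.1f-%.1f mL/min\n",
              min(x$pressure), max(x$pressure), min(x$flow), max(x$flow)))
  if (length(x$beat_onsets)) cat(sprintf("  %d beat onsets\n", length(x$beat_onsets)))
  if (!is.null(x$pause_segments)) {
    cat(sprintf("  %d pause segments\n", nrow(x$pause_segments)))
  }
  invisible(x)
}

#' @rdname hemodynamic_recording
#' @param row.names,optional Passed on conventionally; unused.
#' @export
as.data.frame.hemodynamic_recording <- function(x, row.names = NULL,
                                                optional = FALSE, ...) {
  df <- data.frame(time_s = x$time, pressure_mmHg = x$pressure,
                   flow_mlmin = x$flow, diameter_mm = x$diameter)
  if (!is.null(x$ppg)) df$ppg_au <- x$ppg
  df
}

#' Write a recording to the package CSV dialect
#'
#' Header `time_s,pressure_mmHg,flow_mlmin,diameter_mm,ppg_au` (the PPG column
#' is omitted when absent), UTF-8, `.` decimal separator, one row per sample.
#'
#' @param recording A `hemodynamic_recording`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_recording_csv <- function(recording, path) {
  stopifnot(inherits(recording, "hemodynamic_recording"))
  utils::write.csv(as.data.frame(recording), path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a recording from the package CSV dialect
#'
#' @param path CSV file with columns `time_s,pressure_mmHg,flow_mlmin,
#'   diameter_mm` and optionally `ppg_au`.
#' @param protocol Protocol label to attach (`"unknown"` when unspecified).
#' @return A `hemodynamic_recording`. The sampling rate is inferred from the
#'   time grid, which must be uniform.
#' @export
read_recording_csv <- function(path, protocol = "unknown") {
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  need <- c("time_s", "pressure_mmHg", "flow_mlmin", "diameter_mm")
  if (!all(need %in% names(df))) {
    stop("CSV is missing required columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  dt <- diff(df$time_s)
  if (length(dt) < 1 || any(abs(dt - dt[1]) > 1e-6 * dt[1] + 1e-12)) {
    stop("time grid is not uniform")
  }
  new_recording(time = df$time_s, pressure = df$pressure_mmHg,
                flow = df$flow_mlmin, diameter = df$diameter_mm,
                ppg = if ("ppg_au" %in% names(df)) df$ppg_au else NULL,
                sampling_rate = 1 / dt[1], protocol = protocol)
}
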