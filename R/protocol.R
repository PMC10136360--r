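#' Specification of a synthetic mock-circulation protocol
#'
#' Describes one of the four in-vitro protocols emulated by the waveform
#' generator:
#'
#' * `"static_steps"`: pressure held at a series of plateaus with no flow;
#' * `"flow_sweep"`: flow stepped over a range at constant pressure
#'   (typically with a stiff segment);
#' * `"pulsatile"`: periodic beats of pressure and flow against a resistance;
#' * `"intermittent"`: isolated flow pulses separated by long zero-flow pauses
#'   at constant pressure, used to observe disorientation/aggregation decays.
#'
#' All random draws in the generators flow from `seed`; the same
#' (spec, vessel, seed) triple yields bit-identical recordings.
#'
#' @param protocol One of `"static_steps"`, `"flow_sweep"`, `"pulsatile"`,
#'   `"intermittent"`.
#' @param sampling_rate Sampling rate (Hz), default 1000.
#' @param seed Integer seed for the noise draws.
#' @param pressure_levels Plateau pressures (mmHg) for `static_steps`.
#' @param flow_levels Plateau flows (mL/min) for `flow_sweep`; must be
#'   non-negative (retrograde flow is not modelled).
#' @param level_duration Plateau duration (s); plateaus must be at least 4 s so
#'   the 4-s averaging convention used by the calibration fits applies.
#' @param ramp_duration Raised-cosine ramp between plateaus (s).
#' @param pressure_range Diastolic/systolic pressure (mmHg) for `pulsatile`.
#' @param flow_range Diastolic/systolic flow (mL/min) for `pulsatile`.
#' @param heart_rate Beats per minute for `pulsatile`.
#' @param n_beats Number of beats for `pulsatile`.
#' @param n_pulses Number of flow pulses for `intermittent`.
#' @param pulse_flow Plateau flow (mL/min) of each intermittent pulse.
#' @param pulse_rise Rise time (s) of each intermittent pulse.
#' @param pulse_hold Hold time (s) at plateau before the abrupt stop.
#' @param pause_duration Zero-flow pause between pulses (s), default 10.
#' @param hold_pressure Constant pressure (mmHg) for `flow_sweep` and
#'   `intermittent` (defaults to the vessel reference at generation time when
#'   `NULL`).
#' @param noise_sd Named list of per-channel additive Gaussian noise SDs in
#'   channel units: `pressure` (mmHg), `flow` (mL/min), `diameter` (mm),
#'   `ppg` (a.u.).
#'
#' @return An object of class `protocol_spec`.
#' @export
protocol_spec <- function(protocol = c("static_steps", "flow_sweep",
                                       "pulsatile", "intermittent"),
                          sampling_rate = 1000,
                          seed = 1L,
                          pressure_levels = NULL,
                          flow_levels = NULL,
                          level_duration = 6,
                          ramp_duration = 1,
                          pressure_range = c(80, 120),
                          flow_range = c(0, 600),
                          heart_rate = 60,
                          n_beats = 10,
                          n_pulses = 20,
                          pulse_flow = 600,
                          pulse_rise = 0.3,
                          pulse_hold = 2,
                          pause_duration = 10,
                          hold_pressure = NULL,
                          noise_sd = list(pressure = 0.5, flow = 2,
                                          diameter = 0.008, ppg = 5)) {
  protocol <- match.arg(protocol)
  stopifnot(sampling_rate > 0, level_duration > 0, ramp_duration >= 0)
  default_noise <- list(pressure = 0.5, flow = 2, diameter = 0.008, ppg = 5)
  noise_sd <- utils::modifyList(default_noise, as.list(noise_sd))
  if (any(unlist(noise_sd) < 0)) stop("noise_sd values must be >= 0")

  if (protocol == "static_steps") {
    if (is.null(pressure_levels) || length(pressure_levels) < 2) {
      stop("static_steps requires >= 2 pressure_levels")
    }
  }
  if (protocol == "flow_sweep") {
    if (is.null(flow_levels) || length(flow_levels) < 2) {
      stop("flow_sweep requires >= 2 flow_levels")
    }
    if (any(flow_levels < 0)) stop("negative flows not modelled (no retrograde flow)")
  }
  if (protocol == "pulsatile") {
    if (heart_rate <= 0) stop("heart_rate must be positive")
    if (diff(pressure_range) <= 0 || diff(flow_range) < 0) {
      stop("pressure_range/flow_range must be (low, high) with low < high")
    }
    if (any(flow_range < 0)) stop("negative flows not modelled")
    if (sampling_rate <= 2 * (4 * heart_rate / 60)) {
      stop("sampling_rate must exceed twice the highest generated harmonic")
    }
  }
  if (protocol == "intermittent") {
    if (pause_duration <= 0 || n_pulses < 1 || pulse_flow < 0) {
      stop("invalid intermittent-protocol parameters")
    }
  }

  structure(
    list(protocol = protocol, sampling_rate = sampling_rate, seed = as.integer(seed),
         pressure_levels = pressure_levels, flow_levels = flow_levels,
         level_duration = level_duration, ramp_duration = ramp_duration,
         pressure_range = pressure_range, flow_range = flow_range,
         heart_rate = heart_rate, n_beats = n_beats,
         n_pulses = n_pulses, pulse_flow = pulse_flow, pulse_rise = pulse_rise,
         pulse_hold = pulse_hold, pause_duration = pause_duration,
         hold_pressure = hold_pressure, noise_sd = noise_sd),
    class = "protocol_spec"
  )
}

#' @export
print.protocol_spec <- function(x, ...) {
  cat(sprintf("<protocol_spec> %s @ %g Hz, seed %d\n",
              x$protocol, x$sampling_rate, x$seed))
  invisible(x)
}

#' Read a protocol/vessel configuration from JSON or YAML
#'
#' The document mirrors the `protocol_spec()` / `vessel_model()` argument
#' names, under top-level keys `protocol_spec` and (optionally) `vessel_model`.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return A list with elements `spec` (a `protocol_spec`) and `vessel`
#'   (a `vessel_model`, defaults applied when absent).
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  doc <- switch(ext,
                json = jsonlite::read_json(path, simplifyVector = TRUE),
                yaml = ,
                yml  = yaml::read_yaml(path),
                stop("config must be .json, .yaml or .yml"))
  if (is.null(doc$protocol_spec)) stop("config missing 'protocol_spec' block")
  spec <- do.call(protocol_spec, doc$protocol_spec)
  vessel <- if (is.null(doc$vessel_model)) vessel_model() else {
    do.call(vessel_model, doc$vessel_model)
  }
  list(spec = spec, vessel = vessel)
}
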