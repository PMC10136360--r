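# Synthetic waveform generation for the four mock-circulation protocols.
# Waveforms are phenomenological templates (no Windkessel / wave propagation):
# smooth, band-limited well below the 50-Hz analysis filter.

# piecewise-constant levels joined by raised-cosine ramps; returns the signal
# and the plateau index ranges (pre-noise)
piecewise_levels <- function(levels, level_duration, ramp_duration, fs) {
  np <- round(level_duration * fs)
  nr <- round(ramp_duration * fs)
  out <- numeric(0)
  segs <- matrix(0L, nrow = length(levels), ncol = 2,
                 dimnames = list(NULL, c("start", "end")))
  for (i in seq_along(levels)) {
    if (i > 1 && nr > 0) {
      s <- seq_len(nr) / (nr + 1)
      ramp <- levels[i - 1] + (levels[i] - levels[i - 1]) * (1 - cos(pi * s)) / 2
      out <- c(out, ramp)
    }
    segs[i, 1] <- length(out) + 1L
    out <- c(out, rep(levels[i], np))
    segs[i, 2] <- length(out)
  }
  list(signal = out, segments = segs)
}

# additive iid Gaussian noise on each channel, all draws under one seed
apply_channel_noise <- function(spec, pressure, flow, diameter) {
  sd <- spec$noise_sd
  withr::with_seed(spec$seed, {
    list(pressure = pressure + stats::rnorm(length(pressure), 0, sd$pressure),
         flow     = flow     + stats::rnorm(length(flow), 0, sd$flow),
         diameter = diameter + stats::rnorm(length(diameter), 0, sd$diameter))
  })
}

#' Generate a static pressure-step recording
#'
#' Pressure is held at each requested plateau (raised-cosine ramps in
#' between), flow is identically zero before noise, and the diameter channel
#' follows the vessel's pressure--diameter law. Additive Gaussian noise is
#' applied per channel at the SDs in the protocol spec.
#'
#' @param spec A [protocol_spec()] with `protocol = "static_steps"`.
#' @param vessel A [vessel_model()].
#' @return A [hemodynamic_recording].
#' @export
generate_static_steps <- function(spec, vessel) {
  stopifnot(inherits(spec, "protocol_spec"), spec$protocol == "static_steps")
  fs <- spec$sampling_rate
  pw <- piecewise_levels(spec$pressure_levels, spec$level_duration,
                         spec$ramp_duration, fs)
  pressure0 <- pw$signal
  n <- length(pressure0)
  flow0 <- numeric(n)
  diameter0 <- pressure_to_diameter(pressure0, vessel)
  ch <- apply_channel_noise(spec, pressure0, flow0, diameter0)
  new_recording(time = (seq_len(n) - 1) / fs,
                pressure = ch$pressure, flow = ch$flow, diameter = ch$diameter,
                sampling_rate = fs, protocol = "static_steps", vessel = vessel,
                truth = list(pressure = pressure0, flow = flow0,
                             diameter = diameter0))
}

#' Generate a flow-sweep recording at constant pressure
#'
#' Flow is stepped through the requested plateaus (each held at least 4 s so
#' the plateau-averaging convention of the saturation fit applies) while
#' pressure stays at the hold level with noise only. A stiff vessel gives a
#' constant diameter channel, mirroring the rigid segment used to isolate the
#' flow pathway.
#'
#' @inheritParams generate_static_steps
#' @export
generate_flow_sweep <- function(spec, vessel) {
  stopifnot(inherits(spec, "protocol_spec"), spec$protocol == "flow_sweep")
  if (spec$level_duration < 4) {
    stop("flow plateaus must be held >= 4 s for the 4-s averaging convention")
  }
  fs <- spec$sampling_rate
  pw <- piecewise_levels(spec$flow_levels, spec$level_duration,
                         spec$ramp_duration, fs)
  flow0 <- pw$signal
  n <- length(flow0)
  p_hold <- if (is.null(spec$hold_pressure)) vessel$reference_pressure else spec$hold_pressure
  pressure0 <- rep(p_hold, n)
  diameter0 <- pressure_to_diameter(pressure0, vessel)
  ch <- apply_channel_noise(spec, pressure0, flow0, diameter0)
  new_recording(time = (seq_len(n) - 1) / fs,
                pressure = ch$pressure, flow = ch$flow, diameter = ch$diameter,
                sampling_rate = fs, protocol = "flow_sweep", vessel = vessel,
                truth = list(pressure = pressure0, flow = flow0,
                             diameter = diameter0))
}

# periodic beat templates -----------------------------------------------------

# truncated-Fourier pressure beat: fundamental + 3 harmonics with fixed
# phases, rotated so the beat starts at the diastolic minimum and min-max
# scaled to [0, 1]
pressure_beat_template <- function(n) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  raw <- sin(th) + 0.35 * sin(2 * th - 0.9) +
    0.15 * sin(3 * th - 1.8) + 0.06 * sin(4 * th - 2.7)
  k <- which.min(raw)
  raw <- raw[c(k:n, seq_len(k - 1))]
  (raw - min(raw)) / (max(raw) - min(raw))
}

# gamma-shaped systolic ejection, zero-based, peak scaled to 1
flow_beat_template <- function(n, peak_frac = 0.25, shape_k = 4) {
  s <- (seq_len(n) - 1) / n
  q <- (s / peak_frac)^shape_k * exp(shape_k * (1 - s / peak_frac))
  q / max(q)
}

#' Generate a pulsatile (flow-against-resistance) recording
#'
#' Periodic beats built from a truncated-Fourier pressure template (systolic
#' upstroke plus dicrotic decay) and a gamma-shaped systolic flow ejection
#' whose upstroke coincides with the pressure upstroke and which decays toward
#' the diastolic flow baseline. Per-beat diastolic/systolic extremes match the
#' requested ranges exactly before noise. Beat-onset indices are returned on
#' the recording.
#'
#' @inheritParams generate_static_steps
#' @export
generate_pulsatile <- function(spec, vessel) {
  stopifnot(inherits(spec, "protocol_spec"), spec$protocol == "pulsatile")
  fs <- spec$sampling_rate
  nbeat <- round(fs * 60 / spec$heart_rate)
  p_t <- pressure_beat_template(nbeat)
  q_t <- flow_beat_template(nbeat)
  pr <- spec$pressure_range
  qr <- spec$flow_range
  pressure0 <- rep(pr[1] + diff(pr) * p_t, spec$n_beats)
  flow0 <- rep(qr[1] + diff(qr) * q_t, spec$n_beats)
  n <- length(pressure0)
  diameter0 <- pressure_to_diameter(pressure0, vessel)
  ch <- apply_channel_noise(spec, pressure0, flow0, diameter0)
  new_recording(time = (seq_len(n) - 1) / fs,
                pressure = ch$pressure, flow = ch$flow, diameter = ch$diameter,
                sampling_rate = fs, protocol = "pulsatile",
                beat_onsets = 1L + (seq_len(spec$n_beats) - 1L) * nbeat,
                vessel = vessel,
                truth = list(pressure = pressure0, flow = flow0,
                             diameter = diameter0))
}

#' Generate an intermittent-flow recording
#'
#' Isolated flow pulses (raised-cosine rise, plateau hold, instantaneous stop
#' emulating the pump halt) separated by `pause_duration` seconds of exactly
#' zero flow at constant pressure. The pause index ranges are returned so the
#' biexponential decay fit can select the post-deceleration windows; the pause
#' decay observed through the forward model is exactly biexponential from the
#' first pause sample because the stop is abrupt.
#'
#' @inheritParams generate_static_steps
#' @export
generate_intermittent <- function(spec, vessel) {
  stopifnot(inherits(spec, "protocol_spec"), spec$protocol == "intermittent")
  fs <- spec$sampling_rate
  n_rise <- round(spec$pulse_rise * fs)
  n_hold <- round(spec$pulse_hold * fs)
  n_pause <- round(spec$pause_duration * fs)
  lead_in <- round(1 * fs)

  flow0 <- rep(0, lead_in)
  onsets <- integer(spec$n_pulses)
  pauses <- matrix(0L, nrow = spec$n_pulses, ncol = 2,
                   dimnames = list(NULL, c("start", "end")))
  rise <- spec$pulse_flow * (1 - cos(pi * seq_len(n_rise) / (n_rise + 1))) / 2
  for (i in seq_len(spec$n_pulses)) {
    onsets[i] <- length(flow0) + 1L
    flow0 <- c(flow0, rise, rep(spec$pulse_flow, n_hold))
    pauses[i, 1] <- length(flow0) + 1L
    flow0 <- c(flow0, rep(0, n_pause))
    pauses[i, 2] <- length(flow0)
  }
  n <- length(flow0)
  p_hold <- if (is.null(spec$hold_pressure)) vessel$reference_pressure else spec$hold_pressure
  pressure0 <- rep(p_hold, n)
  diameter0 <- pressure_to_diameter(pressure0, vessel)
  ch <- apply_channel_noise(spec, pressure0, flow0, diameter0)
  # the pump is off during pauses: flow is exactly zero there, not just in mean
  ch$flow[flow0 == 0] <- 0
  new_recording(time = (seq_len(n) - 1) / fs,
                pressure = ch$pressure, flow = ch$flow, diameter = ch$diameter,
                sampling_rate = fs, protocol = "intermittent",
                beat_onsets = onsets,
                pause_segments = as.data.frame(pauses), vessel = vessel,
                truth = list(pressure = pressure0, flow = flow0,
                             diameter = diameter0))
}
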