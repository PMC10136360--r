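# Shared fixtures: all inputs are built in code, under fixed seeds.

noiseless <- list(pressure = 0, flow = 0, diameter = 0, ppg = 0)

ref <- reference_constants()

# noiseless protocol recordings with forward-modelled PPG
make_static <- function(levels = seq(50, 200, length.out = 10), seed = 1,
                        noise = noiseless, constants = ref,
                        mode = "P_only", level_duration = 6) {
  spec <- protocol_spec("static_steps", seed = seed, pressure_levels = levels,
                        level_duration = level_duration, noise_sd = noise)
  simulate_recording(spec, constants$vessel, constants, with_ppg = TRUE,
                     mode = mode)
}

make_sweep <- function(levels = seq(0, 800, length.out = 12), seed = 1,
                       noise = noiseless, constants = ref) {
  spec <- protocol_spec("flow_sweep", seed = seed, flow_levels = levels,
                        level_duration = 5, noise_sd = noise)
  simulate_recording(spec, vessel_model(is_stiff = TRUE), constants,
                     with_ppg = TRUE)
}

make_intermittent <- function(n_pulses = 3, seed = 1, noise = noiseless,
                              constants = ref, pause_duration = 10) {
  spec <- protocol_spec("intermittent", seed = seed, n_pulses = n_pulses,
                        pulse_flow = 600, pulse_hold = 2,
                        pause_duration = pause_duration, noise_sd = noise)
  simulate_recording(spec, constants$vessel, constants, with_ppg = TRUE)
}

# brute-force reference for the flow-pathway dynamics: each component is the
# strongest surviving decayed drive, evaluated by direct search over all
# earlier samples (O(n^2))
brute_eq_flow <- function(flow, params, fs) {
  u <- eq_high(flow, params)
  r <- params$nd_na_ratio
  wd <- r / (r + 1)
  wa <- 1 / (r + 1)
  n <- length(u)
  pow_d <- exp(-(0:(n - 1)) / (fs * params$tau_d))
  pow_a <- exp(-(0:(n - 1)) / (fs * params$tau_a))
  y <- numeric(n)
  for (k in seq_len(n)) {
    j <- seq_len(k)
    y[k] <- wd * max(u[j] * pow_d[k - j + 1]) + wa * max(u[j] * pow_a[k - j + 1])
  }
  y
}
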