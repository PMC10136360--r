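# The forward optical model: constant background irradiance, a blood-volume
# (pressure) pathway, and a blood-flow pathway with red-blood-cell
# orientation/aggregation kinetics, followed by the receiver response.

#' Photodetector response model
#'
#' The receiver follows a power law `V = c * E^d` (phototransistor in common
#' collector configuration); `d = 1.3` for the probe used throughout. The
#' wavelength is metadata only: the model is single-wavelength.
#'
#' @param response_coefficient_c Gain (a.u. per irradiance^d).
#' @param response_exponent_d Dimensionless exponent, `> 0`.
#' @param wavelength Probe wavelength (nm), recorded but not used.
#' @param dc_offset Additive offset (a.u.).
#' @return An object of class `sensor_model`.
#' @export
sensor_model <- function(response_coefficient_c = 1,
                         response_exponent_d = 1.3,
                         wavelength = 830,
                         dc_offset = 0) {
  if (response_exponent_d <= 0) stop("response_exponent_d must be > 0")
  structure(list(response_coefficient_c = response_coefficient_c,
                 response_exponent_d = response_exponent_d,
                 wavelength = wavelength, dc_offset = dc_offset),
            class = "sensor_model")
}

#' Volume-pathway (pressure) optical constants
#'
#' In the linearised form the volume-related irradiance is `E_V = a' + b' * P`
#' with `b' > 0` under the PPG sign convention (pressure up, PPG up). The
#' optional full-form constants parameterise the diffusion-approximation
#' expression `E0 * exp(-mu_a z) * cosh(z * sqrt(2 mu_a mu_s'))` evaluated at
#' `z = D(P)`; see [ev_diffusion()].
#'
#' @param intercept_a Intercept a' (a.u.).
#' @param slope_b Slope b' (a.u./mmHg), `> 0`; the fitted value on the static
#'   pressure-step data is 2.15 a.u./mmHg.
#' @param incident_irradiance_E0,absorption_mu_a,reduced_scattering_mu_s_prime
#'   Optional full-form constants (irradiance; 1/mm; 1/mm).
#' @return An object of class `pressure_optics`.
#' @export
pressure_optics <- function(intercept_a = 0,
                            slope_b = 2.15,
                            incident_irradiance_E0 = NULL,
                            absorption_mu_a = NULL,
                            reduced_scattering_mu_s_prime = NULL) {
  if (slope_b <= 0) stop("slope_b must be positive under the sign convention")
  structure(list(intercept_a = intercept_a, slope_b = slope_b,
                 incident_irradiance_E0 = incident_irradiance_E0,
                 absorption_mu_a = absorption_mu_a,
                 reduced_scattering_mu_s_prime = reduced_scattering_mu_s_prime),
            class = "pressure_optics")
}

#' Flow-pathway optical and kinetic constants
#'
#' `m_prime` and `Q_c` parameterise the saturating orientation law
#' `E_Q,H = m' (Q/Q_c) / (1 + Q/Q_c)`; `tau_d` and `tau_a` are the
#' disorientation and aggregation decay constants engaged after flow
#' deceleration, and `nd_na_ratio` the relative amplitude of the two decay
#' components (only the ratio is identifiable, as the kernel is normalised).
#' `alignment_m` and `gamma_c` carry the equivalent shear-domain law for use
#' with the Poiseuille conversion [wall_shear_rate()].
#'
#' @param m_prime Saturation amplitude (a.u.), `>= 0`.
#' @param Q_c Critical (half-saturation) flow rate (mL/min), `> 0`.
#' @param tau_d Disorientation time constant (s), `> 0`.
#' @param tau_a Aggregation time constant (s), `> 0`.
#' @param nd_na_ratio Disorientation-to-aggregation amplitude ratio, `> 0`.
#' @param alignment_m,gamma_c Optional shear-domain constants (dimensionless;
#'   1/s).
#' @param decel_flow_fraction Low-shear flow threshold as a fraction of `Q_c`
#'   used by the regime classifier.
#' @param kernel_horizon Truncation horizon (s) of the sampled decay kernel;
#'   must be at least `5 * max(tau_d, tau_a)` (default `8 *`).
#' @return An object of class `flow_optics`.
#' @export
flow_optics <- function(m_prime = 1613,
                        Q_c = 328,
                        tau_d = 0.39,
                        tau_a = 1.78,
                        nd_na_ratio = 2.2,
                        alignment_m = NULL,
                        gamma_c = NULL,
                        decel_flow_fraction = 0.5,
                        kernel_horizon = 8 * max(tau_d, tau_a)) {
  if (m_prime < 0 || Q_c <= 0 || tau_d <= 0 || tau_a <= 0 || nd_na_ratio <= 0) {
    stop("invalid flow_optics constants")
  }
  if (kernel_horizon < 5 * max(tau_d, tau_a)) {
    stop("kernel_horizon must be >= 5 * max(tau_d, tau_a)")
  }
  structure(list(m_prime = m_prime, Q_c = Q_c, tau_d = tau_d, tau_a = tau_a,
                 nd_na_ratio = nd_na_ratio, alignment_m = alignment_m,
                 gamma_c = gamma_c, decel_flow_fraction = decel_flow_fraction,
                 kernel_horizon = kernel_horizon),
            class = "flow_optics")
}

# volume pathway ---------------------------------------------------------------

#' Linearised volume-pathway irradiance
#'
#' Elementwise `a' + b' * P`: the linear approximation of the
#' diffusion-equation expression around the reference state, valid for the
#' small diameter excursions of a radial artery over the cardiac cycle.
#'
#' @param pressure Pressure series (mmHg), finite.
#' @param params A [pressure_optics()].
#' @return Irradiance series (a.u.), same length.
#' @export
ev_from_pressure <- function(pressure, params) {
  stopifnot(inherits(params, "pressure_optics"))
  if (any(!is.finite(pressure))) stop("pressure contains non-finite values")
  params$intercept_a + params$slope_b * pressure
}

#' Full diffusion-approximation volume-pathway irradiance
#'
#' Evaluates `E0 * exp(-mu_a * z) * cosh(z * sqrt(2 * mu_a * mu_s'))` with the
#' optical path `z` taken as the pressure-dependent diameter `D(P)`. This is
#' the nonlinear alternative to [ev_from_pressure()]; around the reference
#' pressure the two agree to first order when the linear constants are derived
#' from the same optical constants (see [linearize_diffusion()]).
#'
#' @inheritParams ev_from_pressure
#' @param vessel A [vessel_model()] providing `D(P)`.
#' @export
ev_diffusion <- function(pressure, params, vessel) {
  stopifnot(inherits(params, "pressure_optics"), inherits(vessel, "vessel_model"))
  if (is.null(params$incident_irradiance_E0) || is.null(params$absorption_mu_a) ||
      is.null(params$reduced_scattering_mu_s_prime)) {
    stop("full-form optical constants missing; use ev_from_pressure() for the ",
         "linearised model")
  }
  z <- pressure_to_diameter(pressure, vessel)
  E0 <- params$incident_irradiance_E0
  mua <- params$absorption_mu_a
  musp <- params$reduced_scattering_mu_s_prime
  E0 * exp(-mua * z) * cosh(z * sqrt(2 * mua * musp))
}

#' First-order linearisation of the diffusion form at the reference pressure
#'
#' @inheritParams ev_diffusion
#' @return A list with `intercept_a` and `slope_b` such that
#'   `intercept_a + slope_b * P` is tangent to [ev_diffusion()] at the vessel's
#'   reference pressure.
#' @export
linearize_diffusion <- function(params, vessel) {
  p0 <- vessel$reference_pressure
  f0 <- ev_diffusion(p0, params, vessel)
  z0 <- pressure_to_diameter(p0, vessel)
  mua <- params$absorption_mu_a
  musp <- params$reduced_scattering_mu_s_prime
  kappa <- sqrt(2 * mua * musp)
  # dE/dz analytically, dz/dP = b
  dEdz <- params$incident_irradiance_E0 * exp(-mua * z0) *
    (-mua * cosh(kappa * z0) + kappa * sinh(kappa * z0))
  slope <- dEdz * vessel$pd_slope_b
  list(intercept_a = f0 - slope * p0, slope_b = slope)
}

# flow pathway -----------------------------------------------------------------

#' Fraction of shear-aligned red blood cells
#'
#' The saturating alignment law in the shear domain:
#' `p* = m * (g/g_c) / (1 + g/g_c)` for shear rate `g`. Bounded in `[0, m)`
#' and strictly increasing; half-saturates at the critical shear rate.
#'
#' @param shear_rate Shear rate series (1/s), `>= 0`.
#' @param m Saturation amplitude (dimensionless).
#' @param gamma_c Critical shear rate (1/s), `> 0`.
#' @export
aligned_fraction <- function(shear_rate, m, gamma_c) {
  if (gamma_c <= 0) stop("gamma_c must be positive")
  if (any(shear_rate < 0)) stop("negative shear rates are not admissible")
  x <- shear_rate / gamma_c
  m * x / (1 + x)
}

#' High-shear flow-pathway irradiance
#'
#' The flow-domain form of the alignment law for developed flow in a vessel of
#' nearly constant diameter: `E_Q,H = m' * (Q/Q_c) / (1 + Q/Q_c)`.
#'
#' @param flow Flow series (mL/min), `>= 0`.
#' @param params A [flow_optics()].
#' @export
eq_high <- function(flow, params) {
  stopifnot(inherits(params, "flow_optics"))
  if (any(flow < 0)) stop("negative flows are not admissible")
  x <- flow / params$Q_c
  params$m_prime * x / (1 + x)
}

#' Sampled biexponential decay kernel
#'
#' Causal kernel `h[k] = r * exp(-t_k/tau_d) + exp(-t_k/tau_a)` with
#' `r = nd_na_ratio`, truncated at `kernel_horizon` and normalised so its
#' discrete time-integral `sum(h) * dt` equals one. Only the component ratio
#' matters for the relaxation shape, which is `h(t) / h(0)`.
#'
#' @param params A [flow_optics()].
#' @param dt Sampling interval (s), `> 0`.
#' @return Numeric kernel vector.
#' @export
decay_kernel <- function(params, dt) {
  stopifnot(inherits(params, "flow_optics"), dt > 0)
  if (params$kernel_horizon < 5 * max(params$tau_d, params$tau_a)) {
    stop("kernel_horizon too short: need >= 5 * max(tau_d, tau_a)")
  }
  tk <- seq(0, params$kernel_horizon, by = dt)
  r <- params$nd_na_ratio
  h <- r * exp(-tk / params$tau_d) + exp(-tk / params$tau_a)
  h / (sum(h) * dt)
}

# normalised relaxation shape g(dt_vec) = (r e^{-t/tau_d} + e^{-t/tau_a})/(r+1)
relaxation_shape <- function(t, params) {
  r <- params$nd_na_ratio
  (r * exp(-t / params$tau_d) + exp(-t / params$tau_a)) / (r + 1)
}

#' Classify per-sample shear regimes
#'
#' Labels each sample `"high_shear"` or `"low_shear"`. Low shear requires a
#' negative smoothed flow derivative (50-ms moving-average window) together
#' with flow below `decel_flow_fraction * Q_c`, or near-zero flow; a 20-ms
#' hysteresis suppresses label chattering within a beat.
#'
#' @param flow Flow series (mL/min) on a uniform grid.
#' @param params A [flow_optics()].
#' @param fs Sampling rate (Hz).
#' @return Character vector of labels, one per sample.
#' @export
classify_regimes <- function(flow, params, fs) {
  stopifnot(inherits(params, "flow_optics"), fs > 0)
  n <- length(flow)
  w <- max(1L, round(0.05 * fs))
  sm <- stats::filter(flow, rep(1 / w, w), sides = 2)
  sm[is.na(sm)] <- flow[is.na(sm)]
  dq <- c(0, diff(as.numeric(sm))) * fs
  low <- (dq < 0 & flow < params$decel_flow_fraction * params$Q_c) |
    flow <= 1e-9 * params$Q_c
  # hysteresis: a state change must persist >= 20 ms to take effect
  hold <- max(1L, round(0.02 * fs))
  lab <- logical(n)
  lab[1] <- low[1]
  run <- 0L
  for (k in 2:n) {
    if (low[k] != lab[k - 1]) run <- run + 1L else run <- 0L
    if (run >= hold) {
      lab[k] <- low[k]
      run <- 0L
    } else {
      lab[k] <- lab[k - 1]
    }
  }
  ifelse(lab, "low_shear", "high_shear")
}

#' Flow-pathway irradiance along a recording
#'
#' Tracks the two reflectance components of the flow pathway through time.
#' Orientation (weight `r/(r+1)`, release constant `tau_d`) and aggregation
#' (weight `1/(r+1)`, release constant `tau_a`) each follow the saturating
#' drive `eq_high(Q)` instantaneously while the drive exceeds their decayed
#' state (orientation under shear is effectively immediate) and relax
#' exponentially with their own time constant when the drive falls. For an
#' abrupt stop from flow `Q0` the result is exactly the normalised
#' biexponential relaxation
#' `E_Q(t) = eq_high(Q0) * (r e^{-t/tau_d} + e^{-t/tau_a}) / (r + 1)`, and for
#' steady or accelerating flow it reduces to `eq_high(Q)`. The output is
#' continuous at regime boundaries by construction.
#'
#' @param flow Flow series (mL/min), `>= 0`, uniform grid.
#' @param params A [flow_optics()].
#' @param fs Sampling rate (Hz).
#' @return A list with `irradiance` (a.u.) and `regimes` (labels from
#'   [classify_regimes()]).
#' @export
eq_flow_series <- function(flow, params, fs) {
  stopifnot(inherits(params, "flow_optics"), fs > 0)
  if (any(flow < 0)) stop("negative flows are not admissible")
  u <- eq_high(flow, params)
  r <- params$nd_na_ratio
  wd <- r / (r + 1)
  wa <- 1 / (r + 1)
  ld <- exp(-1 / (fs * params$tau_d))
  la <- exp(-1 / (fs * params$tau_a))
  n <- length(u)
  sd_ <- numeric(n)
  sa_ <- numeric(n)
  sd_[1] <- wd * u[1]
  sa_[1] <- wa * u[1]
  for (k in 2:n) {
    sd_[k] <- max(sd_[k - 1] * ld, wd * u[k])
    sa_[k] <- max(sa_[k - 1] * la, wa * u[k])
  }
  list(irradiance = sd_ + sa_,
       regimes = classify_regimes(flow, params, fs))
}

# composition ------------------------------------------------------------------

#' Compose the three irradiance contributions
#'
#' Total irradiance is `E = E_DC + E_V + E_Q`; the components are retained for
#' inspection.
#'
#' @param E_DC Constant background irradiance (length-1 numeric).
#' @param E_V Volume-pathway irradiance series.
#' @param E_Q Flow-pathway irradiance series (same length as `E_V`).
#' @return A list of class `irradiance_components` with `E_DC`, `E_V`, `E_Q`
#'   and `total`.
#' @export
compose_irradiance <- function(E_DC, E_V, E_Q) {
  stopifnot(length(E_DC) == 1L)
  if (length(E_V) != length(E_Q)) stop("E_V and E_Q must have equal length")
  structure(list(E_DC = E_DC, E_V = E_V, E_Q = E_Q,
                 total = E_DC + E_V + E_Q),
            class = "irradiance_components")
}

#' Receiver response
#'
#' Power-law mode (default) returns `c * E^d + dc_offset`; linearised mode
#' returns the first-order expansion around the series mean, valid for the
#' small irradiance fluctuations expected in rPPG.
#'
#' @param E Irradiance series, `> 0` (required for non-integer exponents).
#' @param sensor A [sensor_model()].
#' @param mode `"power"` or `"linear"`.
#' @return PPG series (a.u.).
#' @export
sensor_response <- function(E, sensor, mode = c("power", "linear")) {
  stopifnot(inherits(sensor, "sensor_model"))
  mode <- match.arg(mode)
  d <- sensor$response_exponent_d
  if (any(E <= 0) && d != round(d)) {
    stop("non-positive irradiance with non-integer exponent")
  }
  cc <- sensor$response_coefficient_c
  if (mode == "power") {
    return(cc * E^d + sensor$dc_offset)
  }
  Em <- mean(E)
  cc * Em^d + cc * d * Em^(d - 1) * (E - Em) + sensor$dc_offset
}

#' Predict the rPPG signal from a hemodynamic recording
#'
#' Applies the calibrated model under the standard sign convention (a pressure
#' rise increases PPG, i.e. reduces reflected light), in PPG units:
#' `PPG = a' + b' * P - E_Q(Q)`. The flow term enters with negative sign
#' because red-blood-cell orientation increases the reflected light, which the
#' convention inverts. Mode `"P_only"` zeroes the flow term (the
#' volume-only hypothesis); mode `"P_and_Q"` uses both pathways. Output is
#' uncalibrated (a.u.); when `reference` is supplied the series mean is
#' shifted to match its mean.
#'
#' @param recording A [hemodynamic_recording].
#' @param pressure_params A [pressure_optics()].
#' @param flow_params A [flow_optics()]; required in `"P_and_Q"` mode.
#' @param mode `"P_and_Q"` (default) or `"P_only"`.
#' @param sensor Optional [sensor_model()]; when supplied, the composed signal
#'   (offset by the sensor `dc_offset`) is passed through the receiver power
#'   law. The default `NULL` returns the signal in the a.u. scale in which the
#'   constants were fitted.
#' @param reference Optional series whose mean the output is shifted to match.
#' @return Numeric PPG series (a.u.).
#' @export
predict_ppg <- function(recording, pressure_params, flow_params = NULL,
                        mode = c("P_and_Q", "P_only"), sensor = NULL,
                        reference = NULL) {
  stopifnot(inherits(recording, "hemodynamic_recording"),
            inherits(pressure_params, "pressure_optics"))
  mode <- match.arg(mode)
  out <- ev_from_pressure(recording$pressure, pressure_params)
  if (mode == "P_and_Q") {
    if (is.null(flow_params)) stop("flow_params required in P_and_Q mode")
    if (is.null(recording$flow)) stop("recording has no flow channel")
    eq <- eq_flow_series(pmax(recording$flow, 0), flow_params,
                         recording$sampling_rate)
    out <- out - eq$irradiance
  }
  if (!is.null(sensor)) {
    out <- sensor_response(out + sensor$dc_offset, sensor)
  }
  if (!is.null(reference)) {
    out <- out - mean(out) + mean(reference)
  }
  out
}
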