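#' Arterial segment model with a linear pressure--diameter law
#'
#' Describes the silicone artery-model geometry and its linearised elastic
#' behaviour: around a reference state the lumen diameter varies linearly with
#' intraluminal pressure, `D(P) = D_ref + b * (P - P_ref)`. A stiff segment
#' (`is_stiff = TRUE`) has an effective slope of zero and keeps its reference
#' diameter at every pressure.
#'
#' @param reference_diameter Lumen diameter (mm) at `reference_pressure`.
#'   The default 4.0 mm is back-calculated from the Poiseuille wall-shear
#'   relation linking the fitted critical flow rate (328 mL/min) to the
#'   critical shear rate (870 s^-1); see `wall_shear_rate()`.
#' @param reference_pressure Pressure (mmHg) of the reference state.
#' @param pd_slope_b Pressure--diameter slope (mm/mmHg), `>= 0`.
#' @param is_stiff Logical; `TRUE` models the rigid segment used to isolate
#'   flow effects (effective slope 0).
#' @param length_segment Segment length (mm); metadata used only for shear-rate
#'   conversions, never for the optics.
#'
#' @return An object of class `vessel_model`.
#' @examples
#' v <- vessel_model()
#' pressure_to_diameter(c(80, 100, 120), v)
#' @export
vessel_model <- function(reference_diameter = 4.0,
                         reference_pressure = 100,
                         pd_slope_b = 1.245e-3,
                         is_stiff = FALSE,
                         length_segment = 50) {
  stopifnot(is.numeric(reference_diameter), length(reference_diameter) == 1L,
            is.numeric(reference_pressure), length(reference_pressure) == 1L,
            is.numeric(pd_slope_b), length(pd_slope_b) == 1L,
            is.logical(is_stiff), length(is_stiff) == 1L)
  if (reference_diameter <= 0) stop("reference_diameter must be positive")
  if (pd_slope_b < 0) stop("pd_slope_b must be >= 0")
  structure(
    list(reference_diameter = reference_diameter,
         reference_pressure = reference_pressure,
         pd_slope_b = if (is_stiff) 0 else pd_slope_b,
         is_stiff = is_stiff,
         length_segment = length_segment),
    class = "vessel_model"
  )
}

#' @export
print.vessel_model <- function(x, ...) {
  cat(sprintf("<vessel_model> D_ref = %.3f mm at %.0f mmHg, b = %.4g mm/mmHg%s\n",
              x$reference_diameter, x$reference_pressure, x$pd_slope_b,
              if (x$is_stiff) " (stiff)" else ""))
  invisible(x)
}

#' Map intraluminal pressure to lumen diameter
#'
#' Applies the linearised wall law `D = D_ref + b * (P - P_ref)`. Stiff
#' segments return the reference diameter for every pressure. Pressures
#' outside the 50--200 mmHg range over which the linearisation was established
#' trigger a warning; a non-positive resulting diameter is an error.
#'
#' @param pressure Numeric vector of pressures (mmHg).
#' @param vessel A [vessel_model()].
#' @return Numeric vector of diameters (mm), same length as `pressure`.
#' @export
pressure_to_diameter <- function(pressure, vessel) {
  stopifnot(inherits(vessel, "vessel_model"), is.numeric(pressure))
  if (any(!is.finite(pressure))) stop("pressure contains non-finite values")
  if (any(pressure < 50 | pressure > 200)) {
    warning("pressures outside the supported 50-200 mmHg linearisation range")
  }
  if (vessel$is_stiff) {
    return(rep(vessel$reference_diameter, length(pressure)))
  }
  d <- vessel$reference_diameter +
    vessel$pd_slope_b * (pressure - vessel$reference_pressure)
  if (any(d <= 0)) stop("pressure_to_diameter: non-positive diameter")
  d
}
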