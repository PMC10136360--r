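#' Fitted model constants bundled with the package
#'
#' Loads the set of calibrated constants obtained on the in-vitro mock
#' circulation: pressure-pathway slope 2.15 a.u./mmHg, flow-pathway saturation
#' m' = 1613 a.u. and critical flow Q_c = 328 mL/min, decay constants
#' tau_d = 0.39 s and tau_a = 1.78 s with amplitude ratio 2.2 for whole
#' (control) blood and 3.6 for Poloxamer-treated blood, receiver exponent
#' d = 1.3, and the wall slope b = 1.245e-3 mm/mmHg.
#'
#' @param blood `"control"` or `"poloxamer"`; selects the
#'   disorientation-to-aggregation amplitude ratio.
#' @param path Path to a constants JSON document mirroring the parameter-type
#'   field names (defaults to the bundled file).
#' @return A list with elements `pressure` ([pressure_optics()]), `flow`
#'   ([flow_optics()]), `sensor` ([sensor_model()]), `vessel`
#'   ([vessel_model()]) and `raw` (the parsed document).
#' @examples
#' k <- reference_constants()
#' eq_high(k$flow$Q_c, k$flow)  # half-saturation: m'/2
#' @export
reference_constants <- function(blood = c("control", "poloxamer"),
                                path = system.file("extdata",
                                                   "reference_constants.json",
                                                   package = "rppgmodel")) {
  blood <- match.arg(blood)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  fo <- doc$flow_optics
  if (blood == "poloxamer") fo$nd_na_ratio <- doc$poloxamer_nd_na_ratio
  list(pressure = do.call(pressure_optics, doc$pressure_optics),
       flow = do.call(flow_optics, fo),
       sensor = do.call(sensor_model, doc$sensor_model),
       vessel = do.call(vessel_model, doc$vessel_model),
       raw = doc)
}

#' Effect of an aggregation inhibitor on the decay amplitude ratio
#'
#' Pure arithmetic on two disorientation-to-aggregation amplitude ratios:
#' the relative increase of the ratio, and the implied reduction of the
#' aggregation amplitude at fixed disorientation amplitude
#' (`1 - r_control / r_treated`).
#'
#' @param r_control Amplitude ratio of untreated blood.
#' @param r_treated Amplitude ratio of treated blood.
#' @return A list with `ratio_increase_pct` and `aggregation_reduction_pct`.
#' @examples
#' poloxamer_contrast(2.2, 3.6)
#' @export
poloxamer_contrast <- function(r_control, r_treated) {
  stopifnot(r_control > 0, r_treated > 0)
  list(ratio_increase_pct = 100 * (r_treated - r_control) / r_control,
       aggregation_reduction_pct = 100 * (1 - r_control / r_treated))
}
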