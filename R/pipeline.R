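# End-to-end orchestration: simulate a protocol (optionally with
# forward-modelled PPG), dispatch calibration by protocol label, and the full
# synthetic reproduction of the study's quantitative results.

# deterministic child seeds spawned from one master seed (all < 2^31)
child_seeds <- function(master, n) {
  withr::with_seed(as.integer(master), sample.int(.Machine$integer.max, n))
}

#' Simulate a protocol recording, optionally with forward-modelled PPG
#'
#' Generates the recording for `spec`'s protocol, optionally runs the forward
#' model to attach a noisy PPG channel, and optionally writes the recording
#' (CSV dialect) together with a provenance sidecar (JSON with package
#' version, seed and the full configuration). The same `spec` and seed give a
#' byte-identical CSV.
#'
#' @param spec A [protocol_spec()].
#' @param vessel A [vessel_model()].
#' @param constants Model constants as returned by [reference_constants()];
#'   required when `with_ppg = TRUE`.
#' @param with_ppg Attach `predict_ppg()` output plus Gaussian noise at the
#'   spec's `ppg` noise SD.
#' @param mode Forward-model mode, `"P_and_Q"` or `"P_only"`.
#' @param out_csv Optional output CSV path (must not already exist as an input:
#'   outputs never overwrite inputs).
#' @param meta_json Optional sidecar path.
#' @return The [hemodynamic_recording], invisibly when written to file.
#' @export
simulate_recording <- function(spec, vessel = vessel_model(), constants = NULL,
                               with_ppg = FALSE, mode = "P_and_Q",
                               out_csv = NULL, meta_json = NULL) {
  stopifnot(inherits(spec, "protocol_spec"))
  rec <- switch(spec$protocol,
                static_steps = generate_static_steps(spec, vessel),
                flow_sweep = generate_flow_sweep(spec, vessel),
                pulsatile = generate_pulsatile(spec, vessel),
                intermittent = generate_intermittent(spec, vessel))
  if (with_ppg) {
    if (is.null(constants)) {
      stop("with_ppg = TRUE requires 'constants' (see reference_constants())")
    }
    # forward-model from the noiseless channels: the physical signal responds
    # to the true pressure and flow, measurement noise lives on the recorded
    # channels only
    rec_true <- rec
    rec_true$pressure <- rec$truth$pressure
    rec_true$flow <- rec$truth$flow
    rec_true$diameter <- rec$truth$diameter
    ppg0 <- predict_ppg(rec_true, constants$pressure, constants$flow,
                        mode = mode)
    noise_seed <- child_seeds(spec$seed, 2)[2]
    rec$ppg <- ppg0 + withr::with_seed(noise_seed, {
      stats::rnorm(length(ppg0), 0, spec$noise_sd$ppg)
    })
  }
  if (!is.null(out_csv)) {
    write_recording_csv(rec, out_csv)
    if (!is.null(meta_json)) {
      meta <- list(package = "rppgmodel",
                   version = as.character(utils::packageVersion("rppgmodel")),
                   seed = spec$seed, protocol = spec$protocol,
                   mode = if (with_ppg) mode else NULL,
                   config = spec[setdiff(names(spec), NULL)],
                   vessel = unclass(vessel))
      jsonlite::write_json(meta, meta_json, auto_unbox = TRUE, digits = NA,
                           null = "null")
    }
    return(invisible(rec))
  }
  rec
}

#' Calibrate a recording according to its protocol
#'
#' Dispatches to the fit matching the recording's protocol label: static
#' steps to [fit_pressure_slope()], flow sweeps to [fit_flow_saturation()]
#' (with a dispersion warning for elastic vessels, whose small diameter
#' changes at high flow inflate the scatter), intermittent recordings to
#' [fit_biexponential()].
#'
#' @param recording A [hemodynamic_recording] with a PPG channel.
#' @return A `ppg_fit`.
#' @export
calibrate_recording <- function(recording) {
  stopifnot(inherits(recording, "hemodynamic_recording"))
  switch(recording$protocol,
         static_steps = fit_pressure_slope(recording),
         flow_sweep = {
           if (!is.null(recording$vessel) && !recording$vessel$is_stiff) {
             warning("elastic vessel: expect higher dispersion from diameter ",
                     "changes at high flow; a stiff segment is preferred")
           }
           fit_flow_saturation(recording)
         },
         intermittent = fit_biexponential(recording),
         stop("no calibration fit is defined for protocol '",
              recording$protocol, "'"))
}

# scenario pieces used by reproduce_study -------------------------------------

mc_static_slope <- function(constants, seeds) {
  vapply(seeds, function(s) {
    spec <- protocol_spec("static_steps", seed = s,
                          pressure_levels = seq(50, 200, length.out = 10),
                          level_duration = 6)
    rec <- simulate_recording(spec, constants$vessel, constants,
                              with_ppg = TRUE, mode = "P_only")
    unname(fit_pressure_slope(rec)$estimates["slope_b"])
  }, numeric(1))
}

mc_flow_saturation <- function(constants, seeds) {
  stiff <- vessel_model(is_stiff = TRUE)
  out <- vapply(seeds, function(s) {
    spec <- protocol_spec("flow_sweep", seed = s,
                          flow_levels = seq(0, 800, length.out = 12),
                          level_duration = 5)
    rec <- simulate_recording(spec, stiff, constants, with_ppg = TRUE)
    f <- fit_flow_saturation(rec)
    c(f$estimates["m_prime"], f$estimates["Q_c"])
  }, numeric(2))
  list(m_prime = out[1, ], Q_c = out[2, ])
}

intermittent_batch <- function(constants, seed, n_pulses) {
  spec <- protocol_spec("intermittent", seed = seed, n_pulses = n_pulses,
                        pulse_flow = 600, pulse_hold = 2, pause_duration = 10)
  rec <- simulate_recording(spec, constants$vessel, constants, with_ppg = TRUE)
  fit_biexponential(rec)
}

mc_wall_slope <- function(constants, seeds, duration = 20, fs = 1000,
                          sd_diameter = 0.008) {
  vapply(seeds, function(s) {
    p <- seq(50, 200, length.out = duration * fs)
    d0 <- pressure_to_diameter(p, constants$vessel)
    d <- d0 + withr::with_seed(s, stats::rnorm(length(d0), 0, sd_diameter))
    unname(fit_pressure_diameter(p, d)$estimates["slope_b"])
  }, numeric(1))
}

counterphase_demo <- function(constants, systolic_low = TRUE) {
  pr <- if (systolic_low) c(75, 92) else c(100, 160)
  spec <- protocol_spec("pulsatile", seed = 1L, pressure_range = pr,
                        flow_range = c(300, 420), heart_rate = 60, n_beats = 8,
                        noise_sd = list(pressure = 0, flow = 0,
                                        diameter = 0, ppg = 0))
  rec <- generate_pulsatile(spec, constants$vessel)
  ppg <- predict_ppg(rec, constants$pressure, constants$flow)
  beat_phase(ppg, rec$pressure, rec$beat_onsets, rec$sampling_rate)
}

prediction_comparison <- function(constants, seed, n_beats = 12) {
  spec <- protocol_spec("pulsatile", seed = seed, pressure_range = c(80, 120),
                        flow_range = c(0, 600), heart_rate = 60,
                        n_beats = n_beats)
  rec <- simulate_recording(spec, constants$vessel, constants, with_ppg = TRUE)
  meas <- rec$ppg
  pred_p <- predict_ppg(rec, constants$pressure, mode = "P_only")
  pred_pq <- predict_ppg(rec, constants$pressure, constants$flow)
  fs <- rec$sampling_rate
  list(agreement_p = agreement(pred_p, meas),
       agreement_pq = agreement(pred_pq, meas),
       msc_p = band_mean_coherence(welch_msc(pred_p, meas, fs), 0, 10),
       msc_pq = band_mean_coherence(welch_msc(pred_pq, meas, fs), 0, 10))
}

#' Reproduce the study's quantitative results on synthetic data
#'
#' Runs the full synthetic reproduction: Monte-Carlo recovery of every fitted
#' constant from generated protocol recordings with the bundled constants and
#' protocol-level noise, the aggregation-inhibitor arithmetic, the
#' counter-phase demonstration, and the pressure-only versus pressure-plus-flow
#' prediction comparison. Every random draw descends from `seed`.
#'
#' @param seed Master seed (integer).
#' @param quick Reduce replicate counts (10 Monte-Carlo seeds, 6 pauses) for a
#'   fast smoke run; the result is flagged `quick = TRUE`.
#' @param out_dir Optional directory; when given, a `report.json` bundle is
#'   written there.
#' @return A list with `targets` (named list of `list(value, n)`), `extras`
#'   (counter-phase flags, agreement/coherence comparison, inhibitor t-test),
#'   `seed` and `quick`.
#' @export
reproduce_study <- function(seed = 1L, quick = FALSE, out_dir = NULL) {
  constants <- reference_constants()
  constants_px <- reference_constants("poloxamer")
  n_mc <- if (quick) 10L else 100L
  n_pulses <- if (quick) 6L else 20L
  seeds <- child_seeds(seed, 5L)

  slopes <- mc_static_slope(constants, child_seeds(seeds[1], n_mc))
  sat <- mc_flow_saturation(constants, child_seeds(seeds[2], n_mc))
  bi_ctrl <- intermittent_batch(constants, seeds[3], n_pulses)
  bi_polox <- intermittent_batch(constants_px, seeds[4], n_pulses)
  wall <- mc_wall_slope(constants, child_seeds(seeds[5], n_mc))

  px <- poloxamer_contrast(constants$raw$flow_optics$nd_na_ratio,
                           constants$raw$poloxamer_nd_na_ratio)
  ttest <- stats::t.test(bi_polox$per_pause$nd_na_ratio,
                         bi_ctrl$per_pause$nd_na_ratio, var.equal = FALSE)

  cp_low <- counterphase_demo(constants, systolic_low = TRUE)
  cp_high <- counterphase_demo(constants, systolic_low = FALSE)
  cmp <- prediction_comparison(constants, seeds[1])

  targets <- list(
    t1 = list(value = px$ratio_increase_pct, n = 2),
    t2 = list(value = px$aggregation_reduction_pct, n = 2),
    t3 = list(value = mean(slopes), n = n_mc),
    t4 = list(value = stats::median(sat$Q_c), n = n_mc),
    t5 = list(value = stats::median(sat$m_prime), n = n_mc),
    t6 = list(value = unname(bi_ctrl$estimates["tau_d"]), n = bi_ctrl$n),
    t7 = list(value = unname(bi_ctrl$estimates["tau_a"]), n = bi_ctrl$n),
    t8 = list(value = mean(wall), n = n_mc),
    t9 = list(value = unname(bi_ctrl$estimates["nd_na_ratio"]), n = bi_ctrl$n)
  )
  extras <- list(
    counterphase_low = all(cp_low$counter_phase),
    counterphase_high = !any(cp_high$counter_phase),
    pearson_p = cmp$agreement_p$pearson_r,
    pearson_pq = cmp$agreement_pq$pearson_r,
    bias_p = cmp$agreement_p$bias_mean,
    bias_pq = cmp$agreement_pq$bias_mean,
    msc_p = cmp$msc_p,
    msc_pq = cmp$msc_pq,
    poloxamer_ratio_control = unname(bi_ctrl$estimates["nd_na_ratio"]),
    poloxamer_ratio_treated = unname(bi_polox$estimates["nd_na_ratio"]),
    poloxamer_p_value = ttest$p.value
  )
  res <- list(targets = targets, extras = extras, seed = seed, quick = quick)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(res, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  res
}
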