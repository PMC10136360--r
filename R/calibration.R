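# Calibration of the model constants from protocol recordings: linear fits
# for the pressure pathway and the wall law, nonlinear least squares for the
# flow saturation, per-pause biexponential decay fits, and the Poiseuille
# shear-rate conversion. Units: flow mL/min, diameter mm, shear 1/s, time s.

new_fit_result <- function(estimates, se, r_squared, residuals, n, converged,
                           ...) {
  structure(list(estimates = estimates, se = se, r_squared = r_squared,
                 residuals = residuals, n = n, converged = converged, ...),
            class = "ppg_fit")
}

#' @export
print.ppg_fit <- function(x, ...) {
  cat("<ppg_fit>", if (!x$converged) "(NOT converged - estimates unreliable)",
      "\n")
  for (nm in names(x$estimates)) {
    cat(sprintf("  %-12s %.6g", nm, x$estimates[[nm]]))
    if (!is.null(x$se) && nm %in% names(x$se) && is.finite(x$se[[nm]])) {
      cat(sprintf("  (SE/SD %.3g)", x$se[[nm]]))
    }
    cat("\n")
  }
  cat(sprintf("  R^2 = %.4f, n = %d\n", x$r_squared, x$n))
  invisible(x)
}

#' Serialise a fit report to JSON
#'
#' @param fit A `ppg_fit`.
#' @param path Optional output path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
fit_report_json <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "ppg_fit"))
  pars <- lapply(names(fit$estimates), function(nm) {
    list(estimate = unname(fit$estimates[[nm]]),
         se = if (!is.null(fit$se) && nm %in% names(fit$se))
           unname(fit$se[[nm]]) else NA_real_)
  })
  names(pars) <- names(fit$estimates)
  doc <- list(parameters = pars, r_squared = fit$r_squared, n = fit$n,
              converged = fit$converged)
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, na = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

# variance-based plateau detection on 1-s windows: windows whose SD stays at
# the noise floor are plateau candidates; consecutive candidates with a common
# mean form a plateau; plateaus shorter than min_duration are discarded and a
# margin is trimmed at both ends
detect_plateaus <- function(x, fs, min_duration = 4, window = 1,
                            margin = 0.5) {
  nw <- floor(length(x) / (window * fs))
  if (nw < 2) stop("recording too short for plateau detection")
  wlen <- round(window * fs)
  idx <- matrix(x[seq_len(nw * wlen)], nrow = wlen)
  sds <- apply(idx, 2, stats::sd)
  mus <- colMeans(idx)
  floor_sd <- stats::median(sds)
  stable <- sds <= 3 * floor_sd + 1e-12
  jump_tol <- max(10 * floor_sd / sqrt(wlen), 0.02 * diff(range(x)), 1e-9)
  plateaus <- list()
  run_start <- NA_integer_
  for (i in seq_len(nw)) {
    open <- !is.na(run_start)
    breaks <- !stable[i] || (open && i > run_start &&
                               abs(mus[i] - mus[i - 1]) > jump_tol)
    if (breaks && open) {
      plateaus[[length(plateaus) + 1L]] <- c(run_start, i - 1L)
      run_start <- NA_integer_
    }
    if (stable[i] && (is.na(run_start) || breaks)) run_start <- i
  }
  if (!is.na(run_start)) plateaus[[length(plateaus) + 1L]] <- c(run_start, nw)
  keep <- vapply(plateaus, function(p) (p[2] - p[1] + 1) * window >= min_duration,
                 logical(1))
  plateaus <- plateaus[keep]
  m <- round(margin * fs)
  out <- do.call(rbind, lapply(plateaus, function(p) {
    s <- (p[1] - 1L) * wlen + 1L + m
    e <- p[2] * wlen - m
    c(start = s, end = e)
  }))
  as.data.frame(out)
}

segment_means <- function(x, segments) {
  vapply(seq_len(nrow(segments)), function(i) {
    mean(x[segments$start[i]:segments$end[i]])
  }, numeric(1))
}

#' Fit the static pressure--PPG slope
#'
#' Ordinary least squares of plateau-averaged PPG on plateau pressure from a
#' static pressure-step recording (zero flow). Returns the intercept a' and
#' the slope b' (a.u./mmHg) of the linearised volume pathway.
#'
#' @param recording A static-steps [hemodynamic_recording] with a PPG channel.
#' @return A `ppg_fit` with estimates `intercept_a` and `slope_b`.
#' @export
fit_pressure_slope <- function(recording) {
  stopifnot(inherits(recording, "hemodynamic_recording"))
  if (is.null(recording$ppg)) stop("recording has no PPG channel")
  if (mean(abs(recording$flow)) > 10) {
    stop("nonzero flow: fit_pressure_slope requires a static (no-flow) recording")
  }
  fs <- recording$sampling_rate
  if (diff(range(recording$pressure)) < 1e-9) {
    stop("constant pressure: degenerate design, slope not identifiable")
  }
  segs <- detect_plateaus(recording$pressure, fs)
  if (nrow(segs) < 3) stop("need >= 3 pressure plateaus")
  p <- segment_means(recording$pressure, segs)
  y <- segment_means(recording$ppg, segs)
  fit <- stats::lm(y ~ p)
  sm <- suppressWarnings(summary(fit))  # noiseless data trips lm's perfect-fit warning
  new_fit_result(
    estimates = c(intercept_a = unname(stats::coef(fit)[1]),
                  slope_b = unname(stats::coef(fit)[2])),
    se = c(intercept_a = sm$coefficients[1, 2],
           slope_b = sm$coefficients[2, 2]),
    r_squared = sm$r.squared, residuals = stats::residuals(fit),
    n = length(p), converged = TRUE, plateaus = segs)
}

#' Fit the flow-saturation law
#'
#' Plateau means (4-s convention) of PPG versus plateau flow are fitted by
#' multi-start nonlinear least squares against
#' `K - m' * (Q/Q_c) / (1 + Q/Q_c)` (the sign of the flow term is detected
#' from the data, and its magnitude reported). Standard errors come from the
#' Jacobian at the optimum. A fit with an exploding `Q_c` standard error
#' (no curvature in the data) is flagged as not converged.
#'
#' @param recording A flow-sweep [hemodynamic_recording] with a PPG channel.
#' @return A `ppg_fit` with estimates `m_prime` (a.u.), `Q_c` (mL/min) and the
#'   baseline `K`.
#' @export
fit_flow_saturation <- function(recording) {
  stopifnot(inherits(recording, "hemodynamic_recording"))
  if (is.null(recording$ppg)) stop("recording has no PPG channel")
  fs <- recording$sampling_rate
  segs <- detect_plateaus(recording$flow, fs)
  if (nrow(segs) < 4) stop("need >= 4 flow plateaus")
  q <- pmax(segment_means(recording$flow, segs), 0)
  y <- segment_means(recording$ppg, segs)
  if (max(q) <= 0) stop("no nonzero flow plateaus: saturation not identifiable")
  s <- if (stats::cor(q, y) < 0) -1 else 1
  qc_grid <- exp(seq(log(max(q) / 20), log(max(q) * 2), length.out = 5))
  if (all(q > 0.2 * min(qc_grid)) && max(q) < 0.2 * stats::median(qc_grid)) {
    stop("all flows far below the candidate critical flow: not identifiable")
  }
  dat <- data.frame(q = q, y = y)
  best <- NULL
  for (qc0 in qc_grid) {
    st <- list(K = if (s < 0) max(y) else min(y),
               mp = abs(diff(range(y))) * 1.5, Qc = qc0)
    f <- try(minpack.lm::nlsLM(
      y ~ K + s * mp * (q / Qc) / (1 + q / Qc), data = dat, start = st,
      lower = c(K = -Inf, mp = 0, Qc = 1e-6),
      control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
    if (!inherits(f, "try-error")) {
      if (is.null(best) || stats::deviance(f) < stats::deviance(best)) best <- f
    }
  }
  if (is.null(best)) stop("flow-saturation fit failed from every start")
  co <- stats::coef(best)
  sm <- summary(best)
  ses <- sm$coefficients[, 2]
  tss <- sum((y - mean(y))^2)
  converged <- is.finite(ses["Qc"]) && ses["Qc"] < abs(co["Qc"]) * 10
  new_fit_result(
    estimates = c(m_prime = unname(co["mp"]), Q_c = unname(co["Qc"]),
                  K = unname(co["K"])),
    se = c(m_prime = unname(ses["mp"]), Q_c = unname(ses["Qc"]),
           K = unname(ses["K"])),
    r_squared = 1 - stats::deviance(best) / tss,
    residuals = stats::residuals(best), n = length(q),
    converged = converged, plateaus = segs)
}

# one pause decay fit; returns NULL on failure
fit_one_pause <- function(t, y, starts) {
  dat <- data.frame(t = t, y = y)
  tail_n <- max(16L, round(length(y) * 0.1))
  C0 <- mean(utils::tail(y, tail_n))
  A0 <- (y[1] - C0) / 3
  best <- NULL
  for (st in starts) {
    init <- list(C = C0, A = if (abs(A0) > 0) A0 else 1,
                 lr = log(2), ltd = log(st[1]), phi = log(st[2] / st[1] - 1))
    f <- try(minpack.lm::nlsLM(
      y ~ C + A * (exp(lr) * exp(-t / exp(ltd)) +
                     exp(-t / (exp(ltd) * (1 + exp(phi))))),
      data = dat, start = init,
      control = minpack.lm::nls.lm.control(maxiter = 400)), silent = TRUE)
    if (!inherits(f, "try-error")) {
      if (is.null(best) || stats::deviance(f) < stats::deviance(best)) best <- f
    }
  }
  if (is.null(best)) return(NULL)
  co <- stats::coef(best)
  tau_d <- exp(co[["ltd"]])
  tau_a <- tau_d * (1 + exp(co[["phi"]]))
  condition <- tryCatch({
    J <- best$m$gradient()
    sv <- svd(J)$d
    sv[1] / max(sv[length(sv)], .Machine$double.eps)
  }, error = function(e) NA_real_)
  list(tau_d = tau_d, tau_a = tau_a, nd_na_ratio = exp(co[["lr"]]),
       amplitude = co[["A"]], offset = co[["C"]],
       rss = stats::deviance(best), condition = condition)
}

#' Fit the biexponential disorientation/aggregation decay
#'
#' Fits `C + A * (r * exp(-t/tau_d) + exp(-t/tau_a))` to the PPG relaxation of
#' each zero-flow pause of an intermittent recording (`t = 0` at the end of
#' deceleration, i.e. the first pause sample). The ordering `tau_d < tau_a`
#' is enforced by parameterisation (`tau_a = tau_d * (1 + exp(phi))`), and
#' per-pause estimates are pooled into mean (SD), mirroring protocol-level
#' reporting. The Jacobian condition number of each pause fit is recorded; a
#' fit with `tau_d` within 5 % of `tau_a` is flagged as ill-conditioned.
#'
#' @param recording An intermittent [hemodynamic_recording] with PPG and pause
#'   segments.
#' @param settle Portion (s) discarded at the start of each pause (0 by
#'   default; the generator's stop is abrupt).
#' @return A `ppg_fit` with pooled estimates `tau_d`, `tau_a`, `nd_na_ratio`;
#'   `se` holds the across-pause SDs; `$per_pause` the per-pause table.
#' @export
fit_biexponential <- function(recording, settle = 0) {
  stopifnot(inherits(recording, "hemodynamic_recording"))
  if (is.null(recording$ppg)) stop("recording has no PPG channel")
  if (is.null(recording$pause_segments) || nrow(recording$pause_segments) < 1) {
    stop("recording has no pause segments")
  }
  fs <- recording$sampling_rate
  starts <- list(c(0.1, 0.5), c(0.2, 1), c(0.4, 2), c(0.8, 4), c(0.3, 3))
  rows <- list()
  for (i in seq_len(nrow(recording$pause_segments))) {
    s <- recording$pause_segments$start[i] + round(settle * fs)
    e <- recording$pause_segments$end[i]
    y <- recording$ppg[s:e]
    # t = 0 at the end of deceleration (the last driven sample precedes the
    # pause), so the first pause sample sits one step into the decay
    t <- seq_along(y) / fs
    r <- fit_one_pause(t, y, starts)
    if (!is.null(r)) rows[[length(rows) + 1L]] <- as.data.frame(r)
  }
  if (!length(rows)) stop("every pause fit failed")
  per <- do.call(rbind, rows)
  if (any(per$tau_a < per$tau_d * 1.05)) {
    warning("tau_d and tau_a within 5%: biexponential is ill-conditioned")
  }
  if (any(is.finite(per$condition) & per$condition > 1e6)) {
    warning("Jacobian condition number exceeds 1e6 in at least one pause fit")
  }
  pause_len <- min(recording$pause_segments$end -
                     recording$pause_segments$start + 1) / fs
  if (pause_len < 5 * stats::median(per$tau_a)) {
    warning("pauses shorter than 5 * tau_a: decay not fully observed")
  }
  est <- c(tau_d = mean(per$tau_d), tau_a = mean(per$tau_a),
           nd_na_ratio = mean(per$nd_na_ratio))
  sds <- if (nrow(per) > 1) {
    c(tau_d = stats::sd(per$tau_d), tau_a = stats::sd(per$tau_a),
      nd_na_ratio = stats::sd(per$nd_na_ratio))
  } else c(tau_d = NA_real_, tau_a = NA_real_, nd_na_ratio = NA_real_)
  new_fit_result(estimates = est, se = sds, r_squared = NA_real_,
                 residuals = NULL, n = nrow(per), converged = TRUE,
                 per_pause = per)
}

#' Fit the linear pressure--diameter wall law
#'
#' Ordinary least squares of diameter on pressure over paired samples; the
#' slope is the wall constant b (mm/mmHg).
#'
#' @param pressure Pressure samples (mmHg).
#' @param diameter Paired diameter samples (mm).
#' @return A `ppg_fit` with estimates `intercept` (mm) and `slope_b`
#'   (mm/mmHg).
#' @export
fit_pressure_diameter <- function(pressure, diameter) {
  stopifnot(length(pressure) == length(diameter))
  if (diff(range(pressure)) < 1e-9) {
    stop("constant pressure: slope not identifiable")
  }
  if (diff(range(pressure)) < 50) {
    warning("pressure span < 50 mmHg: slope estimate may be imprecise")
  }
  fit <- stats::lm(diameter ~ pressure)
  sm <- suppressWarnings(summary(fit))
  new_fit_result(
    estimates = c(intercept = unname(stats::coef(fit)[1]),
                  slope_b = unname(stats::coef(fit)[2])),
    se = c(intercept = sm$coefficients[1, 2],
           slope_b = sm$coefficients[2, 2]),
    r_squared = sm$r.squared, residuals = stats::residuals(fit),
    n = length(pressure), converged = TRUE)
}

#' Poiseuille wall shear rate
#'
#' For fully developed laminar tube flow, `gamma = 32 Q / (pi D^3)` with the
#' flow converted from mL/min to mm^3/s. Homogeneous of degree 1 in `Q` and
#' degree -3 in `D`. At the fitted critical flow rate of 328 mL/min and a
#' 4.0-mm lumen this gives the critical shear rate of 870 1/s.
#'
#' @param flow Flow (mL/min), `>= 0`.
#' @param diameter Lumen diameter (mm), `> 0`.
#' @return Wall shear rate (1/s).
#' @export
wall_shear_rate <- function(flow, diameter) {
  if (any(flow < 0)) stop("negative flows are not admissible")
  if (any(diameter <= 0)) stop("diameter must be positive")
  32 * (flow * 1000 / 60) / (pi * diameter^3)
}
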