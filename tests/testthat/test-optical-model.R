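test_that("linearised volume pathway is affine in pressure", {
  pp <- pressure_optics(intercept_a = 12, slope_b = 2.15)
  expect_equal(ev_from_pressure(0, pp), 12)
  # the fitted slope: 10 mmHg moves the volume irradiance by 21.5 a.u.
  expect_equal(ev_from_pressure(110, pp) - ev_from_pressure(100, pp), 21.5)
  p <- seq(50, 200, by = 1)
  expect_true(all(diff(ev_from_pressure(p, pp)) > 0))
  expect_error(ev_from_pressure(NA_real_, pp), "non-finite")
})

test_that("diffusion form has the correct limits and tangent", {
  pp <- pressure_optics(incident_irradiance_E0 = 100, absorption_mu_a = 0.2,
                        reduced_scattering_mu_s_prime = 1.1)
  v <- vessel_model()
  # mu_s' = 0: pure Beer-Lambert attenuation
  pp0 <- pressure_optics(incident_irradiance_E0 = 100, absorption_mu_a = 0.2,
                         reduced_scattering_mu_s_prime = 0)
  z <- pressure_to_diameter(100, v)
  expect_equal(ev_diffusion(100, pp0, v), 100 * exp(-0.2 * z))
  # zero optical path returns the incident irradiance
  vz <- vessel_model(reference_diameter = 1e-9, pd_slope_b = 0, is_stiff = TRUE)
  expect_equal(ev_diffusion(100, pp, vz), 100, tolerance = 1e-6)
  # tangent at the reference pressure matches a central-difference derivative
  lin <- linearize_diffusion(pp, v)
  h <- 1e-3
  slope_num <- (ev_diffusion(100 + h, pp, v) - ev_diffusion(100 - h, pp, v)) / (2 * h)
  expect_equal(lin$slope_b, slope_num, tolerance = 1e-7)
  expect_equal(lin$intercept_a + lin$slope_b * 100, ev_diffusion(100, pp, v))
  # missing constants direct the user to the linear form
  expect_error(ev_diffusion(100, pressure_optics(), v), "linear")
})

test_that("alignment laws saturate at half their amplitude at the critical point", {
  expect_equal(aligned_fraction(0, m = 0.9, gamma_c = 870), 0)
  expect_equal(aligned_fraction(870, m = 0.9, gamma_c = 870), 0.45)
  expect_equal(aligned_fraction(1e12, m = 0.9, gamma_c = 870), 0.9,
               tolerance = 1e-6)
  expect_error(aligned_fraction(-1, 0.9, 870), "negative")

  fo <- ref$flow
  expect_equal(eq_high(0, fo), 0)
  expect_equal(eq_high(328, fo), 1613 / 2)  # half-saturation: 806.5 a.u.
  expect_equal(eq_high(3 * 328, fo), 0.75 * 1613)
  q <- sort(abs(rnorm(200, 300, 200)))
  e <- eq_high(q, fo)
  expect_true(all(e >= 0 & e < fo$m_prime))
  expect_true(all(diff(e) >= 0))
})

test_that("decay kernel is normalised and tends to a single exponential", {
  fo <- ref$flow
  dt <- 1e-3
  h <- decay_kernel(fo, dt)
  expect_lt(abs(sum(h) * dt - 1), 1e-6)
  # h[0] * (r tau_d + tau_a) / (r + 1) -> 1 as dt -> 0 (closed-form integral)
  r <- fo$nd_na_ratio
  expect_equal(h[1] * (r * fo$tau_d + fo$tau_a) / (r + 1), 1, tolerance = 5e-3)
  # large amplitude ratio: kernel shape approaches exp(-t/tau_d)
  fo_r <- flow_optics(tau_d = 0.39, tau_a = 1.78, nd_na_ratio = 1e9)
  hr <- decay_kernel(fo_r, dt)
  tk <- seq(0, fo_r$kernel_horizon, by = dt)
  pure <- exp(-tk / 0.39)
  pure <- pure / (sum(pure) * dt)
  expect_equal(hr, pure, tolerance = 1e-5)
  expect_error(decay_kernel(flow_optics(kernel_horizon = 1), dt), "horizon")
})

test_that("regime classification separates acceleration from deceleration", {
  fo <- ref$flow
  fs <- 1000
  expect_true(all(classify_regimes(rep(2 * fo$Q_c, 3000), fo, fs) == "high_shear"))
  expect_true(all(classify_regimes(rep(0, 3000), fo, fs) == "low_shear"))
  # one gamma-shaped pulse: exactly one high-to-low switch on the falling limb
  tt <- (0:4999) / fs
  pulse <- 600 * (tt / 0.3)^3 * exp(3 * (1 - tt / 0.3))
  lab <- classify_regimes(pulse, fo, fs)
  rl <- rle(lab)
  trans_hl <- sum(rl$values[-length(rl$values)] == "high_shear" &
                    rl$values[-1] == "low_shear")
  expect_equal(trans_hl, 1)
  peak <- which.max(pulse)
  expect_true(all(lab[51:peak] == "high_shear"))  # rising limb, past onset lag
})

test_that("flow-pathway dynamics match the closed-form step response", {
  fo <- ref$flow
  fs <- 1000
  expect_equal(eq_flow_series(rep(0, 2000), fo, fs)$irradiance, rep(0, 2000))
  # step from Q_c to zero: normalised biexponential relaxation, t = 0 at the
  # last driven sample
  flow <- c(rep(328, 3000), rep(0, 9000))
  y <- eq_flow_series(flow, fo, fs)$irradiance
  u0 <- eq_high(328, fo)
  t <- (1:9000) / fs
  r <- fo$nd_na_ratio
  g <- (r * exp(-t / fo$tau_d) + exp(-t / fo$tau_a)) / (r + 1)
  expect_lt(max(abs(y[3000 + seq_along(t)] - u0 * g) / u0), 1e-6)
  # decay during the pause is strictly monotone toward the zero-flow asymptote
  expect_true(all(diff(y[3001:12000]) < 0))
  expect_lt(y[12000], 0.01 * u0)
})

test_that("fast recursion equals brute-force direct evaluation", {
  fo <- ref$flow
  fs <- 1000
  # a composite 10^4-sample profile: pulse train, abrupt stop, pause, re-rise
  tt <- (0:9999) / fs
  flow <- 300 + 150 * sin(2 * pi * tt) + 100 * sin(4 * pi * tt + 1)
  flow[4000:7000] <- 0
  flow <- pmax(flow, 0)
  fast <- eq_flow_series(flow, fo, fs)$irradiance
  slow <- brute_eq_flow(flow, fo, fs)
  expect_lt(max(abs(fast - slow)) / max(slow), 1e-9)
  # continuity: no sample-to-sample jump exceeds the drive's own jump plus
  # one kernel step
  max_drive_step <- max(abs(diff(eq_high(flow, fo))))
  kernel_step <- max(fast) * (1 - exp(-1 / (fs * fo$tau_d)))
  expect_lte(max(abs(diff(fast))), max_drive_step + kernel_step + 1e-9)
})

test_that("irradiance composition is additive and conserving", {
  ev <- c(1, 2, 3)
  eq <- c(0.5, 0.25, 0)
  ic <- compose_irradiance(10, ev, eq)
  expect_equal(ic$total, 10 + ev + eq)
  ic2 <- compose_irradiance(5, 2 * ev, 2 * eq)
  expect_equal(compose_irradiance(15, 3 * ev, 3 * eq)$total, ic$total + ic2$total)
  expect_error(compose_irradiance(1, 1:3, 1:4), "length")
})

test_that("receiver response is a power law with a valid linearisation", {
  s1 <- sensor_model(response_coefficient_c = 1, response_exponent_d = 1)
  expect_equal(sensor_response(c(1, 2, 3), s1), c(1, 2, 3))
  s13 <- sensor_model(response_exponent_d = 1.3)
  expect_equal(sensor_response(2, s13) / sensor_response(1, s13), 2^1.3)
  # linearised mode agrees to first order; discrepancy bounded by the
  # squared relative fluctuation
  E <- 100 + 0.5 * sin(seq(0, 10, by = 0.01))
  pw <- sensor_response(E, s13)
  ln <- sensor_response(E, s13, mode = "linear")
  rel_fluct <- max(abs(E - mean(E))) / mean(E)
  expect_lt(max(abs(pw - ln) / abs(pw)), rel_fluct^2)
  expect_error(sensor_response(c(-1, 1), s13), "non-positive")
})

test_that("predicted PPG rises with pressure and falls with flow", {
  rec <- make_static(levels = c(60, 120, 180), level_duration = 5)
  p_only <- predict_ppg(rec, ref$pressure, mode = "P_only")
  p_and_q <- predict_ppg(rec, ref$pressure, ref$flow)
  expect_equal(p_only, p_and_q)  # no flow: the two modes coincide

  sweep <- make_sweep(levels = seq(0, 800, length.out = 6))
  segs <- rppgmodel:::detect_plateaus(sweep$flow, sweep$sampling_rate)
  means <- rppgmodel:::segment_means(sweep$ppg, segs)
  expect_true(all(diff(means) < 0))  # strictly decreasing in flow

  # sign structure on a grid: dPPG/dP > 0 at fixed flow, dPPG/dQ < 0 at fixed P
  fo <- ref$flow
  pp <- ref$pressure
  expect_true(all(diff(ev_from_pressure(seq(60, 180, 10), pp)) > 0))
  expect_true(all(diff(-eq_high(seq(0, 800, 50), fo)) < 0))
  expect_error(predict_ppg(rec, ref$pressure, NULL, mode = "P_and_Q"),
               "flow_params")
})
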