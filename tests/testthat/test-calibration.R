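test_that("noiseless recordings give back the generating constants exactly", {
  # pressure pathway
  f1 <- fit_pressure_slope(make_static())
  expect_equal(unname(f1$estimates["slope_b"]), 2.15, tolerance = 1e-10)
  # flow saturation
  f2 <- fit_flow_saturation(make_sweep())
  expect_equal(unname(f2$estimates["m_prime"]), 1613, tolerance = 1e-6)
  expect_equal(unname(f2$estimates["Q_c"]), 328, tolerance = 1e-6)
  # decay kinetics
  f3 <- fit_biexponential(make_intermittent())
  expect_equal(unname(f3$estimates["tau_d"]), 0.39, tolerance = 1e-4)
  expect_equal(unname(f3$estimates["tau_a"]), 1.78, tolerance = 1e-4)
  expect_equal(unname(f3$estimates["nd_na_ratio"]), 2.2, tolerance = 1e-4)
  # wall law
  p <- seq(50, 200, length.out = 5000)
  d <- 4 + 1.245e-3 * (p - 100)
  f4 <- fit_pressure_diameter(p, d)
  expect_equal(unname(f4$estimates["slope_b"]), 1.245e-3, tolerance = 1e-10)
})

test_that("pressure-slope fit rejects misuse", {
  rec <- make_static()
  rec$flow <- rec$flow + 200
  expect_error(fit_pressure_slope(rec), "static")
  rec2 <- make_static(levels = c(100, 150))
  expect_error(fit_pressure_slope(rec2), ">= 3")
  rec3 <- make_static(levels = c(100, 100, 100))
  expect_error(fit_pressure_slope(rec3), "constant pressure|degenerate")
  rec4 <- make_static()
  rec4$ppg <- NULL
  expect_error(fit_pressure_slope(rec4), "PPG")
})

test_that("saturation fit flags data without curvature", {
  # PPG linear in flow: Q_c is unidentifiable and the fit must not pretend
  spec <- protocol_spec("flow_sweep", seed = 2,
                        flow_levels = seq(100, 700, length.out = 7),
                        level_duration = 5, noise_sd = noiseless)
  rec <- generate_flow_sweep(spec, vessel_model(is_stiff = TRUE))
  rec$ppg <- 2000 - 0.5 * rec$truth$flow +
    withr::with_seed(4, rnorm(length(rec$flow), 0, 1))
  f <- try(fit_flow_saturation(rec), silent = TRUE)
  expect_true(inherits(f, "try-error") || !f$converged)
})

test_that("human-artery wall slope is recovered from noisy paired data", {
  p <- seq(50, 200, length.out = 20000)
  d <- 3.0 + 1.1e-3 * (p - 100) +
    withr::with_seed(11, rnorm(length(p), 0, 0.008))
  f <- fit_pressure_diameter(p, d)
  expect_equal(unname(f$estimates["slope_b"]), 1.1e-3,
               tolerance = 3 * f$se[["slope_b"]] / 1.1e-3)
  expect_gt(f$r_squared, 0.9)
  expect_error(fit_pressure_diameter(rep(100, 50), rnorm(50)), "constant")
  expect_warning(fit_pressure_diameter(seq(90, 110, length.out = 100),
                                       seq(1, 2, length.out = 100)), "span")
})

test_that("wall shear rate follows the Poiseuille closed form", {
  expect_equal(wall_shear_rate(0, 4), 0)
  # doubling the diameter divides the shear rate by 8
  expect_equal(wall_shear_rate(300, 8), wall_shear_rate(300, 4) / 8)
  # homogeneity: degree 1 in Q, degree -3 in D
  q <- withr::with_seed(5, runif(20, 10, 800))
  d <- withr::with_seed(6, runif(20, 2, 6))
  a <- withr::with_seed(7, runif(20, 0.5, 3))
  expect_equal(wall_shear_rate(a * q, d), a * wall_shear_rate(q, d))
  expect_equal(wall_shear_rate(q, a * d), wall_shear_rate(q, d) / a^3)
  # the critical pair: 328 mL/min in a 4.0-mm lumen gives 870 1/s
  expect_equal(wall_shear_rate(328, 4.0), 870.0, tolerance = 1e-4)
  expect_error(wall_shear_rate(100, 0), "diameter")
})

test_that("noisy static steps recover the pressure slope without bias", {
  noise <- list(pressure = 0.5, flow = 2, diameter = 0.008, ppg = 5)
  slopes <- vapply(1:10, function(s) {
    rec <- make_static(seed = s, noise = noise)
    unname(fit_pressure_slope(rec)$estimates["slope_b"])
  }, numeric(1))
  mc_se <- sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes) - 2.15), max(2 * mc_se, 5e-3))
})

test_that("aggregation-inhibited batches separate in the amplitude ratio", {
  noise <- list(pressure = 0.5, flow = 2, diameter = 0.008, ppg = 5)
  ctrl <- fit_biexponential(make_intermittent(n_pulses = 8, seed = 21,
                                              noise = noise))
  polox <- fit_biexponential(make_intermittent(
    n_pulses = 8, seed = 22, noise = noise,
    constants = reference_constants("poloxamer")))
  tt <- t.test(polox$per_pause$nd_na_ratio, ctrl$per_pause$nd_na_ratio,
               var.equal = FALSE)
  expect_lt(tt$p.value, 0.05)
  expect_equal(unname(polox$estimates["nd_na_ratio"]), 3.6,
               tolerance = 0.1)
  expect_gt(tt$estimate[1], tt$estimate[2])
})

test_that("short pauses trigger an incomplete-decay warning", {
  expect_warning(fit_biexponential(make_intermittent(pause_duration = 5)),
                 "5 \\* tau_a|shorter")
})

test_that("fit reports serialise to well-formed JSON", {
  f <- fit_pressure_diameter(seq(50, 200, length.out = 200),
                             4 + 1.245e-3 * (seq(50, 200, length.out = 200) - 100))
  js <- jsonlite::fromJSON(fit_report_json(f))
  expect_named(js, c("parameters", "r_squared", "n", "converged"))
  expect_equal(js$parameters$slope_b$estimate, 1.245e-3, tolerance = 1e-8)
  expect_true(js$converged)
})
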