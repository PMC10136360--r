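test_that("zero-phase low-pass keeps the passband and kills 100 Hz", {
  fs <- 1000
  t <- (0:9999) / fs
  mid <- 2001:8000
  amp <- function(x) (max(x[mid]) - min(x[mid])) / 2
  # DC passes untouched
  expect_equal(lowpass_50(rep(3.7, 10000), fs), rep(3.7, 10000),
               tolerance = 1e-9)
  # deep passband: 1-Hz tone loses < 0.1 % amplitude
  y1 <- lowpass_50(sin(2 * pi * 1 * t), fs)
  expect_lt(abs(amp(y1) - 1), 1e-3)
  # passband edge: < 0.1 dB ripple at 40 Hz
  y40 <- lowpass_50(sin(2 * pi * 40 * t), fs)
  expect_gt(amp(y40), 10^(-0.1 / 20))
  # stopband: 100-Hz tone attenuated by more than 97 %
  y100 <- lowpass_50(sin(2 * pi * 100 * t), fs)
  expect_lt(amp(y100), 0.03)
  # zero phase: the filtered 1-Hz tone has no measurable delay
  lag <- which.max(ccf(y1[mid], sin(2 * pi * t)[mid], lag.max = 20,
                       plot = FALSE)$acf) - 21
  expect_equal(lag, 0)
  expect_error(lowpass_50(rnorm(100), fs), "shorter")
})

test_that("agreement reproduces Pearson and Bland-Altman exactly", {
  x <- withr::with_seed(1, rnorm(500, 100, 10))
  a <- agreement(x, x)
  expect_equal(a$pearson_r, 1)
  expect_equal(a$bias_mean, 0)
  expect_equal(a$bias_sd, 0)
  # a pure shift leaves r at 1 and appears fully in the bias
  b <- agreement(x + 20.7, x)
  expect_equal(b$pearson_r, 1)
  expect_equal(b$bias_mean, 20.7)
  expect_equal(b$limits_of_agreement, b$bias_mean + c(-1.96, 1.96) * b$bias_sd)
  expect_equal(agreement(-x, x)$pearson_r, -1)
  expect_warning(cc <- agreement(rep(1, 500), x), "constant")
  expect_true(cc$degenerate)
  expect_error(agreement(x[1:10], x[1:10]), "30")
})

test_that("Welch coherence is exact for self, invariant, and biased as known", {
  fs <- 1000
  x <- withr::with_seed(2, rnorm(8192))
  cs <- welch_msc(x, x, fs)
  expect_true(all(abs(cs$coherence - 1) < 1e-10, na.rm = TRUE))
  # invariance to scaling and offsets of either input
  y <- withr::with_seed(3, rnorm(8192))
  c0 <- welch_msc(x, y, fs)
  c1 <- welch_msc(5 * x + 11, -2 * y + 3, fs)
  expect_equal(c0$coherence, c1$coherence, tolerance = 1e-10)
  # a delayed copy keeps magnitude coherence ~1 at every energetic bin
  d <- 25
  cd <- welch_msc(x[1:8000], c(rep(0, d), x[1:(8000 - d)]), fs)
  expect_gt(median(cd$coherence, na.rm = TRUE), 0.95)
  # independent white noise: mean MSC near 1/K segments, shrinking with length
  short_k <- welch_msc(x[1:4096], y[1:4096], fs)
  long_k <- welch_msc(x, y, fs)
  expect_lt(mean(long_k$coherence, na.rm = TRUE),
            mean(short_k$coherence, na.rm = TRUE))
  expect_lt(abs(mean(long_k$coherence, na.rm = TRUE) - 1 / long_k$n_segments),
            0.6 / long_k$n_segments)
  expect_error(welch_msc(x[1:1000], y[1:1000], fs), "4096")
})

test_that("coherence tracks the signal-to-noise ratio", {
  # y = x + independent noise: per-bin MSC should sit near snr/(1+snr)
  fs <- 1000
  n <- 65536
  x <- withr::with_seed(4, rnorm(n))
  noise <- withr::with_seed(5, rnorm(n))
  for (snr in c(4, 1)) {
    y <- sqrt(snr) * x + noise
    cc <- welch_msc(sqrt(snr) * x, y, fs)
    expect_equal(mean(cc$coherence, na.rm = TRUE), snr / (1 + snr),
                 tolerance = 0.05)
  }
  expect_error(band_mean_coherence(welch_msc(x, x, fs), 600, 700), "band")
})

test_that("wavelet coherence recovers magnitude and phase conventions", {
  fs <- 100
  t <- (0:1999) / fs
  x <- sin(2 * pi * 2 * t) + 0.5 * sin(2 * pi * 5 * t + 1)
  wc <- wavelet_coherence(x, x, fs)
  expect_true(all(wc$coherence[wc$coi_mask] > 0.999))
  expect_lt(max(abs(wc$phase[wc$coi_mask])), 1e-6)
  # sign flip: phase pi wherever coherent
  wn <- wavelet_coherence(x, -x, fs)
  sel <- wn$coi_mask & wn$high_coherence
  expect_lt(max(abs(abs(wn$phase[sel]) - pi)), 1e-6)
  expect_error(wavelet_coherence(x[1:100], x[1:100], fs), "4 s")
})

test_that("wavelet phase of a quarter-period shift is pi/2 at the tone", {
  fs <- 100
  f0 <- 2.5  # 40-sample period: the quarter-period shift is a whole 10 samples
  t <- (0:2999) / fs
  shift <- round(fs / f0 / 4)
  x <- sin(2 * pi * f0 * t)
  y <- sin(2 * pi * f0 * (t - shift / fs))
  wc <- wavelet_coherence(x, y, fs)
  j <- which.min(abs(wc$frequency - f0))
  mid <- wc$coi_mask[j, ] & seq_along(wc$time) > 1000 &
    seq_along(wc$time) < 2000
  expect_lt(max(abs(wc$phase[j, mid] - pi / 2)), 0.05)
})

test_that("beat phase flags counter-phase beats", {
  fs <- 1000
  onsets <- seq(1, 8000, by = 1000)
  t <- (0:8999) / fs
  pr <- 100 + 20 * sin(2 * pi * t) + 5 * sin(4 * pi * t + 1)
  bp0 <- beat_phase(pr, pr, onsets, fs)
  expect_true(all(abs(bp0$phase) < 1e-8))
  expect_false(any(bp0$counter_phase))
  bp1 <- beat_phase(-pr + 400, pr, onsets, fs)
  expect_true(all(abs(abs(bp1$phase) - pi) < 1e-8))
  expect_true(all(bp1$counter_phase))
  expect_warning(beat_phase(pr[1:40], pr[1:40], c(1L, 35L), fs), "short")
})

test_that("forward-model counter-phase appears only at low systolic pressure", {
  spec_for <- function(pr) {
    protocol_spec("pulsatile", seed = 1, pressure_range = pr,
                  flow_range = c(300, 420), heart_rate = 60, n_beats = 6,
                  noise_sd = noiseless)
  }
  run <- function(pr) {
    rec <- generate_pulsatile(spec_for(pr), ref$vessel)
    ppg <- predict_ppg(rec, ref$pressure, ref$flow)
    beat_phase(ppg, rec$pressure, rec$beat_onsets, rec$sampling_rate)
  }
  low <- run(c(75, 92))    # systolic below 100 mmHg: flow effect dominates
  high <- run(c(100, 160)) # light attenuation dominates
  expect_true(all(low$counter_phase))
  expect_false(any(high$counter_phase))
})
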