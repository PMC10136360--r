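# Agreement and spectral machinery: zero-phase low-pass filtering, Pearson /
# Bland-Altman agreement, Welch magnitude-squared coherence with the exact
# 2048/1024 rectangular windowing, Morlet wavelet coherence with phase, and
# per-beat counter-phase detection.

#' Zero-phase 50-Hz low-pass filter
#'
#' Removes utility-frequency and high-frequency noise without touching the
#' 0--40-Hz band that carries the hemodynamic signal content. Realised as a
#' linear-phase FIR (Hamming windowed-sinc, 201 taps at 1 kHz, scaled with the
#' sampling rate) applied with reflection padding and group-delay
#' compensation, so the response is exactly zero-phase; passband ripple below
#' 40 Hz is under 0.1 dB and a 100-Hz tone is attenuated by more than 97 %.
#'
#' @param x Signal vector.
#' @param fs Sampling rate (Hz), `> 100`.
#' @param cutoff Cut-off frequency (Hz), default 50.
#' @return Filtered signal, same length as `x`.
#' @export
lowpass_50 <- function(x, fs, cutoff = 50) {
  if (fs <= 100) stop("fs must exceed 100 Hz")
  ntaps <- 2L * max(10L, round(100 * fs / 1000)) + 1L
  if (length(x) < 3L * ntaps) {
    stop("signal shorter than 3x the filter order (", 3L * ntaps, " samples)")
  }
  h <- signal::fir1(ntaps - 1L, cutoff / (fs / 2), type = "low")
  h <- h / sum(h)  # exact unit DC gain
  half <- (ntaps - 1L) %/% 2L
  # reflect edges so the convolution is defined across the full record
  xp <- c(rev(x[2:(half + 1L)]), x, rev(x[(length(x) - half):(length(x) - 1L)]))
  y <- stats::filter(xp, h, sides = 2L)
  as.numeric(y[(half + 1L):(half + length(x))])
}

#' Pearson and Bland--Altman agreement between two series
#'
#' Pearson correlation on instantaneous values, plus Bland--Altman bias
#' statistics on the pairwise differences `pred - meas`: mean bias, SD, and
#' the 1.96-SD limits of agreement.
#'
#' @param pred Predicted series.
#' @param meas Measured series, same length, at least 30 samples.
#' @return An object of class `agreement_report`: `pearson_r`, `bias_mean`,
#'   `bias_sd`, `limits_of_agreement` (length-2), `n_samples`, and `degenerate`
#'   (TRUE when either input is constant and r is undefined).
#' @export
agreement <- function(pred, meas) {
  if (length(pred) != length(meas)) stop("series must have equal length")
  if (length(pred) < 30) stop("need at least 30 samples")
  degenerate <- stats::sd(pred) == 0 || stats::sd(meas) == 0
  r <- if (degenerate) {
    warning("constant series: Pearson r undefined")
    NA_real_
  } else stats::cor(pred, meas)
  d <- pred - meas
  bias <- mean(d)
  bsd <- stats::sd(d)
  structure(list(pearson_r = r, bias_mean = bias, bias_sd = bsd,
                 limits_of_agreement = bias + c(-1.96, 1.96) * bsd,
                 n_samples = length(pred), degenerate = degenerate),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement> r = %.3f, bias = %.2f (SD %.2f), LoA [%.2f, %.2f], n = %d\n",
              x$pearson_r, x$bias_mean, x$bias_sd,
              x$limits_of_agreement[1], x$limits_of_agreement[2], x$n_samples))
  invisible(x)
}

#' Welch magnitude-squared coherence
#'
#' Overlapped averaged periodograms with 2048-sample rectangular windows and
#' 1024-sample overlap (both scaled by `fs/1000` when the sampling rate
#' differs from 1 kHz, preserving the window's duration in seconds). Each
#' series is demeaned once, so the estimate is invariant to scaling and
#' constant offsets.
#'
#' @param x,y Equal-length series covering at least 3 windows.
#' @param fs Sampling rate (Hz).
#' @param nfft Window length in samples (default 2048 at 1 kHz).
#' @return An object of class `coherence_result` with `frequency` (Hz),
#'   `coherence` (MSC per bin, in `[0,1]`) and `n_segments`.
#' @export
welch_msc <- function(x, y, fs, nfft = round(2048 * fs / 1000)) {
  if (length(x) != length(y)) stop("series must have equal length")
  step <- nfft %/% 2L
  min_n <- nfft + 2L * step
  if (length(x) < min_n) {
    stop("input too short: need >= ", min_n, " samples (3 windows of ", nfft,
         " with ", step, "-sample overlap)")
  }
  x <- x - mean(x)
  y <- y - mean(y)
  starts <- seq(1L, length(x) - nfft + 1L, by = step)
  nb <- nfft %/% 2L + 1L
  pxx <- pyy <- numeric(nb)
  pxy <- complex(nb)
  for (s in starts) {
    xs <- stats::fft(x[s:(s + nfft - 1L)])[seq_len(nb)]
    ys <- stats::fft(y[s:(s + nfft - 1L)])[seq_len(nb)]
    pxx <- pxx + Mod(xs)^2
    pyy <- pyy + Mod(ys)^2
    pxy <- pxy + xs * Conj(ys)
  }
  coh <- Mod(pxy)^2 / (pxx * pyy)
  coh[pxx == 0 | pyy == 0] <- NA_real_
  structure(list(frequency = (seq_len(nb) - 1) * fs / nfft,
                 coherence = coh, n_segments = length(starts)),
            class = "coherence_result")
}

#' Band-mean of a coherence spectrum
#'
#' Arithmetic mean over the FFT bins lying inside `[f_lo, f_hi]`, endpoints
#' included.
#'
#' @param coh A `coherence_result` from [welch_msc()].
#' @param f_lo,f_hi Band edges (Hz).
#' @export
band_mean_coherence <- function(coh, f_lo, f_hi) {
  stopifnot(inherits(coh, "coherence_result"), f_lo <= f_hi)
  sel <- coh$frequency >= f_lo & coh$frequency <= f_hi
  if (!any(sel)) stop("no frequency bins inside the band")
  mean(coh$coherence[sel], na.rm = TRUE)
}

# Morlet wavelet machinery -----------------------------------------------------

# analytic Morlet CWT (omega0 = 6) via FFT; returns complex matrix scales x time
morlet_cwt <- function(x, fs, scales, omega0 = 6) {
  n <- length(x)
  npad <- 2^ceiling(log2(n))
  xf <- stats::fft(c(x - mean(x), numeric(npad - n)))
  omega <- 2 * pi * fs * c(seq(0, floor(npad / 2)),
                           seq(-(ceiling(npad / 2) - 1), -1)) / npad
  W <- matrix(0 + 0i, nrow = length(scales), ncol = n)
  for (j in seq_along(scales)) {
    s <- scales[j]
    psi <- pi^(-0.25) * sqrt(2 * pi * s * fs) * exp(-0.5 * (s * omega - omega0)^2)
    psi[omega <= 0] <- 0
    w <- stats::fft(xf * psi, inverse = TRUE) / npad
    W[j, ] <- w[seq_len(n)]
  }
  W
}

# Gaussian time smoothing (width = scale) per row, then boxcar scale smoothing
# over 0.6 octave
smooth_tf <- function(M, fs, scales, dj) {
  n <- ncol(M)
  npad <- 2^ceiling(log2(n))
  omega <- 2 * pi * fs * c(seq(0, floor(npad / 2)),
                           seq(-(ceiling(npad / 2) - 1), -1)) / npad
  out <- M
  for (j in seq_along(scales)) {
    row <- c(M[j, ], rep(0 + 0i, npad - n))
    rf <- stats::fft(row)
    gain <- exp(-0.5 * (scales[j] * omega)^2)
    sm <- stats::fft(rf * gain, inverse = TRUE) / npad
    out[j, ] <- sm[seq_len(n)]
  }
  nsc <- max(1L, round(0.6 / dj))
  if (nsc > 1L && nrow(out) > 1L) {
    k <- rep(1 / nsc, nsc)
    for (t in seq_len(n)) {
      col <- out[, t]
      smc <- stats::filter(Re(col), k, sides = 2) +
        1i * stats::filter(Im(col), k, sides = 2)
      smc <- as.complex(smc)
      bad <- is.na(smc)
      smc[bad] <- col[bad]
      out[, t] <- smc
    }
  }
  out
}

#' Morlet wavelet coherence with phase
#'
#' Continuous-wavelet coherence between two series using the analytic Morlet
#' wavelet (centre frequency 6), with the standard smoothing in time (Gaussian
#' of width equal to the scale) and in scale (boxcar over 0.6 octave), the
#' scale-normalised cross-spectrum, a phase map (0 = in phase, pi =
#' counter-phase) and the cone of influence.
#'
#' @param x,y Equal-length series of at least 4 s.
#' @param fs Sampling rate (Hz).
#' @param dj Scale resolution in octaves (default 1/12).
#' @return An object of class `wavelet_coherence_result`: `time`, `frequency`
#'   (Hz, one per scale), `coherence` and `phase` matrices (scale x time),
#'   `coi` (per-sample lowest edge-safe frequency, Hz),
#'   `coi_mask` (TRUE inside the cone), and
#'   `high_coherence` (TRUE where coherence > 0.5, the conventional threshold
#'   for displaying phase arrows).
#' @export
wavelet_coherence <- function(x, y, fs, dj = 1 / 12) {
  if (length(x) != length(y)) stop("series must have equal length")
  n <- length(x)
  if (n < 4 * fs) stop("need at least 4 s of data")
  omega0 <- 6
  fourier_factor <- 4 * pi / (omega0 + sqrt(2 + omega0^2))
  s0 <- 2 / fs
  jmax <- floor(log2((n / fs) / (3 * s0)) / dj)
  scales <- s0 * 2^(dj * seq(0, jmax))
  Wx <- morlet_cwt(x, fs, scales, omega0)
  Wy <- morlet_cwt(y, fs, scales, omega0)
  inv_s <- 1 / scales
  Sxx <- Re(smooth_tf(sweep(Mod(Wx)^2, 1, inv_s, `*`) + 0i, fs, scales, dj))
  Syy <- Re(smooth_tf(sweep(Mod(Wy)^2, 1, inv_s, `*`) + 0i, fs, scales, dj))
  Sxy <- smooth_tf(sweep(Wx * Conj(Wy), 1, inv_s, `*`), fs, scales, dj)
  coh <- Mod(Sxy)^2 / (Sxx * Syy)
  coh[!is.finite(coh)] <- 0
  coh <- pmin(pmax(coh, 0), 1)
  phase <- Arg(Sxy)
  tgrid <- (seq_len(n) - 1) / fs
  edge_dist <- pmin(tgrid, rev(tgrid))
  period <- fourier_factor * scales
  # e-folding time of the Morlet envelope is sqrt(2)*s: a cell is inside the
  # cone when its period is shorter than fourier_factor * d / sqrt(2)
  coi_period <- fourier_factor * edge_dist / sqrt(2)
  coi_mask <- outer(period, coi_period, `<=`)
  structure(list(time = tgrid, frequency = 1 / period,
                 coherence = coh, phase = phase,
                 coi = 1 / pmax(coi_period, .Machine$double.eps),
                 coi_mask = coi_mask,
                 high_coherence = coh > 0.5),
            class = "wavelet_coherence_result")
}

#' Per-beat phase of PPG relative to pressure
#'
#' For each beat window (onset to next onset), both series are demeaned and
#' the phase of the cross-spectrum at the beat fundamental (first DFT bin of
#' the window) is computed; a beat is flagged counter-phase when the absolute
#' phase exceeds pi/2. A positive-pressure-dominated beat sits near 0; a
#' flow-dominated beat near pi.
#'
#' @param ppg PPG series (a.u.).
#' @param pressure Pressure series (mmHg), same length.
#' @param beat_onsets Beat-onset sample indices (ascending).
#' @param fs Sampling rate (Hz).
#' @return A data frame with one row per complete beat: `beat`, `start`,
#'   `end`, `phase` (radians in (-pi, pi]) and `counter_phase`.
#' @export
beat_phase <- function(ppg, pressure, beat_onsets, fs) {
  if (length(ppg) != length(pressure)) stop("series must have equal length")
  if (length(beat_onsets) < 1) stop("need at least one beat onset")
  # the final beat gets a window of the median beat length, not the record tail
  med_len <- if (length(beat_onsets) > 1) {
    as.integer(round(stats::median(diff(beat_onsets))))
  } else length(ppg) - beat_onsets[1] + 1L
  last_end <- min(length(ppg), beat_onsets[length(beat_onsets)] + med_len - 1L)
  ends <- c(beat_onsets[-1] - 1L, last_end)
  rows <- list()
  for (i in seq_along(beat_onsets)) {
    s <- beat_onsets[i]
    e <- ends[i]
    if (e - s + 1L < 32L) {
      warning("beat ", i, " too short for phase estimation; skipped")
      next
    }
    w <- s:e
    a <- ppg[w] - mean(ppg[w])
    b <- pressure[w] - mean(pressure[w])
    k <- 2L  # first non-DC bin = beat fundamental
    fa <- stats::fft(a)[k]
    fb <- stats::fft(b)[k]
    ph <- Arg(fa * Conj(fb))
    rows[[length(rows) + 1L]] <- data.frame(
      beat = i, start = s, end = e, phase = ph,
      counter_phase = abs(ph) > pi / 2)
  }
  do.call(rbind, rows)
}
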