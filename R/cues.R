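# Extraction of interaural time/level differences and monaural spectral
# maps from binaural impulse responses.

#' Extract the interaural time difference (ITD) from an HRIR pair
#'
#' Implements the multi-stage ITD estimator used for dummy-head
#' measurements: (1) a linear-phase FIR bandpass 0.1--1.5 kHz applied
#' identically to both ears (identical group delay, so interaural timing is
#' untouched), (2) half-wave rectification, (3) a brickwall lowpass at
#' 1.4 kHz realized as FFT-bin zeroing, and (4) the peak of the
#' cross-correlation function restricted to `|lag| <= max_lag`. The sign
#' convention is positive ITD = sound reaching the right ear first.
#'
#' If several correlation bins tie at the maximum, the smallest `|lag|` is
#' returned (the physiologically conservative estimate). The peak is located
#' at sample resolution by default; `interpolate = TRUE` adds parabolic
#' sub-sample interpolation.
#'
#' @param left,right Impulse responses (equal length).
#' @param sample_rate Sampling rate, Hz (>= 8000).
#' @param max_lag Maximum cross-correlation lag, seconds. Default 1 ms,
#'   encompassing the physiological ITD limit (~800 us).
#' @param interpolate Logical; parabolic sub-sample peak interpolation.
#' @return ITD in microseconds, bounded by `+/-max_lag`.
#' @export
#' @examples
#' fs <- 44100
#' x <- stats::rnorm(512)
#' extract_itd(x, x, fs) # 0
#' extract_itd(c(rep(0, 31), x), c(x, rep(0, 31)), fs) # right leads: +702.9
extract_itd <- function(left, right, sample_rate, max_lag = 1e-3,
                        interpolate = FALSE) {
  stop_arg(length(left) == length(right),
           "`left` and `right` must have equal length")
  stop_arg(sample_rate >= 8000, "`sample_rate` must be >= 8 kHz")
  ntaps <- 513L
  stop_arg(length(left) >= 32L, "signals too short for the analysis filters")

  b <- signal::fir1(ntaps - 1L, c(100, 1500) / (sample_rate / 2), type = "pass")
  l <- fft_conv(c(left, rep(0, ntaps)), b)
  r <- fft_conv(c(right, rep(0, ntaps)), b)

  # half-wave rectification, then brickwall lowpass at 1.4 kHz
  l <- pmax(l, 0)
  r <- pmax(r, 0)
  brickwall <- function(x, fc) {
    nfft <- next_pow2(length(x))
    X <- stats::fft(c(x, rep(0, nfft - length(x))))
    f <- (0:(nfft - 1)) * sample_rate / nfft
    f <- pmin(f, sample_rate - f) # alias to 0..fs/2
    X[f > fc] <- 0
    Re(stats::fft(X, inverse = TRUE))[seq_along(x)] / nfft
  }
  l <- brickwall(l, 1400)
  r <- brickwall(r, 1400)

  K <- floor(max_lag * sample_rate)
  cc <- xcorr_lags(l, r, K)
  peak <- max(cc$values)
  cand <- which(cc$values >= peak * (1 - 1e-12))
  best <- cand[which.min(abs(cc$lags[cand]))]
  lag <- cc$lags[best]
  if (interpolate && best > 1 && best < length(cc$values)) {
    y0 <- cc$values[best - 1]; y1 <- cc$values[best]; y2 <- cc$values[best + 1]
    den <- y0 - 2 * y1 + y2
    if (den < 0) lag <- lag + 0.5 * (y0 - y2) / den
  }
  lag / sample_rate * 1e6
}

#' Extract the interaural level difference (ILD) from an HRIR pair
#'
#' Both ears are passed through an IIR bandpass 3--20 kHz (4th-order
#' Butterworth, applied forward only; level, not phase, matters here),
#' focusing on the band where head-shadow effects are most prominent, and
#' the ILD is the RMS-amplitude ratio in dB. Positive ILD = louder on the
#' right.
#'
#' @param left,right Impulse responses (equal length).
#' @param sample_rate Sampling rate, Hz.
#' @return ILD in dB, or `NA` (with a warning) if either ear has no energy
#'   in the band.
#' @export
#' @examples
#' x <- stats::rnorm(512)
#' extract_ild(x, 2 * x, 44100) # +6.02 dB
extract_ild <- function(left, right, sample_rate) {
  stop_arg(length(left) == length(right),
           "`left` and `right` must have equal length")
  hi <- min(20000, 0.95 * sample_rate / 2)
  flt <- signal::butter(4, c(3000, hi) / (sample_rate / 2), type = "pass")
  l <- signal::filter(flt, c(left, rep(0, 256)))
  r <- signal::filter(flt, c(right, rep(0, 256)))
  rl <- rms(l)
  rr <- rms(r)
  if (rl < 1e-14 || rr < 1e-14) {
    warning("zero in-band energy: ILD undefined", call. = FALSE)
    return(NA_real_)
  }
  db(rr / rl)
}

#' Binaural cue profile along the azimuth plane
#'
#' Computes ITD and ILD per azimuth at a fixed elevation (default 0, the
#' horizontal plane), propagating the set's condition and SNR labels.
#'
#' @param hrirs An [hrir_set()].
#' @param elevation Elevation row to use, degrees.
#' @param ... Passed to [extract_itd()].
#' @return A data frame of class `cue_profile` with columns `azimuth_deg`,
#'   `itd_us`, `ild_db`, `condition`, `snr_db`.
#' @export
cue_profile <- function(hrirs, elevation = 0, ...) {
  az <- hrir_azimuths(hrirs, elevation)
  stop_arg(length(az) > 0, paste0("no HRIRs at elevation ", elevation))
  fs <- hrirs$sample_rate
  itd <- numeric(length(az))
  ild <- numeric(length(az))
  for (i in seq_along(az)) {
    e <- hrir_at(hrirs, az[i], elevation)
    itd[i] <- extract_itd(e$left, e$right, fs, ...)
    ild[i] <- extract_ild(e$left, e$right, fs)
  }
  out <- data.frame(azimuth_deg = az, itd_us = itd, ild_db = ild,
                    condition = hrirs$condition,
                    snr_db = if (is.null(hrirs$snr)) NA_real_ else hrirs$snr)
  class(out) <- c("cue_profile", "data.frame")
  out
}

#' Monaural spectral map across elevations
#'
#' Per-elevation magnitude responses of one ear's HRIRs at a fixed azimuth
#' (default 0, the median plane), evaluated by FFT on a log-spaced frequency
#' grid within `band` (default 3--16 kHz, the range critical for elevation
#' perception).
#'
#' @param hrirs An [hrir_set()].
#' @param ear `"left"` or `"right"`.
#' @param band Two-element frequency range, Hz, within 3--16 kHz.
#' @param azimuth Azimuth column to use, degrees.
#' @param n_freq Number of log-spaced frequency points.
#' @param nfft FFT length (zero-padded).
#' @return An object of class `spectral_map`: list with `ear`, `elevations`,
#'   `frequencies` and a `magnitude` matrix (elevation x frequency, dB).
#' @export
spectral_map <- function(hrirs, ear = c("left", "right"),
                         band = c(3000, 16000), azimuth = 0,
                         n_freq = 96, nfft = 4096) {
  ear <- match.arg(ear)
  stop_arg(band[1] >= 3000 && band[2] <= 16000 && band[1] < band[2],
           "`band` must lie within [3, 16] kHz")
  el <- hrir_elevations(hrirs, azimuth)
  stop_arg(length(el) > 0, paste0("no HRIRs at azimuth ", azimuth))
  fs <- hrirs$sample_rate
  freqs <- 10^seq(log10(band[1]), log10(band[2]), length.out = n_freq)
  mag <- matrix(NA_real_, nrow = length(el), ncol = n_freq)
  for (i in seq_along(el)) {
    h <- hrir_at(hrirs, azimuth, el[i])[[ear]]
    if (all(abs(h) < 1e-14)) {
      warning("all-zero HRIR at elevation ", el[i], ": magnitude undefined",
              call. = FALSE)
      next
    }
    sp <- magnitude_spectrum(h, nfft)
    fgrid <- sp$f_index * fs / nfft
    mag[i, ] <- db(pmax(stats::approx(fgrid, sp$magnitude, xout = freqs)$y,
                        1e-12))
  }
  structure(list(ear = ear, elevations = el, frequencies = freqs,
                 magnitude = mag, condition = hrirs$condition),
            class = "spectral_map")
}

#' Difference between two spectral maps
#'
#' Elementwise magnitude difference (dB) of two maps on identical grids,
#' e.g. unoccluded minus transparency-mode.
#'
#' @param a,b [spectral_map()] objects with identical ear and grids.
#' @return A `spectral_map` holding `a$magnitude - b$magnitude`.
#' @export
spectral_difference <- function(a, b) {
  stop_arg(inherits(a, "spectral_map") && inherits(b, "spectral_map"),
           "inputs must be spectral_map objects")
  stop_arg(identical(a$ear, b$ear), "maps are for different ears")
  stop_arg(isTRUE(all.equal(a$elevations, b$elevations)) &&
             isTRUE(all.equal(a$frequencies, b$frequencies)),
           "spectral maps are on different grids")
  structure(list(ear = a$ear, elevations = a$elevations,
                 frequencies = a$frequencies,
                 magnitude = a$magnitude - b$magnitude,
                 condition = paste(a$condition, b$condition, sep = " - ")),
            class = "spectral_map")
}

#' @export
print.spectral_map <- function(x, ...) {
  cat("<spectral_map> ear=", x$ear, ", ", length(x$elevations),
      " elevations x ", length(x$frequencies), " frequencies (",
      round(min(x$frequencies)), "-", round(max(x$frequencies)), " Hz), ",
      "condition=", x$condition, "\n", sep = "")
  invisible(x)
}
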