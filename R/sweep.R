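# Exponential sine sweeps and inverse-sweep deconvolution for impulse
# response measurement.

#' Generate an exponential (logarithmic) sine sweep
#'
#' The excitation used for impulse-response measurement: instantaneous
#' frequency rises exponentially from `f_start` to `f_end` over `duration`,
#' \deqn{x(t) = \sin\left(\frac{2\pi f_1 T}{\ln(f_2/f_1)}
#'   \left(e^{t \ln(f_2/f_1)/T} - 1\right)\right),}
#' at unit amplitude. The instantaneous frequency at `duration/2` is the
#' geometric mean \eqn{\sqrt{f_1 f_2}}.
#'
#' @param f_start Start frequency, Hz (default 20).
#' @param f_end End frequency, Hz (default 20000).
#' @param duration Sweep duration, seconds (default 15).
#' @param sample_rate Sampling rate, Hz (default 44100).
#' @param fade Optional raised-cosine fade-in/out length, seconds, to limit
#'   band-edge ripple.
#' @return An object of class `ess_sweep`: list with `samples`,
#'   `sample_rate`, `f_start`, `f_end`, `duration`.
#' @export
make_log_sweep <- function(f_start = 20, f_end = 20000, duration = 15,
                           sample_rate = 44100, fade = 0.01) {
  stop_arg(f_start > 0 && f_start < f_end && f_end <= sample_rate / 2,
           "need 0 < f_start < f_end <= sample_rate/2")
  stop_arg(duration > 0, "`duration` must be > 0")
  n <- round(duration * sample_rate)
  t <- (0:(n - 1)) / sample_rate
  L <- log(f_end / f_start)
  x <- sin(2 * pi * f_start * duration / L * (exp(t * L / duration) - 1))
  if (fade > 0) {
    nf <- min(round(fade * sample_rate), floor(n / 4))
    if (nf > 1) {
      w <- 0.5 - 0.5 * cos(pi * (0:(nf - 1)) / (nf - 1))
      x[1:nf] <- x[1:nf] * w
      x[(n - nf + 1):n] <- x[(n - nf + 1):n] * rev(w)
    }
  }
  structure(list(samples = x, sample_rate = sample_rate,
                 f_start = f_start, f_end = f_end, duration = duration),
            class = "ess_sweep")
}

#' @export
print.ess_sweep <- function(x, ...) {
  cat("<ess_sweep> ", x$f_start, "-", x$f_end, " Hz, ", x$duration, " s at ",
      x$sample_rate, " Hz (", length(x$samples), " samples)\n", sep = "")
  invisible(x)
}

#' Inverse filter of an exponential sweep
#'
#' The time-reversed sweep with a +6 dB/octave amplitude modulation (a
#' decaying exponential envelope in time), such that `sweep` convolved with
#' its inverse approximates a band-limited unit impulse within
#' `[f_start, f_end]`. Applying the inverse filter twice is not an identity:
#' the inverse is specific to the forward sweep.
#'
#' @param sweep An [make_log_sweep()] object.
#' @return Numeric vector, the inverse filter, scaled so the sweep-inverse
#'   convolution peaks at 1.
#' @export
inverse_filter <- function(sweep) {
  stop_arg(inherits(sweep, "ess_sweep"), "`sweep` must be an ess_sweep")
  x <- sweep$samples
  n <- length(x)
  t <- (0:(n - 1)) / sweep$sample_rate
  R <- log(sweep$f_end / sweep$f_start) / sweep$duration
  inv <- rev(x) * exp(-t * R)
  # normalize so that conv(sweep, inverse) has unit peak
  p <- fft_conv(x, inv)
  inv / max(abs(p))
}

#' Recover a binaural impulse-response pair by inverse-sweep deconvolution
#'
#' Deconvolution is performed in the frequency domain by multiplying the
#' recording spectrum with the (regularized) inverse of the sweep spectrum
#' \eqn{\bar S(f) / (|S(f)|^2 + \epsilon)} - the spectral form of
#' convolution with the compensated inverse sweep, tractable at full
#' measurement length. Out-of-band content is controlled by the Tikhonov
#' term `reg`. Both ears are cropped with the same offset around the main
#' peak, so interaural timing is preserved exactly; only nonnegative lags
#' are kept, discarding harmonic-distortion artifacts that an exponential
#' sweep pushes to negative lags.
#'
#' @param recording A [binaural_recording()] (or any list with `left`,
#'   `right`, `sample_rate`).
#' @param sweep The [make_log_sweep()] object that was played back.
#' @param out_length Crop length in samples (default 2048, ~46 ms, ample
#'   for an anechoic dummy-head response).
#' @param pre_peak Samples retained before the main peak (within the
#'   nonnegative-lag constraint).
#' @param reg Relative Tikhonov regularization (fraction of the peak of
#'   `|S|^2`).
#' @return A list with `left`, `right` (length `out_length`),
#'   `sample_rate`, and `crop_offset` (samples, identical for both ears).
#' @export
deconvolve <- function(recording, sweep, out_length = 2048, pre_peak = 64,
                       reg = 1e-10) {
  stop_arg(inherits(sweep, "ess_sweep"), "`sweep` must be an ess_sweep")
  stop_arg(recording$sample_rate == sweep$sample_rate,
           "recording and sweep sample rates differ; resample first")
  nl <- length(recording$left)
  stop_arg(nl == length(recording$right),
           "left/right recordings must have equal length")
  stop_arg(nl >= length(sweep$samples), "recording is shorter than the sweep")

  ns <- length(sweep$samples)
  nfft <- next_pow2(nl + ns)
  S <- stats::fft(c(sweep$samples, rep(0, nfft - ns)))
  denom <- Mod(S)^2 + reg * max(Mod(S)^2)
  inv_spec <- Conj(S) / denom
  dec <- function(x) {
    X <- stats::fft(c(x, rep(0, nfft - length(x))))
    Re(stats::fft(X * inv_spec, inverse = TRUE)) / nfft
  }
  l <- dec(recording$left)
  r <- dec(recording$right)

  # main peak over both ears; identical crop offset preserves ITD
  search <- seq_len(min(nl, nfft)) # nonnegative lags only
  peak <- which.max(abs(l[search]) + abs(r[search]))
  start <- max(1L, peak - pre_peak)
  idx <- start:(start + out_length - 1L)
  idx <- idx[idx <= nfft]
  pad <- out_length - length(idx)
  list(left = c(l[idx], rep(0, pad)),
       right = c(r[idx], rep(0, pad)),
       sample_rate = sweep$sample_rate,
       crop_offset = start - 1L)
}
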