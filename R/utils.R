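# Internal numerical helpers shared across modules.

#' @keywords internal
"_PACKAGE"

## next power of two >= n
next_pow2 <- function(n) {
  2L^ceiling(log2(max(2, n)))
}

## full linear convolution of two real vectors via the FFT
fft_conv <- function(x, y) {
  nx <- length(x)
  ny <- length(y)
  nfft <- next_pow2(nx + ny - 1L)
  z <- Re(stats::fft(stats::fft(c(x, rep(0, nfft - nx))) *
                       stats::fft(c(y, rep(0, nfft - ny))), inverse = TRUE)) / nfft
  z[seq_len(nx + ny - 1L)]
}

## cross-correlation c(k) = sum_t L[t] R[t - k], restricted to |k| <= max_lag.
## Positive peak lag means the right-ear signal leads (arrives earlier).
xcorr_lags <- function(left, right, max_lag) {
  n <- length(left)
  nfft <- next_pow2(n + max_lag)
  cc <- Re(stats::fft(stats::fft(c(left, rep(0, nfft - n))) *
                        Conj(stats::fft(c(right, rep(0, nfft - n)))),
                      inverse = TRUE)) / nfft
  lags <- -max_lag:max_lag
  idx <- ifelse(lags >= 0, lags + 1L, nfft + lags + 1L)
  list(lags = lags, values = cc[idx])
}

db <- function(x) 20 * log10(x)

undb <- function(x) 10^(x / 20)

rms <- function(x) sqrt(mean(x^2))

deg2rad <- function(x) x * pi / 180

## raised-cosine transition: 0 below f0, 1 above f1, smooth in between
raised_cosine <- function(f, f0, f1) {
  w <- numeric(length(f))
  w[f >= f1] <- 1
  mid <- f > f0 & f < f1
  w[mid] <- 0.5 - 0.5 * cos(pi * (f[mid] - f0) / (f1 - f0))
  w
}

## Build a real impulse response of even length n from a one-sided magnitude
## spectrum (length n/2 + 1, on frequencies 0..fs/2) and a pure delay in
## seconds. Linear phase, so interaural timing is controlled exactly.
ir_from_magnitude <- function(mag, delay_s, n, fs) {
  stopifnot(length(mag) == n / 2 + 1, n %% 2 == 0)
  f <- (0:(n / 2)) * fs / n
  half <- mag * exp(-2i * pi * f * delay_s)
  full <- c(half, Conj(rev(half[2:(n / 2)])))
  Re(stats::fft(full, inverse = TRUE)) / n
}

## one-sided FFT magnitude of a real signal, zero-padded to nfft
magnitude_spectrum <- function(x, nfft) {
  X <- stats::fft(c(x, rep(0, nfft - length(x))))
  list(f_index = 0:(nfft / 2), magnitude = Mod(X[1:(nfft / 2 + 1)]))
}

stop_arg <- function(cond, msg) {
  if (!cond) stop(msg, call. = FALSE)
  invisible(TRUE)
}

## deterministic child seed derived from a master seed and a label,
## kept below 2^31 so it is a valid R integer seed
child_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 69069 + h) %% 2147483647)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
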