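# Exponential sweep generation and inverse-sweep deconvolution.

fs <- 44100

test_that("exponential sweep has the expected length and log-linear frequency track", {
  expect_length(make_log_sweep(duration = 15)$samples, 661500)
  sw <- make_log_sweep(100, 10000, duration = 1, sample_rate = fs, fade = 0)

  # instantaneous frequency from the analytic signal phase, estimated by
  # short-window zero-crossing counting; ridge must be linear in log f vs t
  n <- length(sw$samples)
  win <- 2205 # 50 ms
  starts <- seq(1, n - win, by = win)
  f_est <- vapply(starts, function(s) {
    seg <- sw$samples[s:(s + win - 1)]
    sum(diff(sign(seg)) != 0) / 2 / (win / fs)
  }, numeric(1))
  t_mid <- (starts + win / 2) / fs
  fit <- stats::lm(log(f_est) ~ t_mid)
  expect_gt(summary(fit)$r.squared, 0.999)

  # frequency at mid-sweep is the geometric mean of the edges (evaluated
  # on the fitted log-linear ridge, which averages out window quantization)
  f_mid <- exp(unname(stats::predict(fit, data.frame(t_mid = 0.5))))
  expect_equal(f_mid, sqrt(100 * 10000), tolerance = 0.02)
})

test_that("sweep parameter invariants are enforced", {
  expect_error(make_log_sweep(f_start = 0), "f_start")
  expect_error(make_log_sweep(f_start = 2000, f_end = 100), "f_start")
  expect_error(make_log_sweep(f_end = 40000), "f_start")
  expect_error(make_log_sweep(duration = 0), "duration")
})

test_that("inverse filter compresses the sweep to a clean band-limited pulse", {
  sw <- make_log_sweep(20, 20000, duration = 2, sample_rate = fs)
  inv <- inverse_filter(sw)
  expect_true(all(is.finite(inv)) && sum(inv^2) > 0)
  p <- hearspace:::fft_conv(sw$samples, inv)
  pk <- which.max(abs(p))
  # peak within one sample of the expected delay (sweep length)
  expect_lte(abs(pk - length(sw$samples)), 1)
  # sidelobes below -40 dB outside the band-limited mainlobe (+/-64 samples)
  side <- abs(p)
  side[(pk - 64):(pk + 64)] <- 0
  expect_lt(20 * log10(max(side) / abs(p[pk])), -40)
  # the inverse is sweep-specific: convolving it with itself does not
  # compress to a pulse (energy stays spread, unlike sweep * inverse)
  p2 <- hearspace:::fft_conv(inv, inv)
  pk2 <- which.max(abs(p2))
  lo <- max(1, pk2 - 64)
  hi <- min(length(p2), pk2 + 64)
  conc <- function(x, a, b) sum(x[a:b]^2) / sum(x^2)
  expect_gt(conc(p, pk - 64, pk + 64), 0.9)
  expect_lt(conc(p2, lo, hi), 0.5)
})

test_that("deconvolution round-trips a known 2-tap impulse response to <1% error", {
  sw <- make_log_sweep(5, 22050, duration = 2, sample_rate = fs, fade = 0.05)
  h <- c(1, rep(0, 4), 0.5, rep(0, 1018))
  rec_ch <- hearspace:::fft_conv(sw$samples, h)
  rec <- binaural_recording(rec_ch, rec_ch, fs)
  ir <- deconvolve(rec, sw, out_length = 1024, pre_peak = 0)
  est <- ir$left / max(abs(ir$left))
  expect_lt(sqrt(sum((est - h)^2) / sum(h^2)), 0.01)
})

test_that("deconvolution round-trips a synthetic HRIR through the sweep chain", {
  sw <- make_log_sweep(20, 20000, duration = 2, sample_rate = fs)
  set <- make_hrir_set(azimuths = c(-50, 50), elevations = 0, seed = 1)
  for (az in c(-50, 50)) {
    h <- hrir_at(set, az)
    rec <- render_recording(sw$samples, h, fs, target_level = 70)
    ir <- deconvolve(rec, sw, out_length = 1024)
    truth <- c(h$left, rep(0, 2048))[(ir$crop_offset + 1):(ir$crop_offset + 1024)]
    sc <- sum(ir$left * truth) / sum(ir$left^2)
    expect_lt(sqrt(sum((sc * ir$left - truth)^2) / sum(truth^2)), 0.01)
    # interaural timing survives the measurement chain exactly
    expect_equal(extract_itd(ir$left, ir$right, fs),
                 extract_itd(h$left, h$right, fs))
  }
})

test_that("deconvolution is linear and preserves a pure interaural delay", {
  sw <- make_log_sweep(5, 22050, duration = 1, sample_rate = fs, fade = 0.05)
  # both responses peak at lag 0, so all three deconvolutions share the
  # same crop offset and linearity can be compared sample-by-sample
  h1 <- c(1, rep(0, 255))
  h2 <- c(0.9, rep(0, 9), 0.4, rep(0, 245))
  r1 <- hearspace:::fft_conv(sw$samples, h1)
  r2 <- hearspace:::fft_conv(sw$samples, h2)
  d_sum <- deconvolve(binaural_recording(r1 + r2, r1 + r2, fs), sw,
                      out_length = 256, pre_peak = 0)
  d1 <- deconvolve(binaural_recording(r1, r1, fs), sw, out_length = 256,
                   pre_peak = 0)
  d2 <- deconvolve(binaural_recording(r2, r2, fs), sw, out_length = 256,
                   pre_peak = 0)
  expect_equal(d_sum$left, d1$left + d2$left, tolerance = 1e-6)

  # right ear delayed by 31 samples: left leads, ITD = -31/fs
  rR <- c(rep(0, 31), r1)[seq_along(r1)]
  ir <- deconvolve(binaural_recording(r1, rR, fs), sw, out_length = 256)
  expect_equal(extract_itd(ir$left, ir$right, fs), -31 / fs * 1e6)
})

test_that("degenerate deconvolution inputs are handled explicitly", {
  sw <- make_log_sweep(20, 20000, duration = 0.5, sample_rate = fs)
  z <- numeric(length(sw$samples))
  ir <- deconvolve(binaural_recording(z, z, fs), sw, out_length = 256)
  expect_equal(max(abs(ir$left)), 0)
  expect_error(deconvolve(binaural_recording(z, z, 48000), sw), "rate")
  short <- numeric(100)
  expect_error(deconvolve(binaural_recording(short, short, fs), sw),
               "shorter")
})
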