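# Synthetic dummy-head acoustics, transparency transform, stimuli,
# rendering, trials and trajectories.

fs <- 44100

test_that("head model calibration: midline symmetry and Woodworth-derived lateral ITD", {
  prof <- nh_profile()
  mid <- prof[prof$azimuth_deg == 0, ]
  expect_equal(mid$itd_us, 0)
  expect_equal(mid$ild_db, 0, tolerance = 1e-10)

  # effective radius from the closed-form inversion tau(90) = 700 us
  p <- head_model_params()
  expect_equal(p$effective_radius, 343 * 700e-6 / (pi / 2 + 1))

  # extracted lateral ITD within one sample period of 700 us
  lateral <- prof[abs(prof$azimuth_deg) == 90, ]
  expect_lt(max(abs(abs(lateral$itd_us) - 700)), 1e6 / fs)

  # broadband lateral ILD reaches the head-shadow calibration target
  expect_equal(max(abs(lateral$ild_db)), p$shadow_peak, tolerance = 0.1)
})

test_that("negating azimuth swaps the left and right impulse responses exactly", {
  set <- nh_set()
  for (az in c(10, 40, 90)) {
    a <- hrir_at(set, az)
    b <- hrir_at(set, -az)
    expect_identical(a$left, b$right)
    expect_identical(a$right, b$left)
  }
})

test_that("NH cue profile is monotone in azimuth and mirror-antisymmetric", {
  prof <- nh_profile()
  expect_true(all(diff(prof$itd_us) >= 0))
  neg <- prof[match(-prof$azimuth_deg, prof$azimuth_deg), ]
  expect_lt(max(abs(prof$itd_us + neg$itd_us)), 1)   # 1 us
  expect_lt(max(abs(prof$ild_db + neg$ild_db)), 0.1) # 0.1 dB
})

test_that("azimuths and elevations outside the measured grid are rejected", {
  expect_error(make_hrir_set(azimuths = c(0, 120)), "\\+/-90")
  expect_error(make_hrir_set(elevations = c(0, 45)), "\\+/-30")
})

test_that("identity transparency parameters leave extracted cues unchanged", {
  id <- transparency_params(ild_boost_peak = c(0, 0),
                            itd_perturbation_bound = 0,
                            spectral_flatten_cutoff = NULL,
                            processing_delay = 0)
  out <- cue_profile(apply_transparency(nh_set(), id, seed = 1))
  prof <- nh_profile()
  expect_equal(out$itd_us, prof$itd_us)
  expect_equal(out$ild_db, prof$ild_db, tolerance = 1e-9)
})

test_that("default transparency transform inflates ILD by 8 dB at -50 deg and spares ITD", {
  dild <- tm_profile()$ild_db - nh_profile()$ild_db
  ditd <- tm_profile()$itd_us - nh_profile()$itd_us
  az <- nh_profile()$azimuth_deg
  expect_equal(max(abs(dild)), 8.0, tolerance = 0.2)
  expect_equal(az[which.max(abs(dild))], -50)
  expect_lt(max(abs(ditd)), 45)
  # near the median plane the ILD residual collapses
  expect_lt(max(abs(dild[abs(az) <= 10])), 2.5)
})

test_that("transparency parameter invariants are enforced", {
  expect_error(transparency_params(itd_perturbation_bound = 50), "45")
  expect_error(transparency_params(spectral_flatten_cutoff = 3000), "5000")
  expect_error(transparency_params(ild_boost_peak = -1), ">= 0")
})

test_that("stimulus bursts are band-limited, sized, and seed-deterministic", {
  for (kind in c("BB", "LP", "HP", "buzzer")) {
    x <- generate_stimulus(kind, seed = 3)
    expect_length(x, 6615) # 150 ms at 44.1 kHz
    expect_equal(mean(x), 0, tolerance = 1e-12)
    expect_identical(x, generate_stimulus(kind, seed = 3))
  }
  # >= 99% of LP energy below 1.6 kHz (periodogram integration)
  x <- generate_stimulus("LP", seed = 3)
  sp <- Mod(stats::fft(x))^2
  f <- (0:(length(x) - 1)) * fs / length(x)
  f <- pmin(f, fs - f)
  expect_gte(sum(sp[f < 1600]) / sum(sp), 0.99)
  expect_error(generate_stimulus("chirp"), "BB, LP, HP, buzzer")
})

test_that("rendering tracks SNR bookkeeping and reduces to exact convolution in quiet", {
  set <- nh_set()
  h <- hrir_at(set, 30)
  src <- generate_stimulus("BB", seed = 4)
  nf <- noise_field()
  for (lev in c(50, 60, 70)) {
    rec <- render_recording(src, h, fs, target_level = lev, noise = nf,
                            hrirs_for_noise = set, seed = 5)
    expect_equal(rec$snr, lev - 55)
  }
  quiet <- render_recording(src, h, fs, target_level = 70)
  expect_null(quiet$snr)
  direct <- convolve(src, rev(h$left), type = "open")
  expect_equal(quiet$left / max(abs(quiet$left)), direct / max(abs(direct)),
               tolerance = 1e-9)
  expect_error(render_recording(numeric(0), h, fs), "non-empty")
  expect_error(render_recording(src, h, fs, target_level = -10), "positive")
})

test_that("rear noise azimuths fold to the nearest measured direction", {
  set <- nh_set()
  rec <- render_recording(generate_stimulus("BB", seed = 1), hrir_at(set, 0),
                          fs, noise = noise_field(), hrirs_for_noise = set,
                          seed = 1)
  folds <- attr(rec, "noise_folds")
  expect_equal(folds$used[folds$requested == 150], 90)
  expect_equal(folds$used[folds$requested == -110], -90)
  expect_equal(folds$used[folds$requested == 30], 30)
})

test_that("noiseless identity response model reproduces targets exactly", {
  tg <- data.frame(azimuth = seq(-90, 90, 10), elevation = rep(0, 19))
  tr <- simulate_trials(tg, model = identity_model(), seed = 6)
  expect_equal(tr$response_azimuth_deg, tg$azimuth)
  expect_equal(tr$response_elevation_deg, tg$elevation)
})

test_that("zero promptness spread yields constant reciprocal reaction times", {
  m <- identity_model()
  m$promptness_mean <- 4
  m$promptness_sd <- 0
  tg <- data.frame(azimuth = c(-10, 0, 10), elevation = c(0, 0, 0))
  tr <- simulate_trials(tg, model = m, seed = 7)
  expect_equal(tr$reaction_time_ms, rep(250, 3))
})

test_that("trial simulation rejects empty or out-of-range target sets", {
  expect_error(simulate_trials(data.frame(azimuth = numeric(0),
                                          elevation = numeric(0))),
               "at least one")
  expect_error(simulate_trials(data.frame(azimuth = 120, elevation = 0)),
               "\\+/-90")
})

test_that("fitting simulated trials recovers the generating gain and bias", {
  # parameter-recovery suite: 100 replicates at n = 500; the analytic 95%
  # OLS interval should cover the generating slope in >= 90% of them
  gen_gain <- 0.97
  gen_bias <- 0.72
  sdev <- 6.81 / sqrt(2 / pi)
  m <- identity_model(gain = gen_gain, bias = gen_bias, sd = sdev)
  hits_g <- logical(100)
  hits_b <- logical(100)
  set.seed(42)
  for (i in 1:100) {
    tg <- data.frame(azimuth = stats::runif(500, -90, 90), elevation = 0)
    tr <- simulate_trials(tg, model = m, seed = i)
    fit <- stats::lm(response_azimuth_deg ~ target_azimuth_deg, tr)
    ci <- stats::confint(fit)
    hits_g[i] <- ci[2, 1] <= gen_gain && gen_gain <= ci[2, 2]
    hits_b[i] <- ci[1, 1] <= gen_bias && gen_bias <= ci[1, 2]
  }
  expect_gte(mean(hits_g), 0.9)
  expect_gte(mean(hits_b), 0.9)
})

test_that("minimum-jerk trajectories have the closed-form peak speed and determinism", {
  tp <- trajectory_params(end_azimuth = 40, movement_duration = 400,
                          noise_sd = 0)
  tr <- simulate_trajectory(tp, seed = 8)
  gt <- attr(tr, "ground_truth")
  expect_equal(gt$peak_speed, 15 / 8 * 40 / 0.4) # 187.5 deg/s
  tp2 <- trajectory_params()
  expect_identical(simulate_trajectory(tp2, seed = 9),
                   simulate_trajectory(tp2, seed = 9))
  # zero-length movement: flagged, no ground-truth onset
  still <- simulate_trajectory(trajectory_params(end_azimuth = 0,
                                                 noise_sd = 0), seed = 1)
  expect_true(is.na(attr(still, "ground_truth")$onset_s))
})
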