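# Movement detection, localization regression, MAE, promptness, pooling.

test_that("movement detection finds the threshold crossing of a known movement", {
  tp <- trajectory_params(end_azimuth = 40, movement_latency = 300,
                          movement_duration = 400, noise_sd = 0)
  tr <- simulate_trajectory(tp, seed = 1)
  gt <- attr(tr, "ground_truth")
  ev <- detect_movement(tr)
  expect_true(ev$moved)
  expect_lt(abs(ev$onset_s - gt$onset_s), 1 / 120) # one tracker sample
  expect_equal(ev$reaction_time_ms, ev$onset_s * 1000)
  expect_gt(ev$offset_s, ev$onset_s)
  expect_equal(ev$final_azimuth, 40, tolerance = 1)
})

test_that("stationary trajectories raise the no-movement flag", {
  still <- simulate_trajectory(trajectory_params(end_azimuth = 0,
                                                 noise_sd = 0), seed = 2)
  ev <- detect_movement(still)
  expect_false(ev$moved)
  expect_true(is.na(ev$onset_s))
  # with realistic tracker noise the detector still stays quiet
  noisy <- simulate_trajectory(trajectory_params(end_azimuth = 0), seed = 3)
  expect_false(detect_movement(noisy)$moved)
})

test_that("detection is invariant to a constant orientation offset", {
  tr <- simulate_trajectory(trajectory_params(), seed = 4)
  shifted <- tr
  shifted$azimuth_deg <- shifted$azimuth_deg + 55
  shifted$elevation_deg <- shifted$elevation_deg - 20
  attr(shifted, "tracker_rate") <- attr(tr, "tracker_rate")
  a <- detect_movement(tr)
  b <- detect_movement(shifted)
  expect_equal(a$onset_s, b$onset_s)
  expect_equal(a$offset_s, b$offset_s)
})

test_that("perfect responses yield gain 1, bias 0, r2 1 and MAE 0", {
  tg <- seq(-90, 90, 10)
  fit <- fit_localization(trial_fixture(tg, tg), "azimuth")
  expect_equal(fit$gain, 1)
  expect_equal(fit$bias, 0)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$mae, 0)
})

test_that("flat responses yield zero gain with the constant as bias", {
  fit <- fit_localization(trial_fixture(c(-30, 0, 30), c(12, 12, 12)),
                          "azimuth")
  expect_equal(fit$gain, 0)
  expect_equal(fit$bias, 12)
})

test_that("regression matches the hand-computed 3-point least-squares solution", {
  # targets (-30, 0, 30), responses (-20, 5, 30):
  # slope = sum((x - xbar)(y - ybar)) / sum((x - xbar)^2) = 1500/1800 = 5/6
  # intercept = ybar - slope * xbar = 5
  fit <- fit_localization(trial_fixture(c(-30, 0, 30), c(-20, 5, 30)),
                          "azimuth")
  expect_equal(fit$gain, 25 / 30)
  expect_equal(fit$bias, 5)
})

test_that("degenerate fits are explicit errors", {
  expect_error(fit_localization(trial_fixture(0, 0), "azimuth"),
               "at least 2")
  expect_error(fit_localization(trial_fixture(c(10, 10), c(1, 2)), "azimuth"),
               "identical")
})

test_that("MAE is the mean absolute target-response deviation", {
  expect_equal(mean_absolute_error(trial_fixture(c(0, 0), c(5, -15))), 10)
  tg <- c(-40, 10, 60)
  rs <- c(-30, -5, 70)
  expect_equal(mean_absolute_error(trial_fixture(tg, rs)),
               mean_absolute_error(trial_fixture(-tg, -rs)))
})

test_that("promptness is the reciprocal reaction time in 1/s", {
  expect_equal(promptness(250), 4)
  expect_equal(promptness(1000), 1)
  rt <- seq(100, 2000, by = 100)
  expect_true(all(diff(promptness(rt)) < 0))
  expect_error(promptness(-5), "positive")
})

test_that("pooling concatenates trials before fitting", {
  set.seed(31)
  tg <- stats::runif(40, -90, 90)
  rs <- 0.9 * tg + stats::rnorm(40, 0, 5)
  one <- trial_fixture(tg, rs)
  pooled <- pool_conditions(one, grouping = "condition",
                            dimensions = "azimuth")
  direct <- fit_localization(one, "azimuth")
  expect_equal(pooled$gain, direct$gain)
  expect_equal(pooled$mae, direct$mae)

  # duplicating the trial set leaves the OLS solution unchanged
  dup <- rbind(one, one)
  pooled2 <- pool_conditions(dup, grouping = "condition",
                             dimensions = "azimuth")
  expect_equal(pooled2$gain, direct$gain)
  expect_equal(pooled2$bias, direct$bias)

  # pooled MAE = trial-count-weighted mean of per-set MAEs
  two <- trial_fixture(tg[1:10] / 2, rs[1:10])
  both <- rbind(one, two)
  w <- c(nrow(one), nrow(two))
  expect_equal(mean_absolute_error(both),
               sum(w * c(mean_absolute_error(one),
                         mean_absolute_error(two))) / sum(w))
  expect_error(pool_conditions(one, grouping = "nonexistent"),
               "nonexistent")
})

test_that("r2 stays in [0,1] and is 1 only for zero residuals", {
  set.seed(32)
  for (i in 1:20) {
    tg <- stats::runif(15, -90, 90)
    rs <- stats::runif(15, -90, 90)
    fit <- fit_localization(trial_fixture(tg, rs), "azimuth")
    expect_gte(fit$r_squared, 0)
    expect_lte(fit$r_squared, 1)
    if (fit$r_squared == 1) {
      res <- rs - (fit$bias + fit$gain * tg)
      expect_equal(max(abs(res)), 0)
    }
  }
})

test_that("MAE converges to sd * sqrt(2/pi) for unbiased Gaussian scatter", {
  sdev <- 8
  m <- identity_model(gain = 1, bias = 0, sd = sdev)
  tg <- with(list(), {
    set.seed(33)
    data.frame(azimuth = stats::runif(2000, -90, 90), elevation = 0)
  })
  tr <- simulate_trials(tg, model = m, seed = 34)
  expect_equal(mean_absolute_error(tr, "azimuth"), sdev * sqrt(2 / pi),
               tolerance = 0.05)
})
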