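# Simulation of listener responses and head trajectories.

#' Simulate localization trials from a linear response model
#'
#' Draws one response per target from the linear target-response model
#' `response = bias + gain * target + Gaussian scatter` independently for
#' azimuth and elevation, with parameters looked up in the
#' [behavior_model()] table by (condition, stimulus, dimension). Reaction
#' times are the reciprocal of a promptness drawn from a positive-truncated
#' normal, so they are strictly positive and positively skewed.
#'
#' @param targets Data frame with columns `azimuth` and `elevation`
#'   (degrees), within +/-90 and +/-30 respectively.
#' @param condition Condition label present in `model`.
#' @param stimulus Stimulus label present in `model`.
#' @param model A [behavior_model()]-style table.
#' @param listener_id Listener label.
#' @param level Presentation level, dBA.
#' @param snr SNR label, dB, or `NA` for quiet.
#' @param seed Integer seed.
#' @return A data frame of class `trial_table` with columns `listener_id`,
#'   `condition`, `stimulus`, `level_dba`, `snr_db`,
#'   `target_azimuth_deg`, `target_elevation_deg`, `response_azimuth_deg`,
#'   `response_elevation_deg`, `reaction_time_ms`.
#' @export
simulate_trials <- function(targets, condition = "NH", stimulus = "BB",
                            model = behavior_model(), listener_id = "S01",
                            level = 60, snr = NA, seed = default_seed()) {
  stop_arg(nrow(targets) > 0, "`targets` must contain at least one trial")
  stop_arg(all(abs(targets$azimuth) <= 90),
           "target azimuths must be within +/-90 degrees")
  stop_arg(all(abs(targets$elevation) <= 30),
           "target elevations must be within +/-30 degrees")
  row_for <- function(dim) {
    r <- model[model$condition == condition & model$stimulus == stimulus &
                 model$dimension == dim, ]
    stop_arg(nrow(r) == 1, paste0("no unique model row for (", condition,
                                  ", ", stimulus, ", ", dim, ")"))
    r
  }
  ma <- row_for("azimuth")
  me <- row_for("elevation")
  n <- nrow(targets)
  with_seed(child_seed(seed, paste(listener_id, condition, stimulus, level,
                                   snr, sep = "-")), {
    resp_az <- ma$bias + ma$gain * targets$azimuth +
      stats::rnorm(n, 0, ma$response_sd)
    resp_el <- me$bias + me$gain * targets$elevation +
      stats::rnorm(n, 0, me$response_sd)
    # promptness (1/s), truncated positive; RT = 1/promptness
    p <- stats::rnorm(n, ma$promptness_mean, ma$promptness_sd)
    while (any(p <= 0)) {
      p[p <= 0] <- stats::rnorm(sum(p <= 0), ma$promptness_mean,
                                ma$promptness_sd)
    }
    out <- data.frame(listener_id = listener_id, condition = condition,
                      stimulus = stimulus, level_dba = level, snr_db = snr,
                      target_azimuth_deg = targets$azimuth,
                      target_elevation_deg = targets$elevation,
                      response_azimuth_deg = resp_az,
                      response_elevation_deg = resp_el,
                      reaction_time_ms = 1000 / p)
    class(out) <- c("trial_table", "data.frame")
    out
  })
}

## minimum-jerk position profile on s in [0, 1]
min_jerk_s <- function(s) 10 * s^3 - 15 * s^4 + 6 * s^5

#' Simulate a head-orientation trajectory
#'
#' A minimum-jerk angular path from the start to the end orientation,
#' beginning `movement_latency` after stimulus onset (time 0), sampled at
#' `tracker_rate` with additive Gaussian position noise. The minimum-jerk
#' speed profile is \eqn{v(s) = 30 s^2 (1-s)^2 \, A / T}, peaking at
#' \eqn{(15/8) A / T} mid-movement, where `A` is the total angular
#' amplitude and `T` the movement duration.
#'
#' The returned trajectory carries ground truth as attributes: the first
#' and last times the noiseless path's angular speed crosses `threshold`,
#' and the peak speed. A zero-length movement is flagged (`onset = NA`).
#'
#' @param params A [trajectory_params()] object.
#' @param threshold Detection threshold the ground truth refers to,
#'   degrees/s.
#' @param seed Integer seed for the tracker noise.
#' @return A data frame of class `trajectory` with columns `time_s`,
#'   `azimuth_deg`, `elevation_deg`; attributes `tracker_rate` and
#'   `ground_truth` (list with `onset_s`, `offset_s`, `peak_speed`).
#' @export
simulate_trajectory <- function(params = trajectory_params(), threshold = 20,
                                seed = default_seed()) {
  stop_arg(inherits(params, "trajectory_params"),
           "`params` must be a trajectory_params object")
  rate <- params$tracker_rate
  lat <- params$movement_latency / 1000
  dur <- params$movement_duration / 1000
  total <- lat + dur + params$hold_time / 1000
  t <- seq(0, total, by = 1 / rate)
  s <- pmin(pmax((t - lat) / dur, 0), 1)
  daz <- params$end_azimuth - params$start_azimuth
  del <- params$end_elevation - params$start_elevation
  az <- params$start_azimuth + daz * min_jerk_s(s)
  el <- params$start_elevation + del * min_jerk_s(s)

  amp <- sqrt(daz^2 + del^2)
  peak_speed <- 15 / 8 * amp / dur
  if (amp == 0 || peak_speed <= threshold) {
    gt <- list(onset_s = NA_real_, offset_s = NA_real_,
               peak_speed = peak_speed)
  } else {
    # solve 30 s^2 (1-s)^2 * amp / dur = threshold on the rising flank
    f <- function(s) 30 * s^2 * (1 - s)^2 * amp / dur - threshold
    s_on <- stats::uniroot(f, c(0, 0.5), tol = 1e-10)$root
    gt <- list(onset_s = lat + s_on * dur,
               offset_s = lat + (1 - s_on) * dur,
               peak_speed = peak_speed)
  }
  if (params$noise_sd > 0) {
    noise <- with_seed(child_seed(seed, "tracker-noise"), {
      matrix(stats::rnorm(2 * length(t), 0, params$noise_sd), ncol = 2)
    })
    az <- az + noise[, 1]
    el <- el + noise[, 2]
  }
  out <- data.frame(time_s = t, azimuth_deg = az, elevation_deg = el)
  class(out) <- c("trajectory", "data.frame")
  attr(out, "tracker_rate") <- rate
  attr(out, "ground_truth") <- gt
  out
}
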