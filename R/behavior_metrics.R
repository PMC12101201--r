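# Localization metrics: movement detection, target-response regression,
# mean absolute error, promptness.

#' Detect head-movement onset and offset by a velocity threshold
#'
#' Angular speed is computed from central differences of the
#' low-pass-smoothed (default 10 Hz, zero-phase) azimuth/elevation series,
#' combined as the magnitude of the 2-D angular velocity vector. The
#' movement onset is the first time the speed exceeds `threshold`
#' (optionally sustained for `min_above` seconds), and the offset is the
#' first subsequent time it stays below the threshold for `min_below`
#' seconds. The reaction time is the onset relative to stimulus onset at
#' time 0; the final response position is the orientation at offset.
#'
#' Smoothing before differentiation keeps tracker noise from triggering the
#' threshold spuriously; the detection decision is invariant to adding a
#' constant offset to the whole trajectory.
#'
#' @param traj A [simulate_trajectory()]-style data frame (`time_s`,
#'   `azimuth_deg`, `elevation_deg`) with a `tracker_rate` attribute, or
#'   pass `rate`.
#' @param threshold Velocity threshold, degrees/s (default 20, > 0).
#' @param rate Tracker rate, Hz (defaults to the trajectory attribute).
#' @param smooth_cutoff Position low-pass cutoff, Hz; `NULL` disables.
#' @param min_above Sustain time above threshold required for an onset, s.
#' @param min_below Sustain time below threshold defining the offset, s.
#' @return A list of class `movement_event`: `moved`, `onset_s`,
#'   `offset_s`, `reaction_time_ms`, `final_azimuth`, `final_elevation`,
#'   `peak_speed`. If the speed never exceeds the threshold, `moved` is
#'   `FALSE` and the remaining fields are `NA` (trial to be excluded and
#'   logged downstream).
#' @export
detect_movement <- function(traj, threshold = 20, rate = NULL,
                            smooth_cutoff = 10, min_above = 0,
                            min_below = 0.1) {
  stop_arg(threshold > 0, "`threshold` must be > 0")
  if (is.null(rate)) rate <- attr(traj, "tracker_rate")
  stop_arg(!is.null(rate), "tracker rate not given and not found on `traj`")
  az <- traj$azimuth_deg
  el <- traj$elevation_deg
  t <- traj$time_s
  n <- length(t)
  stop_arg(n >= 5, "trajectory too short")
  if (!is.null(smooth_cutoff) && smooth_cutoff < rate / 2) {
    flt <- signal::butter(2, smooth_cutoff / (rate / 2), type = "low")
    # odd-reflection padding avoids start/end transients of the zero-phase
    # filter, which would otherwise masquerade as head movements
    smooth_lp <- function(x) {
      pad <- min(n - 1L, ceiling(3 * rate / smooth_cutoff))
      xp <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
      signal::filtfilt(flt, xp)[(pad + 1):(pad + n)]
    }
    az <- smooth_lp(az)
    el <- smooth_lp(el)
  }
  vaz <- c(0, (az[3:n] - az[1:(n - 2)]) * rate / 2, 0)
  vel <- c(0, (el[3:n] - el[1:(n - 2)]) * rate / 2, 0)
  speed <- sqrt(vaz^2 + vel^2)

  k_above <- max(1L, round(min_above * rate))
  k_below <- max(1L, round(min_below * rate))
  above <- speed > threshold
  onset_idx <- NA_integer_
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- which(r$values & r$lengths >= k_above)
  if (length(ok) > 0) onset_idx <- starts[ok[1]]
  if (is.na(onset_idx)) {
    return(structure(list(moved = FALSE, onset_s = NA_real_,
                          offset_s = NA_real_, reaction_time_ms = NA_real_,
                          final_azimuth = NA_real_,
                          final_elevation = NA_real_,
                          peak_speed = max(speed)),
                     class = "movement_event"))
  }
  offset_idx <- n
  ok_below <- which(!r$values & r$lengths >= k_below & starts > onset_idx)
  if (length(ok_below) > 0) offset_idx <- starts[ok_below[1]]
  structure(list(moved = TRUE,
                 onset_s = t[onset_idx],
                 offset_s = t[offset_idx],
                 reaction_time_ms = t[onset_idx] * 1000,
                 final_azimuth = traj$azimuth_deg[offset_idx],
                 final_elevation = traj$elevation_deg[offset_idx],
                 peak_speed = max(speed)),
            class = "movement_event")
}

#' @export
print.movement_event <- function(x, ...) {
  if (!x$moved) {
    cat("<movement_event> no movement detected (peak speed ",
        round(x$peak_speed, 1), " deg/s)\n", sep = "")
  } else {
    cat("<movement_event> onset ", round(x$onset_s * 1000), " ms, offset ",
        round(x$offset_s * 1000), " ms, final (",
        round(x$final_azimuth, 1), ", ", round(x$final_elevation, 1),
        ") deg\n", sep = "")
  }
  invisible(x)
}

dim_cols <- function(dimension) {
  dimension <- match.arg(dimension, c("azimuth", "elevation"))
  list(target = paste0("target_", dimension, "_deg"),
       response = paste0("response_", dimension, "_deg"))
}

#' Fit the target-response localization regression
#'
#' Ordinary least-squares fit of response on target in one dimension,
#' `response = bias + gain * target`, returning the gain (slope,
#' dimensionless), bias (intercept, degrees), the coefficient of
#' determination r-squared of the fit, and the mean absolute error over the
#' same trials. A perfect localizer yields gain 1, bias 0 degrees and
#' r-squared 1.
#'
#' @param trials A trial table (see [simulate_trials()] for columns).
#' @param dimension `"azimuth"` or `"elevation"`.
#' @return An object of class `localization_fit`: list with `dimension`,
#'   `gain`, `bias`, `r_squared`, `mae`, `n_trials`.
#' @export
#' @examples
#' tg <- data.frame(azimuth = seq(-90, 90, 10), elevation = 0)
#' tr <- simulate_trials(tg, model = within(behavior_model(), {
#'   gain <- 1; bias <- 0; response_sd <- 0
#' }))
#' fit_localization(tr, "azimuth") # gain 1, bias 0, r2 1, mae 0
fit_localization <- function(trials, dimension = "azimuth") {
  cols <- dim_cols(dimension)
  x <- trials[[cols$target]]
  y <- trials[[cols$response]]
  stop_arg(!is.null(x) && !is.null(y),
           paste0("trial table lacks ", cols$target, "/", cols$response))
  stop_arg(length(x) >= 2, "need at least 2 trials for a regression fit")
  stop_arg(length(unique(x)) >= 2,
           "all targets identical: localization fit undefined")
  fit <- stats::lm(y ~ x)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) as.numeric(ss_res == 0) else 1 - ss_res / ss_tot
  structure(list(dimension = dimension,
                 gain = unname(stats::coef(fit)[2]),
                 bias = unname(stats::coef(fit)[1]),
                 r_squared = max(0, min(1, r2)),
                 mae = mean(abs(y - x)),
                 n_trials = length(x)),
            class = "localization_fit")
}

#' @export
print.localization_fit <- function(x, ...) {
  cat("<localization_fit> ", x$dimension, ": gain=", signif(x$gain, 3),
      ", bias=", signif(x$bias, 3), " deg, r2=", signif(x$r_squared, 3),
      ", MAE=", signif(x$mae, 3), " deg (n=", x$n_trials, ")\n", sep = "")
  invisible(x)
}

#' Mean absolute localization error
#'
#' \eqn{MAE = (1/N) \sum_n |response_n - target_n|} in the chosen
#' dimension, degrees.
#'
#' @inheritParams fit_localization
#' @return MAE in degrees.
#' @export
mean_absolute_error <- function(trials, dimension = "azimuth") {
  cols <- dim_cols(dimension)
  x <- trials[[cols$target]]
  y <- trials[[cols$response]]
  stop_arg(!is.null(x) && !is.null(y) && length(x) >= 1,
           "need at least 1 trial with target and response columns")
  mean(abs(y - x))
}

#' Promptness: the reciprocal of reaction time
#'
#' Reaction-time distributions are positively skewed; their reciprocals
#' (promptness, 1/s) are closer to normal and are used for statistical
#' comparison. Higher promptness = faster response.
#'
#' @param reaction_time_ms Reaction time(s) in milliseconds, > 0.
#' @return Promptness in 1/s.
#' @export
#' @examples
#' promptness(250) # 4
promptness <- function(reaction_time_ms) {
  stop_arg(all(reaction_time_ms > 0), "reaction times must be positive")
  1000 / reaction_time_ms
}

#' Pool trials and fit localization metrics per group
#'
#' Concatenates trials within each group defined by `grouping` (pooling at
#' the trial level, so pooled fits equal fits of the concatenated trials)
#' and fits the localization regression in each requested dimension.
#'
#' @param trials A trial table.
#' @param grouping Character vector of grouping column names present in
#'   `trials` (e.g. `c("listener_id", "condition", "stimulus")`).
#' @param dimensions Dimensions to fit.
#' @return A data frame with one row per group x dimension: the grouping
#'   keys plus `dimension`, `gain`, `bias`, `r_squared`, `mae`, `n_trials`.
#' @export
pool_conditions <- function(trials, grouping = c("condition", "stimulus"),
                            dimensions = c("azimuth", "elevation")) {
  missing_keys <- setdiff(grouping, names(trials))
  stop_arg(length(missing_keys) == 0,
           paste0("unknown grouping key(s): ",
                  paste(missing_keys, collapse = ", ")))
  groups <- split(trials, trials[grouping], drop = TRUE)
  rows <- list()
  for (g in names(groups)) {
    gt <- groups[[g]]
    for (d in dimensions) {
      fit <- fit_localization(gt, d)
      key <- gt[1, grouping, drop = FALSE]
      rows[[length(rows) + 1L]] <- cbind(
        key,
        data.frame(dimension = d, gain = fit$gain, bias = fit$bias,
                   r_squared = fit$r_squared, mae = fit$mae,
                   n_trials = fit$n_trials),
        row.names = NULL)
    }
  }
  do.call(rbind, rows)
}
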