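# Parameter objects for the synthetic dummy-head and listener models.

#' Spherical-head model parameters
#'
#' Parameters of the parametric dummy-head model used to synthesize
#' head-related impulse responses (HRIRs): a Woodworth-type interaural delay,
#' a first-order frequency-dependent head-shadow level difference, and a
#' single elevation-dependent pinna notch.
#'
#' The default `effective_radius` is not assumed but derived by inverting the
#' Woodworth delay formula \eqn{\tau(\theta) = (r/c)(\theta + \sin\theta)} at
#' \eqn{\theta = 90^\circ} so that the lateral-extreme interaural time
#' difference (ITD) equals 700 microseconds, the upper end of the
#' physiological range. With `speed_of_sound = 343` m/s this gives
#' \eqn{r = c \cdot 700\,\mu s / (\pi/2 + 1) \approx 9.34} cm.
#'
#' `shadow_peak` is the broadband interaural level difference (ILD), in dB,
#' reached at +/-90 degrees azimuth in the 3--20 kHz band; the default
#' 18.5 dB places the lateral ILD span inside the 17--20 dB range typical of
#' an adult-sized dummy head. The pinna notch is centered at
#' `notch_base_freq + notch_slope * elevation` and must stay above 5 kHz,
#' the band where in-ear devices are known to erase spectral detail.
#'
#' @param effective_radius Effective head radius in meters. Default derived
#'   from the 700 microsecond lateral ITD (see Details).
#' @param speed_of_sound Speed of sound in m/s.
#' @param shadow_peak Maximum broadband ILD magnitude at +/-90 degrees, dB.
#' @param notch_base_freq Pinna-notch center frequency at 0 degrees
#'   elevation, Hz. Must exceed 5000 Hz.
#' @param notch_slope Notch-center shift per degree of elevation, Hz/degree.
#' @param notch_depth Notch depth, dB.
#' @param notch_width_oct Notch half-width in octaves (Gaussian profile on a
#'   log-frequency axis).
#' @param sample_rate Sampling rate, Hz.
#' @param ir_length HRIR length in samples (even).
#' @param bulk_delay_s Common acoustic bulk delay applied to both ears, s.
#'
#' @return An object of class `head_model_params`.
#' @export
#' @examples
#' p <- head_model_params()
#' p$effective_radius # ~0.0934 m, from the 700 us Woodworth inversion
head_model_params <- function(effective_radius = NULL,
                              speed_of_sound = 343,
                              shadow_peak = 18.5,
                              notch_base_freq = 8000,
                              notch_slope = 50,
                              notch_depth = 15,
                              notch_width_oct = 0.15,
                              sample_rate = 44100,
                              ir_length = 1024,
                              bulk_delay_s = 128 / 44100) {
  if (is.null(effective_radius)) {
    effective_radius <- speed_of_sound * 700e-6 / (pi / 2 + 1)
  }
  stop_arg(effective_radius > 0, "`effective_radius` must be > 0")
  stop_arg(speed_of_sound > 0, "`speed_of_sound` must be > 0")
  stop_arg(notch_base_freq > 5000,
           "`notch_base_freq` must be > 5000 Hz (pinna notches live above 5 kHz)")
  stop_arg(sample_rate > 0, "`sample_rate` must be > 0")
  stop_arg(ir_length %% 2 == 0 && ir_length >= 64,
           "`ir_length` must be even and >= 64")
  structure(list(effective_radius = effective_radius,
                 speed_of_sound = speed_of_sound,
                 shadow_peak = shadow_peak,
                 notch_base_freq = notch_base_freq,
                 notch_slope = notch_slope,
                 notch_depth = notch_depth,
                 notch_width_oct = notch_width_oct,
                 sample_rate = sample_rate,
                 ir_length = ir_length,
                 bulk_delay_s = bulk_delay_s),
            class = "head_model_params")
}

#' Transparency-mode transform parameters
#'
#' Parameters of the parametric hear-through transform applied to an HRIR
#' set. The transform (i) inflates interaural level differences by signed
#' Gaussian bumps centered off-axis, (ii) perturbs interaural time
#' differences by at most `itd_perturbation_bound`, (iii) flattens the
#' magnitude spectrum above `spectral_flatten_cutoff` (removing
#' elevation-dependent pinna notches), and (iv) delays both ears by a common
#' `processing_delay`.
#'
#' The defaults are calibrated to acoustic measurements of a first-generation
#' consumer hearable in transparency mode: ILD inflation peaking at 8.0 dB
#' near -50 degrees azimuth and 7.5 dB near +40 degrees, ITD deviations well
#' under 45 microseconds, and spectral detail erased above 5 kHz. Each ILD
#' bump is applied in the direction that amplifies the natural level
#' difference on its side of the head (sign taken from the bump-center
#' azimuth), which reproduces the measured left/right asymmetry.
#'
#' @param ild_boost_peak Peak ILD inflation per bump, dB (vector, one per
#'   bump). Must be >= 0.
#' @param ild_boost_azimuth Bump-center azimuths, degrees (same length).
#' @param ild_boost_width Gaussian bump standard deviation(s), degrees.
#' @param spectral_flatten_cutoff Flattening cutoff, Hz (>= 5000). `NULL`
#'   disables flattening.
#' @param itd_perturbation_bound Bound on per-direction ITD jitter,
#'   microseconds; must be < 45. Jitter is drawn uniformly in
#'   `[-bound, bound]`.
#' @param processing_delay Common pass-through latency, ms.
#' @param boost_band Two-element frequency range (Hz) over which the ILD
#'   gain is applied at full strength; tapered to zero below its lower edge.
#' @return An object of class `transparency_params`.
#' @export
transparency_params <- function(ild_boost_peak = c(8.0, 7.5),
                                ild_boost_azimuth = c(-50, 40),
                                ild_boost_width = c(20, 20),
                                spectral_flatten_cutoff = 5000,
                                itd_perturbation_bound = 20,
                                processing_delay = 0.5,
                                boost_band = c(2000, 20000)) {
  stop_arg(all(ild_boost_peak >= 0), "`ild_boost_peak` must be >= 0")
  stop_arg(length(ild_boost_azimuth) == length(ild_boost_peak),
           "`ild_boost_azimuth` and `ild_boost_peak` must have equal length")
  if (length(ild_boost_width) == 1L) {
    ild_boost_width <- rep(ild_boost_width, length(ild_boost_peak))
  }
  stop_arg(all(ild_boost_width > 0), "`ild_boost_width` must be > 0")
  stop_arg(is.null(spectral_flatten_cutoff) || spectral_flatten_cutoff >= 5000,
           "`spectral_flatten_cutoff` must be >= 5000 Hz")
  stop_arg(itd_perturbation_bound >= 0 && itd_perturbation_bound < 45,
           "`itd_perturbation_bound` must be in [0, 45) microseconds")
  stop_arg(processing_delay >= 0, "`processing_delay` must be >= 0")
  structure(list(ild_boost_peak = ild_boost_peak,
                 ild_boost_azimuth = ild_boost_azimuth,
                 ild_boost_width = ild_boost_width,
                 spectral_flatten_cutoff = spectral_flatten_cutoff,
                 itd_perturbation_bound = itd_perturbation_bound,
                 processing_delay = processing_delay,
                 boost_band = boost_band),
            class = "transparency_params")
}

#' Diffuse background-noise field
#'
#' Describes the spatial noise field used in the in-noise conditions:
#' continuous Gaussian white noise distributed over eight loudspeakers at
#' +/-30, +/-70, +/-110 and +/-150 degrees azimuth (0 degrees elevation) at
#' a fixed overall level of 55 dBA. Noise onset leads the target by a
#' randomized 200--300 ms.
#'
#' @param noise_azimuths Azimuths of the noise sources, degrees.
#' @param noise_level Overall noise level, dBA.
#' @param onset_lead Two-element range of noise-to-target lead times, ms.
#' @return An object of class `noise_field`.
#' @export
noise_field <- function(noise_azimuths = c(-150, -110, -70, -30, 30, 70, 110, 150),
                        noise_level = 55,
                        onset_lead = c(200, 300)) {
  stop_arg(noise_level > 0, "`noise_level` must be > 0")
  stop_arg(all(abs(noise_azimuths) <= 180),
           "all `noise_azimuths` must be within +/-180 degrees")
  structure(list(noise_azimuths = noise_azimuths,
                 noise_level = noise_level,
                 onset_lead = onset_lead),
            class = "noise_field")
}

#' Head-trajectory generator parameters
#'
#' Parameters for a simulated goal-directed head movement: a minimum-jerk
#' angular path from the start to the end orientation, beginning at
#' `movement_latency` after stimulus onset, sampled at `tracker_rate`, with
#' additive Gaussian position noise emulating optical-tracker jitter.
#'
#' @param start_azimuth,start_elevation Starting orientation, degrees.
#' @param end_azimuth,end_elevation Final orientation, degrees.
#' @param movement_latency Time from stimulus onset to movement start, ms.
#' @param movement_duration Movement duration, ms (> 0).
#' @param tracker_rate Tracker sampling rate, Hz (> 0).
#' @param noise_sd Tracker position noise, degrees (sd).
#' @param hold_time Stationary recording time appended after movement end, ms.
#' @return An object of class `trajectory_params`.
#' @export
trajectory_params <- function(start_azimuth = 0, start_elevation = 0,
                              end_azimuth = 40, end_elevation = 0,
                              movement_latency = 300,
                              movement_duration = 400,
                              tracker_rate = 120,
                              noise_sd = 0.1,
                              hold_time = 300) {
  stop_arg(movement_duration > 0, "`movement_duration` must be > 0")
  stop_arg(tracker_rate > 0, "`tracker_rate` must be > 0")
  stop_arg(noise_sd >= 0, "`noise_sd` must be >= 0")
  structure(list(start_azimuth = start_azimuth,
                 start_elevation = start_elevation,
                 end_azimuth = end_azimuth,
                 end_elevation = end_elevation,
                 movement_latency = movement_latency,
                 movement_duration = movement_duration,
                 tracker_rate = tracker_rate,
                 noise_sd = noise_sd,
                 hold_time = hold_time),
            class = "trajectory_params")
}

#' Default behavioral response model
#'
#' A table of linear target-response model parameters per (condition,
#' stimulus, dimension): response = bias + gain * target + Gaussian scatter,
#' and reaction times drawn as the reciprocal of a positive-truncated normal
#' "promptness" (rate, 1/s).
#'
#' The default gains, biases and scatter are calibrated to group-level
#' normal-hearing (NH) and transparency-mode summary statistics: accurate
#' azimuth localization under NH (gain ~0.97, bias ~0.7 degrees, MAE
#' ~6.8 degrees), collapsed elevation gain under the device (~0.07) with an
#' upward bias, and poor low-pass elevation performance even under NH.
#' The response scatter is not set naively from
#' \eqn{\sigma = MAE \sqrt{\pi/2}}: for a collapsed gain the systematic
#' term \eqn{b + (g-1)\,target} contributes most of the error, so
#' \eqn{\sigma} is found by numerically inverting the expected MAE of the
#' full linear model under uniformly distributed targets (+/-90 degrees
#' azimuth, +/-30 degrees elevation). Promptness means are 4.77 1/s in
#' quiet and 3.64 1/s in noise, with spreads converted from group standard
#' errors over 10 listeners.
#'
#' @return A data frame of class `behavior_model` with columns `condition`,
#'   `stimulus`, `dimension`, `gain`, `bias`, `response_sd`,
#'   `promptness_mean`, `promptness_sd`.
#' @export
behavior_model <- function() {
  # expected |b + (g-1)U + N(0, s)| for U ~ Unif(-R, R): the MAE implied
  # by the linear response model under uniformly distributed targets
  expected_mae <- function(s, gain, bias, half_range) {
    folded <- function(mu) {
      s * sqrt(2 / pi) * exp(-mu^2 / (2 * s^2)) +
        mu * (1 - 2 * stats::pnorm(-mu / s))
    }
    stats::integrate(function(u) folded(abs(bias + (gain - 1) * u)),
                     -half_range, half_range)$value / (2 * half_range)
  }
  mae_to_sd <- function(mae, gain, bias, half_range) {
    floor_mae <- expected_mae(1e-6, gain, bias, half_range)
    if (mae <= floor_mae) return(1e-6)
    stats::uniroot(function(s) expected_mae(s, gain, bias, half_range) - mae,
                   c(1e-6, 10 * mae), tol = 1e-8)$root
  }
  rows <- list(
    # condition, stimulus, dimension, gain, bias, target MAE (deg)
    list("NH", "BB", "azimuth", 0.97, 0.72, 6.81),
    list("NH", "LP", "azimuth", 0.97, 0.72, 6.81),
    list("NH", "HP", "azimuth", 0.97, 0.72, 6.81),
    list("NH", "BB", "elevation", 0.93, 1.42, 6.79),
    list("NH", "HP", "elevation", 0.93, 1.42, 6.79),
    list("NH", "LP", "elevation", 0.17, 1.42, 15.0),
    list("AirPods", "BB", "azimuth", 0.85, 0.72, 14.0),
    list("AirPods", "LP", "azimuth", 0.95, 0.72, 9.0),
    list("AirPods", "HP", "azimuth", 0.80, 0.72, 16.0),
    list("AirPods", "BB", "elevation", 0.07, 9.01, 19.4),
    list("AirPods", "HP", "elevation", 0.07, 9.01, 19.4),
    list("AirPods", "LP", "elevation", 0.05, 9.01, 19.4),
    list("NH", "buzzer", "azimuth", 0.99, 0.13, 7.58),
    list("NH", "buzzer", "elevation", 0.80, 1.42, 9.0),
    list("AirPods", "buzzer", "azimuth", 0.85, 0.50, 12.0),
    list("AirPods", "buzzer", "elevation", -0.02, 7.90, 19.6)
  )
  tab <- do.call(rbind, lapply(rows, function(r) {
    hr <- if (r[[3]] == "azimuth") 90 else 30
    data.frame(condition = r[[1]], stimulus = r[[2]], dimension = r[[3]],
               gain = r[[4]], bias = r[[5]],
               response_sd = mae_to_sd(r[[6]], r[[4]], r[[5]], hr),
               stringsAsFactors = FALSE)
  }))
  # promptness: quiet (buzzer is the in-noise stimulus)
  tab$promptness_mean <- ifelse(tab$stimulus == "buzzer", 3.64, 4.77)
  tab$promptness_sd <- ifelse(tab$stimulus == "buzzer", 0.19, 0.47)
  class(tab) <- c("behavior_model", "data.frame")
  tab
}

#' Default seed used by stochastic generators
#' @return An integer seed.
#' @export
default_seed <- function() 20211149L
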