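# Synthetic dummy-head HRIRs and the parametric transparency-mode transform.

#' Construct an HRIR set container
#'
#' A set of directional binaural impulse responses keyed by (azimuth,
#' elevation), with a shared sample rate and condition label. Used both for
#' synthetically generated sets and for sets recovered by sweep
#' deconvolution.
#'
#' @param entries List of entries, each a list with fields `azimuth`,
#'   `elevation`, `left`, `right` (numeric impulse responses of equal
#'   length).
#' @param sample_rate Sampling rate, Hz.
#' @param condition Condition label, e.g. `"NH"` or `"AirPods"`.
#' @param snr Signal-to-noise ratio label in dB, or `NULL` for quiet.
#' @return An object of class `hrir_set`.
#' @export
hrir_set <- function(entries, sample_rate, condition = "NH", snr = NULL) {
  keys <- vapply(entries, function(e) paste(e$azimuth, e$elevation, sep = "/"),
                 character(1))
  stop_arg(!anyDuplicated(keys), "duplicate (azimuth, elevation) keys")
  names(entries) <- keys
  structure(list(entries = entries,
                 sample_rate = sample_rate,
                 condition = condition,
                 snr = snr),
            class = "hrir_set")
}

#' @export
print.hrir_set <- function(x, ...) {
  az <- sort(unique(vapply(x$entries, `[[`, numeric(1), "azimuth")))
  el <- sort(unique(vapply(x$entries, `[[`, numeric(1), "elevation")))
  cat("<hrir_set> ", length(x$entries), " directions, condition=", x$condition,
      if (!is.null(x$snr)) paste0(", snr=", x$snr, " dB"), "\n", sep = "")
  cat("  azimuths:  ", paste(range(az), collapse = " to "), " deg (",
      length(az), " steps)\n", sep = "")
  cat("  elevations:", paste(range(el), collapse = " to "), "deg (",
      length(el), "steps)\n")
  invisible(x)
}

#' Look up one direction in an HRIR set
#'
#' @param hrirs An [hrir_set()].
#' @param azimuth,elevation Direction, degrees.
#' @return The entry (list with `left`, `right`, `azimuth`, `elevation`).
#' @export
hrir_at <- function(hrirs, azimuth, elevation = 0) {
  key <- paste(azimuth, elevation, sep = "/")
  e <- hrirs$entries[[key]]
  if (is.null(e)) {
    stop("no HRIR at azimuth ", azimuth, ", elevation ", elevation,
         " in this set", call. = FALSE)
  }
  e
}

hrir_azimuths <- function(hrirs, elevation = 0) {
  az <- vapply(hrirs$entries, `[[`, numeric(1), "azimuth")
  el <- vapply(hrirs$entries, `[[`, numeric(1), "elevation")
  unname(sort(az[el == elevation]))
}

hrir_elevations <- function(hrirs, azimuth = 0) {
  az <- vapply(hrirs$entries, `[[`, numeric(1), "azimuth")
  el <- vapply(hrirs$entries, `[[`, numeric(1), "elevation")
  unname(sort(el[az == azimuth]))
}

## per-ear magnitude/delay model at one direction; right ear leads and is
## louder for positive azimuth
head_model_spectrum <- function(params, azimuth, elevation, ear) {
  n <- params$ir_length
  fs <- params$sample_rate
  f <- (0:(n / 2)) * fs / n
  th <- deg2rad(azimuth)
  side <- if (ear == "right") 1 else -1

  # interaural delay split symmetrically across ears (Woodworth)
  tau <- params$effective_radius / params$speed_of_sound * (th + sin(th))
  delay <- params$bulk_delay_s - side * tau / 2

  # head shadow: frequency-flat level offset above 2 kHz (tapered below),
  # so the band-limited ILD equals shadow_peak * sin(azimuth) exactly
  w_shadow <- 0.15 + 0.85 * raised_cosine(f, 500, 2000)
  level_db <- (params$shadow_peak / 2) * side * sin(th) * w_shadow

  # elevation-dependent pinna notch (Gaussian on log-frequency axis)
  fn <- params$notch_base_freq + params$notch_slope * elevation
  notch_db <- numeric(length(f))
  pos <- f > 0
  notch_db[pos] <- -params$notch_depth *
    exp(-(log2(f[pos] / fn))^2 / (2 * params$notch_width_oct^2))

  # band edges: no energy at DC or above 20 kHz (microphone/band limits)
  base <- raised_cosine(f, 5, 40) * (1 - raised_cosine(f, 17000, 21000))

  list(f = f, magnitude = base * undb(level_db + notch_db), delay = delay)
}

#' Synthesize a dummy-head HRIR set
#'
#' Builds directional binaural impulse responses on an (azimuth, elevation)
#' grid from the parametric head model of [head_model_params()]: each
#' direction embeds (i) a Woodworth interaural delay
#' \eqn{\tau(\theta) = (r/c)(\theta + \sin\theta)}, signed so the right ear
#' leads for positive azimuth, (ii) an azimuth-dependent high-frequency
#' head-shadow level difference, and (iii) an elevation-dependent pinna
#' notch centered at `notch_base_freq + notch_slope * elevation`. Impulse
#' responses are linear phase, so the construction controls interaural
#' timing exactly.
#'
#' @param params A [head_model_params()] object.
#' @param azimuths Azimuth grid, degrees, within +/-90.
#' @param elevations Elevation grid, degrees, within +/-30.
#' @param seed Integer seed (the construction is deterministic; the seed is
#'   recorded for provenance).
#' @return An [hrir_set()] with condition `"NH"`.
#' @export
#' @examples
#' set <- make_hrir_set(azimuths = c(-90, 0, 90), elevations = 0)
#' extract_itd(hrir_at(set, 90)$left, hrir_at(set, 90)$right, 44100) # ~700 us
make_hrir_set <- function(params = head_model_params(),
                          azimuths = seq(-90, 90, by = 10),
                          elevations = seq(-30, 30, by = 15),
                          seed = default_seed()) {
  stop_arg(all(abs(azimuths) <= 90),
           "azimuths must be within +/-90 degrees (the measured grid)")
  stop_arg(all(abs(elevations) <= 30),
           "elevations must be within +/-30 degrees (the measured grid)")
  n <- params$ir_length
  fs <- params$sample_rate
  entries <- list()
  for (el in elevations) {
    for (az in azimuths) {
      sl <- head_model_spectrum(params, az, el, "left")
      sr <- head_model_spectrum(params, az, el, "right")
      entries[[length(entries) + 1L]] <- list(
        azimuth = az, elevation = el,
        left = ir_from_magnitude(sl$magnitude, sl$delay, n, fs),
        right = ir_from_magnitude(sr$magnitude, sr$delay, n, fs))
    }
  }
  out <- hrir_set(entries, sample_rate = fs, condition = "NH")
  attr(out, "params") <- params
  attr(out, "seed") <- seed
  out
}

## signed ILD-inflation profile (dB) at azimuth theta: each Gaussian bump
## pushes the ILD away from zero on its own side of the head
ild_boost_profile <- function(params, theta) {
  d <- 0
  for (j in seq_along(params$ild_boost_peak)) {
    s <- sign(params$ild_boost_azimuth[j])
    if (s == 0) s <- 1
    d <- d + s * params$ild_boost_peak[j] *
      exp(-(theta - params$ild_boost_azimuth[j])^2 /
            (2 * params$ild_boost_width[j]^2))
  }
  d
}

#' Apply a transparency-mode transform to an HRIR set
#'
#' Emulates the acoustic effect of a hearable's hear-through mode on
#' measured HRIRs: interaural level differences are inflated by signed
#' off-axis Gaussian bumps, interaural time differences are jittered within
#' `itd_perturbation_bound`, the magnitude spectrum above
#' `spectral_flatten_cutoff` is replaced by a power-preserving flat level
#' (erasing pinna notches), and a common processing delay is added to both
#' ears. Magnitude edits are zero phase, so interaural timing is altered
#' only by the explicit jitter term.
#'
#' @param hrirs An [hrir_set()], normally the unoccluded (NH) set.
#' @param params A [transparency_params()] object.
#' @param seed Integer seed for the per-direction ITD jitter.
#' @return A transformed [hrir_set()] with condition `"AirPods"`.
#' @export
apply_transparency <- function(hrirs, params = transparency_params(),
                               seed = default_seed()) {
  stop_arg(inherits(hrirs, "hrir_set"), "`hrirs` must be an hrir_set")
  stop_arg(inherits(params, "transparency_params"),
           "`params` must be a transparency_params object")
  fs <- hrirs$sample_rate
  n <- length(hrirs$entries[[1]]$left)
  nfft <- next_pow2(2L * n)
  f <- (0:(nfft / 2)) * fs / nfft
  w_boost <- raised_cosine(f, params$boost_band[1] / 4, params$boost_band[1])

  jitter_us <- with_seed(child_seed(seed, "itd-jitter"), {
    stats::runif(length(hrirs$entries), -params$itd_perturbation_bound,
                 params$itd_perturbation_bound)
  })

  one_sided <- function(x) {
    X <- stats::fft(c(x, rep(0, nfft - length(x))))
    X[1:(nfft / 2 + 1)]
  }
  back <- function(H) {
    full <- c(H, Conj(rev(H[2:(nfft / 2)])))
    Re(stats::fft(full, inverse = TRUE))[seq_len(n)] / nfft
  }

  flatten <- function(H) {
    co <- params$spectral_flatten_cutoff
    if (is.null(co)) return(H)
    band <- f > co & f <= 17000
    if (!any(band)) return(H)
    flat <- sqrt(mean(Mod(H[band])^2))
    hi <- f > co
    target <- flat * (1 - raised_cosine(f[hi], 17000, 21000))
    ratio <- target / pmax(Mod(H[hi]), 1e-12)
    H[hi] <- H[hi] * ratio
    H
  }

  entries <- vector("list", length(hrirs$entries))
  for (i in seq_along(hrirs$entries)) {
    e <- hrirs$entries[[i]]
    dild <- ild_boost_profile(params, e$azimuth)
    d_common <- params$processing_delay * 1e-3
    d_itd <- jitter_us[i] * 1e-6
    HL <- one_sided(e$left)
    HR <- one_sided(e$right)
    HL <- flatten(HL) * undb(-dild / 2 * w_boost) *
      exp(-2i * pi * f * (d_common + d_itd / 2))
    HR <- flatten(HR) * undb(+dild / 2 * w_boost) *
      exp(-2i * pi * f * (d_common - d_itd / 2))
    entries[[i]] <- list(azimuth = e$azimuth, elevation = e$elevation,
                         left = back(HL), right = back(HR))
  }
  out <- hrir_set(entries, sample_rate = fs, condition = "AirPods",
                  snr = hrirs$snr)
  attr(out, "params") <- params
  attr(out, "seed") <- seed
  out
}
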