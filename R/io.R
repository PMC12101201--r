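# File formats: multichannel WAV, manifest/trial/cue CSV, YAML study config.

#' Write a multichannel WAV file
#'
#' Minimal RIFF/WAVE writer supporting IEEE float32 (lossless round-trip
#' for analysis signals) and PCM 16/24-bit integer encodings at any rate.
#'
#' @param samples Numeric vector (mono) or matrix (frames x channels).
#' @param path Output path.
#' @param sample_rate Sampling rate, Hz.
#' @param encoding `"float32"` (default), `"pcm16"` or `"pcm24"`.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, path, sample_rate = 44100,
                      encoding = c("float32", "pcm16", "pcm24")) {
  encoding <- match.arg(encoding)
  if (is.vector(samples)) samples <- matrix(samples, ncol = 1)
  nch <- ncol(samples)
  nfr <- nrow(samples)
  bits <- switch(encoding, float32 = 32L, pcm16 = 16L, pcm24 = 24L)
  fmt_code <- if (encoding == "float32") 3L else 1L
  bytes_per <- bits / 8L
  data_size <- nfr * nch * bytes_per
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt_code, con, size = 2, endian = "little")
  writeBin(nch, con, size = 2, endian = "little")
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * nch * bytes_per), con, size = 4,
           endian = "little")
  writeBin(as.integer(nch * bytes_per), con, size = 2, endian = "little")
  writeBin(bits, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  inter <- as.vector(t(samples))
  if (encoding == "float32") {
    writeBin(inter, con, size = 4, endian = "little")
  } else if (encoding == "pcm16") {
    q <- as.integer(pmax(-32768, pmin(32767, round(inter * 32767))))
    writeBin(q, con, size = 2, endian = "little")
  } else {
    q <- round(pmax(-1, pmin(1, inter)) * 8388607)
    q[q < 0] <- q[q < 0] + 16777216
    b <- matrix(0L, nrow = 3, ncol = length(q))
    b[1, ] <- q %% 256
    b[2, ] <- (q %/% 256) %% 256
    b[3, ] <- (q %/% 65536) %% 256
    writeBin(as.raw(as.vector(b)), con)
  }
  invisible(path)
}

#' Read a WAV file
#'
#' Counterpart of [write_wav()]; reads PCM 16/24-bit and IEEE float32
#' RIFF/WAVE files. No resampling is performed: if the file's rate is not
#' what a caller expects, resolve it explicitly rather than silently.
#'
#' @param path Input path.
#' @param expect_rate Optional required sample rate, Hz; a mismatch is an
#'   error proposing explicit resampling.
#' @return List with `samples` (frames x channels matrix), `sample_rate`,
#'   `encoding`.
#' @export
read_wav <- function(path, expect_rate = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  stop_arg(identical(riff, "RIFF"), paste0(path, ": not a RIFF/WAVE file"))
  invisible(readBin(con, integer(), size = 4, endian = "little"))
  wave <- readChar(con, 4)
  stop_arg(identical(wave, "WAVE"), paste0(path, ": not a RIFF/WAVE file"))
  fmt <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) {
      stop(path, ": no data chunk found", call. = FALSE)
    }
    size <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      raw_fmt <- readBin(con, raw(), n = size)
      u16 <- function(off) as.integer(raw_fmt[off + 1]) +
        256L * as.integer(raw_fmt[off + 2])
      u32 <- function(off) u16(off) + 65536L * u16(off + 2)
      fmt <- list(code = u16(0), channels = u16(2), rate = u32(4),
                  bits = u16(14))
    } else if (id == "data") {
      stop_arg(!is.null(fmt), paste0(path, ": data chunk before fmt chunk"))
      n_samp <- size %/% (fmt$bits / 8)
      if (fmt$code == 3 && fmt$bits == 32) {
        v <- readBin(con, numeric(), n = n_samp, size = 4, endian = "little")
        enc <- "float32"
      } else if (fmt$code == 1 && fmt$bits == 16) {
        v <- readBin(con, integer(), n = n_samp, size = 2, signed = TRUE,
                     endian = "little") / 32767
        enc <- "pcm16"
      } else if (fmt$code == 1 && fmt$bits == 24) {
        b <- as.integer(readBin(con, raw(), n = n_samp * 3))
        q <- b[seq(1, length(b), 3)] + 256 * b[seq(2, length(b), 3)] +
          65536 * b[seq(3, length(b), 3)]
        q[q >= 8388608] <- q[q >= 8388608] - 16777216
        v <- q / 8388607
        enc <- "pcm24"
      } else {
        stop(path, ": unsupported WAV encoding (format code ", fmt$code,
             ", ", fmt$bits, " bits)", call. = FALSE)
      }
      if (!is.null(expect_rate) && fmt$rate != expect_rate) {
        stop(path, ": sample rate is ", fmt$rate, " Hz but ", expect_rate,
             " Hz was required; resample the file explicitly (no silent ",
             "resampling is performed)", call. = FALSE)
      }
      samples <- matrix(v, ncol = fmt$channels, byrow = TRUE)
      return(list(samples = samples, sample_rate = fmt$rate, encoding = enc))
    } else {
      invisible(readBin(con, raw(), n = size + size %% 2))
    }
  }
}

#' Write an HRIR set as per-direction stereo WAVs plus a CSV manifest
#'
#' @param hrirs An [hrir_set()].
#' @param dir Output directory (created if missing).
#' @param prefix Filename prefix.
#' @param encoding WAV encoding (see [write_wav()]).
#' @return Path of the manifest CSV, invisibly.
#' @export
write_hrir_set <- function(hrirs, dir, prefix = "hrir",
                           encoding = "float32") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(hrirs$entries, function(e) {
    fn <- sprintf("%s_az%+04d_el%+03d.wav", prefix, e$azimuth, e$elevation)
    write_wav(cbind(e$left, e$right), file.path(dir, fn),
              hrirs$sample_rate, encoding)
    data.frame(azimuth_deg = e$azimuth, elevation_deg = e$elevation,
               condition = hrirs$condition,
               snr_db = if (is.null(hrirs$snr)) NA_real_ else hrirs$snr,
               sample_rate_hz = hrirs$sample_rate, filename = fn)
  })
  manifest <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  mpath <- file.path(dir, paste0(prefix, "_manifest.csv"))
  utils::write.csv(manifest, mpath, row.names = FALSE)
  invisible(mpath)
}

#' Read an HRIR set from a CSV manifest written by [write_hrir_set()]
#'
#' @param manifest_path Path to the manifest CSV.
#' @return An [hrir_set()].
#' @export
read_hrir_set <- function(manifest_path) {
  manifest <- utils::read.csv(manifest_path)
  req <- c("azimuth_deg", "elevation_deg", "condition", "sample_rate_hz",
           "filename")
  missing <- setdiff(req, names(manifest))
  stop_arg(length(missing) == 0,
           paste0(manifest_path, ": manifest lacks column(s) ",
                  paste(missing, collapse = ", ")))
  dir <- dirname(manifest_path)
  rate <- manifest$sample_rate_hz[1]
  entries <- lapply(seq_len(nrow(manifest)), function(i) {
    w <- read_wav(file.path(dir, manifest$filename[i]), expect_rate = rate)
    list(azimuth = manifest$azimuth_deg[i],
         elevation = manifest$elevation_deg[i],
         left = w$samples[, 1], right = w$samples[, 2])
  })
  snr <- manifest$snr_db[1]
  hrir_set(entries, sample_rate = rate, condition = manifest$condition[1],
           snr = if (is.na(snr)) NULL else snr)
}

trial_columns <- c("listener_id", "condition", "stimulus", "level_dba",
                   "snr_db", "target_azimuth_deg", "target_elevation_deg",
                   "response_azimuth_deg", "response_elevation_deg",
                   "reaction_time_ms")

#' Write a trial table to CSV
#' @param trials A trial table (see [simulate_trials()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  missing <- setdiff(trial_columns, names(trials))
  stop_arg(length(missing) == 0,
           paste0("trial table lacks column(s): ",
                  paste(missing, collapse = ", ")))
  utils::write.csv(trials[trial_columns], path, row.names = FALSE)
  invisible(path)
}

#' Read a trial table from CSV, validating the documented header
#' @param path Input CSV path.
#' @return A `trial_table` data frame.
#' @export
read_trials <- function(path) {
  tab <- utils::read.csv(path)
  missing <- setdiff(trial_columns, names(tab))
  stop_arg(length(missing) == 0,
           paste0(path, ": trial CSV lacks column(s): ",
                  paste(missing, collapse = ", ")))
  class(tab) <- c("trial_table", "data.frame")
  tab
}

#' Default study configuration
#'
#' One flat configuration governing the whole synthetic-study pipeline:
#' head-model and transparency calibration constants, measurement grids,
#' presentation and noise levels (50/60/70 dBA targets against 55 dBA
#' noise, giving SNRs of -5/+5/+15 dB), sweep parameters, behavioral
#' problem sizes and the master seed. All values are plain scalars/vectors
#' so the configuration round-trips through YAML byte-identically.
#'
#' @return A nested list of class `study_config`.
#' @export
default_study_config <- function() {
  structure(list(
    sample_rate = 44100L,
    seed = default_seed(),
    grids = list(azimuths = seq(-90L, 90L, by = 10L),
                 elevations = seq(-30L, 30L, by = 15L)),
    head_model = list(speed_of_sound = 343, shadow_peak = 18.5,
                      notch_base_freq = 8000, notch_slope = 50,
                      notch_depth = 15, ir_length = 1024L),
    transparency = list(ild_boost_peak = c(8.0, 7.5),
                        ild_boost_azimuth = c(-50, 40),
                        ild_boost_width = c(20, 20),
                        spectral_flatten_cutoff = 5000,
                        itd_perturbation_bound = 20,
                        processing_delay = 0.5),
    sweep = list(f_start = 20, f_end = 20000, duration = 1, fade = 0.01),
    levels = list(target_dba = c(50, 60, 70), noise_dba = 55,
                  snr_db = c(-5, 5, 15), quiet_target_dba = 70),
    noise_azimuths = c(-150L, -110L, -70L, -30L, 30L, 70L, 110L, 150L),
    behavior = list(n_listeners = 10L, n_trials_per_cell = 50L,
                    stimuli = c("BB", "LP", "HP")),
    deconvolution = list(out_length = 1024L)
  ), class = "study_config")
}

#' Write a study configuration to YAML
#' @param config A `study_config` list.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_study_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Read a study configuration from YAML
#' @param path Input YAML path.
#' @return A `study_config` list.
#' @export
read_study_config <- function(path) {
  structure(yaml::read_yaml(path), class = "study_config")
}
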