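# Shared fixtures, built in code and cached for the session.

.fixtures <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

nh_set <- function() {
  cached("nh", function() make_hrir_set(seed = 1))
}

tm_set <- function() {
  cached("tm", function() apply_transparency(nh_set(), seed = 1))
}

nh_profile <- function() {
  cached("nh_profile", function() cue_profile(nh_set()))
}

tm_profile <- function() {
  cached("tm_profile", function() cue_profile(tm_set()))
}

## zero-scatter identity response model, for noiseless behavioral fixtures
identity_model <- function(gain = 1, bias = 0, sd = 0) {
  m <- behavior_model()
  m$gain <- gain
  m$bias <- bias
  m$response_sd <- sd
  m
}

## plain trial table with chosen targets/responses
trial_fixture <- function(target_az, response_az,
                          target_el = rep(0, length(target_az)),
                          response_el = target_el) {
  data.frame(listener_id = "S01", condition = "NH", stimulus = "BB",
             level_dba = 60, snr_db = NA,
             target_azimuth_deg = target_az,
             target_elevation_deg = target_el,
             response_azimuth_deg = response_az,
             response_elevation_deg = response_el,
             reaction_time_ms = 500)
}
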