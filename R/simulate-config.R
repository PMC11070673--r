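# Simulation configuration and arena geometry for the two-platform
# linear-track reward-seeking task.

#' Default arena geometry
#'
#' A 50 cm linear track (8 cm wide) joining two 25 x 25 cm platforms. The
#' axis coordinate runs from the back of the reward platform (x = -25) across
#' the track (x in 0..50) to the back of the trigger platform (x = 75).
#' The reward port sits in the back wall of the reward platform.
#'
#' @return a list of geometry parameters (cm).
#' @export
arena_geometry <- function() {
  list(track_length = 50, track_halfwidth = 4,
       platform_depth = 25, platform_halfwidth = 12.5,
       reward_port_x = -20, body_length = 15)
}

#' Simulation configuration
#'
#' Defaults encode the task conditions the pipeline expects: reward delivered
#' in 85% of correct trials, 20 Hz video frames, 1 kHz LFP, faster running
#' toward reward than toward the trigger, gamma (30-50 Hz) bursts at 5.9/4.8
#' bursts per second in the two traversal directions, and optotagging light
#' trains of 1 s at 10/20/40 Hz with 2 ms pulses.
#'
#' @param n_trials number of trials to simulate.
#' @param reward_probability probability that a correct trial is rewarded.
#' @param frame_rate video frame rate, Hz.
#' @param lfp_rate LFP sampling rate, Hz (>= 1000).
#' @param speed_to_trigger,speed_to_reward plateau running speeds, cm/s.
#' @param accel_ramp_s time to reach plateau speed, s.
#' @param burst_rate_to_reward,burst_rate_to_trigger gamma-burst rates
#'   (bursts/s) during traversals in each direction.
#' @param burst_band gamma band for injected bursts, Hz.
#' @param burst_amplitude burst peak amplitude relative to background SD.
#' @param burst_duration_range_s burst duration range, s.
#' @param burst_min_separation_s minimum separation between burst centers
#'   within a traversal (inter-burst refractoriness). Default 0: burst
#'   times are a pure Poisson process at the configured rates. Set > 0 for
#'   detector-validation fixtures needing individually resolvable bursts.
#' @param noise_spectrum_exponent background 1/f^alpha exponent.
#' @param noise_amplitude background noise SD (arbitrary microvolt units).
#' @param gamma_ref_freq,gamma_ref_amplitude continuous gamma reference
#'   oscillation used as the phase-locking target.
#' @param tracking_noise_sd marker observation noise SD, cm.
#' @param invalid_frame_prob per-frame probability of a dropped marker.
#' @param reward_dwell_s,trigger_dwell_s dwell-duration ranges on the two
#'   platforms (turning included), s.
#' @param opto_frequencies light-train frequencies, Hz.
#' @param opto_pulse_ms light pulse width, ms.
#' @param opto_train_s light train duration, s.
#' @param opto_trains_per_freq number of trains per frequency.
#' @param opto_gap_s gap between trains, s.
#' @param opto_resonance_gain LFP evoked-response gain per stimulation
#'   frequency (same order as `opto_frequencies`).
#' @param rate_ceiling_hz generative firing-rate ceiling; exceeding it is an
#'   error naming the unit.
#' @param hemisphere recorded hemisphere, for the turning sign convention.
#' @param seed integer RNG seed.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_trials = 100,
                       reward_probability = 0.85,
                       frame_rate = 20,
                       lfp_rate = 1000,
                       speed_to_trigger = 45,
                       speed_to_reward = 60,
                       accel_ramp_s = 0.25,
                       burst_rate_to_reward = 5.9,
                       burst_rate_to_trigger = 4.8,
                       burst_band = c(30, 50),
                       burst_amplitude = 2.5,
                       burst_duration_range_s = c(0.075, 0.150),
                       burst_min_separation_s = 0,
                       noise_spectrum_exponent = 1.5,
                       noise_amplitude = 1,
                       gamma_ref_freq = 40,
                       gamma_ref_amplitude = 0.5,
                       tracking_noise_sd = 0.5,
                       invalid_frame_prob = 0.005,
                       reward_dwell_s = c(2.0, 3.5),
                       trigger_dwell_s = c(0.5, 1.5),
                       opto_frequencies = c(10, 20, 40),
                       opto_pulse_ms = 2,
                       opto_train_s = 1,
                       opto_trains_per_freq = 8,
                       opto_gap_s = 3,
                       opto_resonance_gain = c(1, 1.5, 3),
                       rate_ceiling_hz = 500,
                       hemisphere = "right",
                       seed = 1L) {
  cfg <- as.list(environment())
  cfg$arena <- arena_geometry()
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  chk <- function(cond, msg) if (!isTRUE(cond))
    abort(paste0("invalid simulation config: ", msg))
  chk(cfg$n_trials >= 1, "n_trials must be >= 1")
  chk(cfg$reward_probability >= 0 && cfg$reward_probability <= 1,
      "reward_probability must be in [0, 1]")
  chk(cfg$frame_rate > 0, "frame_rate must be positive")
  chk(cfg$lfp_rate >= 1000, "lfp_rate must be >= 1000 Hz")
  chk(cfg$speed_to_trigger > 0 && cfg$speed_to_reward > 0,
      "running speeds must be positive")
  chk(cfg$burst_rate_to_reward >= 0 && cfg$burst_rate_to_trigger >= 0,
      "burst rates must be non-negative")
  chk(cfg$burst_band[1] > 0 && cfg$burst_band[2] < cfg$lfp_rate / 2 &&
        cfg$burst_band[1] < cfg$burst_band[2],
      "burst_band must lie inside (0, lfp_rate/2)")
  chk(length(cfg$opto_frequencies) >= 1, "need at least one opto frequency")
  chk(length(cfg$opto_resonance_gain) == length(cfg$opto_frequencies),
      "opto_resonance_gain must match opto_frequencies")
  chk(cfg$hemisphere %in% c("left", "right"),
      "hemisphere must be 'left' or 'right'")
  invisible(cfg)
}
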