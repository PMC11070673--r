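# Ground-truth unit populations for the synthetic-session generator.

GLM_TRUTH_VARIABLES <- ENCODING_VARIABLES

#' Construct ground truth for one unit
#'
#' @param unit_id identifier.
#' @param cell_type `"WS"`, `"NS"`, or `"FSPV"`.
#' @param baseline_rate_hz baseline firing rate (> 0).
#' @param weights named list of log-rate coefficient vectors; names must be
#'   encoding variables (10 values for `linear_position`, 2 for `run_phase`
#'   and `trial_outcome`, 1 for the continuous variables).
#' @param kappa von Mises concentration of gamma phase locking (>= 0).
#' @param preferred_phase preferred gamma phase, radians.
#' @param lock_to_reward,lock_to_trigger per-direction phase-locking flags.
#' @param is_tagged whether the unit responds to light pulses.
#' @param tag_latency_ms,tag_jitter_ms,tag_reliability evoked-spike latency,
#'   jitter (SD), and per-pulse probability.
#' @param spike_width_us,peak_to_valley_ratio waveform features.
#' @return a one-row tibble (list-column `weights`).
#' @export
unit_truth <- function(unit_id, cell_type = c("WS", "NS", "FSPV"),
                       baseline_rate_hz = 5, weights = list(),
                       kappa = 0, preferred_phase = 0,
                       lock_to_reward = TRUE, lock_to_trigger = TRUE,
                       is_tagged = FALSE, tag_latency_ms = 2,
                       tag_jitter_ms = 0.3, tag_reliability = 0.9,
                       spike_width_us = 350, peak_to_valley_ratio = 2) {
  cell_type <- match.arg(cell_type)
  assert_that(baseline_rate_hz > 0, "baseline_rate_hz must be positive")
  assert_that(kappa >= 0, "kappa must be >= 0")
  assert_that(tag_reliability >= 0 && tag_reliability <= 1,
              "tag_reliability must be in [0, 1]")
  bad <- setdiff(names(weights), GLM_TRUTH_VARIABLES)
  if (length(bad))
    abort(paste0("unknown weight variable(s): ", paste(bad, collapse = ", ")))
  expected_len <- c(linear_position = 10, run_phase = 2, trial_outcome = 2,
                    speed = 1, acceleration = 1, turning = 1)
  for (v in names(weights))
    assert_that(length(weights[[v]]) == expected_len[[v]],
                sprintf("weights$%s must have length %d", v,
                        expected_len[[v]]))
  tibble(unit_id = unit_id, cell_type = cell_type,
         baseline_rate_hz = baseline_rate_hz,
         weights = list(weights), kappa = kappa,
         preferred_phase = preferred_phase,
         lock_to_reward = lock_to_reward, lock_to_trigger = lock_to_trigger,
         is_tagged = is_tagged, tag_latency_ms = tag_latency_ms,
         tag_jitter_ms = tag_jitter_ms, tag_reliability = tag_reliability,
         spike_width_us = spike_width_us,
         peak_to_valley_ratio = peak_to_valley_ratio)
}

# Gaussian bump of positional weights over the 10 bins.
position_bump <- function(center_bin, peak = 1.2, width = 1.2) {
  peak * exp(-0.5 * ((1:10 - center_bin) / width)^2)
}

#' Generate a ground-truth population
#'
#' Cell-type proportions default to roughly 80% wide-spiking (WS), 15%
#' narrow-spiking (NS) and 5% FS-PV units. Waveform features are drawn from
#' class-specific Gaussians (WS: width 372 +/- 35 us, PVR 2.1 +/- 0.5;
#' NS: 239 +/- 30 us, 1.6 +/- 0.4; FS-PV: 242 +/- 23 us, 1.1 +/- 0.3).
#' A `tuned_fraction` of units get positional tuning (a Gaussian bump at a
#' random bin), and smaller fractions get run-phase, outcome, and kinematic
#' weights; FS-PV units share a common trigger-zone/direction template (a
#' homogeneous population), and a subset of units is gamma phase-locked.
#'
#' @param n_units population size.
#' @param proportions named fractions for WS/NS/FSPV.
#' @param tuned_fraction fraction of WS/NS units with positional tuning.
#' @param seed RNG seed.
#' @return tibble of unit truths (one row per unit).
#' @export
make_population_truth <- function(n_units = 60,
                                  proportions = c(WS = 0.80, NS = 0.15,
                                                  FSPV = 0.05),
                                  tuned_fraction = 0.6, seed = 1L) {
  with_seed(seed, {
    n_fspv <- max(1, round(n_units * proportions[["FSPV"]]))
    n_ns <- max(1, round(n_units * proportions[["NS"]]))
    n_ws <- n_units - n_fspv - n_ns
    types <- c(rep("WS", n_ws), rep("NS", n_ns), rep("FSPV", n_fspv))
    rows <- purrr::map(seq_len(n_units), function(i) {
      ct <- types[i]
      wf <- switch(ct,
        WS = c(rnorm(1, 372, 35), rnorm(1, 2.1, 0.5)),
        NS = c(rnorm(1, 239, 30), rnorm(1, 1.6, 0.4)),
        FSPV = c(rnorm(1, 242, 23), rnorm(1, 1.1, 0.3)))
      wf[2] <- max(wf[2], 0.3)
      base <- switch(ct,
        WS = exp(rnorm(1, log(3.5), 0.5)),
        NS = exp(rnorm(1, log(4.3), 0.5)),
        FSPV = exp(rnorm(1, log(13), 0.25)))
      w <- list()
      if (ct == "FSPV") {
        # homogeneous template: elevated trigger-zone firing plus a
        # direction preference
        w$linear_position <- position_bump(10, peak = 0.8, width = 1.5)
        w$run_phase <- c(-0.25, 0.25)
        kappa <- 1.5
      } else {
        if (runif(1) < tuned_fraction)
          w$linear_position <- position_bump(sample(1:10, 1),
                                             peak = runif(1, 0.8, 1.6))
        if (runif(1) < 0.4) {
          # +/- 0.25 log-rate units produce direction modulation in the
          # regime where single-neuron direction decoding sits near 65%
          pref <- sample(c(1, 2), 1)
          w$run_phase <- if (pref == 1) c(0.25, -0.25) else c(-0.25, 0.25)
        }
        if (runif(1) < 0.25) w$trial_outcome <- c(runif(1, 0.2, 0.6), 0)
        if (runif(1) < 0.3) w$speed <- rnorm(1, 0, 0.25)
        if (runif(1) < 0.2) w$acceleration <- rnorm(1, 0, 0.2)
        if (runif(1) < 0.2) w$turning <- rnorm(1, 0, 0.2)
        kappa <- if (runif(1) < 0.4) runif(1, 0.4, 1.5) else 0
      }
      unit_truth(
        unit_id = sprintf("u%03d", i), cell_type = ct,
        baseline_rate_hz = base, weights = w, kappa = kappa,
        preferred_phase = runif(1, -pi, pi),
        is_tagged = ct == "FSPV",
        spike_width_us = wf[1], peak_to_valley_ratio = wf[2])
    })
    dplyr::bind_rows(rows)
  })
}

#' Standard encoding-recovery population
#'
#' Ground truth for validating the encoding pipeline: each unit is tuned to
#' a random subset of the six model variables (each independently with
#' probability `tuned_prob`) at fixed moderate effect sizes -- a positional
#' Gaussian bump of peak 1.2 log-rate units at a random bin, +/- 0.35 for
#' run phase, 0.5 for a rewarded-outcome response, and +/- 0.3 for each
#' kinematic variable -- on a 6 Hz baseline. The tuned set of every unit is
#' recorded in the `tuned` list-column, so significance flags can be scored
#' against the truth.
#'
#' @param n_units population size.
#' @param tuned_prob per-variable tuning probability (default 0.5).
#' @param baseline_rate_hz baseline firing rate (default 6).
#' @param seed RNG seed.
#' @return tibble of unit truths with a `tuned` list-column.
#' @export
make_encoding_population <- function(n_units = 200, tuned_prob = 0.5,
                                     baseline_rate_hz = 6, seed = 1L) {
  with_seed(seed, {
    rows <- purrr::map(seq_len(n_units), function(i) {
      tuned <- ENCODING_VARIABLES[runif(6) < tuned_prob]
      w <- list()
      if ("linear_position" %in% tuned)
        w$linear_position <- position_bump(sample(1:10, 1), peak = 1.2)
      if ("run_phase" %in% tuned)
        w$run_phase <- sample(c(1, -1), 1) * c(0.35, -0.35)
      if ("trial_outcome" %in% tuned) w$trial_outcome <- c(0.5, 0)
      if ("speed" %in% tuned) w$speed <- sample(c(1, -1), 1) * 0.3
      if ("acceleration" %in% tuned)
        w$acceleration <- sample(c(1, -1), 1) * 0.3
      if ("turning" %in% tuned) w$turning <- sample(c(1, -1), 1) * 0.3
      u <- unit_truth(sprintf("enc%03d", i), "WS",
                      baseline_rate_hz = baseline_rate_hz, weights = w)
      u$tuned <- list(tuned)
      u
    })
    dplyr::bind_rows(rows)
  })
}

# Parametric mean waveform (arbitrary units, 32 samples at 32 kHz): an
# initial positive peak followed by a trough `width_us` later, with
# peak/trough amplitude ratio = pvr.
waveform_template <- function(width_us, pvr, n = 32, fs = 32000) {
  t_us <- (seq_len(n) - 1) / fs * 1e6
  tp <- 200
  tt <- tp + width_us
  peak <- pvr * exp(-0.5 * ((t_us - tp) / 60)^2)
  trough <- -1 * exp(-0.5 * ((t_us - tt) / (0.4 * width_us + 40))^2)
  peak + trough
}
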