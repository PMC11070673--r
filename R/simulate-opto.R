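# Optotagging simulator: light trains appended after the behavioral epoch,
# evoked spikes for tagged units, baseline firing for all units during the
# light epoch, and stimulus-locked LFP resonance with harmonics.

#' Simulate an optotagging epoch
#'
#' Appends light-stimulation trains (1 s at each configured frequency,
#' `opto_trains_per_freq` repetitions) after the behavioral session. Tagged
#' units emit an extra spike after each pulse with probability
#' `tag_reliability`, at latency `tag_latency_ms` +/- `tag_jitter_ms`;
#' untagged units are unaffected. All units keep firing at their baseline
#' rate during the epoch so that pre-pulse baseline windows contain spikes.
#' The LFP gains a pulse-locked evoked response (an alpha-function kernel
#' per pulse) whose amplitude follows `opto_resonance_gain`, producing
#' spectral peaks at the stimulation frequency and its harmonics.
#'
#' @param session session with behavior, LFP, and spikes simulated.
#' @param truth ground-truth unit table.
#' @param cfg the [sim_config()].
#' @return the session with light events, extended LFP and spikes, and
#'   `truth$opto` (train schedule).
#' @export
simulate_optotagging <- function(session, truth, cfg) {
  validate_sim_config(cfg)
  with_seed(child_seed(cfg$seed, "opto"),
            simulate_optotagging_impl(session, truth, cfg))
}

simulate_optotagging_impl <- function(session, truth, cfg) {
  fs <- session$lfp$rate_hz
  t_behav_end <- length(session$lfp$samples) / fs
  t0 <- t_behav_end + 2

  pulse_list <- list()
  train_list <- list()
  t_cursor <- t0
  for (fi in seq_along(cfg$opto_frequencies)) {
    f <- cfg$opto_frequencies[fi]
    for (k in seq_len(cfg$opto_trains_per_freq)) {
      onsets <- t_cursor + seq(0, cfg$opto_train_s - 1 / f, by = 1 / f)
      pulse_list[[length(pulse_list) + 1]] <- tibble(
        time_s = onsets, event_type = "light_pulse_on", payload = f)
      train_list[[length(train_list) + 1]] <- tibble(
        freq_hz = f, train_onset_s = t_cursor)
      t_cursor <- t_cursor + cfg$opto_train_s + cfg$opto_gap_s
    }
  }
  pulses <- dplyr::bind_rows(pulse_list)
  t_end <- t_cursor + 2

  # extend the LFP with background noise + pulse-locked evoked response
  n_ext <- ceiling((t_end - t_behav_end) * fs)
  ext <- cfg$noise_amplitude *
    colored_noise(n_ext, fs, cfg$noise_spectrum_exponent)
  tau <- 0.005
  kern_t <- seq(0, 0.06, by = 1 / fs)
  kern <- (kern_t / tau) * exp(1 - kern_t / tau)
  gain <- setNames(cfg$opto_resonance_gain,
                   as.character(cfg$opto_frequencies))
  for (j in seq_len(nrow(pulses))) {
    i0 <- round((pulses$time_s[j] - t_behav_end) * fs) + 1
    ii <- i0:(i0 + length(kern) - 1)
    ok <- ii >= 1 & ii <= n_ext
    ext[ii[ok]] <- ext[ii[ok]] +
      gain[[as.character(pulses$payload[j])]] * cfg$noise_amplitude *
      kern[ok]
  }
  session$lfp$samples <- c(session$lfp$samples, ext)

  # baseline firing for every unit through the light epoch
  extra <- purrr::map_dfr(seq_len(nrow(truth)), function(i) {
    u <- truth[i, ]
    nsp <- rpois(1, u$baseline_rate_hz * (t_end - t_behav_end))
    base_sp <- sort(runif(nsp, t_behav_end, t_end))
    ev <- numeric(0)
    if (isTRUE(u$is_tagged) && u$tag_reliability > 0) {
      resp <- runif(nrow(pulses)) < u$tag_reliability
      ev <- pulses$time_s[resp] + u$tag_latency_ms / 1000 +
        rnorm(sum(resp), 0, u$tag_jitter_ms / 1000)
    }
    tibble(unit_id = u$unit_id, time_s = sort(c(base_sp, ev)))
  })
  spikes <- dplyr::bind_rows(session$spikes, extra) |>
    dplyr::arrange(.data$unit_id, .data$time_s) |>
    dplyr::group_by(.data$unit_id) |>
    dplyr::filter(c(diff(.data$time_s) >= 0.001, TRUE)) |>  # later spike wins
    dplyr::ungroup()

  session$spikes <- spikes
  session$events <- dplyr::arrange(dplyr::bind_rows(session$events, pulses),
                                   .data$time_s)
  session$truth$opto <- dplyr::bind_rows(train_list)
  session
}

#' Simulate a complete session
#'
#' Runs the full generative pipeline: behavior, LFP, spikes, and the
#' optotagging epoch. Identical configurations (including seed) produce
#' byte-identical sessions.
#'
#' @param cfg a [sim_config()].
#' @param truth optional ground-truth unit table; defaults to
#'   [make_population_truth()] seeded from the config.
#' @param opto whether to append the optotagging epoch.
#' @return a complete `ephys_session`.
#' @export
simulate_session <- function(cfg = sim_config(), truth = NULL, opto = TRUE) {
  truth <- truth %||% make_population_truth(seed = child_seed(cfg$seed,
                                                              "truth"))
  s <- simulate_behavior(cfg)
  s <- simulate_lfp(s, cfg)
  s <- simulate_spikes(s, truth, cfg)
  if (opto) s <- simulate_optotagging(s, truth, cfg)
  s
}
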