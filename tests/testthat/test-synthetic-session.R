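# Generator-level guarantees: task structure, determinism, generative
# rates, burst/optotagging ground truth.

test_that("simulated task structure matches the trial definition", {
  s <- fx_session()
  tr <- s$truth$trials
  tv <- s$truth$traversals
  expect_equal(nrow(tr), 30)
  expect_equal(nrow(tv), 60)
  # within each trial the to-trigger traversal precedes the to-reward one
  by_trial <- split(tv, tv$trial)
  for (b in by_trial) {
    expect_setequal(b$direction, c("to_trigger", "to_reward"))
    expect_lt(b$end_s[b$direction == "to_trigger"],
              b$start_s[b$direction == "to_reward"])
  }
  # traversals to reward are faster than to trigger
  dur <- tapply(tv$end_s - tv$start_s, tv$direction, mean)
  expect_lt(dur[["to_reward"]], dur[["to_trigger"]])
  # frame clock strictly increasing at the nominal rate
  dt <- diff(s$tracking$frame_time_s)
  expect_true(all(dt > 0))
  expect_equal(max(abs(dt - 0.05)), 0, tolerance = 1e-12)
})

test_that("a single-trial config yields exactly one traversal per direction", {
  cfg <- sim_config(n_trials = 1, seed = 5)
  s <- simulate_behavior(cfg)
  expect_equal(sum(s$truth$traversals$direction == "to_trigger"), 1)
  expect_equal(sum(s$truth$traversals$direction == "to_reward"), 1)
})

test_that("reward delivery fraction sits inside the binomial 99% CI", {
  cfg <- sim_config(n_trials = 100, seed = 11)
  s <- simulate_behavior(cfg)
  frac <- mean(s$truth$trials$outcome == "rewarded")
  ci <- qbinom(c(0.005, 0.995), 100, 0.85) / 100
  expect_within(frac, ci[1], ci[2])
})

test_that("identical config and seed give identical sessions", {
  cfg <- sim_config(n_trials = 5, seed = 99)
  tru <- make_population_truth(n_units = 4, seed = 3)
  s1 <- simulate_session(cfg, truth = tru)
  s2 <- simulate_session(cfg, truth = tru)
  expect_identical(serialize(s1, NULL), serialize(s2, NULL))
})

test_that("non-physical configs are rejected with a validation error", {
  expect_error(sim_config(n_trials = 0), "n_trials")
  expect_error(sim_config(speed_to_reward = -5), "speeds")
  expect_error(sim_config(reward_probability = 1.4), "reward_probability")
  expect_error(sim_config(burst_band = c(30, 800)), "burst_band")
  expect_error(sim_config(opto_frequencies = numeric(0)), "opto")
})

test_that("an untuned unit's realized rate matches its baseline", {
  cfg <- sim_config(n_trials = 60, seed = 12)
  s <- simulate_behavior(cfg)
  s <- simulate_lfp(s, cfg)
  s <- simulate_spikes(s, unit_truth("flat", "WS", 10), cfg)
  T <- max(s$tracking$frame_time_s)
  rate <- nrow(s$spikes) / T
  se <- sqrt(10 / T)
  expect_within(rate, 10 - 3 * se, 10 + 3 * se)
})

test_that("a positional weight peak reappears as the tuning-curve peak", {
  fx <- fx_targeted()
  av <- activity_vectors(fx$binned, fx$session$truth$traversals, "place4")
  peak_bins <- av |>
    dplyr::group_by(direction) |>
    dplyr::summarise(peak = bin[which.max(rate_hz)])
  expect_true(all(abs(peak_bins$peak - 4) <= 1))
})

test_that("rates above the ceiling abort naming the unit", {
  cfg <- sim_config(n_trials = 2, seed = 8)
  s <- simulate_behavior(cfg)
  s <- simulate_lfp(s, cfg)
  hot <- unit_truth("hot_unit", "WS", 400,
                    weights = list(run_phase = c(3, 3)))
  expect_error(simulate_spikes(s, hot, cfg), "hot_unit")
})

test_that("every spike lies within the session span and bursts within traversals", {
  s <- fx_session()
  span <- range(c(0, length(s$lfp$samples) / s$lfp$rate_hz))
  expect_true(all(s$spikes$time_s >= span[1] &
                    s$spikes$time_s <= span[2]))
  tv <- s$truth$traversals
  inside <- vapply(s$truth$bursts$time_s, function(t)
    any(t >= tv$start_s & t <= tv$end_s), logical(1))
  expect_true(all(inside))
})

test_that("phase-locked spikes follow a von Mises law; kappa 0 is uniform", {
  cfg <- sim_config(n_trials = 40, seed = 14, gamma_ref_amplitude = 0.5)
  s0 <- simulate_behavior(cfg)
  s0 <- simulate_lfp(s0, cfg)
  tru <- dplyr::bind_rows(
    unit_truth("locked", "WS", 15, kappa = 2, preferred_phase = 1),
    unit_truth("unlocked", "WS", 15, kappa = 0))
  s <- simulate_spikes(s0, tru, cfg)
  gref <- s$truth$gamma_ref
  phase_at <- function(t) {
    ph <- 2 * pi * gref$freq_hz * t + gref$phase0
    atan2(sin(ph), cos(ph))
  }
  tv <- s$truth$traversals
  in_trav <- function(t) vapply(t, function(x)
    any(x >= tv$start_s & x <= tv$end_s), logical(1))
  st_l <- s$spikes$time_s[s$spikes$unit_id == "locked"]
  st_l <- st_l[in_trav(st_l)]
  ph_l <- phase_at(st_l)
  expect_gt(mrl(ph_l), 0.4)  # kappa = 2 implies MRL near 0.7
  expect_lt(abs(atan2(mean(sin(ph_l)), mean(cos(ph_l))) - 1), 0.3)
  st_u <- s$spikes$time_s[s$spikes$unit_id == "unlocked"]
  ph_u <- phase_at(st_u[in_trav(st_u)])
  expect_gt(rayleigh_test(ph_u)$p, 0.001)
})

test_that("optotagging adds evoked spikes only to tagged units", {
  cfg <- sim_config(n_trials = 3, seed = 23, opto_trains_per_freq = 10)
  tru <- dplyr::bind_rows(
    unit_truth("tagged", "FSPV", 12, is_tagged = TRUE,
               tag_latency_ms = 2, tag_jitter_ms = 0.3,
               tag_reliability = 0.9),
    unit_truth("untagged", "WS", 12, is_tagged = FALSE))
  s <- simulate_session(cfg, truth = tru)
  pulses <- s$events[s$events$event_type == "light_pulse_on", ]
  # 40 Hz x 1 s x 10 trains at reliability 0.9: expect >= 300 evoked
  p40 <- pulses$time_s[pulses$payload == 40]
  expect_equal(length(p40), 400)
  count_evoked <- function(u) {
    st <- s$spikes$time_s[s$spikes$unit_id == u]
    sum(vapply(p40, function(t)
      any(st > t + 0.0005 & st < t + 0.004), logical(1)))
  }
  expect_gte(count_evoked("tagged"), 300)
  # untagged: chance coincidences only (12 Hz * 3.5 ms window)
  expect_lt(count_evoked("untagged"), 40)
})
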