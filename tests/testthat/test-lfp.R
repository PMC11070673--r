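# LFP spectral statistics: PSD estimator checks, optogenetic resonance,
# traversal spectra, burst detection, speed-resolved power.

test_that("Welch PSD integrates to the signal variance on white noise", {
  withr::with_seed(1, x <- rnorm(20000))
  p <- welch_psd(x, fs = 1000)
  total <- sum(p$power) * (p$freq_hz[2] - p$freq_hz[1])
  expect_equal(total, var(x), tolerance = 0.05)
})

test_that("relative power over the analysis band sums to one", {
  s <- fx_session()
  spec <- traversal_spectrum(s$lfp, s$truth$traversals)
  sums <- as.numeric(tapply(spec$rel_power, spec$direction, sum))
  expect_equal(sums, c(1, 1), tolerance = 1e-6)
})

test_that("a constructed 40 Hz drive produces band-specific resonance", {
  fs <- 1000
  withr::with_seed(3, x <- rnorm(fs * 130) * 0.5)
  onsets <- seq(5, 120, by = 5)
  freqs <- rep(c(10, 20, 40), length.out = length(onsets))
  tt <- seq_len(fs) / fs
  for (i in seq_along(onsets)) {
    idx <- (onsets[i] * fs):(onsets[i] * fs + fs - 1)
    amp <- c(`10` = 0.4, `20` = 0.6, `40` = 1.2)[[as.character(freqs[i])]]
    x[idx] <- x[idx] + amp * sin(2 * pi * freqs[i] * tt)
  }
  events <- tibble::tibble(time_s = onsets, event_type = "light_pulse_on",
                           payload = freqs)
  res <- opto_resonance(list(samples = x, rate_hz = fs), events)
  # the 40 Hz drive has the largest +/-4 Hz power ratio
  expect_equal(res$ratios$stim_freq_hz[which.max(res$ratios$ratio)], 40)
  expect_true(all(res$ratios$ratio > 1.5))
  # 36-44 Hz relative power rises under 40 Hz light only
  bp <- res$band_power
  r4036 <- bp$rel_power[bp$stim_freq_hz == 40 & bp$band == "36-44"]
  expect_gt(r4036[1], 2 * r4036[2])  # light >> baseline
})

test_that("pulse-train drives produce detectable harmonic peaks", {
  cfg <- sim_config(n_trials = 3, seed = 47, opto_trains_per_freq = 8)
  tru <- unit_truth("t1", "FSPV", 12, is_tagged = TRUE)
  s <- simulate_session(cfg, truth = tru)
  res <- opto_resonance(s$lfp, s$events)
  sp <- res$spectra[res$spectra$stim_freq_hz == 10 &
                      res$spectra$phase == "light", ]
  peak_at <- function(f0) {
    band <- sp$power[sp$freq_hz >= f0 - 2 & sp$freq_hz <= f0 + 2]
    flank <- sp$power[(sp$freq_hz >= f0 - 6 & sp$freq_hz < f0 - 2) |
                        (sp$freq_hz > f0 + 2 & sp$freq_hz <= f0 + 6)]
    max(band) > max(flank)
  }
  # fundamental plus at least two harmonics at integer multiples
  expect_true(peak_at(10))
  expect_true(sum(vapply(c(20, 30, 40), peak_at, logical(1))) >= 2)
})

test_that("gamma relative power is higher toward reward when burst rates differ", {
  # constructed direction contrast over a background without the
  # continuous reference oscillation
  cfg <- sim_config(n_trials = 30, seed = 73, burst_amplitude = 2,
                    gamma_ref_amplitude = 0.2,
                    burst_rate_to_reward = 8, burst_rate_to_trigger = 4)
  s <- simulate_behavior(cfg)
  s <- simulate_lfp(s, cfg)
  spec <- traversal_spectrum(s$lfp, s$truth$traversals)
  gamma <- spec |>
    dplyr::filter(freq_hz >= 30, freq_hz <= 50) |>
    dplyr::group_by(direction) |>
    dplyr::summarise(p = sum(rel_power))
  expect_gt(gamma$p[gamma$direction == "to_reward"],
            gamma$p[gamma$direction == "to_trigger"])
})

test_that("traversals outside the duration window are excluded", {
  tv <- tibble::tibble(trial = 1:3, direction = "to_reward",
                       start_s = c(0, 10, 20), end_s = c(2, 11, 20.4))
  q <- trackephys:::qualifying_traversals(tv, c(0.5, 1.5))
  expect_equal(q$trial, 2L)  # 2.0 s and 0.4 s traversals dropped
})

test_that("the burst detector validates against ground truth", {
  cfg <- sim_config(n_trials = 25, seed = 57, burst_amplitude = 3,
                    burst_rate_to_reward = 2.5,
                    burst_rate_to_trigger = 2.5,
                    burst_duration_range_s = c(0.1, 0.15),
                    burst_min_separation_s = 0.15)
  s <- simulate_behavior(cfg)
  s <- simulate_lfp(s, cfg)
  gb <- detect_gamma_bursts(s$lfp, s$truth$traversals)
  qt <- trackephys:::qualifying_traversals(s$truth$traversals, c(0.5, 1.5))
  keep <- rep(FALSE, nrow(s$truth$bursts))
  for (i in seq_len(nrow(qt)))
    keep <- keep | (s$truth$bursts$time_s >= qt$start_s[i] &
                      s$truth$bursts$time_s <= qt$end_s[i])
  tru <- s$truth$bursts[keep, ]
  recall <- mean(vapply(tru$time_s, function(t)
    any(abs(gb$bursts$time_s - t) <= 0.025), logical(1)))
  precision <- mean(vapply(gb$bursts$time_s, function(t)
    any(abs(tru$time_s - t) <= 0.025), logical(1)))
  expect_gte(recall, 0.9)
  expect_gte(precision, 0.9)
})

test_that("burst detection is invariant to LFP rescaling", {
  s <- fx_session()
  gb1 <- detect_gamma_bursts(s$lfp, s$truth$traversals)
  lfp2 <- s$lfp
  lfp2$samples <- lfp2$samples * 37
  gb2 <- detect_gamma_bursts(lfp2, s$truth$traversals)
  expect_equal(gb1$bursts$time_s, gb2$bursts$time_s)
  expect_equal(gb1$rates$n_bursts, gb2$rates$n_bursts)
})

test_that("a burst-free LFP shows no direction difference in burst rate", {
  cfg <- sim_config(n_trials = 25, seed = 59, burst_rate_to_reward = 0,
                    burst_rate_to_trigger = 0)
  s <- simulate_behavior(cfg)
  s <- simulate_lfp(s, cfg)
  gb <- detect_gamma_bursts(s$lfp, s$truth$traversals)
  p <- suppressWarnings(
    wilcox.test(bursts_per_s ~ direction, data = gb$rates)$p.value)
  expect_gt(p, 0.01)
})

test_that("speed-resolved power respects the common speed range", {
  s <- fx_session()
  kin <- compute_kinematics(s$truth$clean, "right")
  srp <- speed_resolved_power(s$lfp, s$truth$traversals, kin)
  expect_true(all(srp$speed_cms >= 15 & srp$speed_cms <= 75))
  # gamma power higher toward reward after speed adjustment: compare
  # within speed bins present in both directions
  g <- srp[srp$band == "30-50", ]
  wide <- tidyr::pivot_wider(g, id_cols = "speed_cms",
                             names_from = "direction",
                             values_from = "power")
  wide <- wide[complete.cases(wide), ]
  expect_gt(mean(wide$to_reward > wide$to_trigger), 0.5)
})
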