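# Behavioral preprocessing: Kalman smoothing, kinematics, linearization,
# trial segmentation, run phase, MAD exclusion, and binning.

test_that("Kalman smoothing shrinks stationary observation noise below half", {
  set.seed(1)
  n <- 600
  tr <- tibble::tibble(frame_time_s = (0:(n - 1)) / 20,
                       head_x = rnorm(n, 10, 1), head_y = rnorm(n, 5, 1),
                       tail_x = rnorm(n, -5, 1), tail_y = rnorm(n, 5, 1),
                       valid = TRUE)
  sm <- suppressWarnings(smooth_tracking(tr))
  expect_lt(sd(sm$head_x), 0.5)
  expect_lt(sd(sm$tail_y), 0.5)
})

test_that("noiseless straight-line motion passes through unchanged", {
  tr <- line_tracking()
  sm <- suppressWarnings(smooth_tracking(tr))
  expect_lt(max(abs(sm$head_x - tr$head_x)), 0.01)
})

test_that("a larger observation covariance multiplier smooths more", {
  s <- fx_session()
  d2 <- function(v) sum(diff(diff(v))^2)
  sm1 <- suppressWarnings(smooth_tracking(s$tracking, obs_cov_scale = 1))
  sm5 <- suppressWarnings(smooth_tracking(s$tracking, obs_cov_scale = 5))
  expect_lt(d2(sm5$head_x), d2(sm1$head_x))
  # gaps are imputed
  expect_false(any(is.na(sm5$head_x)))
})

test_that("kinematics of uniform motion are speed-constant and turn-free", {
  k <- compute_kinematics(line_tracking(speed_cms = 30), "right")
  expect_equal(range(k$speed_cms), c(30, 30), tolerance = 1e-9)
  expect_lt(max(abs(k$accel_cms2)), 1e-8)
  expect_lt(max(abs(k$turning_degs)), 1e-8)
})

test_that("circular walking yields |turning| equal to the angular rate", {
  fps <- 20; omega <- 45  # deg/s
  tt <- (0:400) / fps
  ang <- omega * pi / 180 * tt
  R <- 20
  tr <- tibble::tibble(frame_time_s = tt,
                       head_x = R * cos(ang), head_y = R * sin(ang),
                       tail_x = (R + 15) * cos(ang),
                       tail_y = (R + 15) * sin(ang),
                       valid = TRUE)
  k <- compute_kinematics(tr, "right")
  mid <- 50:350
  expect_equal(mean(abs(k$turning_degs[mid])), omega, tolerance = 0.02)
  # mirror-flipping the arena flips the turning sign
  tr2 <- dplyr::mutate(tr, head_x = -head_x, tail_x = -tail_x)
  k2 <- compute_kinematics(tr2, "right")
  expect_equal(k2$turning_degs[mid], -k$turning_degs[mid],
               tolerance = 1e-6)
  # hemisphere metadata is mandatory
  expect_error(compute_kinematics(tr), "hemisphere")
  # left-hemisphere convention is the sign flip of the right
  kl <- compute_kinematics(tr, "left")
  expect_equal(kl$turning_degs[mid], -k$turning_degs[mid],
               tolerance = 1e-9)
})

test_that("linearization maps zones to end bins and is monotone", {
  mk <- function(x) tibble::tibble(frame_time_s = seq_along(x) / 20,
                                   head_x = x, head_y = 0,
                                   tail_x = x - 15, tail_y = 0,
                                   valid = TRUE)
  lin <- linearize_position(mk(c(-20, -10, 25, 60, 70)))
  expect_equal(lin$position_bin, c(1L, 1L, 6L, 10L, 10L))
  # axis midpoint lands on the half-open boundary convention
  expect_equal(linearize_position(mk(c(24.999, 25)))$position_bin,
               c(5L, 6L))
  # monotone traversal => monotone bins
  lin2 <- linearize_position(mk(seq(-24, 74, by = 2)))
  expect_true(all(diff(lin2$position_bin) >= 0))
  expect_equal(range(lin2$position_bin), c(1L, 10L))
  # far out of bounds is invalid
  expect_true(is.na(linearize_position(mk(200))$position_bin))
})

test_that("trial segmentation reconstructs the generator truth exactly", {
  s <- fx_session()
  seg <- segment_trials(s$truth$clean, s$events)
  expect_equal(nrow(seg$trials), nrow(s$truth$trials))
  expect_equal(seg$trials$start_time_s, s$truth$trials$start_time_s,
               tolerance = 1e-9)
  expect_equal(seg$trials$outcome, s$truth$trials$outcome)
  expect_equal(seg$traversals$start_s, s$truth$traversals$start_s,
               tolerance = 1e-9)
  expect_equal(seg$traversals$end_s, s$truth$traversals$end_s,
               tolerance = 1e-9)
})

test_that("a truncated session drops the trailing incomplete trial", {
  s <- fx_session()
  tv <- s$truth$traversals
  cut_t <- tv$start_s[tv$trial == 30 & tv$direction == "to_reward"] + 0.1
  tr_cut <- s$truth$clean[s$truth$clean$frame_time_s <= cut_t, ]
  ev_cut <- s$events[s$events$time_s <= cut_t, ]
  seg <- suppressMessages(segment_trials(tr_cut, ev_cut))
  expect_equal(nrow(seg$trials), 29)
})

test_that("double beam breaks within the debounce window are deduplicated", {
  s <- fx_session()
  port <- s$events[s$events$event_type == "reward_port", ]
  dup <- dplyr::mutate(port[1, ], time_s = time_s + 0.05)
  ev <- dplyr::arrange(dplyr::bind_rows(s$events, dup), time_s)
  seg <- segment_trials(s$truth$clean, ev)
  expect_equal(nrow(seg$trials), nrow(s$truth$trials))
})

test_that("run phase requires both a traversal segment and running speed", {
  fx <- fx_targeted()
  s <- fx$session
  kin <- compute_kinematics(s$truth$clean, "right")
  phase <- score_run_phase(kin, s$truth$traversals)
  tv <- s$truth$traversals
  mid_t <- mean(unlist(tv[1, c("start_s", "end_s")]))
  i <- which.min(abs(kin$frame_time_s - mid_t))
  expect_equal(phase[i], tv$direction[1])
  # platform frames are "none" even though the animal moves while turning
  dwell_t <- tv$end_s[1] + 0.3
  j <- which.min(abs(kin$frame_time_s - dwell_t))
  expect_equal(phase[j], "none")
  # speed below threshold inside a segment scores "none"
  kin2 <- kin
  kin2$speed_cms[i] <- 1
  expect_equal(score_run_phase(kin2, tv)[i], "none")
})

test_that("MAD-based animal exclusion applies the quoted rule", {
  cohort <- tibble::tibble(
    animal_id = paste0("r", 1:10),
    median_trial_time_s = c(rep(6, 9), 12),
    n_trials = c(600, 612, 594, 606, 596, 618, 602, 598, 608, 100))
  out <- suppressMessages(exclude_animals(cohort))
  expect_false(out$keep[10])
  expect_true(all(out$keep[1:9]))
  # identical animals: zero MAD, nobody excluded
  same <- tibble::tibble(animal_id = c("a", "b", "c"),
                         median_trial_time_s = c(5, 5, 5),
                         n_trials = c(500, 500, 500))
  expect_true(all(suppressMessages(exclude_animals(same))$keep))
  # tiny cohorts are refused unless overridden
  expect_error(exclude_animals(same[1:2, ]), "3 animals")
  expect_silent(suppressMessages(exclude_animals(same[1:2, ],
                                                 allow_small = TRUE)))
})

test_that("binning conserves spike mass and calibrates rates", {
  b <- fx_binned()
  for (u in b$unit_ids[1:5])
    expect_equal(sum(b$counts[, u]), sum(b$counts_raw[, u]),
                 tolerance = 1e-6)
  # z-scored regressors are standardized over included bins
  inc <- b$bins$included
  expect_lt(abs(mean(b$bins$speed_z[inc])), 1e-9)
  expect_equal(sd(b$bins$speed_z[inc]), 1, tolerance = 1e-9)
  # a constant 10 Hz train averages 0.5 counts per 50 ms bin
  fx <- fx_targeted()
  s <- fx$session
  T <- max(s$tracking$frame_time_s)
  flat_rate <- sum(fx$binned$counts_raw[, "flat"]) / T / 8  # baseline 8 Hz
  expect_equal(flat_rate * 8 * 0.05,
               mean(fx$binned$counts_raw[, "flat"]), tolerance = 0.05)
})
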