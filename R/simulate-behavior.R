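# Behavioral simulator: trajectory, task events, and ground-truth trial
# structure for the two-platform linear-track task.

# Trapezoidal run along the axis from x0 to x1: accelerate at
# plateau/ramp_s, cruise near the plateau with a smooth sinusoidal speed
# modulation (speed naturally varies along the track), decelerate to stop
# at x1. Returns clean per-frame axis positions (excluding the start).
run_leg <- function(x0, x1, plateau, ramp_s, dt, mod_amp = 0.25,
                    mod_phase = 0, mod_cycles = 1.5) {
  L <- abs(x1 - x0)
  dir <- sign(x1 - x0)
  a <- plateau / ramp_s
  pos <- 0; v <- 0
  out <- numeric(0)
  while (pos < L - 1e-9) {
    remaining <- L - pos
    v_stop <- sqrt(2 * a * remaining)
    target <- plateau * (1 + mod_amp *
                           sin(2 * pi * mod_cycles * pos / L + mod_phase))
    # track the modulated target with bounded acceleration, capped by the
    # stopping envelope
    v <- min(max(target, v - a * dt), v + a * dt, v_stop)
    if (v * dt > remaining) v <- remaining / dt
    pos <- pos + v * dt
    out <- c(out, pos)
    if (length(out) > 1e5) abort("run_leg failed to terminate")
  }
  x0 + dir * out
}

# Linear interpolation of the time (in frame units) at which x crosses c.
crossing_idx <- function(x, c, increasing) {
  if (increasing) i <- which(x[-1] >= c & x[-length(x)] < c)[1]
  else i <- which(x[-1] <= c & x[-length(x)] > c)[1]
  if (is.na(i)) return(NA_real_)
  frac <- (c - x[i]) / (x[i + 1] - x[i])
  i + frac
}

#' Simulate task behavior
#'
#' Generates the tracking trajectory, beam-break and reward events, and the
#' ground-truth trial/traversal table for a session of the linear-track
#' reward-seeking task. Each trial starts when the animal leaves the reward
#' zone, runs to the trigger zone (traversal "to trigger"), turns 180
#' degrees, runs back (traversal "to reward"), and collects reward at the
#' port in a `reward_probability` fraction of trials. Running toward reward
#' is faster than toward the trigger under the default speed profiles.
#'
#' @param cfg a [sim_config()].
#' @return an `ephys_session` with tracking, events, and ground truth
#'   (`truth$trials`, `truth$traversals`, `truth$clean` noiseless trajectory).
#' @export
simulate_behavior <- function(cfg) {
  validate_sim_config(cfg)
  with_seed(child_seed(cfg$seed, "behavior"), simulate_behavior_impl(cfg))
}

simulate_behavior_impl <- function(cfg) {
  dt <- 1 / cfg$frame_rate
  g <- cfg$arena
  port_x <- g$reward_port_x
  trig_center <- g$track_length + g$platform_depth / 2

  x <- numeric(0); heading <- numeric(0)
  events <- list(); trials <- list(); traversals <- list()
  cur_heading <- 0

  add_dwell <- function(dur, h0, h1) {
    nfr <- max(1, round(dur / dt))
    list(x = rep(x_last(), nfr),
         heading = h0 + (h1 - h0) * seq_len(nfr) / nfr)
  }
  x_last <- function() if (length(x)) x[length(x)] else port_x

  # initial dwell at the port, facing the track
  nfr0 <- round(2 / dt)
  x <- rep(port_x, nfr0); heading <- rep(0, nfr0)

  for (tr in seq_len(cfg$n_trials)) {
    jitter_t <- runif(1, 0.92, 1.08)
    jitter_r <- runif(1, 0.92, 1.08)

    # leg A: run to the trigger platform
    xa <- run_leg(x_last(), trig_center, cfg$speed_to_trigger * jitter_t,
                  cfg$accel_ramp_s, dt, mod_phase = runif(1, 0, 2 * pi))
    offA <- length(x)
    x <- c(x, xa); heading <- c(heading, rep(0, length(xa)))
    startA <- (offA + crossing_idx(c(x[offA], xa), 0, TRUE) - 2) * dt
    trigA <- (offA + crossing_idx(c(x[offA], xa), g$track_length, TRUE) - 2) * dt
    events[[length(events) + 1]] <- tibble(
      time_s = trigA, event_type = "trigger_beam", payload = NA_real_)

    # leg B: 180-degree turn on the trigger platform
    turn_sign <- sample(c(-1, 1), 1)
    dw <- add_dwell(runif(1, cfg$trigger_dwell_s[1], cfg$trigger_dwell_s[2]),
                    0, turn_sign * pi)
    x <- c(x, dw$x); heading <- c(heading, dw$heading)
    h_back <- turn_sign * pi

    # leg C: run back to the reward port
    xc <- run_leg(x_last(), port_x, cfg$speed_to_reward * jitter_r,
                  cfg$accel_ramp_s, dt, mod_phase = runif(1, 0, 2 * pi))
    offC <- length(x)
    x <- c(x, xc); heading <- c(heading, rep(h_back, length(xc)))
    startC <- (offC + crossing_idx(c(x[offC], xc), g$track_length, FALSE) - 2) * dt
    endC <- (offC + crossing_idx(c(x[offC], xc), 0, FALSE) - 2) * dt
    port_t <- (length(x) - 1) * dt
    events[[length(events) + 1]] <- tibble(
      time_s = port_t, event_type = "reward_port", payload = NA_real_)

    rewarded <- runif(1) < cfg$reward_probability
    if (rewarded) {
      events[[length(events) + 1]] <- tibble(
        time_s = port_t + 0.2, event_type = "reward_delivered",
        payload = NA_real_)
      dwell_dur <- runif(1, cfg$reward_dwell_s[1], cfg$reward_dwell_s[2])
    } else {
      dwell_dur <- runif(1, 0.5, 1.2)
    }

    # leg D: consume/turn on the reward platform, end facing the track
    turn_sign2 <- sample(c(-1, 1), 1)
    dw2 <- add_dwell(dwell_dur, h_back, h_back + turn_sign2 * pi)
    x <- c(x, dw2$x)
    heading <- c(heading, dw2$heading)

    trials[[tr]] <- tibble(
      trial = tr, start_time_s = startA, trigger_entry_time_s = trigA,
      reward_port_time_s = port_t,
      outcome = if (rewarded) "rewarded" else "omitted")
    traversals[[length(traversals) + 1]] <- tibble(
      trial = tr, direction = "to_trigger",
      start_s = startA, end_s = trigA)
    traversals[[length(traversals) + 1]] <- tibble(
      trial = tr, direction = "to_reward",
      start_s = startC, end_s = endC)
  }

  n <- length(x)
  frame_time_s <- (seq_len(n) - 1) * dt
  trials <- dplyr::bind_rows(trials)
  trials$end_time_s <- c(trials$start_time_s[-1],
                         frame_time_s[n])[seq_len(nrow(trials))]
  traversals <- dplyr::bind_rows(traversals)

  head_x <- x
  head_y <- rep(0, n)
  tail_x <- head_x - g$body_length * cos(heading)
  tail_y <- head_y - g$body_length * sin(heading)

  valid <- runif(n) >= cfg$invalid_frame_prob
  noise <- function() rnorm(n, 0, cfg$tracking_noise_sd)
  tracking <- tibble(
    frame_time_s = frame_time_s,
    head_x = head_x + noise(), head_y = head_y + noise(),
    tail_x = tail_x + noise(), tail_y = tail_y + noise(),
    valid = valid)
  tracking[!valid, c("head_x", "head_y", "tail_x", "tail_y")] <- NA_real_

  clean <- tibble(frame_time_s = frame_time_s,
                  head_x = head_x, head_y = head_y,
                  tail_x = tail_x, tail_y = tail_y,
                  heading = heading, valid = TRUE)

  events <- dplyr::arrange(dplyr::bind_rows(events), .data$time_s)
  new_session(
    tracking = tracking, events = events,
    spikes = tibble(unit_id = character(), time_s = numeric()),
    units = tibble(unit_id = character()),
    lfp = NULL, config = unclass(cfg),
    truth = list(trials = trials, traversals = traversals, clean = clean),
    meta = list(hemisphere = cfg$hemisphere, arena = g))
}
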