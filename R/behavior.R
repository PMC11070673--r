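# Behavioral preprocessing: tracking smoothing, kinematics, trial
# segmentation, position linearization, run-phase scoring, animal-level
# exclusion, and 50-ms binning.

#' Two-pass Kalman smoothing of tracking coordinates
#'
#' Each marker coordinate is modelled as a constant-velocity linear-Gaussian
#' state-space process. Model parameters (process and observation noise,
#' initial state) are estimated by Expectation Maximization; a second
#' smoothing pass is then run with the observation covariance multiplied by
#' `obs_cov_scale`, reducing trust in the raw observations and yielding
#' smoother estimates. Missing frames are filled by the smoother.
#'
#' @param tracking tibble with `frame_time_s`, `head_x`, `head_y`, `tail_x`,
#'   `tail_y`, `valid`.
#' @param obs_cov_scale multiplier applied to the estimated observation
#'   covariance on the second pass (default 5).
#' @param em_iter maximum EM iterations.
#' @return tracking tibble of the same shape with smoothed coordinates and
#'   `valid = TRUE` everywhere (gaps imputed).
#' @export
smooth_tracking <- function(tracking, obs_cov_scale = 5, em_iter = 100) {
  assert_that(sum(tracking$valid, na.rm = TRUE) >= 100,
              "need at least 100 valid frames to smooth tracking")
  dt <- median(diff(tracking$frame_time_s))
  out <- tracking
  for (col in c("head_x", "head_y", "tail_x", "tail_y")) {
    y <- tracking[[col]]
    y[!tracking$valid] <- NA_real_
    if (sd(y, na.rm = TRUE) < 1e-9) next  # degenerate constant input
    fit <- cpp_kalman_two_pass(y, dt, em_iter, 1e-4, obs_cov_scale)
    if (!fit$converged) {
      warn(sprintf(
        "Kalman EM did not converge for %s after %d iterations; using pass-1 estimates",
        col, em_iter))
      out[[col]] <- fit$pass1
    } else {
      out[[col]] <- fit$pass2
    }
  }
  out$valid <- TRUE
  out
}

#' Kinematic regressors from a smoothed trajectory
#'
#' Speed is the magnitude of the head velocity (cm/s), acceleration its time
#' derivative (cm/s^2), and turning the angular velocity of the heading --
#' the angle of the head relative to the tail base -- in degrees/s. The
#' turning sign convention is ipsiversive-positive: turns toward the
#' recorded hemisphere are positive.
#'
#' @param tracking smoothed tracking tibble.
#' @param hemisphere `"left"` or `"right"`; required for the sign convention.
#' @return tibble with `frame_time_s`, `speed_cms`, `accel_cms2`,
#'   `turning_degs`, `heading_rad`.
#' @export
compute_kinematics <- function(tracking, hemisphere) {
  if (missing(hemisphere) || is.null(hemisphere) ||
      !hemisphere %in% c("left", "right"))
    abort("hemisphere metadata ('left' or 'right') is required for the turning sign convention")
  t <- tracking$frame_time_s
  dt <- c(diff(t), NA)
  cdiff <- function(v) {
    n <- length(v)
    d <- numeric(n)
    d[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)])
    d[1] <- (v[2] - v[1]) / (t[2] - t[1])
    d[n] <- (v[n] - v[n - 1]) / (t[n] - t[n - 1])
    d
  }
  vx <- cdiff(tracking$head_x)
  vy <- cdiff(tracking$head_y)
  speed <- sqrt(vx^2 + vy^2)
  accel <- cdiff(speed)
  heading <- atan2(tracking$head_y - tracking$tail_y,
                   tracking$head_x - tracking$tail_x)
  hu <- unwrap_phase(heading)
  dhead <- cdiff(hu) * 180 / pi
  # ipsiversive-positive: clockwise for a right-hemisphere recording
  turning <- if (hemisphere == "right") -dhead else dhead
  tibble(frame_time_s = t, speed_cms = speed, accel_cms2 = accel,
         turning_degs = turning, heading_rad = heading)
}

unwrap_phase <- function(p) {
  d <- diff(p)
  d <- d - 2 * pi * round(d / (2 * pi))
  cumsum(c(p[1], d))
}

#' Linearize position onto the track axis
#'
#' Projects the head position onto the 1D axis running reward platform ->
#' track -> trigger platform and discretizes it into 10 bins. The normalized
#' axis coordinate maps the reward platform to bin 1, the eight equal track
#' segments to bins 2-9, and the trigger platform to bin 10; bins are
#' half-open with the last bin right-closed. Frames outside the arena
#' (beyond a tolerance) are marked invalid.
#'
#' @param tracking tracking tibble (smoothed or clean).
#' @param arena arena geometry list (see [arena_geometry()]).
#' @param tolerance_cm out-of-bounds tolerance, cm.
#' @return tibble with `frame_time_s`, `axis_cm`, `s` (normalized 0-1),
#'   `position_bin` (1-10, NA when invalid).
#' @export
linearize_position <- function(tracking, arena = arena_geometry(),
                               tolerance_cm = 5) {
  x <- tracking$head_x
  L <- arena$track_length
  pd <- arena$platform_depth
  s <- ifelse(x < 0, 0.1 * (x + pd) / pd,
              ifelse(x < L, 0.1 + 0.8 * x / L,
                     0.9 + 0.1 * (x - L) / pd))
  valid <- !is.na(x) & x >= -pd - tolerance_cm & x <= L + pd + tolerance_cm
  s <- pmin(pmax(s, 0), 1)
  bin <- pmin(floor(10 * s) + 1, 10)
  bin[!valid] <- NA_integer_
  tibble(frame_time_s = tracking$frame_time_s, axis_cm = x, s = s,
         position_bin = as.integer(bin))
}

# Debounce repeated events of the same type closer than window_s.
debounce_events <- function(events, window_s = 0.1) {
  events |>
    dplyr::arrange(.data$time_s) |>
    dplyr::group_by(.data$event_type) |>
    dplyr::filter(c(TRUE, diff(.data$time_s) > window_s)) |>
    dplyr::ungroup()
}

# All interpolated crossing times of the axis value `c` in direction
# increasing (TRUE) or decreasing.
all_crossings <- function(t, x, c, increasing) {
  n <- length(x)
  if (increasing) idx <- which(x[-1] >= c & x[-n] < c)
  else idx <- which(x[-1] <= c & x[-n] > c)
  if (!length(idx)) return(numeric(0))
  frac <- (c - x[idx]) / (x[idx + 1] - x[idx])
  t[idx] + frac * (t[idx + 1] - t[idx])
}

#' Segment a session into trials and traversals
#'
#' Trials are delimited by reward-zone exits; each correct trial contains one
#' trigger-zone entry followed by one reward-port beam break, with the
#' outcome read from reward-delivery events. Beam-break events closer than
#' the debounce window are deduplicated. A trailing incomplete trial is
#' dropped.
#'
#' @param tracking tracking tibble (clean or smoothed).
#' @param events events tibble.
#' @param arena arena geometry.
#' @param debounce_s debounce window for duplicate beam breaks, s.
#' @return list with `trials` and `traversals` tibbles.
#' @export
segment_trials <- function(tracking, events, arena = arena_geometry(),
                           debounce_s = 0.1) {
  ev <- debounce_events(events, debounce_s)
  t <- tracking$frame_time_s
  x <- tracking$head_x
  L <- arena$track_length
  exits <- all_crossings(t, x, 0, TRUE)          # leaving the reward zone
  ret_entries <- all_crossings(t, x, 0, FALSE)   # re-entering the reward zone
  trig_in <- all_crossings(t, x, L, TRUE)        # entering the trigger zone
  trig_out <- all_crossings(t, x, L, FALSE)      # leaving the trigger zone
  trig_beams <- ev$time_s[ev$event_type == "trigger_beam"]
  ports <- ev$time_s[ev$event_type == "reward_port"]
  rewards <- ev$time_s[ev$event_type == "reward_delivered"]

  trials <- list(); traversals <- list()
  n_dropped <- 0L
  for (i in seq_along(exits)) {
    e <- exits[i]
    e_next <- if (i < length(exits)) exits[i + 1] else Inf
    tb <- trig_beams[trig_beams > e & trig_beams < e_next]
    if (!length(tb)) { n_dropped <- n_dropped + 1L; next }
    pb <- ports[ports > tb[1] & ports < e_next + 5]
    if (!length(pb)) { n_dropped <- n_dropped + 1L; next }
    ti <- trig_in[trig_in >= e - 1e-9 & trig_in < e_next][1]
    to <- trig_out[trig_out > ti & trig_out < e_next + 5][1]
    re <- ret_entries[ret_entries > to & ret_entries < e_next + 5][1]
    if (is.na(ti) || is.na(to) || is.na(re)) { n_dropped <- n_dropped + 1L; next }
    rewarded <- any(rewards > pb[1] - 1e-9 & rewards < pb[1] + 1)
    k <- length(trials) + 1L
    trials[[k]] <- tibble(
      trial = k, start_time_s = e,
      trigger_entry_time_s = tb[1], reward_port_time_s = pb[1],
      end_time_s = if (is.finite(e_next)) e_next else max(t),
      outcome = if (rewarded) "rewarded" else "omitted")
    traversals[[length(traversals) + 1]] <- tibble(
      trial = k, direction = "to_trigger", start_s = e, end_s = ti)
    traversals[[length(traversals) + 1]] <- tibble(
      trial = k, direction = "to_reward", start_s = to, end_s = re)
  }
  if (n_dropped > 0)
    message(sprintf("segment_trials: dropped %d incomplete trial(s)",
                    n_dropped))
  trials <- if (length(trials)) dplyr::bind_rows(trials) else
    tibble(trial = integer(), start_time_s = numeric(),
           trigger_entry_time_s = numeric(), reward_port_time_s = numeric(),
           end_time_s = numeric(), outcome = character())
  traversals <- if (length(traversals)) dplyr::bind_rows(traversals) else
    tibble(trial = integer(), direction = character(), start_s = numeric(),
           end_s = numeric())
  traversals$duration_s <- traversals$end_s - traversals$start_s
  list(trials = trials, traversals = traversals)
}

#' Score the run phase of every frame
#'
#' Frames inside a traversal segment and moving faster than the running
#' threshold are labelled with the traversal direction; platform dwell,
#' turning, and sub-threshold frames are labelled `"none"`.
#'
#' @param kinematics output of [compute_kinematics()].
#' @param traversals traversal tibble from [segment_trials()].
#' @param speed_threshold_cms running-speed threshold, cm/s.
#' @return character vector, one of `"to_reward"`, `"to_trigger"`, `"none"`
#'   per frame.
#' @export
score_run_phase <- function(kinematics, traversals, speed_threshold_cms = 5) {
  t <- kinematics$frame_time_s
  phase <- rep("none", length(t))
  for (d in c("to_reward", "to_trigger")) {
    seg <- traversals[traversals$direction == d, ]
    if (!nrow(seg)) next
    inside <- rep(FALSE, length(t))
    for (j in seq_len(nrow(seg)))
      inside <- inside | (t >= seg$start_s[j] & t <= seg$end_s[j])
    phase[inside & kinematics$speed_cms > speed_threshold_cms] <- d
  }
  phase
}

#' Animal-level exclusion by median absolute deviation
#'
#' Excludes animals with an outlying median trial time (above
#' median + scale * MAD of the cohort's median trial times) or an outlying
#' low trial count (below median - scale * MAD of the cohort's counts).
#' The raw MAD is used (no 1.4826 consistency constant), matching the
#' standardized outlier rule with a scale factor of 1.5. A zero-MAD
#' criterion excludes nobody.
#'
#' @param summaries tibble with `animal_id`, `median_trial_time_s`,
#'   `n_trials`.
#' @param scale MAD scale factor (default 1.5).
#' @param mad_constant consistency constant passed to [stats::mad()]
#'   (default 1 = raw MAD).
#' @param allow_small override the >= 3 animals requirement.
#' @return the input tibble with `keep` and `reason` columns; thresholds in
#'   `attr(, "thresholds")`.
#' @export
exclude_animals <- function(summaries, scale = 1.5, mad_constant = 1,
                            allow_small = FALSE) {
  if (nrow(summaries) < 3 && !allow_small)
    abort("need summaries for at least 3 animals (MAD is unstable below that); set allow_small = TRUE to override")
  tt <- summaries$median_trial_time_s
  nn <- summaries$n_trials
  mad_tt <- stats::mad(tt, constant = mad_constant)
  mad_nn <- stats::mad(nn, constant = mad_constant)
  thr_time <- median(tt) + scale * mad_tt
  thr_n <- median(nn) - scale * mad_nn
  too_slow <- if (mad_tt > 0) tt > thr_time else rep(FALSE, length(tt))
  too_few <- if (mad_nn > 0) nn < thr_n else rep(FALSE, length(nn))
  if (mad_tt == 0 || mad_nn == 0)
    message("exclude_animals: zero MAD for a criterion; no exclusions applied for it")
  out <- summaries
  out$keep <- !(too_slow | too_few)
  out$reason <- dplyr::case_when(
    too_slow & too_few ~ "slow_trials+few_trials",
    too_slow ~ "slow_trials",
    too_few ~ "few_trials",
    TRUE ~ NA_character_)
  attr(out, "thresholds") <- c(max_median_trial_time_s = thr_time,
                               min_n_trials = thr_n)
  out
}

#' Bin a session into 50-ms bins
#'
#' Builds the substrate for the encoding models: behavioral regressors
#' sampled at bin centers and per-unit spike counts smoothed with a Gaussian
#' kernel (SD 100 ms, truncated at 4 SD, renormalized so total counts are
#' conserved). Continuous regressors are z-scored over included bins.
#'
#' @param tracking smoothed tracking tibble.
#' @param trials,traversals output of [segment_trials()].
#' @param spikes spikes tibble (`unit_id`, `time_s`).
#' @param hemisphere recorded hemisphere.
#' @param arena arena geometry.
#' @param bin_s bin width in seconds (default 0.05).
#' @param smooth_sd_s Gaussian smoothing SD in seconds (default 0.1).
#' @param speed_threshold_cms running threshold for run-phase scoring.
#' @return a `binned_session`: list with `bins` (regressor tibble), `counts`
#'   (smoothed bins x units matrix), `counts_raw`, `unit_ids`, `bin_s`.
#' @export
bin_session <- function(tracking, trials, traversals, spikes,
                        hemisphere, arena = arena_geometry(),
                        bin_s = 0.05, smooth_sd_s = 0.1,
                        speed_threshold_cms = 5) {
  t0 <- tracking$frame_time_s[1]
  t1 <- tracking$frame_time_s[nrow(tracking)]
  assert_that(t1 - t0 > bin_s, "session shorter than one bin")
  edges <- seq(t0, t1, by = bin_s)
  centers <- edges[-length(edges)] + bin_s / 2
  nb <- length(centers)

  kin <- compute_kinematics(tracking, hemisphere)
  lin <- linearize_position(tracking, arena)
  phase_frame <- score_run_phase(kin, traversals, speed_threshold_cms)

  at_centers <- function(v) approx(tracking$frame_time_s, v, centers,
                                   rule = 2)$y
  nearest_frame <- findInterval(centers, tracking$frame_time_s,
                                all.inside = TRUE)
  speed <- at_centers(kin$speed_cms)
  accel <- at_centers(kin$accel_cms2)
  turning <- at_centers(kin$turning_degs)
  position_bin <- lin$position_bin[nearest_frame]
  run_phase <- phase_frame[nearest_frame]

  # trial membership and trial-level covariates
  trial_id <- rep(NA_integer_, nb)
  outcome <- rep("none", nb)
  if (nrow(trials)) {
    idx <- findInterval(centers, trials$start_time_s)
    ok <- idx >= 1 & centers < trials$end_time_s[pmax(idx, 1)]
    trial_id[ok] <- trials$trial[idx[ok]]
    # the outcome is only known once the animal reaches the port; bins
    # before that stay "none" (distinguishes outcome from trial type)
    outcome[ok] <- ifelse(
      centers[ok] >= trials$reward_port_time_s[idx[ok]],
      trials$outcome[idx[ok]], "none")
    dur <- trials$end_time_s - trials$start_time_s
    cutoff <- median(dur) + 3 * stats::mad(dur, constant = 1)
    slow <- dur > cutoff
    hist_rew <- c(FALSE, (trials$outcome == "rewarded")[-nrow(trials)])
    type_rew <- trials$outcome == "rewarded"
    trial_time_slow <- rep(0, nb)
    trial_history_rewarded <- rep(0, nb)
    trial_type_rewarded <- rep(0, nb)
    m <- match(trial_id, trials$trial)
    has <- !is.na(m)
    trial_time_slow[has] <- as.numeric(slow[m[has]])
    trial_history_rewarded[has] <- as.numeric(hist_rew[m[has]])
    trial_type_rewarded[has] <- as.numeric(type_rew[m[has]])
  } else {
    trial_time_slow <- trial_history_rewarded <- trial_type_rewarded <-
      rep(0, nb)
  }

  included <- !is.na(position_bin) & is.finite(speed) & is.finite(accel) &
    is.finite(turning)
  zs <- function(v) {
    mu <- mean(v[included]); s <- sd(v[included])
    if (!is.finite(s) || s == 0) s <- 1
    (v - mu) / s
  }
  bins <- tibble(
    bin_time_s = centers,
    position_bin = position_bin,
    run_phase = run_phase,
    trial_id = trial_id,
    trial_outcome = outcome,
    speed_cms = speed, accel_cms2 = accel, turning_degs = turning,
    speed_z = zs(speed), accel_z = zs(accel), turning_z = zs(turning),
    trial_time_slow = trial_time_slow,
    trial_history_rewarded = trial_history_rewarded,
    trial_type_rewarded = trial_type_rewarded,
    included = included)

  unit_ids <- unique(spikes$unit_id)
  counts_raw <- matrix(0, nb, length(unit_ids),
                       dimnames = list(NULL, unit_ids))
  for (u in unit_ids) {
    st <- spikes$time_s[spikes$unit_id == u]
    st <- st[st >= edges[1] & st < edges[length(edges)]]
    if (length(st))
      counts_raw[, u] <- tabulate(findInterval(st, edges), nbins = nb)
  }
  counts <- apply(counts_raw, 2, gauss_smooth, sd_bins = smooth_sd_s / bin_s)
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = nb,
                                             dimnames = list(NULL, unit_ids))
  structure(list(bins = bins, counts = counts, counts_raw = counts_raw,
                 unit_ids = unit_ids, bin_s = bin_s,
                 smooth_sd_s = smooth_sd_s),
            class = "binned_session")
}

#' @export
print.binned_session <- function(x, ...) {
  cat(sprintf("<binned_session> %d bins of %g ms, %d units\n",
              nrow(x$bins), 1000 * x$bin_s, length(x$unit_ids)))
  invisible(x)
}
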