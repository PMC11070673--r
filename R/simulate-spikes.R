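# Spike-train simulator: inhomogeneous Poisson firing driven by the
# generative log-linear model on the binned behavioral regressors, with
# optional von Mises phase locking to the gamma reference oscillation.

# Best-Fisher von Mises sampler.
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-8) return(runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1
  while (i <= n) {
    u <- runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c <- kappa * (r - f)
    if (c * (2 - c) - u[2] > 0 || log(c / u[2]) + 1 - c >= 0) {
      out[i] <- mu + sign(u[3] - 0.5) * acos(f)
      i <- i + 1
    }
  }
  atan2(sin(out), cos(out))
}

# Binned regressors from the generator's noiseless trajectory.
truth_binned <- function(session, cfg) {
  clean <- session$truth$clean
  bin_session(clean, session$truth$trials, session$truth$traversals,
              tibble(unit_id = character(), time_s = numeric()),
              hemisphere = cfg$hemisphere, arena = cfg$arena)
}

# Per-bin rate (Hz) for one unit's generative weights.
generative_rate <- function(design, unit_row, rate_ceiling_hz, n_bins) {
  w <- unit_row$weights[[1]]
  eta <- rep(log(unit_row$baseline_rate_hz), n_bins)
  for (v in names(w)) {
    cols <- design$cols[[v]]
    eta <- eta + as.vector(design$X[, cols, drop = FALSE] %*% w[[v]])
  }
  lambda <- exp(eta)
  if (any(lambda > rate_ceiling_hz))
    abort(sprintf(
      "generative rate for unit %s exceeds the %g Hz ceiling (max %.1f Hz)",
      unit_row$unit_id, rate_ceiling_hz, max(lambda)))
  lambda
}

#' Simulate spike trains from ground-truth tuning
#'
#' Per-bin spike counts are Poisson with log-rate = log(baseline) +
#' weights x regressors, where the regressors are computed from the
#' noiseless trajectory with the same binning conventions the analysis
#' pipeline uses. Spikes of phase-locked units are placed within their bin
#' at gamma phases drawn from a von Mises law around the unit's preferred
#' phase (during traversals of the flagged directions); all other spikes
#' are placed uniformly.
#'
#' @param session session with behavior and LFP simulated.
#' @param truth tibble from [make_population_truth()] or [unit_truth()].
#' @param cfg the [sim_config()].
#' @return the session with `spikes` and `units` filled in and the truth
#'   table stored in `truth$units`.
#' @export
simulate_spikes <- function(session, truth, cfg) {
  validate_sim_config(cfg)
  assert_that(!is.null(session$truth$gamma_ref),
              "simulate_lfp() must run before simulate_spikes()")
  with_seed(child_seed(cfg$seed, "spikes"),
            simulate_spikes_impl(session, truth, cfg))
}

simulate_spikes_impl <- function(session, truth, cfg) {
  binned <- truth_binned(session, cfg)
  nb <- nrow(binned$bins)
  design <- build_design_matrix(binned, ENCODING_VARIABLES,
                                rows = rep(TRUE, nb))
  bin_s <- binned$bin_s
  edges0 <- binned$bins$bin_time_s - bin_s / 2
  gref <- session$truth$gamma_ref
  run_phase <- binned$bins$run_phase

  all_spikes <- list()
  for (i in seq_len(nrow(truth))) {
    u <- truth[i, ]
    lambda <- generative_rate(design, u, cfg$rate_ceiling_hz, nb)
    counts <- rpois(nb, lambda * bin_s)
    idx <- which(counts > 0)
    if (!length(idx)) {
      all_spikes[[i]] <- tibble(unit_id = u$unit_id, time_s = numeric(0))
      next
    }
    bin_of_spike <- rep(idx, counts[idx])
    lock_dirs <- c("to_reward", "to_trigger")[c(u$lock_to_reward,
                                                u$lock_to_trigger)]
    locked <- u$kappa > 0 & run_phase[bin_of_spike] %in% lock_dirs
    times <- numeric(length(bin_of_spike))
    if (any(!locked)) {
      nb_u <- sum(!locked)
      times[!locked] <- edges0[bin_of_spike[!locked]] + runif(nb_u, 0, bin_s)
    }
    if (any(locked)) {
      nlk <- sum(locked)
      theta <- rvonmises(nlk, u$preferred_phase, u$kappa)
      # solve 2*pi*f*t + phase0 = theta (mod 2*pi) for t inside the bin
      f <- gref$freq_hz
      t_lo <- edges0[bin_of_spike[locked]]
      base <- (theta - gref$phase0) / (2 * pi * f)
      k_lo <- ceiling((t_lo - base) * f)
      n_cyc <- pmax(1, floor((t_lo + bin_s - base) * f) - k_lo + 1)
      k <- k_lo + floor(runif(nlk) * n_cyc)
      times[locked] <- base + k / f
      # numerical safety: clamp into the bin
      times[locked] <- pmin(pmax(times[locked], t_lo),
                            t_lo + bin_s - 1e-6)
    }
    times <- sort(times)
    if (length(times) > 1) {
      drop <- c(diff(times) < 0.001, FALSE)  # collision: later spike wins
      times <- times[!drop]
    }
    all_spikes[[i]] <- tibble(unit_id = u$unit_id, time_s = times)
  }
  spikes <- dplyr::bind_rows(all_spikes)
  dur <- max(session$tracking$frame_time_s)
  units <- truth |>
    dplyr::mutate(mean_rate_hz = vapply(truth$unit_id, function(uid)
      sum(spikes$unit_id == uid) / dur, numeric(1))) |>
    dplyr::select("unit_id", "spike_width_us", "peak_to_valley_ratio",
                  "mean_rate_hz")
  units$mean_waveform <- purrr::map2(truth$spike_width_us,
                                     truth$peak_to_valley_ratio,
                                     waveform_template)
  session$spikes <- spikes
  session$units <- units
  session$truth$units <- truth
  session
}
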