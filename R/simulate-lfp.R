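# LFP simulator: power-law background, a continuous gamma reference
# oscillation (the phase-locking target), and transient gamma bursts whose
# rate depends on the traversal direction.

# 1/f^alpha Gaussian noise, unit variance. Generated at a highly
# composite FFT length and truncated.
colored_noise <- function(n, fs, alpha) {
  n0 <- n
  n <- stats::nextn(n, c(2, 3, 5))
  nf <- floor(n / 2)
  f <- seq_len(nf) * fs / n
  amp <- f^(-alpha / 2)
  z <- complex(real = rnorm(nf), imaginary = rnorm(nf)) * amp
  spec <- complex(real = numeric(n))
  spec[2:(nf + 1)] <- z
  if (n %% 2 == 0) spec[nf + 1] <- complex(real = rnorm(1) * amp[nf])
  spec[n:(n - nf + 2)] <- Conj(spec[2:(nf)])
  x <- (Re(fft(spec, inverse = TRUE)) / n)[seq_len(n0)]
  x / sd(x)
}

#' Simulate the LFP trace
#'
#' The trace is the sum of 1/f^alpha background noise, a weak continuous
#' narrow-band gamma oscillation serving as the spike phase-locking target,
#' and Gaussian-enveloped oscillatory bursts (center frequency inside the
#' gamma band, duration 75-150 ms) injected as a Poisson process whose rate
#' is `burst_rate_to_reward` during to-reward traversals and
#' `burst_rate_to_trigger` during to-trigger traversals. Ground-truth burst
#' times are recorded in `truth$bursts` for detector validation.
#'
#' @param session session from [simulate_behavior()].
#' @param cfg the [sim_config()].
#' @return the session with `lfp` and `truth$bursts`/`truth$gamma_ref`.
#' @export
simulate_lfp <- function(session, cfg) {
  validate_sim_config(cfg)
  with_seed(child_seed(cfg$seed, "lfp"), simulate_lfp_impl(session, cfg))
}

simulate_lfp_impl <- function(session, cfg) {
  fs <- cfg$lfp_rate
  dur <- max(session$tracking$frame_time_s) + 1 / cfg$frame_rate
  n <- ceiling(dur * fs)
  x <- cfg$noise_amplitude * colored_noise(n, fs, cfg$noise_spectrum_exponent)
  tvec <- (seq_len(n) - 1) / fs

  phase0 <- runif(1, -pi, pi)
  x <- x + cfg$gamma_ref_amplitude *
    cos(2 * pi * cfg$gamma_ref_freq * tvec + phase0)

  trav <- session$truth$traversals
  bursts <- list()
  for (i in seq_len(nrow(trav))) {
    rate <- if (trav$direction[i] == "to_reward")
      cfg$burst_rate_to_reward else cfg$burst_rate_to_trigger
    seg_dur <- trav$end_s[i] - trav$start_s[i]
    k <- rpois(1, rate * seg_dur)
    if (k == 0) next
    centers <- sort(runif(k, trav$start_s[i], trav$end_s[i]))
    if (cfg$burst_min_separation_s > 0 && length(centers) > 1) {
      keep <- c(TRUE, diff(centers) >= cfg$burst_min_separation_s)
      # greedy thinning: re-check separations after each removal
      while (!all(keep)) {
        centers <- centers[keep]
        keep <- c(TRUE, diff(centers) >= cfg$burst_min_separation_s)
      }
      k <- length(centers)
    }
    freqs <- runif(k, cfg$burst_band[1], cfg$burst_band[2])
    durs <- runif(k, cfg$burst_duration_range_s[1],
                  cfg$burst_duration_range_s[2])
    phases <- runif(k, -pi, pi)
    for (j in seq_len(k)) {
      sigma <- durs[j] / 4
      lo <- max(1, floor((centers[j] - 2 * sigma) * fs))
      hi <- min(n, ceiling((centers[j] + 2 * sigma) * fs))
      tt <- tvec[lo:hi]
      x[lo:hi] <- x[lo:hi] + cfg$burst_amplitude * cfg$noise_amplitude *
        exp(-0.5 * ((tt - centers[j]) / sigma)^2) *
        cos(2 * pi * freqs[j] * (tt - centers[j]) + phases[j])
    }
    bursts[[length(bursts) + 1]] <- tibble(
      time_s = centers, freq_hz = freqs, duration_s = durs,
      trial = trav$trial[i], direction = trav$direction[i])
  }
  session$lfp <- list(samples = x, rate_hz = fs, site_id = "site1")
  session$truth$bursts <- if (length(bursts)) dplyr::bind_rows(bursts) else
    tibble(time_s = numeric(), freq_hz = numeric(), duration_s = numeric(),
           trial = integer(), direction = character())
  session$truth$gamma_ref <- list(freq_hz = cfg$gamma_ref_freq,
                                  phase0 = phase0,
                                  amplitude = cfg$gamma_ref_amplitude)
  session
}
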