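# Spike-gamma phase coupling: instantaneous phase, pairwise phase
# consistency, mean resultant length, Rayleigh significance, coupling
# groups, and the coupling-vs-spatial-information relation.

#' Instantaneous phase of a band-limited oscillation
#'
#' Zero-phase (forward-backward) Butterworth band-pass followed by the
#' analytic-signal angle. Cosine convention: phase 0 at the oscillation
#' peak; the phase of a pure sinusoid advances linearly at its frequency.
#'
#' @param x LFP samples.
#' @param fs sampling rate, Hz.
#' @param band pass band, Hz (default 30-50).
#' @param order Butterworth order (default 4).
#' @return phase series in (-pi, pi], same length as `x`.
#' @export
instantaneous_phase <- function(x, fs, band = c(30, 50), order = 4) {
  filtered <- bandpass(x, fs, band[1], band[2], order)
  Arg(analytic_signal(filtered))
}

#' Pairwise phase consistency
#'
#' The mean over all unordered spike pairs of cos(theta_i - theta_j),
#' computed through the algebraic identity
#' (|sum e^(i theta)|^2 - n) / (n (n - 1)). Unlike the resultant length it
#' is unbiased with respect to the spike count (expectation 0 under
#' uniformity for any n), at the price of occasionally small negative
#' values.
#'
#' @param phases spike phases, radians.
#' @return PPC value, or `NA` for fewer than 2 spikes.
#' @export
ppc <- function(phases) {
  n <- length(phases)
  if (n < 2) return(NA_real_)
  s <- sum(exp(1i * phases))
  (Mod(s)^2 - n) / (n * (n - 1))
}

#' Mean resultant length
#'
#' @param phases spike phases, radians.
#' @return MRL in `[0, 1]`, or `NA` for empty input.
#' @export
mrl <- function(phases) {
  n <- length(phases)
  if (n < 1) return(NA_real_)
  Mod(sum(exp(1i * phases))) / n
}

#' Rayleigh test of circular uniformity
#'
#' Z = n * MRL^2 with the standard finite-sample correction for the
#' p-value.
#'
#' @param phases spike phases, radians.
#' @return tibble with `z`, `p`, `n`.
#' @export
rayleigh_test <- function(phases) {
  n <- length(phases)
  if (n < 1) return(tibble(z = NA_real_, p = NA_real_, n = n))
  R <- mrl(phases)
  Z <- n * R^2
  p <- exp(-Z) * (1 + (2 * Z - Z^2) / (4 * n) -
                    (24 * Z - 132 * Z^2 + 76 * Z^3 - 9 * Z^4) / (288 * n^2))
  tibble(z = Z, p = min(max(p, 0), 1), n = n)
}

#' Spike phases within traversals of one direction
#'
#' @param spike_times spike times of the unit, s.
#' @param phase_series instantaneous phase at the LFP rate.
#' @param fs LFP sampling rate, Hz.
#' @param traversals traversal tibble.
#' @param direction `"to_reward"` or `"to_trigger"`.
#' @return numeric vector of phases of the spikes falling inside the
#'   direction's traversal epochs.
#' @export
spike_phases <- function(spike_times, phase_series, fs, traversals,
                         direction) {
  tv <- traversals[traversals$direction == direction, ]
  keep <- rep(FALSE, length(spike_times))
  for (i in seq_len(nrow(tv)))
    keep <- keep | (spike_times >= tv$start_s[i] &
                      spike_times <= tv$end_s[i])
  idx <- pmin(pmax(round(spike_times[keep] * fs) + 1, 1),
              length(phase_series))
  phase_series[idx]
}

#' Assign a phase-coupling group
#'
#' Groups are defined purely by the per-direction Rayleigh flags
#' (p < alpha): coupled in both directions, only to reward, only to
#' trigger, or not coupled.
#'
#' @param p_reward,p_trigger Rayleigh p-values per direction.
#' @param alpha significance level (default 0.05).
#' @return one of `"coupled_both"`, `"coupled_to_reward"`,
#'   `"coupled_to_trigger"`, `"not_coupled"`.
#' @export
assign_coupling_group <- function(p_reward, p_trigger, alpha = 0.05) {
  sr <- is.finite(p_reward) && p_reward < alpha
  st <- is.finite(p_trigger) && p_trigger < alpha
  if (sr && st) "coupled_both"
  else if (sr) "coupled_to_reward"
  else if (st) "coupled_to_trigger"
  else "not_coupled"
}

#' Phase-coupling table for a population
#'
#' For every unit and direction: spike count within traversal epochs, PPC,
#' MRL, and the Rayleigh p; units with fewer than `min_spikes` spikes in
#' either direction are excluded from grouping.
#'
#' @param session an `ephys_session` with LFP.
#' @param traversals traversal tibble.
#' @param band gamma band, Hz.
#' @param min_spikes inclusion threshold per direction (default 50).
#' @param alpha Rayleigh significance level (default 0.05).
#' @return tibble with `unit_id`, `direction`, `n_spikes`, `ppc`, `mrl`,
#'   `rayleigh_p`, `group` (NA when excluded).
#' @export
phase_coupling_table <- function(session, traversals, band = c(30, 50),
                                 min_spikes = 50, alpha = 0.05) {
  fs <- session$lfp$rate_hz
  ph <- instantaneous_phase(session$lfp$samples, fs, band)
  units <- unique(session$spikes$unit_id)
  rows <- purrr::map_dfr(units, function(u) {
    st <- session$spikes$time_s[session$spikes$unit_id == u]
    purrr::map_dfr(c("to_reward", "to_trigger"), function(d) {
      phs <- spike_phases(st, ph, fs, traversals, d)
      ray <- rayleigh_test(phs)
      tibble(unit_id = u, direction = d, n_spikes = length(phs),
             ppc = ppc(phs), mrl = mrl(phs), rayleigh_p = ray$p)
    })
  })
  rows |>
    dplyr::group_by(.data$unit_id) |>
    dplyr::mutate(group = {
      if (any(.data$n_spikes < min_spikes)) NA_character_
      else assign_coupling_group(
        .data$rayleigh_p[.data$direction == "to_reward"],
        .data$rayleigh_p[.data$direction == "to_trigger"], alpha)
    }) |>
    dplyr::ungroup()
}

#' Phase coupling vs spatial information
#'
#' Pearson correlation between PPC and SI per coupling group and
#' direction, with significance from shuffling the SI values across units
#' within the group.
#'
#' @param coupling tibble from [phase_coupling_table()].
#' @param si tibble from [unit_spatial_information()] (per unit and
#'   direction).
#' @param n_shuffle shuffle repetitions (default 1000).
#' @param min_group group sizes below this get a low-n flag (default 5).
#' @param seed RNG seed.
#' @return tibble with `group`, `direction`, `n`, `r`, `p`, `low_n`.
#' @export
coupling_vs_si <- function(coupling, si, n_shuffle = 1000, min_group = 5,
                           seed = 1L) {
  joined <- dplyr::inner_join(coupling, si, by = c("unit_id", "direction"))
  joined <- joined[!is.na(joined$group), ]
  combos <- dplyr::distinct(joined, .data$group, .data$direction)
  with_seed(seed, {
    purrr::map_dfr(seq_len(nrow(combos)), function(k) {
      sub <- joined[joined$group == combos$group[k] &
                      joined$direction == combos$direction[k], ]
      n <- nrow(sub)
      if (n < 3 || sd(sub$ppc) == 0 || sd(sub$si_bits) == 0)
        return(tibble(group = combos$group[k],
                      direction = combos$direction[k], n = n,
                      r = NA_real_, p = NA_real_, low_n = n < min_group))
      r <- cor(sub$ppc, sub$si_bits)
      null <- replicate(n_shuffle, cor(sub$ppc, sample(sub$si_bits)))
      tibble(group = combos$group[k], direction = combos$direction[k],
             n = n, r = r, p = mean(abs(null) >= abs(r)),
             low_n = n < min_group)
    })
  })
}
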