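# LFP spectral statistics: optogenetic resonance, traversal relative power,
# gamma-burst detection, and speed-resolved power.

band_mask <- function(freq, band) freq >= band[1] & freq <= band[2]

rel_power <- function(psd, band, total_band) {
  sum(psd$power[band_mask(psd$freq_hz, band)]) /
    sum(psd$power[band_mask(psd$freq_hz, total_band)])
}

# group light pulses into trains per stimulation frequency
pulse_trains <- function(events, gap_s = 0.5) {
  p <- events[events$event_type == "light_pulse_on", ]
  if (!nrow(p)) return(tibble(freq_hz = numeric(), onset_s = numeric()))
  p <- dplyr::arrange(p, .data$time_s)
  new_train <- c(TRUE, diff(p$time_s) > gap_s)
  tibble(freq_hz = p$payload[new_train], onset_s = p$time_s[new_train])
}

#' LFP resonance under rhythmic optogenetic drive
#'
#' For each stimulation frequency, epoch spectra (2-100 Hz) are estimated
#' during 1 s light trains and the 1 s baselines preceding them. Relative
#' power (band power / total 2-100 Hz power) is reported for the canonical
#' bands 6-14, 16-24 and 36-44 Hz, and the power ratio P_light/P_baseline
#' is computed in a +/- 4 Hz band around each stimulation frequency.
#' Harmonic peaks at integer multiples of the drive frequency are reported
#' in the returned spectra; cross-band comparisons across different drive
#' frequencies are confounded by those harmonics and are not attempted.
#'
#' @param lfp list with `samples` and `rate_hz`.
#' @param events events tibble containing `light_pulse_on` rows with the
#'   stimulation frequency in `payload`.
#' @param epoch_s epoch length (default 1 s).
#' @param bands list of analysis bands, Hz.
#' @param ratio_halfwidth_hz half-width of the ratio band (default 4).
#' @param min_epochs minimum trains per frequency (default 5).
#' @return list with `band_power` (tibble: stim_freq_hz, band, phase,
#'   rel_power), `ratios` (tibble: stim_freq_hz, ratio), and `spectra`
#'   (mean PSD per stimulation frequency and phase).
#' @export
opto_resonance <- function(lfp, events, epoch_s = 1,
                           bands = list(c(6, 14), c(16, 24), c(36, 44)),
                           ratio_halfwidth_hz = 4, min_epochs = 5) {
  fs <- lfp$rate_hz
  trains <- pulse_trains(events)
  assert_that(nrow(trains) > 0, "no light pulses in events")
  n <- length(lfp$samples)
  total_band <- c(2, 100)
  out_band <- list(); out_ratio <- list(); out_spec <- list()
  for (f in sort(unique(trains$freq_hz))) {
    onsets <- trains$onset_s[trains$freq_hz == f]
    # drop epochs that extend past the recording
    onsets <- onsets[(onsets + epoch_s) * fs <= n & (onsets - epoch_s) > 0]
    assert_that(length(onsets) >= min_epochs,
                sprintf("need >= %d stimulation epochs at %g Hz",
                        min_epochs, f))
    seg <- function(t0) lfp$samples[round(t0 * fs):(round(t0 * fs) +
                                                      epoch_s * fs - 1)]
    psd_l <- lapply(onsets, function(o) welch_psd(seg(o), fs))
    psd_b <- lapply(onsets, function(o) welch_psd(seg(o - epoch_s), fs))
    mean_psd <- function(ps) {
      p <- ps[[1]]
      p$power <- rowMeans(sapply(ps, function(x) x$power))
      p
    }
    ml <- mean_psd(psd_l); mb <- mean_psd(psd_b)
    for (b in bands) {
      lab <- paste0(b[1], "-", b[2])
      out_band[[length(out_band) + 1]] <- tibble(
        stim_freq_hz = f, band = lab,
        phase = c("light", "baseline"),
        rel_power = c(
          mean(vapply(psd_l, rel_power, numeric(1), b, total_band)),
          mean(vapply(psd_b, rel_power, numeric(1), b, total_band))))
    }
    rb <- c(f - ratio_halfwidth_hz, f + ratio_halfwidth_hz)
    rl <- mean(vapply(psd_l, rel_power, numeric(1), rb, total_band))
    rbsl <- mean(vapply(psd_b, rel_power, numeric(1), rb, total_band))
    out_ratio[[length(out_ratio) + 1]] <- tibble(
      stim_freq_hz = f, ratio = rl / rbsl)
    out_spec[[length(out_spec) + 1]] <- dplyr::bind_rows(
      dplyr::mutate(ml, stim_freq_hz = f, phase = "light"),
      dplyr::mutate(mb, stim_freq_hz = f, phase = "baseline"))
  }
  list(band_power = dplyr::bind_rows(out_band),
       ratios = dplyr::bind_rows(out_ratio),
       spectra = dplyr::bind_rows(out_spec))
}

qualifying_traversals <- function(traversals, duration_range) {
  d <- traversals$end_s - traversals$start_s
  traversals[d >= duration_range[1] & d <= duration_range[2], ]
}

#' Relative LFP power during track traversals
#'
#' Restricted to temporally homogeneous traversals (0.5-1.5 s across the
#' track), each traversal's spectrum is normalized by its total 1-100 Hz
#' power and averaged per direction.
#'
#' @param lfp list with `samples` and `rate_hz`.
#' @param traversals traversal tibble.
#' @param duration_range qualifying traversal durations, s.
#' @param min_traversals minimum qualifying traversals per direction.
#' @return tibble with `direction`, `freq_hz`, `rel_power`.
#' @export
traversal_spectrum <- function(lfp, traversals,
                               duration_range = c(0.5, 1.5),
                               min_traversals = 10) {
  fs <- lfp$rate_hz
  tv <- qualifying_traversals(traversals, duration_range)
  nseg <- round(fs / 2)
  out <- list()
  for (d in c("to_reward", "to_trigger")) {
    td <- tv[tv$direction == d, ]
    assert_that(nrow(td) >= min_traversals,
                sprintf("need >= %d qualifying %s traversals",
                        min_traversals, d))
    ps <- lapply(seq_len(nrow(td)), function(i) {
      i0 <- max(1, round(td$start_s[i] * fs))
      i1 <- min(length(lfp$samples), round(td$end_s[i] * fs))
      p <- welch_psd(lfp$samples[i0:i1], fs, nperseg = min(nseg, i1 - i0))
      keep <- band_mask(p$freq_hz, c(1, 100))
      p <- p[keep, ]
      p$power <- p$power / sum(p$power)
      # common frequency grid via interpolation onto 1-100 Hz, 1 Hz steps
      tibble(freq_hz = 1:100,
             rel_power = approx(p$freq_hz, p$power, 1:100, rule = 2)$y)
    })
    avg <- Reduce(`+`, lapply(ps, function(p) p$rel_power)) / length(ps)
    out[[d]] <- tibble(direction = d, freq_hz = 1:100,
                       rel_power = avg / sum(avg))
  }
  dplyr::bind_rows(out)
}

#' Detect gamma bursts during traversals
#'
#' The LFP power is averaged across the gamma band (Morlet spectrogram,
#' 30-50 Hz) and bursts are detected as local power peaks above the 75th
#' percentile of the power over all qualifying traversal epochs of the
#' session (per site), separated by at least one gamma cycle. The burst
#' rate is peaks per second of traversal, averaged per direction.
#'
#' @param lfp list with `samples` and `rate_hz`.
#' @param traversals traversal tibble.
#' @param band gamma band, Hz (default 30-50).
#' @param threshold_quantile power threshold quantile (default 0.75).
#' @param min_sep_s minimum inter-peak separation, s (default 0.025, one
#'   40 Hz cycle).
#' @param duration_range qualifying traversal durations, s.
#' @return list with `bursts` (tibble: time_s, power, trial, direction)
#'   and `rates` (tibble per traversal: trial, direction, duration_s,
#'   n_bursts, bursts_per_s).
#' @export
detect_gamma_bursts <- function(lfp, traversals, band = c(30, 50),
                                threshold_quantile = 0.75,
                                min_sep_s = 0.025,
                                duration_range = c(0.5, 1.5)) {
  fs <- lfp$rate_hz
  tv <- qualifying_traversals(traversals, duration_range)
  assert_that(nrow(tv) > 0, "no qualifying traversals")
  freqs <- seq(band[1], band[2], by = 4)
  pw <- rowMeans(morlet_power(lfp$samples, fs, freqs))
  idx_list <- purrr::map(seq_len(nrow(tv)), function(i) {
    i0 <- max(1, round(tv$start_s[i] * fs))
    i1 <- min(length(pw), round(tv$end_s[i] * fs))
    if (i1 - i0 < 2 * round(min_sep_s * fs)) return(NULL)  # too short
    i0:i1
  })
  all_idx <- unlist(idx_list)
  thr <- quantile(pw[all_idx], threshold_quantile, names = FALSE)
  min_sep <- max(1, round(min_sep_s * fs))
  bursts <- list(); rates <- list()
  for (i in seq_len(nrow(tv))) {
    ii <- idx_list[[i]]
    if (is.null(ii)) next
    x <- pw[ii]
    pk <- pracma::findpeaks(x, minpeakheight = thr,
                            minpeakdistance = min_sep)
    npk <- if (is.null(pk)) 0L else nrow(pk)
    dur <- (length(ii) - 1) / fs
    if (npk > 0) {
      bursts[[length(bursts) + 1]] <- tibble(
        time_s = (ii[pk[, 2]] - 1) / fs, power = pk[, 1],
        trial = tv$trial[i], direction = tv$direction[i])
    }
    rates[[length(rates) + 1]] <- tibble(
      trial = tv$trial[i], direction = tv$direction[i], duration_s = dur,
      n_bursts = npk, bursts_per_s = npk / dur)
  }
  list(bursts = if (length(bursts)) dplyr::bind_rows(bursts) else
         tibble(time_s = numeric(), power = numeric(), trial = integer(),
                direction = character()),
       rates = dplyr::bind_rows(rates))
}

#' Speed-resolved gamma power
#'
#' Morlet spectrogram power in the requested bands, normalized per
#' traversal by its peak power, averaged within 1 cm/s speed bins per
#' direction. Restricted to the speed range covered by both directions
#' (15-75 cm/s by default).
#'
#' @param lfp list with `samples` and `rate_hz`.
#' @param traversals traversal tibble.
#' @param kinematics kinematics tibble ([compute_kinematics()]).
#' @param bands list of bands, Hz.
#' @param speed_range included speed range, cm/s.
#' @param speed_bin_cms speed bin width (default 1).
#' @param duration_range qualifying traversal durations, s.
#' @return tibble with `direction`, `band`, `speed_cms` (bin center),
#'   `power` (normalized), `n_samples`.
#' @export
speed_resolved_power <- function(lfp, traversals, kinematics,
                                 bands = list(c(30, 50), c(60, 80)),
                                 speed_range = c(15, 75),
                                 speed_bin_cms = 1,
                                 duration_range = c(0.5, 1.5)) {
  fs <- lfp$rate_hz
  tv <- qualifying_traversals(traversals, duration_range)
  assert_that(nrow(tv) > 0, "no qualifying traversals")
  out <- list()
  for (bi in seq_along(bands)) {
    b <- bands[[bi]]
    freqs <- seq(b[1], b[2], by = 4)
    pw <- rowMeans(morlet_power(lfp$samples, fs, freqs))
    acc <- list()
    for (i in seq_len(nrow(tv))) {
      i0 <- max(1, round(tv$start_s[i] * fs))
      i1 <- min(length(pw), round(tv$end_s[i] * fs))
      p <- pw[i0:i1]
      p <- p / max(p)  # per-traversal peak normalization
      tt <- (i0:i1 - 1) / fs
      sp <- approx(kinematics$frame_time_s, kinematics$speed_cms, tt,
                   rule = 2)$y
      keep <- sp >= speed_range[1] & sp <= speed_range[2]
      if (!any(keep)) next
      acc[[length(acc) + 1]] <- tibble(
        direction = tv$direction[i],
        speed_cms = floor(sp[keep] / speed_bin_cms) * speed_bin_cms +
          speed_bin_cms / 2,
        power = p[keep])
    }
    out[[bi]] <- dplyr::bind_rows(acc) |>
      dplyr::group_by(.data$direction, .data$speed_cms) |>
      dplyr::summarise(power = mean(.data$power),
                       n_samples = dplyr::n(), .groups = "drop") |>
      dplyr::mutate(band = paste0(b[1], "-", b[2]))
  }
  dplyr::bind_rows(out)
}
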