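# Waveform-based unit classification (wide- vs narrow-spiking) and
# identification of directly light-activated FS-PV units.

#' @importFrom mclust Mclust mclustBIC
NULL

#' Classify units into wide- and narrow-spiking classes
#'
#' Fits a two-component Gaussian mixture to the standardized
#' (spike width, peak-to-valley ratio) features. The component with the
#' smaller mean spike width is the narrow-spiking (NS) component. Units
#' with posterior NS probability > `ns_cut` are labelled NS, units with NS
#' probability < `ws_cut` are labelled WS, and the remainder stay
#' unclassified.
#'
#' @param units tibble with `unit_id`, `spike_width_us`,
#'   `peak_to_valley_ratio`.
#' @param ns_cut posterior threshold for NS (default 0.95).
#' @param ws_cut posterior threshold for WS (default 0.30).
#' @param min_units refuse below this population size (mixture
#'   unidentifiable; default 20).
#' @return the units tibble with `class` (`"WS"`/`"NS"`/`"unclassified"`)
#'   and `ns_probability` columns.
#' @export
classify_units <- function(units, ns_cut = 0.95, ws_cut = 0.30,
                           min_units = 20) {
  assert_that(nrow(units) >= min_units,
              sprintf("need >= %d units to fit the mixture", min_units))
  feats <- cbind(units$spike_width_us, units$peak_to_valley_ratio)
  assert_that(all(is.finite(feats)), "waveform features must be finite")
  if (any(apply(feats, 2, sd) < 1e-12))
    abort("degenerate waveform features (zero variance): mixture unidentifiable")
  z <- scale(feats)
  fit <- Mclust(z, G = 2, modelNames = "VVV", verbose = FALSE)
  if (is.null(fit))
    abort("Gaussian mixture fit failed (singular covariance after retry)")
  width_means <- tapply(units$spike_width_us, fit$classification, mean)
  ns_comp <- as.integer(names(which.min(width_means)))
  ns_prob <- fit$z[, ns_comp]
  out <- units
  out$ns_probability <- as.numeric(ns_prob)
  out$class <- dplyr::case_when(ns_prob > ns_cut ~ "NS",
                                ns_prob < ws_cut ~ "WS",
                                TRUE ~ "unclassified")
  out
}

# Jensen-Shannon divergence between two probability vectors.
js_divergence <- function(p, q) {
  p <- p / sum(p); q <- q / sum(q)
  m <- (p + q) / 2
  kld <- function(a, b) sum(ifelse(a > 0, a * log2(a / b), 0))
  0.5 * kld(p, m) + 0.5 * kld(q, m)
}

first_spike_latency_hist <- function(spike_times, window_starts, window_ms,
                                     bin_ms) {
  nb <- ceiling(window_ms / bin_ms)
  w_s <- window_ms / 1000
  st <- sort(spike_times)
  # index of the first spike at or after each window start
  pos <- findInterval(window_starts - 1e-12, st) + 1
  lat_ms <- rep(Inf, length(window_starts))
  ok <- pos <= length(st)
  lat_ms[ok] <- (st[pos[ok]] - window_starts[ok]) * 1000
  b <- ifelse(lat_ms < window_ms,
              pmin(nb, floor(lat_ms / bin_ms) + 1), nb + 1)
  tabulate(b, nbins = nb + 1)
}

#' Stimulus-associated spike latency test
#'
#' Detects directly light-activated units by comparing the first-spike
#' latency histogram after light pulses against histograms from equally
#' sized baseline windows preceding each pulse. The observed statistic is
#' the median Jensen-Shannon divergence between the test histogram and the
#' baseline histograms; the null distribution applies the identical
#' statistic to each baseline window in turn (its median divergence to the
#' remaining baselines), so test and null values are exchangeable under no
#' light response. p is the mid-p corrected rank of the observed statistic
#' in the null set, uniform on its grid under the null.
#'
#' @param spike_times spike times of the unit, s.
#' @param pulse_onsets light-pulse onset times, s.
#' @param test_window_ms post-pulse window length (default 10 ms).
#' @param bin_ms latency histogram bin (default 1 ms).
#' @param n_baseline_epochs baseline windows per pulse (default 10).
#' @param min_pulses minimum pulses required (default 50). With fewer than
#'   10 post-pulse spikes, p = 1 is returned with a low-count flag.
#' @return tibble with `salt_p`, `n_test_spikes`, `low_count`.
#' @export
salt_test <- function(spike_times, pulse_onsets, test_window_ms = 10,
                      bin_ms = 1, n_baseline_epochs = 10, min_pulses = 50) {
  assert_that(length(pulse_onsets) >= min_pulses,
              sprintf("need >= %d light pulses", min_pulses))
  w_s <- test_window_ms / 1000
  ipi <- diff(sort(pulse_onsets))
  if (length(ipi) && median(ipi) < n_baseline_epochs * w_s)
    warn(paste("salt_test: inter-pulse intervals are shorter than the",
               "baseline span; baseline windows overlap preceding pulses.",
               "Restrict to low-frequency stimulation pulses."))
  test_hist <- first_spike_latency_hist(spike_times, pulse_onsets,
                                        test_window_ms, bin_ms)
  n_test_spikes <- sum(test_hist[-length(test_hist)])
  if (n_test_spikes < 10)
    return(tibble(salt_p = 1, n_test_spikes = n_test_spikes,
                  low_count = TRUE))
  base_hists <- lapply(seq_len(n_baseline_epochs), function(k) {
    starts <- pulse_onsets - k * w_s
    first_spike_latency_hist(spike_times, starts, test_window_ms, bin_ms)
  })
  # regularize empty histograms
  eps <- 1e-6
  obs <- median(vapply(base_hists, function(h)
    js_divergence(test_hist + eps, h + eps), numeric(1)))
  # same statistic for each baseline window against the other baselines
  d_null <- vapply(seq_len(n_baseline_epochs), function(b)
    median(vapply(setdiff(seq_len(n_baseline_epochs), b), function(k)
      js_divergence(base_hists[[b]] + eps, base_hists[[k]] + eps),
      numeric(1))), numeric(1))
  p <- (sum(d_null >= obs) + 0.5) / (n_baseline_epochs + 1)
  tibble(salt_p = p, n_test_spikes = n_test_spikes, low_count = FALSE)
}

#' Promote a narrow-spiking unit to FS-PV
#'
#' A unit is identified as a directly light-activated FS-PV interneuron
#' when it passes the latency test (SALT p < 0.05) and its mean light-evoked
#' waveform matches the mean spontaneous waveform (Pearson r > 0.95),
#' guarding against sorting artefacts during light application. Only units
#' classified NS before tagging are promoted.
#'
#' @param class pre-tagging class label.
#' @param salt_p SALT p-value.
#' @param evoked_waveform,spontaneous_waveform mean waveforms (same length).
#' @param p_cut,r_cut thresholds (defaults 0.05 and 0.95).
#' @return tibble with `class` (possibly `"FSPV"`), `salt_p`,
#'   `waveform_similarity_r`.
#' @export
tag_fspv <- function(class, salt_p, evoked_waveform, spontaneous_waveform,
                     p_cut = 0.05, r_cut = 0.95) {
  r <- cor(evoked_waveform, spontaneous_waveform)
  promoted <- class == "NS" && is.finite(salt_p) && salt_p < p_cut &&
    is.finite(r) && r > r_cut
  tibble(class = if (promoted) "FSPV" else class, salt_p = salt_p,
         waveform_similarity_r = r)
}
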