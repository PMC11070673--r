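# Direction-resolved spatial firing statistics: activity vectors, per-bin
# shuffle tests, modulation index, spatial consistency, spatial information,
# and direction-correlation profiles.

#' Per-traversal firing-rate vectors
#'
#' For every qualifying traversal (duration <= `max_duration_s`), the mean
#' firing rate of the unit in each of the 10 position bins (smoothed counts
#' divided by occupancy time). Bins the animal did not visit in a traversal
#' are `NA`.
#'
#' @param binned a `binned_session`.
#' @param traversals traversal tibble ([segment_trials()] or generator
#'   truth).
#' @param unit unit id.
#' @param max_duration_s traversals longer than this are excluded
#'   (default 10).
#' @param edge_pad_s symmetric extension of each traversal epoch (s) so
#'   that the reward-zone and trigger-zone bins (1 and 10) are sampled at
#'   both ends of the run regardless of direction (default 0.25).
#' @return tibble with `trial`, `direction`, `bin`, `rate_hz`.
#' @export
traversal_rate_matrix <- function(binned, traversals, unit,
                                  max_duration_s = 10, edge_pad_s = 0.25) {
  y <- resolve_response(binned, unit)
  bins <- binned$bins
  trav <- traversals[traversals$end_s - traversals$start_s <=
                       max_duration_s, ]
  out <- list()
  for (i in seq_len(nrow(trav))) {
    sel <- which(bins$bin_time_s >= trav$start_s[i] - edge_pad_s &
                   bins$bin_time_s <= trav$end_s[i] + edge_pad_s &
                   !is.na(bins$position_bin))
    if (!length(sel)) next
    occ <- tabulate(bins$position_bin[sel], 10) * binned$bin_s
    cnt <- vapply(1:10, function(b)
      sum(y[sel][bins$position_bin[sel] == b]), numeric(1))
    rate <- ifelse(occ > 0, cnt / occ, NA_real_)
    out[[length(out) + 1]] <- tibble(
      trial = trav$trial[i], direction = trav$direction[i],
      bin = 1:10, rate_hz = rate)
  }
  dplyr::bind_rows(out)
}

#' Trial-averaged activity vectors
#'
#' The unit's mean firing rate per position bin, averaged over qualifying
#' traversals, separately for the two directions, with a z-scored copy
#' (normalized per unit over the concatenated 20 bins). Units from sessions
#' with fewer than `min_traversals` qualifying traversals in either
#' direction are excluded (zero-row result, with a message).
#'
#' @inheritParams traversal_rate_matrix
#' @param min_traversals minimum qualifying traversals per direction
#'   (default 10).
#' @return tibble with `unit_id`, `direction`, `bin`, `rate_hz`, `rate_z`,
#'   `n_traversals`.
#' @export
activity_vectors <- function(binned, traversals, unit,
                             min_traversals = 10, max_duration_s = 10) {
  tm <- traversal_rate_matrix(binned, traversals, unit, max_duration_s)
  ntr <- tm |>
    dplyr::distinct(.data$trial, .data$direction) |>
    dplyr::count(.data$direction)
  n_rew <- sum(ntr$n[ntr$direction == "to_reward"])
  n_trg <- sum(ntr$n[ntr$direction == "to_trigger"])
  if (n_rew < min_traversals || n_trg < min_traversals) {
    message(sprintf(
      "activity_vectors: unit %s excluded (%d to-reward, %d to-trigger traversals; need %d each)",
      if (is.character(unit)) unit else "?", n_rew, n_trg, min_traversals))
    return(tibble(unit_id = character(), direction = character(),
                  bin = integer(), rate_hz = numeric(), rate_z = numeric(),
                  n_traversals = integer()))
  }
  av <- tm |>
    dplyr::group_by(.data$direction, .data$bin) |>
    dplyr::summarise(rate_hz = mean(.data$rate_hz, na.rm = TRUE),
                     .groups = "drop")
  mu <- mean(av$rate_hz, na.rm = TRUE)
  sdv <- sd(av$rate_hz, na.rm = TRUE)
  if (!is.finite(sdv) || sdv == 0) sdv <- 1
  av$rate_z <- (av$rate_hz - mu) / sdv
  av$unit_id <- if (is.character(unit)) unit else NA_character_
  av$n_traversals <- ifelse(av$direction == "to_reward", n_rew, n_trg)
  dplyr::select(av, "unit_id", "direction", "bin", "rate_hz", "rate_z",
                "n_traversals")
}

# Align the two directions to a common start -> end frame: the to-trigger
# vector is flipped (bin b -> 11 - b).
align_directions <- function(tm) {
  tm$rel_bin <- ifelse(tm$direction == "to_trigger", 11L - tm$bin, tm$bin)
  tm
}

#' Per-bin direction-difference shuffle test
#'
#' The to-trigger activity vector is flipped so both directions share a
#' start -> end frame; the per-bin activity difference is then compared
#' with a null built by shuffling the traversal direction labels `n_shuffle`
#' times. Bins whose real difference exceeds the 97.5th or falls below the
#' 2.5th percentile of the shuffled differences are flagged significantly
#' more or less active (to reward).
#'
#' @param tm per-traversal rate tibble from [traversal_rate_matrix()].
#' @param n_shuffle label shuffles (default 1000).
#' @param seed RNG seed.
#' @return tibble with `rel_bin`, `diff_hz`, `lo`, `hi`, `flag`
#'   (`"more"`/`"less"`/`"ns"`, to-reward relative).
#' @export
per_bin_shuffle_test <- function(tm, n_shuffle = 1000, seed = 1L) {
  tm <- align_directions(tm)
  wide <- tm |>
    dplyr::select("trial", "direction", "rel_bin", "rate_hz") |>
    tidyr::pivot_wider(names_from = "rel_bin", values_from = "rate_hz",
                       names_sort = TRUE)
  M <- as.matrix(wide[, -(1:2)])
  lab <- wide$direction
  diff_fun <- function(l) {
    colMeans(M[l == "to_reward", , drop = FALSE], na.rm = TRUE) -
      colMeans(M[l == "to_trigger", , drop = FALSE], na.rm = TRUE)
  }
  d_obs <- diff_fun(lab)
  with_seed(seed, {
    null <- replicate(n_shuffle, diff_fun(sample(lab)))
  })
  lo <- apply(null, 1, quantile, 0.025, na.rm = TRUE)
  hi <- apply(null, 1, quantile, 0.975, na.rm = TRUE)
  tibble(rel_bin = as.integer(colnames(M)), diff_hz = d_obs,
         lo = lo, hi = hi,
         flag = dplyr::case_when(d_obs > hi ~ "more",
                                 d_obs < lo ~ "less",
                                 TRUE ~ "ns"))
}

#' Direction modulation index
#'
#' MI = (r_reward - r_trigger) / (r_reward + r_trigger), where the r's are
#' the mean rates of the to-reward and to-trigger activity vectors. Ranges
#' from -1 (firing only toward the trigger) through 0 (no modulation) to 1
#' (firing only toward reward); `NA` when both means are zero.
#'
#' @param rate_reward,rate_trigger per-bin rate vectors (or scalar mean
#'   rates) for the two directions.
#' @return MI in `[-1, 1]`, or `NA`.
#' @export
modulation_index <- function(rate_reward, rate_trigger) {
  r1 <- mean(rate_reward, na.rm = TRUE)
  r2 <- mean(rate_trigger, na.rm = TRUE)
  if (!is.finite(r1) || !is.finite(r2) || (r1 == 0 && r2 == 0))
    return(NA_real_)
  (r1 - r2) / (r1 + r2)
}

#' Modulation index with rank-sum significance
#'
#' @param tm per-traversal rate tibble from [traversal_rate_matrix()].
#' @return tibble with `mi` and `mi_p` (Wilcoxon rank-sum on per-traversal
#'   mean rates).
#' @export
modulation_index_test <- function(tm) {
  per_trav <- tm |>
    dplyr::group_by(.data$trial, .data$direction) |>
    dplyr::summarise(rate = mean(.data$rate_hz, na.rm = TRUE),
                     .groups = "drop")
  r_rew <- per_trav$rate[per_trav$direction == "to_reward"]
  r_trg <- per_trav$rate[per_trav$direction == "to_trigger"]
  mi <- modulation_index(mean(r_rew, na.rm = TRUE),
                         mean(r_trg, na.rm = TRUE))
  p <- if (is.na(mi)) NA_real_ else
    suppressWarnings(wilcox.test(r_rew, r_trg)$p.value)
  tibble(mi = mi, mi_p = p)
}

#' Spatial consistency (odd vs even trials)
#'
#' Pearson correlation between activity vectors computed from odd and even
#' trials. The control distribution is obtained by circularly shifting the
#' unit's binned activity relative to behavior `n_shifts` times; p is the
#' fraction of control correlations >= the observed one.
#'
#' @param binned a `binned_session`.
#' @param traversals traversal tibble.
#' @param unit unit id.
#' @param n_shifts control shifts (default 1000).
#' @param min_lag_bins minimum circular-shift offset.
#' @param max_duration_s traversal-duration cutoff.
#' @param seed RNG seed.
#' @return tibble with `direction` (`to_reward`, `to_trigger`, `pooled`),
#'   `consistency_r`, `p`.
#' @export
spatial_consistency <- function(binned, traversals, unit, n_shifts = 1000,
                                min_lag_bins = 100, max_duration_s = 10,
                                seed = 1L) {
  y <- resolve_response(binned, unit)
  bins <- binned$bins
  trav <- traversals[traversals$end_s - traversals$start_s <=
                       max_duration_s, ]
  # precompute (bin index in session, traversal row, position bin)
  sel_list <- purrr::map(seq_len(nrow(trav)), function(i) {
    sel <- which(bins$bin_time_s >= trav$start_s[i] &
                   bins$bin_time_s <= trav$end_s[i] &
                   !is.na(bins$position_bin))
    if (!length(sel)) return(NULL)
    tibble(idx = sel, trav_row = i, pos = bins$position_bin[sel])
  })
  map_tbl <- dplyr::bind_rows(sel_list)
  if (!nrow(map_tbl)) return(tibble(direction = character(),
                                    consistency_r = numeric(),
                                    p = numeric()))
  map_tbl$direction <- trav$direction[map_tbl$trav_row]
  map_tbl$parity <- ifelse(trav$trial[map_tbl$trav_row] %% 2 == 1,
                           "odd", "even")
  occ <- binned$bin_s  # each bin contributes bin_s seconds
  group <- interaction(map_tbl$direction, map_tbl$parity, map_tbl$pos,
                       drop = FALSE)
  lv <- levels(group)
  parts <- do.call(rbind, strsplit(lv, ".", fixed = TRUE))
  occ_g <- as.numeric(tapply(rep(occ, nrow(map_tbl)), group, sum,
                             default = 0))
  occ_g[is.na(occ_g)] <- 0
  vec_from <- function(yy) {
    cnt <- as.numeric(tapply(yy[map_tbl$idx], group, sum, default = 0))
    cnt[is.na(cnt)] <- 0
    ifelse(occ_g > 0, cnt / occ_g, NA_real_)
  }
  corr_parts <- function(rate) {
    get <- function(d, p) {
      sel <- parts[, 1] == d & parts[, 2] == p
      rate[sel][order(as.integer(parts[sel, 3]))]
    }
    rs <- purrr::map_dbl(c("to_reward", "to_trigger"), function(d) {
      a <- get(d, "odd"); b <- get(d, "even")
      ok <- is.finite(a) & is.finite(b)
      if (sum(ok) < 3 || sd(a[ok]) == 0 || sd(b[ok]) == 0) return(NA_real_)
      cor(a[ok], b[ok])
    })
    a <- c(get("to_reward", "odd"), get("to_trigger", "odd"))
    b <- c(get("to_reward", "even"), get("to_trigger", "even"))
    ok <- is.finite(a) & is.finite(b)
    pooled <- if (sum(ok) < 3 || sd(a[ok]) == 0 || sd(b[ok]) == 0)
      NA_real_ else cor(a[ok], b[ok])
    c(rs, pooled)
  }
  r_obs <- corr_parts(vec_from(y))
  n <- length(y)
  min_lag <- min(min_lag_bins, floor(n / 4))
  with_seed(seed, {
    null <- replicate(n_shifts, {
      off <- sample(seq(min_lag, n - min_lag), 1)
      yy <- c(y[(n - off + 1):n], y[1:(n - off)])
      corr_parts(yy)
    })
  })
  p <- vapply(1:3, function(k) {
    if (!is.finite(r_obs[k])) return(NA_real_)
    mean(null[k, ] >= r_obs[k], na.rm = TRUE)
  }, numeric(1))
  tibble(direction = c("to_reward", "to_trigger", "pooled"),
         consistency_r = r_obs, p = p)
}

#' Spatial information (bits/spike)
#'
#' SI = sum_i p_i (f_i / f) log2(f_i / f), where p_i is the occupancy
#' probability of bin i, f_i the mean rate in bin i, and f = sum_i p_i f_i
#' the overall mean rate. Zero-rate bins contribute 0; a silent unit has
#' SI = 0. SI is invariant to rate rescaling and non-negative.
#'
#' @param rate_hz per-bin mean firing rates (non-negative).
#' @param occupancy_p per-bin occupancy probabilities (sum to 1).
#' @return spatial information, bits/spike.
#' @export
spatial_information <- function(rate_hz, occupancy_p) {
  assert_that(all(rate_hz >= 0, na.rm = TRUE), "rates must be non-negative")
  ok <- is.finite(rate_hz) & is.finite(occupancy_p)
  f_i <- rate_hz[ok]
  p_i <- occupancy_p[ok]
  p_i <- p_i / sum(p_i)
  f <- sum(p_i * f_i)
  if (f <= 0) return(0)
  terms <- ifelse(f_i > 0, p_i * (f_i / f) * log2(f_i / f), 0)
  sum(terms)
}

#' Per-unit spatial information across the track
#'
#' Computes SI over the track bins (2-9 by default), separately per
#' direction, with occupancy taken from the time spent per bin during
#' qualifying traversals of that direction.
#'
#' @inheritParams traversal_rate_matrix
#' @param bins_used track bins entering SI (default 2:9).
#' @return tibble with `unit_id`, `direction`, `si_bits`.
#' @export
unit_spatial_information <- function(binned, traversals, unit,
                                     bins_used = 2:9,
                                     max_duration_s = 10) {
  y <- resolve_response(binned, unit)
  bins <- binned$bins
  trav <- traversals[traversals$end_s - traversals$start_s <=
                       max_duration_s, ]
  purrr::map_dfr(c("to_reward", "to_trigger"), function(d) {
    tv <- trav[trav$direction == d, ]
    inside <- rep(FALSE, nrow(bins))
    for (i in seq_len(nrow(tv)))
      inside <- inside | (bins$bin_time_s >= tv$start_s[i] &
                            bins$bin_time_s <= tv$end_s[i])
    sel <- inside & bins$position_bin %in% bins_used
    occ <- tabulate(bins$position_bin[sel], 10)[bins_used] * binned$bin_s
    cnt <- vapply(bins_used, function(b)
      sum(y[sel][bins$position_bin[sel] == b]), numeric(1))
    rate <- ifelse(occ > 0, cnt / occ, 0)
    p <- if (sum(occ) > 0) occ / sum(occ) else rep(0, length(occ))
    tibble(unit_id = if (is.character(unit)) unit else NA_character_,
           direction = d,
           si_bits = if (sum(occ) > 0) spatial_information(rate, p) else
             NA_real_)
  })
}

#' Direction-profile correlation over track segments
#'
#' Correlates the to-reward activity vector with the (flipped) to-trigger
#' vector over the first half of the run (aligned bins 1-5), the full run,
#' the last half (bins 6-10), and the full run without flipping
#' ("reversed"). A 95% band from direction-label shuffles is attached.
#'
#' @param tm per-traversal rate tibble from [traversal_rate_matrix()].
#' @param n_shuffle label shuffles for the band (default 1000).
#' @param seed RNG seed.
#' @return tibble with `segment`, `r`, `lo`, `hi`, `outside_band`.
#' @export
direction_rate_correlation <- function(tm, n_shuffle = 1000, seed = 1L) {
  tm <- align_directions(tm)
  seg_defs <- list(first_half = 1:5, full = 1:10, last_half = 6:10,
                   full_reversed = 1:10)
  corr_of <- function(data) {
    avg <- data |>
      dplyr::group_by(.data$direction, .data$rel_bin) |>
      dplyr::summarise(rate = mean(.data$rate_hz, na.rm = TRUE),
                       .groups = "drop")
    vapply(names(seg_defs), function(sg) {
      idx <- seg_defs[[sg]]
      a <- avg$rate[avg$direction == "to_reward"][idx]
      if (sg == "full_reversed") {
        bvec <- avg$rate[avg$direction == "to_trigger"]
        b <- rev(bvec)[idx]  # undo the flip
      } else {
        b <- avg$rate[avg$direction == "to_trigger"][idx]
      }
      ok <- is.finite(a) & is.finite(b)
      if (sum(ok) < 3 || sd(a[ok]) == 0 || sd(b[ok]) == 0) return(NA_real_)
      cor(a[ok], b[ok])
    }, numeric(1))
  }
  r_obs <- unname(corr_of(tm))
  keys <- dplyr::distinct(tm, .data$trial, .data$direction)
  with_seed(seed, {
    null <- replicate(n_shuffle, {
      keys$shuffled <- sample(keys$direction)
      tm2 <- dplyr::left_join(tm, keys, by = c("trial", "direction"))
      tm2$direction <- tm2$shuffled
      tm2$rel_bin <- ifelse(tm2$direction == "to_trigger",
                            11L - tm2$bin, tm2$bin)
      corr_of(tm2)
    })
  })
  lo <- apply(null, 1, quantile, 0.025, na.rm = TRUE)
  hi <- apply(null, 1, quantile, 0.975, na.rm = TRUE)
  tibble(segment = names(seg_defs), r = r_obs, lo = unname(lo),
         hi = unname(hi), outside_band = r_obs < lo | r_obs > hi)
}
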