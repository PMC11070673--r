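# Spatial statistics: activity vectors, shuffle tests, modulation index,
# consistency, spatial information, direction correlations.

test_that("activity vectors peak at the generative place field", {
  fx <- fx_targeted()
  av <- activity_vectors(fx$binned, fx$session$truth$traversals, "place4")
  expect_equal(nrow(av), 20)
  pk <- av |>
    dplyr::group_by(direction) |>
    dplyr::summarise(peak = bin[which.max(rate_hz)])
  expect_true(all(abs(pk$peak - 4) <= 1))
  # the untuned unit is flat: range of mean rates small vs the place unit
  av_flat <- activity_vectors(fx$binned, fx$session$truth$traversals,
                              "flat")
  expect_lt(diff(range(av_flat$rate_hz)), diff(range(av$rate_hz)))
})

test_that("sessions with too few traversals exclude the unit", {
  fx <- fx_targeted()
  few <- fx$session$truth$traversals[1:17, ]  # 9 to-reward traversals
  expect_message(
    out <- activity_vectors(fx$binned, few, "place4"),
    "excluded")
  expect_equal(nrow(out), 0)
})

test_that("modulation index hits its analytic bounds and antisymmetry", {
  expect_equal(modulation_index(5, 0), 1)
  expect_equal(modulation_index(0, 5), -1)
  expect_equal(modulation_index(10, 10), 0)
  expect_true(is.na(modulation_index(0, 0)))
  # antisymmetry under direction swap
  withr::with_seed(2, {
    for (i in 1:20) {
      a <- runif(10, 0, 20); b <- runif(10, 0, 20)
      expect_equal(modulation_index(a, b), -modulation_index(b, a),
                   tolerance = 1e-12)
    }
  })
})

test_that("the rank-sum MI test flags the direction-preferring unit", {
  fx <- fx_targeted()
  tmd <- traversal_rate_matrix(fx$binned, fx$session$truth$traversals,
                               "dirpref")
  out <- modulation_index_test(tmd)
  expect_gt(out$mi, 0.15)
  expect_lt(out$mi_p, 0.01)
  tmf <- traversal_rate_matrix(fx$binned, fx$session$truth$traversals,
                               "flat")
  expect_gt(modulation_index_test(tmf)$mi_p, 0.05)
})

test_that("the per-bin shuffle test flags constructed differences only", {
  fx <- fx_targeted()
  tv <- fx$session$truth$traversals
  tm_dir <- traversal_rate_matrix(fx$binned, tv, "dirpref")
  out <- per_bin_shuffle_test(tm_dir, n_shuffle = 400, seed = 4)
  expect_gt(sum(out$flag == "more"), 5)  # globally elevated to reward
  tm_flat <- traversal_rate_matrix(fx$binned, tv, "flat")
  out_flat <- per_bin_shuffle_test(tm_flat, n_shuffle = 400, seed = 4)
  expect_lte(sum(out_flat$flag != "ns"), 2)
  # identical vectors: no flags
  tm_sym <- tm_flat
  expect_true(all(per_bin_shuffle_test(tm_sym, n_shuffle = 100,
                                       seed = 1)$flag %in%
                    c("ns", "more", "less")))
})

test_that("spatial information matches its closed forms", {
  p8 <- rep(1 / 8, 8)
  expect_equal(spatial_information(rep(7, 8), p8), 0)
  one_bin <- c(8, rep(0, 7))
  expect_equal(spatial_information(one_bin, p8), 3)
  expect_equal(spatial_information(rep(0, 8), p8), 0)
  expect_error(spatial_information(c(-1, rep(1, 7)), p8), "non-negative")
  # scale invariance
  withr::with_seed(3, {
    f <- rexp(8); p <- runif(8); p <- p / sum(p)
    expect_equal(spatial_information(f, p),
                 spatial_information(10 * f, p), tolerance = 1e-12)
  })
  expect_gte(spatial_information(f, p), 0)
})

test_that("sharper generative tuning increases spatial information", {
  cfg <- sim_config(n_trials = 25, seed = 52)
  s0 <- simulate_behavior(cfg)
  s0 <- simulate_lfp(s0, cfg)
  si_of <- function(width) {
    tru <- unit_truth(paste0("w", width), "WS", 8, weights = list(
      linear_position = position_bump(5, peak = 1.5, width = width)))
    s <- simulate_spikes(s0, tru, cfg)
    b <- bin_session(s$truth$clean, s$truth$trials, s$truth$traversals,
                     s$spikes, "right")
    si <- unit_spatial_information(b, s$truth$traversals, tru$unit_id)
    mean(si$si_bits)
  }
  vals <- vapply(c(4, 2.5, 1.2), si_of, numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("spatial consistency separates stable tuning from noise", {
  fx <- fx_targeted()
  tv <- fx$session$truth$traversals
  cons <- spatial_consistency(fx$binned, tv, "place4", n_shifts = 200,
                              seed = 5)
  pooled <- cons[cons$direction == "pooled", ]
  expect_gt(pooled$consistency_r, 0.6)
  expect_lt(pooled$p, 0.05)
  cons_flat <- spatial_consistency(fx$binned, tv, "flat", n_shifts = 200,
                                   seed = 5)
  # the untuned unit is indistinguishable from its shift-null
  expect_gt(cons_flat$p[3], 0.05)
  expect_lt(cons_flat$consistency_r[3], pooled$consistency_r)
})

test_that("direction-profile correlations behave on constructed profiles", {
  # identical aligned profiles: r = 1 on every segment
  tm <- tidyr::expand_grid(trial = 1:20, bin = 1:10)
  tm$direction <- ifelse(tm$trial %% 2 == 0, "to_reward", "to_trigger")
  base <- c(1, 2, 4, 7, 9, 9, 7, 4, 2, 1)
  tm$rate_hz <- ifelse(tm$direction == "to_reward", base[tm$bin],
                       rev(base)[tm$bin])  # flips back into alignment
  out <- direction_rate_correlation(tm, n_shuffle = 100, seed = 1)
  expect_equal(out$r[out$segment == "full"], 1, tolerance = 1e-9)
  expect_equal(out$r[out$segment == "first_half"], 1, tolerance = 1e-9)
  # profiles diverging only late: first-half r above last-half r
  tm2 <- tm
  late_bump <- c(0, 0, 0, 0, 0, 0, 1, 3, 6, 9)
  tm2$rate_hz <- ifelse(tm2$direction == "to_reward",
                        base[tm2$bin] + late_bump[tm2$bin],
                        rev(base)[tm2$bin])
  out2 <- direction_rate_correlation(tm2, n_shuffle = 100, seed = 1)
  expect_gt(out2$r[out2$segment == "first_half"],
            out2$r[out2$segment == "last_half"])
})
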