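# Phase coupling: analytic-signal phase, PPC/MRL/Rayleigh, grouping,
# and the coupling-vs-SI relation.

test_that("the phase of a pure sinusoid advances at its frequency", {
  fs <- 1000
  tt <- seq(0, 2, by = 1 / fs)
  x <- cos(2 * pi * 40 * tt)
  ph <- instantaneous_phase(x, fs, c(30, 50))
  mid <- 200:1800
  d <- diff(trackephys:::unwrap_phase(ph[mid]))
  slope <- mean(d) * fs
  expect_equal(slope, 2 * pi * 40, tolerance = 0.001)
  # cosine convention: phase 0 at the peak
  pk <- which.max(x[300:400]) + 299
  expect_lt(abs(ph[pk]), 0.05)
  # band outside Nyquist rejected
  expect_error(instantaneous_phase(x, fs, c(30, 600)), "band")
})

test_that("PPC matches the brute-force pairwise mean exactly", {
  brute <- function(ph) {
    n <- length(ph)
    m <- outer(ph, ph, function(a, b) cos(a - b))
    sum(m[upper.tri(m)]) / (n * (n - 1) / 2)
  }
  withr::with_seed(6, {
    for (i in 1:25) {
      ph <- runif(sample(2:300, 1), -pi, pi)
      expect_equal(ppc(ph), brute(ph), tolerance = 1e-12)
    }
  })
  expect_equal(ppc(c(1, 1, 1)), 1, tolerance = 1e-12)
  expect_equal(ppc(c(0, pi)), -1, tolerance = 1e-12)
  expect_true(is.na(ppc(1)))
})

test_that("MRL hits its analytic cases and Rayleigh calibrates", {
  expect_equal(mrl(rep(0.7, 5)), 1, tolerance = 1e-12)
  expect_equal(mrl(c(0, pi)), 0, tolerance = 1e-12)
  expect_true(is.na(mrl(numeric(0))))
  withr::with_seed(12, {
    rej <- mean(replicate(400, rayleigh_test(runif(100, -pi, pi))$p) <
                  0.05)
  })
  expect_within(rej, 0.02, 0.08)
})

test_that("PPC is n-unbiased under uniformity while MRL is biased up", {
  withr::with_seed(13, {
    ppcs <- replicate(400, ppc(runif(40, -pi, pi)))
    mrls <- replicate(400, mrl(runif(40, -pi, pi)))
  })
  expect_lt(abs(mean(ppcs)), 0.01)
  # MRL bias ~ sqrt(pi / (4 n)) = 0.14 at n = 40
  expect_gt(mean(mrls), 0.1)
})

test_that("PPC and MRL increase monotonically with von Mises kappa", {
  withr::with_seed(14, {
    stats <- sapply(c(0, 0.5, 2), function(k) {
      ph <- trackephys:::rvonmises(2000, 0, k)
      c(ppc(ph), mrl(ph))
    })
  })
  expect_true(all(diff(stats[1, ]) > 0))
  expect_true(all(diff(stats[2, ]) > 0))
})

test_that("coupling groups follow the per-direction Rayleigh flags", {
  expect_equal(assign_coupling_group(0.01, 0.2), "coupled_to_reward")
  expect_equal(assign_coupling_group(0.2, 0.01), "coupled_to_trigger")
  expect_equal(assign_coupling_group(0.01, 0.01), "coupled_both")
  expect_equal(assign_coupling_group(0.3, 0.4), "not_coupled")
})

test_that("the coupling table recovers generative locking and applies the
           spike-count filter", {
  cfg <- sim_config(n_trials = 35, seed = 121, gamma_ref_amplitude = 0.6)
  tru <- dplyr::bind_rows(
    unit_truth("lock_both", "WS", 14, kappa = 1.5, preferred_phase = 0.5),
    unit_truth("lock_rew", "WS", 14, kappa = 1.5,
               lock_to_trigger = FALSE),
    unit_truth("no_lock", "WS", 14, kappa = 0),
    unit_truth("sparse", "WS", 0.2, kappa = 0))
  s <- simulate_behavior(cfg)
  s <- simulate_lfp(s, cfg)
  s <- simulate_spikes(s, tru, cfg)
  pc <- phase_coupling_table(s, s$truth$traversals)
  grp <- function(u) pc$group[pc$unit_id == u][1]
  expect_equal(grp("lock_both"), "coupled_both")
  expect_equal(grp("lock_rew"), "coupled_to_reward")
  expect_equal(grp("no_lock"), "not_coupled")
  expect_true(is.na(grp("sparse")))  # < 50 spikes per direction
  # locked units show higher PPC than the unlocked one
  ppc_of <- function(u, d) pc$ppc[pc$unit_id == u & pc$direction == d]
  expect_gt(ppc_of("lock_both", "to_reward"),
            ppc_of("no_lock", "to_reward") + 0.05)
})

test_that("coupling-SI correlations flag dependence but not independence", {
  mk <- function(r_link, seed) {
    withr::with_seed(seed, {
      n <- 40
      ppc_v <- runif(n, 0, 0.3)
      si <- if (r_link) ppc_v * 2 + rnorm(n, 0, 0.05) else
        runif(n, 0, 0.6)
      list(
        coupling = tibble::tibble(unit_id = sprintf("u%02d", 1:n),
                                  direction = "to_reward", ppc = ppc_v,
                                  group = "coupled_both"),
        si = tibble::tibble(unit_id = sprintf("u%02d", 1:n),
                            direction = "to_reward", si_bits = si))
    })
  }
  dep <- mk(TRUE, 31)
  out_dep <- coupling_vs_si(dep$coupling, dep$si, n_shuffle = 300, seed = 2)
  expect_lt(out_dep$p, 0.05)
  indep <- mk(FALSE, 32)
  out_ind <- coupling_vs_si(indep$coupling, indep$si, n_shuffle = 300,
                            seed = 2)
  expect_gt(out_ind$p, 0.05)
  # constant PPC: r reported as NA
  flat <- dep
  flat$coupling$ppc <- 0.1
  expect_true(is.na(coupling_vs_si(flat$coupling, flat$si,
                                   n_shuffle = 50, seed = 1)$r))
})
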